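#' Read a TPS landmark file
#'
#' Parses the tpsDig dialect of the TPS format: each specimen block starts
#' with `LM=<count>`, followed by that many whitespace-separated x/y
#' coordinate lines, then optional `IMAGE=`, `ID=` and `SCALE=` records.
#' Unknown `KEY=value` records are skipped with a warning (tpsDig files in
#' circulation vary in which keys they carry).
#'
#' Coordinates are returned exactly as stored in the file (image units);
#' the `SCALE=` factor is kept separately on the configuration and is not
#' multiplied in here. Downstream, [centroid_size()] applies it exactly
#' once.
#'
#' @param path path to a TPS file.
#' @param view view label attached to every configuration read.
#' @param fixed optional logical vector recycled to each configuration's
#'   landmark count, marking fixed landmarks vs semilandmarks.
#' @param require_scale if `TRUE`, a missing `SCALE=` record is an error
#'   (physical units were requested); otherwise scale defaults to 1.
#' @return list of [landmark_config] objects, in file order.
#' @seealso [write_tps()]
#' @export
read_tps <- function(path, view = "ventral", fixed = NULL,
                     require_scale = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("TPS file '", path, "' is empty")
    return(list())
  }
  configs <- list()
  i <- 1L
  n_seen <- 0L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("expected 'LM=' record at line ", i, " of '", path,
           "', found: ", ln)
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("malformed LM count at line ", i, " of '", path, "'")
    if (i + k > length(lines))
      stop("LM=", k, " declared but file ends after ",
           length(lines) - i, " coordinate lines")
    coord_lines <- lines[(i + 1L):(i + k)]
    coords <- t(vapply(coord_lines, function(s) {
      v <- suppressWarnings(as.numeric(strsplit(s, "\\s+")[[1]]))
      if (length(v) != 2L || anyNA(v))
        stop("non-numeric or malformed coordinate line: '", s, "'")
      v
    }, numeric(2), USE.NAMES = FALSE))
    i <- i + k + 1L
    id <- NULL; scale <- NA_real_
    while (i <= length(lines) &&
           !grepl("^LM\\s*=", lines[[i]], ignore.case = TRUE)) {
      rec <- lines[[i]]
      if (grepl("^ID\\s*=", rec, ignore.case = TRUE)) {
        id <- trimws(sub("^ID\\s*=", "", rec, ignore.case = TRUE))
      } else if (grepl("^SCALE\\s*=", rec, ignore.case = TRUE)) {
        scale <- suppressWarnings(
          as.numeric(sub("^SCALE\\s*=", "", rec, ignore.case = TRUE)))
        if (is.na(scale) || scale <= 0)
          stop("malformed SCALE record: '", rec, "'")
      } else if (grepl("^IMAGE\\s*=", rec, ignore.case = TRUE)) {
        # image filename: metadata only, ignored
      } else if (grepl("^[A-Za-z]+\\s*=", rec)) {
        warning("ignoring unknown TPS record: '", rec, "'")
      } else {
        stop("unexpected line in TPS file (stray coordinates beyond LM count?): '",
             rec, "'")
      }
      i <- i + 1L
    }
    n_seen <- n_seen + 1L
    if (is.null(id)) id <- sprintf("specimen_%d", n_seen)
    if (is.na(scale)) {
      if (require_scale)
        stop("specimen '", id, "' has no SCALE= record but physical units ",
             "were required")
      scale <- 1
    }
    fx <- if (is.null(fixed)) NULL else rep_len(fixed, nrow(coords))
    configs[[length(configs) + 1L]] <-
      landmark_config(coords, id, view = view, scale = scale, fixed = fx)
  }
  counts <- vapply(configs, function(c) nrow(c$coords), integer(1))
  if (length(unique(counts)) > 1L)
    warning("landmark count varies across specimens in '", path,
            "' (", paste(unique(counts), collapse = ", "), ")")
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Emits `LM=`, coordinate lines, `ID=` and `SCALE=` records in the tpsDig
#' dialect accepted by [read_tps()]. Coordinates are written with 15
#' significant digits, so a write/read round trip reproduces the stored
#' values to double precision.
#'
#' @param configs list of [landmark_config] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    writeLines(sprintf("LM=%d", nrow(cf$coords)), con)
    writeLines(sprintf("%.15g %.15g", cf$coords[, 1], cf$coords[, 2]), con)
    writeLines(sprintf("ID=%s", cf$specimen_id), con)
    writeLines(sprintf("SCALE=%.15g", cf$scale), con)
  }
  invisible(path)
}
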