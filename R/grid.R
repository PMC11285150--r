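#' Gridded covariate field
#'
#' A minimal regular-grid raster container for climate and land-cover
#' covariates: a value matrix plus the grid geometry. Cells follow the
#' half-open convention `[x0 + (j-1) * dx, x0 + j * dx)` in each axis, so a
#' point lying exactly on an interior cell boundary is deterministically
#' assigned to the higher-index cell.
#'
#' @param values numeric or integer matrix, `nrow` = number of rows
#'   (latitude bands, first row = southernmost), `ncol` = number of columns
#'   (longitude bands, first column = westernmost).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize positive scalar cell edge, degrees.
#' @param nodata sentinel for missing cells (default `NA`).
#' @return object of class `"covariate_grid"`.
#' @export
covariate_grid <- function(values, xll, yll, cellsize, nodata = NA) {
  values <- as.matrix(values)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("'cellsize' must be a positive scalar")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata,
                 nrow = nrow(values), ncol = ncol(values)),
            class = "covariate_grid")
}

#' @export
print.covariate_grid <- function(x, ...) {
  cat("Covariate grid: ", x$nrow, " x ", x$ncol, " cells of ",
      x$cellsize, " deg, origin (", x$xll, ", ", x$yll, ")\n", sep = "")
  invisible(x)
}

#' Read / write an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' of values from north to south.
#'
#' @param path file path.
#' @return [covariate_grid] (for the reader); `path` invisibly (writer).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[[i]])) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in '", path, "'")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid '", path, "' has ", length(vals),
         " values, expected ", hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(hdr$nrows)), , drop = FALSE]  # store south-up
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA
  if (!is.na(nodata)) m[m == nodata] <- NA
  covariate_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                 nodata = nodata)
}

#' @rdname read_ascii_grid
#' @param grid a [covariate_grid].
#' @export
write_ascii_grid <- function(grid, path) {
  nodata <- if (is.na(grid$nodata)) -9999 else grid$nodata
  m <- grid$values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncol),
               sprintf("nrows %d", grid$nrow),
               sprintf("xllcorner %.10g", grid$xll),
               sprintf("yllcorner %.10g", grid$yll),
               sprintf("cellsize %.10g", grid$cellsize),
               sprintf("NODATA_value %.10g", nodata)), con)
  for (r in rev(seq_len(grid$nrow)))
    writeLines(paste(format(m[r, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}

# half-open cell index for one axis; NA when outside [lo, lo + n * dx)
cell_index <- function(p, lo, dx, n) {
  idx <- floor((p - lo) / dx) + 1
  idx[idx < 1 | idx > n] <- NA_integer_
  as.integer(idx)
}

#' Extract covariate values at point localities
#'
#' Nearest-cell (containing-cell) extraction under the half-open cell
#' convention of [covariate_grid]. Points outside the grid, or falling on
#' no-data cells, raise an error naming the offending locality.
#'
#' @param grid a [covariate_grid].
#' @param lon,lat numeric vectors of point coordinates.
#' @param ids optional labels used in error messages.
#' @return numeric vector of cell values, one per point.
#' @export
extract_covariates <- function(grid, lon, lat, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(lon)
  jx <- cell_index(lon, grid$xll, grid$cellsize, grid$ncol)
  jy <- cell_index(lat, grid$yll, grid$cellsize, grid$nrow)
  out <- which(is.na(jx) | is.na(jy))
  if (length(out))
    stop("locality outside grid bounds: ",
         paste(ids[out], collapse = ", "))
  vals <- grid$values[cbind(jy, jx)]
  nod <- which(is.na(vals))
  if (length(nod))
    stop("no-data cell at locality: ", paste(ids[nod], collapse = ", "))
  vals
}

#' Land-cover class collapse
#'
#' Maps fine source land-cover codes onto the 4 broad classes used in the
#' size models: `forest`, `mixed_forest_grassland`, `grassland`,
#' `bare_ground`. The default mapping table shipped with the package
#' (`landcover_collapse_synthetic.csv`) is a synthetic 28-class legend; any
#' user table with columns `code` and `collapsed` can replace it.
#'
#' @param table optional data.frame with columns `code`, `collapsed`;
#'   defaults to the shipped table.
#' @return for `landcover_collapse_table()`: the mapping data.frame. For
#'   `collapse_landcover()`: a factor over the 4 broad classes (reference
#'   level `forest`).
#' @export
landcover_collapse_table <- function(table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "landcover_collapse_synthetic.csv",
                        package = "hyenamorph", mustWork = TRUE)
    table <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  }
  if (!all(c("code", "collapsed") %in% names(table)))
    stop("collapse table must have columns 'code' and 'collapsed'")
  lev <- c("forest", "mixed_forest_grassland", "grassland", "bare_ground")
  bad <- setdiff(unique(table$collapsed), lev)
  if (length(bad))
    stop("collapse table maps to unknown class(es): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(table$code))
    stop("duplicate source code(s) in collapse table")
  table
}

#' @rdname landcover_collapse_table
#' @param code integer vector of source land-cover codes.
#' @export
collapse_landcover <- function(code, table = NULL) {
  table <- landcover_collapse_table(table)
  idx <- match(code, table$code)
  if (anyNA(idx))
    stop("unmapped land-cover code(s): ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  factor(table$collapsed[idx],
         levels = c("forest", "mixed_forest_grassland", "grassland",
                    "bare_ground"))
}
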