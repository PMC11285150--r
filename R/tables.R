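#' Read a population-density table
#'
#' Reads a delimited transcription of a census-density compilation: one row
#' per study with locality, country, density (animals per square km), study
#' years, method and a reference field. Studies marked with a trailing `*`
#' in the reference field (long-term studies and studies in which
#' individuals were identified) get `robust = TRUE`; they form the control
#' subset used to check that less robust census methods do not distort the
#' interpolated density surface.
#'
#' The transcription shipped with the package
#' (`system.file("extdata", "density_studies.tsv", package = "hyenamorph")`)
#' carries 32 spotted-hyena density estimates spanning 0.005 to 1.65
#' hyenas/km2. Its `lon`/`lat` columns are approximate gazetteer
#' coordinates for the named protected areas (the compilation itself prints
#' none) and are labelled synthetic in the file header.
#'
#' @param path path to a tab- or comma-separated file with columns
#'   `locality`, `country`, `density`, `years`, `method`, `reference`, and
#'   optionally `lon`, `lat`.
#' @param sep field separator, default tab.
#' @return data.frame of class `"density_table"` with columns `locality`,
#'   `country`, `density`, `years`, `method`, `reference`, `robust`
#'   (logical) and, when present in the file, `lon`, `lat`.
#' @export
read_density_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           quote = "\"", comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("locality", "country", "density", "years", "method", "reference")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("density table is missing column(s): ", paste(miss, collapse = ", "))
  dens <- suppressWarnings(as.numeric(tab$density))
  bad <- which(is.na(dens) | dens <= 0)
  if (length(bad))
    stop("non-positive or non-numeric density in row(s) ",
         paste(bad, collapse = ", "), " (",
         paste(tab$locality[bad], collapse = "; "), ")")
  key <- paste(tab$locality, tab$years, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (locality, years) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  out <- data.frame(locality = tab$locality, country = tab$country,
                    density = dens, years = tab$years, method = tab$method,
                    reference = tab$reference,
                    robust = grepl("\\*\\s*$", tab$reference),
                    stringsAsFactors = FALSE)
  for (col in c("lon", "lat"))
    if (col %in% names(tab)) out[[col]] <- as.numeric(tab[[col]])
  class(out) <- c("density_table", "data.frame")
  out
}

#' Read a specimen metadata table
#'
#' One row per museum specimen: id, sex, collection year, country and
#' geographic coordinates in decimal degrees. The sex column is restricted
#' to `female`, `male`, `unknown`; empty or `NA` entries are mapped to
#' `unknown` with a warning, any other token is an error. Coordinates are
#' validated against the geographic range of latitude/longitude.
#'
#' @param path delimited text file with columns `specimen_id`, `sex`,
#'   `year`, `country`, `lon`, `lat` (extra columns are carried through).
#' @param sep field separator, default comma.
#' @return data.frame of class `"specimen_table"`.
#' @export
read_specimen_table <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("specimen_id", "sex", "year", "country", "lon", "lat")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("specimen table is missing column(s): ", paste(miss, collapse = ", "))
  tab$specimen_id <- as.character(tab$specimen_id)
  sex <- tolower(trimws(as.character(tab$sex)))
  blank <- is.na(sex) | sex == "" | sex == "na"
  if (any(blank)) {
    warning(sum(blank), " specimen(s) with empty sex mapped to 'unknown'")
    sex[blank] <- "unknown"
  }
  bad <- setdiff(unique(sex), c("female", "male", "unknown"))
  if (length(bad))
    stop("unknown sex token(s): ", paste(bad, collapse = ", "))
  tab$sex <- factor(sex, levels = c("female", "male", "unknown"))
  tab$lon <- as.numeric(tab$lon); tab$lat <- as.numeric(tab$lat)
  if (any(!is.finite(tab$lon)) || any(!is.finite(tab$lat)))
    stop("non-numeric coordinate in specimen table")
  if (any(tab$lat < -90 | tab$lat > 90))
    stop("latitude out of range [-90, 90] for specimen(s) ",
         paste(tab$specimen_id[tab$lat < -90 | tab$lat > 90], collapse = ", "))
  if (any(tab$lon < -180 | tab$lon > 180))
    stop("longitude out of range [-180, 180] for specimen(s) ",
         paste(tab$specimen_id[tab$lon < -180 | tab$lon > 180],
               collapse = ", "))
  class(tab) <- c("specimen_table", "data.frame")
  tab
}

#' Read a slider-definition table
#'
#' @param path delimited text file with columns `before`, `slider`, `after`
#'   (1-based landmark indices).
#' @param sep field separator, default comma.
#' @return a [slider_table].
#' @export
read_slider_table <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("before", "slider", "after")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("slider table is missing column(s): ", paste(miss, collapse = ", "))
  slider_table(tab$before, tab$slider, tab$after)
}

#' Count specimens by sex
#'
#' @param specimens a specimen table ([read_specimen_table()] output or any
#'   data.frame with a `sex` factor).
#' @return named integer vector with elements `female`, `male`, `unknown`
#'   and attribute `total`.
#' @export
sex_counts <- function(specimens) {
  sx <- factor(specimens$sex, levels = c("female", "male", "unknown"))
  out <- table(sx)
  res <- stats::setNames(as.integer(out), names(out))
  attr(res, "total") <- sum(res)
  res
}
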