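#' Landmark configuration for one specimen view
#'
#' Container for the 2D landmark/semilandmark coordinates digitized on a
#' single photograph of a specimen. Coordinates are kept in image units;
#' the scale factor (physical units per image unit, taken from the 10-mm
#' scale bar in the photograph) is stored separately and applied exactly
#' once, when centroid size is computed. This avoids silent double-scaling
#' when files are round-tripped.
#'
#' @param coords numeric matrix with one row per landmark and two columns
#'   (x, y), in image units.
#' @param specimen_id character scalar identifying the specimen.
#' @param view one of `"ventral"`, `"lateral_cranium"`, `"lateral_mandible"`.
#' @param scale positive scalar: physical units per image unit.
#' @param fixed logical vector, one element per landmark: `TRUE` for fixed
#'   anatomical landmarks, `FALSE` for sliding semilandmarks. Defaults to
#'   all fixed.
#' @return An object of class `"landmark_config"`: a list with elements
#'   `specimen_id`, `view`, `coords`, `scale`, `fixed`.
#' @examples
#' sq <- landmark_config(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0)), "sq1")
#' centroid_size(sq)  # sqrt(2)
#' @export
landmark_config <- function(coords, specimen_id, view = "ventral",
                            scale = 1, fixed = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("'coords' must have two columns (x, y)")
  if (nrow(coords) < 1L)
    stop("'coords' must contain at least one landmark")
  if (!all(is.finite(coords)))
    stop("non-finite coordinate in configuration '", specimen_id, "'")
  view <- match.arg(view, c("ventral", "lateral_cranium", "lateral_mandible"))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("'scale' must be a positive finite scalar")
  if (is.null(fixed)) fixed <- rep(TRUE, nrow(coords))
  if (length(fixed) != nrow(coords))
    stop("'fixed' must have one flag per landmark")
  dimnames(coords) <- NULL
  structure(
    list(specimen_id = as.character(specimen_id), view = view,
         coords = coords, scale = as.numeric(scale),
         fixed = as.logical(fixed)),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$specimen_id, "' (", x$view, ")\n",
      sep = "")
  cat("  ", nrow(x$coords), " landmarks (", sum(!x$fixed),
      " semilandmarks), scale = ", format(x$scale), "\n", sep = "")
  invisible(x)
}

#' Centroid size of a landmark configuration
#'
#' Centroid size is the square root of the summed squared distances of each
#' landmark from the centroid of the configuration -- the standard size
#' metric of landmark morphometrics. The stored scale factor converts image
#' units to physical units, so the returned value is in physical units
#' (e.g. mm). The measure is exactly invariant to translation and rotation
#' of the input coordinates.
#'
#' @param config a [landmark_config], or a bare two-column coordinate
#'   matrix (then `scale` is taken as 1).
#' @return positive scalar; `0` (with a warning) for the degenerate case of
#'   all landmarks coincident.
#' @export
centroid_size <- function(config) {
  if (inherits(config, "landmark_config")) {
    coords <- config$coords
    scale <- config$scale
  } else {
    coords <- as.matrix(config)
    scale <- 1
  }
  ctr <- colMeans(coords)
  cs <- scale * sqrt(sum(sweep(coords, 2L, ctr)^2))
  if (cs == 0)
    warning("degenerate configuration: all landmarks coincide (centroid size 0)")
  cs
}

#' Slider-definition table for semilandmarks
#'
#' Each row names one sliding semilandmark by its index together with the
#' indices of the two neighbors that define its local tangent direction
#' (the chord from `before` to `after`). Indices are 1-based positions in
#' the view's landmark list.
#'
#' @param before,slider,after integer vectors of equal length.
#' @return data.frame of class `"slider_table"` with columns
#'   `before`, `slider`, `after`.
#' @export
slider_table <- function(before, slider, after) {
  tab <- data.frame(before = as.integer(before),
                    slider = as.integer(slider),
                    after = as.integer(after))
  if (any(tab$before == tab$slider | tab$after == tab$slider |
          tab$before == tab$after))
    stop("slider triples must name three distinct landmarks")
  if (anyDuplicated(tab$slider))
    stop("each semilandmark may appear in at most one slider triple")
  class(tab) <- c("slider_table", "data.frame")
  tab
}

# validate a slider table against a configuration (range + semilandmark flag)
check_sliders <- function(sliders, config) {
  k <- nrow(config$coords)
  idx <- unlist(sliders[c("before", "slider", "after")], use.names = FALSE)
  if (any(idx < 1L | idx > k))
    stop("slider index out of range (configuration has ", k, " landmarks)")
  bad <- sliders$slider[config$fixed[sliders$slider]]
  if (length(bad))
    stop("landmark(s) ", paste(bad, collapse = ", "),
         " are flagged fixed but appear as sliders")
  invisible(TRUE)
}
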