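#' Candidate trend-surface terms
#'
#' Enumerates the monomials `X^i * Y^j` (X = longitude, Y = latitude) with
#' per-coordinate degrees `0 <= i, j <= max_degree` and `i + j >= 1`. With
#' the default `max_degree = 4` this yields 24 candidate terms (a 5 x 5
#' grid of exponent pairs minus the constant) -- note the set deliberately
#' includes cross terms of total degree above 4, such as `X3Y4`: the
#' per-coordinate reading is what makes those high-order interactions
#' available to the subset search.
#'
#' @param max_degree maximum per-coordinate degree (default 4).
#' @return object of class `"trend_terms"`: data.frame with columns `i`,
#'   `j`, `name` (e.g. `"X2Y3"`).
#' @export
build_trend_terms <- function(max_degree = 4L) {
  if (max_degree < 1L) stop("'max_degree' must be at least 1")
  g <- expand.grid(i = 0:max_degree, j = 0:max_degree)
  g <- g[g$i + g$j >= 1L, , drop = FALSE]
  g <- g[order(g$i + g$j, g$i, g$j), ]
  rownames(g) <- NULL
  g$name <- trend_term_name(g$i, g$j)
  class(g) <- c("trend_terms", "data.frame")
  g
}

trend_term_name <- function(i, j) {
  xi <- ifelse(i == 0L, "", ifelse(i == 1L, "X", paste0("X", i)))
  yj <- ifelse(j == 0L, "", ifelse(j == 1L, "Y", paste0("Y", j)))
  paste0(xi, yj)
}

#' Trend-surface design matrix
#'
#' Evaluates candidate monomials at specimen coordinates. Coordinates are
#' centered (by default at their means) before powering, which tames the
#' conditioning of high-order monomial bases; the centering constants are
#' attached so the basis is reproducible. Coefficients of downstream fits
#' are therefore reported in the centered basis.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param terms a [build_trend_terms()] table (or subset of its rows).
#' @param center length-2 numeric `(lon0, lat0)`; default `c(mean(lon),
#'   mean(lat))`.
#' @return numeric matrix with one named column per term; attribute
#'   `center`.
#' @export
trend_design <- function(lon, lat, terms = build_trend_terms(),
                         center = NULL) {
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  X <- lon - center[1]; Y <- lat - center[2]
  m <- vapply(seq_len(nrow(terms)),
              function(r) X^terms$i[r] * Y^terms$j[r],
              numeric(length(lon)))
  m <- matrix(m, nrow = length(lon))
  colnames(m) <- terms$name
  attr(m, "center") <- center
  m
}
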