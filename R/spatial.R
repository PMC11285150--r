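#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (delegated to
#' \pkg{geosphere}). Used for nearest-neighbor reporting and outlier
#' exclusion; the kriging chain itself works in degree space, where the
#' fitted variogram range is expressed.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorized).
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  ok <- function(lat, lon) all(lat >= -90 & lat <= 90) &&
    all(lon >= -180 & lon <= 180)
  if (!ok(lat1, lon1) || !ok(lat2, lon2))
    stop("coordinates out of geographic range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371)
}

#' Nearest-neighbor distances among localities
#'
#' @param lon,lat coordinates in decimal degrees.
#' @return numeric vector: for each point, the great-circle distance (km)
#'   to its nearest other point.
#' @export
nearest_neighbor_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2L) stop("need at least two points")
  vapply(seq_len(n), function(i) {
    min(great_circle_km(lon[i], lat[i], lon[-i], lat[-i]))
  }, numeric(1))
}

#' Stable semivariogram model
#'
#' The stable family `gamma(h) = nugget + psill * (1 - exp(-(h/range)^s))`
#' for `h > 0`, with `gamma(0) = 0` by convention; `s` in (0, 2] is the
#' shape exponent (s = 1 exponential, s = 2 Gaussian). The default
#' parameters are the ones fitted for the hyena density surface
#' (nugget 0.439, partial sill 0.2855, range 1.928 degrees); the shape
#' exponent is not reported with them and defaults to 1.5.
#'
#' If the printed "sill" of a GIS fit is a *total* sill rather than a
#' partial sill, pass `sill_is_total = TRUE` and the partial sill is
#' derived as `sill - nugget` (must be positive).
#'
#' @param nugget,psill,range model parameters (semivariance units; range in
#'   the distance units the model is used with -- degrees here).
#' @param shape shape exponent in (0, 2].
#' @param sill_is_total interpret `psill` as the total sill.
#' @return object of class `"variogram_model"`.
#' @export
variogram_model <- function(nugget = 0.439, psill = 0.2855, range = 1.928,
                            shape = 1.5, sill_is_total = FALSE) {
  if (sill_is_total) {
    psill <- psill - nugget
    if (psill <= 0)
      stop("total sill must exceed the nugget")
  }
  if (nugget < 0 || psill < 0 || range <= 0 || shape <= 0 || shape > 2)
    stop("invalid variogram parameters (need nugget >= 0, partial sill >= 0, ",
         "range > 0, shape in (0, 2])")
  structure(list(family = "stable", nugget = nugget, psill = psill,
                 range = range, shape = shape),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat("Stable semivariogram: nugget = ", x$nugget, ", partial sill = ",
      x$psill, ", range = ", x$range, ", shape = ", x$shape, "\n", sep = "")
  invisible(x)
}

#' Evaluate a stable semivariogram
#'
#' @param model a [variogram_model].
#' @param h non-negative distance(s), same units as the model range.
#' @return semivariance(s); `0` at `h = 0`, approaching
#'   `nugget + psill` as `h` grows.
#' @export
stable_semivariance <- function(model, h) {
  if (any(h < 0)) stop("distances must be non-negative")
  ifelse(h == 0, 0,
         model$nugget + model$psill * (1 - exp(-(h / model$range)^model$shape)))
}

#' Empirical semivariogram
#'
#' Classical (Matheron) estimator: pairs are binned by separation distance
#' and `gamma_hat(h_k) = sum (z_i - z_j)^2 / (2 N_k)` within each bin.
#' Empty bins are kept in the output with `NA` semivariance and pair count
#' 0, never interpolated.
#'
#' @param x,y point coordinates (degree space for the density chain).
#' @param z values at the points.
#' @param n_lags number of distance bins (default 12, the lag count used
#'   for the density surface).
#' @param lag_width bin width; defaults to the maximum pair distance
#'   divided by `n_lags`.
#' @return data.frame with columns `lag`, `distance` (bin midpoint),
#'   `semivariance`, `n_pairs`.
#' @export
empirical_semivariogram <- function(x, y, z, n_lags = 12L,
                                    lag_width = NULL) {
  n <- length(z)
  if (n < 2L) stop("need at least two points")
  d <- as.matrix(stats::dist(cbind(x, y)))
  iu <- upper.tri(d)
  dd <- d[iu]
  g2 <- (outer(z, z, "-")^2)[iu]
  if (is.null(lag_width)) lag_width <- max(dd) / n_lags
  bin <- pmin(floor(dd / lag_width) + 1L, n_lags)
  sv <- np <- numeric(n_lags)
  for (k in seq_len(n_lags)) {
    sel <- bin == k
    np[k] <- sum(sel)
    sv[k] <- if (np[k] > 0) sum(g2[sel]) / (2 * np[k]) else NA_real_
  }
  data.frame(lag = seq_len(n_lags),
             distance = (seq_len(n_lags) - 0.5) * lag_width,
             semivariance = sv, n_pairs = np)
}

#' Weighted-least-squares fit of a stable variogram model
#'
#' Fits nugget and partial sill (and optionally range) of a stable model to
#' an empirical semivariogram by minimizing Cressie's weighted criterion
#' `sum N_k (gamma_hat_k / gamma_k - 1)^2` with `optim` (L-BFGS-B, bounded
#' below at 0).
#'
#' @param emp an [empirical_semivariogram()] table.
#' @param shape fixed shape exponent.
#' @param fit_range if `FALSE` (default) the range is held at `start$range`.
#' @param start named list of starting values (`nugget`, `psill`, `range`).
#' @return a [variogram_model].
#' @export
fit_variogram <- function(emp, shape = 1.5, fit_range = TRUE,
                          start = NULL) {
  emp <- emp[!is.na(emp$semivariance) & emp$n_pairs > 0, ]
  if (nrow(emp) < 3L) stop("too few non-empty lags to fit a variogram")
  if (is.null(start))
    start <- list(nugget = min(emp$semivariance) / 2,
                  psill = max(emp$semivariance) - min(emp$semivariance) / 2,
                  range = max(emp$distance) / 3)
  lo <- c(0, 1e-12, if (fit_range) 1e-6)
  obj <- function(p) {
    p <- pmax(p, lo)    # optimizers may probe just past the bound
    m <- variogram_model(p[1], p[2],
                         if (fit_range) p[3] else start$range, shape)
    g <- pmax(stable_semivariance(m, emp$distance), 1e-12)
    sum(emp$n_pairs * (emp$semivariance / g - 1)^2)
  }
  # the weighted criterion is multimodal; restart over a grid of ranges
  range_starts <- if (fit_range)
    max(emp$distance) * c(1 / 12, 1 / 6, 1 / 3, 2 / 3) else start$range
  best <- NULL
  for (r0 in range_starts) {
    p0 <- c(start$nugget, start$psill, if (fit_range) r0)
    fit <- tryCatch(stats::optim(p0, obj, method = "L-BFGS-B", lower = lo),
                    error = function(e) NULL)
    if (is.null(fit))   # L-BFGS-B can fail on ill-scaled criteria
      fit <- tryCatch(stats::optim(p0, obj), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("variogram fit failed from every start")
  par <- pmax(best$par, lo)
  variogram_model(par[1], par[2],
                  if (fit_range) par[3] else start$range, shape)
}
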