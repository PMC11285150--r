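#' Universal kriging under a stable semivariogram
#'
#' Best linear unbiased prediction with a polynomial drift: per query
#' point, solves the bordered system
#' \deqn{[\Gamma F; F' 0] [\lambda; \mu] = [\gamma_0; f_0]}
#' where `Gamma` holds pairwise sample semivariances, `F` the monomial
#' drift basis of total degree `drift_order` in (lon, lat), `gamma_0` the
#' sample-to-query semivariances and `f_0` the drift basis at the query.
#' The prediction is `sum(lambda * z)` and the kriging variance
#' `lambda' gamma_0 + mu' f_0`. The constant drift column guarantees that
#' the weights sum to 1; with a zero-nugget model the predictor
#' interpolates the samples exactly.
#'
#' Distances are Euclidean in degree space -- the units in which the
#' default variogram range (1.928) is expressed. Duplicate sample
#' locations are averaged with a warning (they would make the system
#' singular). Negative predictions are clipped to the smallest positive
#' sample value, with a warning: densities are physical quantities.
#'
#' @param lon,lat,z sample coordinates (decimal degrees) and values.
#' @param model a [variogram_model].
#' @param drift_order polynomial drift degree 0-2 (default 1).
#' @param query_lon,query_lat query point coordinates.
#' @param clip_negative clip negative predictions to the smallest positive
#'   sample value (default `TRUE`; set `FALSE` when kriging a variable,
#'   such as log density, for which negative values are meaningful).
#' @return object of class `"kriged_surface"`: list with `predictions`
#'   (data.frame `lon`, `lat`, `estimate`, `variance`), `weights`
#'   (query-by-sample matrix), `samples`, `model`, `drift_order`,
#'   `n_clipped`.
#' @export
universal_krige <- function(lon, lat, z, model = variogram_model(),
                            drift_order = 1L, query_lon, query_lat,
                            clip_negative = TRUE) {
  stopifnot(inherits(model, "variogram_model"))
  if (!drift_order %in% 0:2)
    stop("'drift_order' must be 0, 1 or 2")
  samples <- data.frame(lon = lon, lat = lat, z = z)
  key <- paste(samples$lon, samples$lat)
  if (anyDuplicated(key)) {
    warning("duplicate sample locations averaged before kriging")
    samples <- do.call(rbind, lapply(split(samples, key), function(s)
      data.frame(lon = s$lon[1], lat = s$lat[1], z = mean(s$z))))
    rownames(samples) <- NULL
  }
  n <- nrow(samples)
  Fd <- drift_basis(samples$lon, samples$lat, drift_order)
  p <- ncol(Fd)
  if (n < p + 1L)
    stop("need at least ", p + 1L, " distinct samples for drift order ",
         drift_order)
  D <- as.matrix(stats::dist(samples[, c("lon", "lat")]))
  G <- matrix(stable_semivariance(model, as.vector(D)), n, n)
  diag(G) <- 0
  A <- rbind(cbind(G, Fd), cbind(t(Fd), matrix(0, p, p)))
  Ai <- tryCatch(solve(A), error = function(e)
    stop("singular kriging system (collinear drift or coincident points)"))
  m <- length(query_lon)
  dq <- sqrt(outer(query_lon, samples$lon, "-")^2 +
             outer(query_lat, samples$lat, "-")^2)      # m x n, degrees
  g0 <- matrix(stable_semivariance(model, as.vector(dq)), m, n)
  f0 <- drift_basis(query_lon, query_lat, drift_order)
  rhs <- cbind(g0, f0)                                  # m x (n + p)
  sol <- rhs %*% t(Ai)                                  # m x (n + p)
  w <- sol[, seq_len(n), drop = FALSE]
  mu <- sol[, n + seq_len(p), drop = FALSE]
  est <- as.vector(w %*% samples$z)
  var <- rowSums(sol * rhs)
  var[var < 0 & var > -1e-8] <- 0
  n_clip <- if (clip_negative) sum(est < 0) else 0L
  if (n_clip > 0) {
    floor_val <- min(samples$z[samples$z > 0])
    warning(n_clip, " negative kriging prediction(s) clipped to the ",
            "smallest positive sample value (", format(floor_val), ")")
    est[est < 0] <- floor_val
  }
  structure(list(predictions = data.frame(lon = query_lon, lat = query_lat,
                                          estimate = est, variance = var),
                 weights = w, samples = samples, model = model,
                 drift_order = drift_order, n_clipped = n_clip),
            class = "kriged_surface")
}

# monomial drift basis of total degree <= order in (lon, lat)
drift_basis <- function(lon, lat, order) {
  out <- cbind(intercept = rep(1, length(lon)))
  if (order >= 1L) out <- cbind(out, x = lon, y = lat)
  if (order >= 2L) out <- cbind(out, x2 = lon^2, xy = lon * lat, y2 = lat^2)
  out
}

#' @export
print.kriged_surface <- function(x, ...) {
  cat("Universal kriging surface: ", nrow(x$samples), " samples, ",
      nrow(x$predictions), " predictions, drift order ", x$drift_order,
      "\n", sep = "")
  print(x$model)
  if (x$n_clipped > 0)
    cat("  ", x$n_clipped, " negative prediction(s) clipped\n", sep = "")
  invisible(x)
}
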