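#' Residual diagnostics for a fitted size model
#'
#' The assumption checks run on every reduced model: Shapiro-Wilk
#' normality test of the residuals, the Durbin-Watson statistic
#' `DW = sum((e_t - e_{t-1})^2) / sum(e_t^2)` for serial independence (in
#' the observation order supplied), Cook's distances for influence, and
#' the residual autocorrelation function with `+/- 1.96 / sqrt(n)`
#' white-noise bounds. Observations with Cook's distance above `4 / n`
#' (a conventional screening threshold) are flagged for inspection.
#'
#' @param model a [fit_ols()] result.
#' @param acf_lag_max maximum ACF lag (default `10 * log10(n)`, the
#'   [stats::acf()] default).
#' @return object of class `"diagnostics_report"`: list with
#'   `shapiro` (list `W`, `p`), `durbin_watson`, `cooks` (numeric vector),
#'   `acf` (data.frame `lag`, `acf`), `acf_bound`, `flagged` (indices),
#'   `n`.
#' @export
diagnostics <- function(model, acf_lag_max = NULL) {
  e <- stats::residuals(model$fit)
  n <- length(e)
  if (n < 3L) stop("diagnostics need at least 3 residuals")
  sw <- stats::shapiro.test(e)
  dw <- sum(diff(e)^2) / sum(e^2)
  cooks <- stats::cooks.distance(model$fit)
  if (is.null(acf_lag_max)) acf_lag_max <- floor(10 * log10(n))
  ac <- stats::acf(e, lag.max = acf_lag_max, plot = FALSE)
  structure(list(shapiro = list(W = unname(sw$statistic),
                                p = sw$p.value),
                 durbin_watson = dw,
                 cooks = as.numeric(cooks),
                 acf = data.frame(lag = as.numeric(ac$lag),
                                  acf = as.numeric(ac$acf)),
                 acf_bound = 1.96 / sqrt(n),
                 flagged = which(as.numeric(cooks) > 4 / n),
                 n = n),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Residual diagnostics (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.4g\n", x$shapiro$W,
              x$shapiro$p))
  cat(sprintf("  Durbin-Watson = %.4f\n", x$durbin_watson))
  cat(sprintf("  max Cook's distance = %.4g; %d observation(s) above 4/n\n",
              max(x$cooks), length(x$flagged)))
  sig <- x$acf$lag > 0 & abs(x$acf$acf) > x$acf_bound
  cat(sprintf("  ACF lags beyond +/-%.3f: %s\n", x$acf_bound,
              if (any(sig)) paste(x$acf$lag[sig], collapse = ", ")
              else "none"))
  invisible(x)
}
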