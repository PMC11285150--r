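# Gaussian AIC used throughout the package: -2 loglik + 2 (p + 1), with
# the error variance counted as a parameter, i.e.
#   AIC = n log(2 pi RSS / n) + n + 2 (p + 1)
# (the stats::AIC convention for lm fits). Only differences matter for
# selection, but the constant is kept so values are comparable to lm's.
aic_gaussian <- function(rss, n, p) {
  n * log(2 * pi * rss / n) + n + 2 * (p + 1)
}

# fast AIC of an OLS fit given a design matrix without intercept
aic_of_subset <- function(Xsub, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xsub), y)
  rss <- sum(fit$residuals^2)
  aic_gaussian(rss, length(y), fit$rank)
}

#' Ordinary least-squares fit of a size model
#'
#' Thin wrapper around [stats::lm()] producing the coefficient table of a
#' centroid-size regression (estimate, SE, t, two-sided p from the t
#' distribution with residual df) together with the fit summary (R2,
#' adjusted R2, residual SE, F statistic, AIC). Factor predictors enter
#' through treatment contrasts; the expected reference levels of the
#' pipeline are `female` (sex), `low` (density class) and `forest`
#' (land cover).
#'
#' @param design data.frame of predictors (numeric spatial terms and/or
#'   factors). An intercept is always included.
#' @param response numeric response (centroid size for one view).
#' @return object of class `"size_model"`: list with `fit` (the `lm`
#'   object), `coefficients` (data.frame: variable, estimate, se, t, p),
#'   `r_squared`, `adj_r_squared`, `sigma`, `df_residual`, `fstatistic`,
#'   `aic`, `terms` (predictor column names of `design`).
#' @export
fit_ols <- function(design, response) {
  design <- as.data.frame(design)
  n <- length(response)
  if (ncol(design) > 0L && nrow(design) != n)
    stop("design and response lengths differ")
  if (ncol(design) == 0L) {
    dat <- data.frame(.response = response)
    fit <- stats::lm(.response ~ 1, data = dat)
  } else {
    dat <- cbind(design, .response = response)
    fit <- stats::lm(.response ~ ., data = dat)
  }
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (n <= fit$rank)
    stop("too few observations (", n, ") for ", fit$rank, " coefficients")
  sm <- summary(fit)
  coefs <- data.frame(variable = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      se = sm$coefficients[, 2],
                      t = sm$coefficients[, 3],
                      p = sm$coefficients[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, coefficients = coefs,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 sigma = sm$sigma, df_residual = fit$df.residual,
                 fstatistic = sm$fstatistic,
                 aic = aic_gaussian(sum(fit$residuals^2), n, fit$rank),
                 terms = names(design)),
            class = "size_model")
}

#' @export
print.size_model <- function(x, ...) {
  cat("Centroid-size regression (", length(x$terms), " predictor terms)\n",
      sep = "")
  print(x$coefficients, digits = 4)
  cat(sprintf("Residual SE %.4g on %d df;  R2 %.4f (adj %.4f);  AIC %.2f\n",
              x$sigma, x$df_residual, x$r_squared, x$adj_r_squared, x$aic))
  if (!is.null(x$fstatistic))
    cat(sprintf("F = %.4g on %d and %d df\n", x$fstatistic[1],
                x$fstatistic[2], x$fstatistic[3]))
  invisible(x)
}

#' Coefficient table in publication layout
#'
#' @param model a [fit_ols()] result.
#' @return data.frame with columns `variable`, `estimate`, `se`, `t`, `p`
#'   (the layout of the regression tables of the analysis).
#' @export
coefficient_table <- function(model) model$coefficients
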