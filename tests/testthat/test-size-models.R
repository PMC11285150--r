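test_that("candidate trend terms enumerate per-coordinate degrees", {
  t1 <- build_trend_terms(1)
  expect_setequal(t1$name, c("X", "Y", "XY"))
  t4 <- build_trend_terms(4)
  expect_equal(nrow(t4), 24L)            # 5 x 5 exponent grid minus constant
  expect_true("X3Y4" %in% t4$name)       # total degree 7 is admissible
  expect_false(any(t4$i == 0 & t4$j == 0))
  expect_false(anyDuplicated(t4$name) > 0)
})

test_that("OLS fits match the normal equations and lm's AIC", {
  set.seed(31)
  n <- 30
  X <- matrix(rnorm(3 * n), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + X %*% c(1, -0.5, 0.2) + rnorm(n, 0, 0.3)
  m <- fit_ols(as.data.frame(X), as.numeric(y))
  beta_hand <- solve(t(cbind(1, X)) %*% cbind(1, X),
                     t(cbind(1, X)) %*% y)
  expect_equal(m$coefficients$estimate, as.numeric(beta_hand),
               tolerance = 1e-10)
  expect_equal(m$aic, as.numeric(stats::AIC(m$fit)), tolerance = 1e-8)

  # exact linear data: R2 = 1, residual SE 0
  yy <- 1 + 2 * X[, 1]
  mx <- suppressWarnings(fit_ols(data.frame(a = X[, 1]), yy))
  expect_equal(mx$r_squared, 1, tolerance = 1e-12)
  expect_lt(mx$sigma, 1e-10)

  # response orthogonal to all centered predictors: zero slopes, R2 = 0
  Xo <- scale(X, scale = FALSE)
  yo <- rep(c(1, -1), n / 2)
  Q <- qr.Q(qr(cbind(1, Xo)))
  yo <- yo - Q %*% crossprod(Q, yo)          # project out design space
  mo <- fit_ols(as.data.frame(Xo), as.numeric(yo) + 5)
  expect_equal(mo$coefficients$estimate[-1], rep(0, 3), tolerance = 1e-10)
  expect_lt(mo$r_squared, 1e-20)

  # rank deficiency is named
  Xd <- data.frame(a = X[, 1], b = X[, 1])
  expect_error(fit_ols(Xd, as.numeric(y)), "rank deficient.*b")
})

test_that("R-squared never decreases along a nested term sequence", {
  set.seed(37)
  n <- 60
  X <- as.data.frame(matrix(rnorm(5 * n), n, 5))
  y <- rnorm(n)
  r2 <- vapply(1:5, function(p) fit_ols(X[seq_len(p)], y)$r_squared,
               numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("subset selection equals exhaustive enumeration", {
  set.seed(43)
  n <- 80
  X <- matrix(rnorm(8 * n), n, 8,
              dimnames = list(NULL, paste0("c", 1:8)))
  y <- 1.5 * X[, 2] - 0.8 * X[, 5] + rnorm(n)
  sel <- select_spatial_model(X, y)
  expect_equal(sel$strategy, "exhaustive")
  # independent oracle: enumerate all 255 subsets with lm + stats::AIC
  best_aic <- Inf; best_sub <- NULL
  for (size in 1:8) for (sub in utils::combn(8, size, simplify = FALSE)) {
    a <- stats::AIC(stats::lm(y ~ X[, sub, drop = FALSE]))
    if (a < best_aic - 1e-10) { best_aic <- a; best_sub <- sub }
  }
  a0 <- stats::AIC(stats::lm(y ~ 1))
  if (a0 < best_aic) { best_aic <- a0; best_sub <- integer(0) }
  expect_setequal(sel$selected, colnames(X)[best_sub])
  expect_equal(sel$aic, best_aic, tolerance = 1e-8)
  expect_lte(sel$aic, sel$global_aic)
})

test_that("selection keeps a generating term and shrinks under pure noise", {
  set.seed(47)
  n <- 100
  lon <- runif(n, 0, 30); lat <- runif(n, -20, 10)
  cand <- trend_design(lon, lat, build_trend_terms(1))
  y <- 3 * cand[, "Y"] + rnorm(n, 0, 0.5)
  sel <- select_spatial_model(cand, y)
  expect_true("Y" %in% sel$selected)
  expect_lte(sel$aic, sel$global_aic)

  ynoise <- rnorm(n)
  seln <- select_spatial_model(cand, ynoise)
  expect_lte(length(seln$selected), ncol(cand))
  expect_lte(seln$aic, seln$global_aic)
})

test_that("VIF equals the brute-force definition and car's computation", {
  set.seed(53)
  n <- 70
  z <- rnorm(n)
  X <- cbind(a = z + rnorm(n, 0, 0.5), b = z + rnorm(n, 0, 0.5),
             c = rnorm(n))
  v <- vif(X)
  oracle <- vapply(1:3, function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-8)

  dat <- as.data.frame(X); dat$y <- rnorm(n)
  vcar <- car::vif(stats::lm(y ~ a + b + c, data = dat))
  expect_equal(unname(v), unname(vcar), tolerance = 1e-6)

  # columns orthogonal to each other and the intercept: VIF exactly 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(3 * n), n, 3))))[, 2:4]
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-8)
  expect_true(any(is.infinite(vif(cbind(d1 = z, d2 = z, c = rnorm(n))))))
})

test_that("backward stepwise drops noise terms, honors protection", {
  set.seed(59)
  n <- 120
  design <- data.frame(X = rnorm(n), Z = rnorm(n),
                       sex = factor(sample(c("female", "male"), n, TRUE),
                                    levels = c("female", "male")))
  y <- 2 * design$X - 1.5 * (design$sex == "male") + rnorm(n, 0, 0.5)
  red <- backward_stepwise_aic(design, y, protected = "sex")
  # checked against an independent one-step AIC comparison: the first
  # drop (if any) must be the one stats::AIC would also prefer
  aic_full <- stats::AIC(stats::lm(y ~ X + Z + sex, data = design))
  aic_dropX <- stats::AIC(stats::lm(y ~ Z + sex, data = design))
  aic_dropZ <- stats::AIC(stats::lm(y ~ X + sex, data = design))
  expect_lt(aic_dropZ, aic_dropX)   # the noise term is the weaker one
  if (aic_dropZ < aic_full) {
    expect_equal(red$path[1], "Z")
  } else {
    expect_length(red$path, 0L)
  }
  expect_false("sex" %in% red$path)
  expect_true(all(diff(red$aic_path) < 0))

  # an AIC-minimal model is a fixed point
  red2 <- backward_stepwise_aic(design["X"], y)
  expect_length(red2$path, 0L)
})

test_that("diagnostics reproduce closed-form and stochastic benchmarks", {
  # alternating residuals (1, -1, 1, -1): DW = 12 / 4 = 3
  y <- c(1, -1, 1, -1) + 10
  m <- fit_ols(data.frame(), y)
  d <- diagnostics(m)
  expect_equal(d$durbin_watson, 3.0, tolerance = 1e-12)

  # iid normal residuals, n = 1000: DW near 2, matching lmtest's statistic
  set.seed(61)
  yy <- rnorm(1000)
  m2 <- fit_ols(data.frame(x = rnorm(1000)), yy)
  d2 <- diagnostics(m2)
  expect_gt(d2$durbin_watson, 1.8)
  expect_lt(d2$durbin_watson, 2.2)
  dw_ref <- lmtest::dwtest(m2$fit)
  expect_equal(d2$durbin_watson, unname(dw_ref$statistic),
               tolerance = 1e-10)
  expect_equal(d2$acf$acf[1], 1)        # ACF(0) = 1
  expect_gt(d2$shapiro$W, 0)
  expect_lte(d2$shapiro$W, 1)
})

test_that("duplicating a leverage point shrinks its Cook's distance", {
  set.seed(67)
  x <- c(rnorm(30), 8)                   # one remote point
  y <- 1 + 0.5 * x + c(rnorm(30, 0, 0.4), 3)
  d1 <- diagnostics(fit_ols(data.frame(x = x), y))
  x2 <- c(x, 8); y2 <- c(y, y[31])
  d2 <- diagnostics(fit_ols(data.frame(x = x2), y2))
  expect_lt(d2$cooks[31], d1$cooks[31])
})

test_that("combined-model CIs cover the generating coefficients", {
  # linear generation: size = b0 + b_sex male + b_dens high + trend + noise
  set.seed(71)
  n <- 200; n_rep <- 200
  b_sex <- -4.4; b_dens <- -18.4
  cover_sex <- cover_dens <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    lon <- runif(n, 0, 30); lat <- runif(n, -25, 10)
    sex <- factor(sample(c("female", "male", "unknown"), n, TRUE,
                         prob = c(0.36, 0.38, 0.26)),
                  levels = c("female", "male", "unknown"))
    dens <- factor(sample(c("low", "high"), n, TRUE, prob = c(0.2, 0.8)),
                   levels = c("low", "high"))
    y <- 369 + b_sex * (sex == "male") + b_dens * (dens == "high") +
      0.3 * lat + 0.02 * lon^2 + rnorm(n, 0, 4)
    design <- cbind(as.data.frame(trend_design(lon, lat,
                                               build_trend_terms(2))),
                    sex = sex, density_class = dens)
    m <- fit_ols(design, y)
    co <- m$coefficients
    ci <- function(row) row$estimate +
      c(-1, 1) * stats::qt(0.975, m$df_residual) * row$se
    cs <- ci(co[co$variable == "sexmale", ])
    cd <- ci(co[co$variable == "density_classhigh", ])
    cover_sex[r] <- b_sex >= cs[1] && b_sex <= cs[2]
    cover_dens[r] <- b_dens >= cd[1] && b_dens <= cd[2]
  }
  expect_gte(mean(cover_sex), 0.90)
  expect_gte(mean(cover_dens), 0.90)
})
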