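make_specimens <- function(n_f, n_m, n_u, cs_f, cs_m, cs_u = cs_m,
                           lon = NULL, lat = NULL) {
  n <- n_f + n_m + n_u
  data.frame(
    specimen_id = sprintf("s%03d", seq_len(n)),
    sex = factor(rep(c("female", "male", "unknown"), c(n_f, n_m, n_u)),
                 levels = c("female", "male", "unknown")),
    country = "Kenya",
    lon = if (is.null(lon)) runif(n, 30, 40) else lon,
    lat = if (is.null(lat)) runif(n, -5, 5) else lat,
    centroid_size = c(rep(cs_f, length.out = n_f),
                      rep(cs_m, length.out = n_m),
                      rep(cs_u, length.out = n_u)))
}

test_that("region assignment follows the half-plane scheme", {
  sp <- data.frame(specimen_id = c("ke1", "ke2", "ng1", "ng2",
                                   "bw1", "bw2", "ml"),
                   country = c("Kenya", "Kenya", "Nigeria", "Nigeria",
                               "Botswana", "Botswana", "Mali"),
                   lon = c(37, 36.5, 8, 8.4, 25, 25.3, -10),
                   lat = c(-1, -1.2, 9, 9.3, -22, -22.2, 21))
  out <- assign_region(sp)
  expect_equal(as.character(out$region[c(1, 3, 5)]),
               c("eastern", "western", "southern"))
  # the isolated Sahel specimen is excluded, with its isolation measured
  expect_equal(as.character(out$region[7]), "excluded")
  expect_gt(out$nn_km[7], 2000)
  expect_equal(out$nn_km[7],
               min(great_circle_km(-10, 21, sp$lon[1:6], sp$lat[1:6])))

  # country overrides take precedence over the half planes
  sc <- region_scheme(country_overrides = c(Kenya = "southern"),
                      exclude_nn_km = Inf)
  out2 <- assign_region(sp, sc)
  expect_equal(as.character(out2$region[1:2]), c("southern", "southern"))
})

test_that("dimorphism ratio is the ratio of sex means", {
  set.seed(73)
  sp <- make_specimens(10, 10, 5, cs_f = 101.2, cs_m = 100)
  r <- dimorphism_ratio(sp)
  expect_equal(r$ratio, 1.012, tolerance = 1e-12)
  expect_equal(r$n_female, 10L)
  expect_equal(r$n_male, 10L)
  # unknown-sex specimens count toward scope n but not the ratio
  expect_equal(r$n_scope, 25L)

  # identical sex distributions: ratio 1
  sp2 <- make_specimens(8, 8, 0, cs_f = c(90, 110), cs_m = c(90, 110))
  expect_equal(dimorphism_ratio(sp2)$ratio, 1)

  # empty sex class: NA with a note, not an error
  sp3 <- make_specimens(5, 0, 2, cs_f = 100, cs_m = numeric(0))
  r3 <- dimorphism_ratio(sp3)
  expect_true(is.na(r3$ratio))
  expect_match(r3$note, "empty sex class")
})

test_that("ratios are invariant to a change of units", {
  set.seed(79)
  sp <- make_specimens(12, 14, 6, cs_f = rnorm(12, 101, 2),
                       cs_m = rnorm(14, 100, 2), cs_u = rnorm(6, 100, 2))
  r1 <- dimorphism_ratio(sp)$ratio
  sp$centroid_size <- sp$centroid_size * 17.3
  expect_equal(dimorphism_ratio(sp)$ratio, r1, tolerance = 1e-12)
})

test_that("regional sample sizes sum to total minus exclusions", {
  set.seed(83)
  cfg <- sim_config(n_specimens = 150L, views = c(ventral = 369))
  run <- run_pipeline(config = cfg, seed = 97, views = "ventral",
                      max_degree = 2)
  tab <- run$dimorphism
  tot <- tab$n[tab$scope == "total"]
  reg <- sum(tab$n[tab$scope != "total"])
  n_excl <- sum(run$records$region == "excluded")
  expect_equal(reg, tot - n_excl + 0L)
  # total n splits into the three sex classes
  rec <- run$records[run$records$region != "excluded", ]
  expect_equal(tot, nrow(rec))
  expect_equal(tab$n_female[tab$scope == "total"],
               sum(rec$sex == "female"))
})

test_that("a 1.2% size advantage is recovered at the study sample sizes", {
  set.seed(89)
  n_rep <- 100
  inside <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    f <- stats::rlnorm(120, log(369 * 1.012), 0.01)
    m <- stats::rlnorm(125, log(369), 0.01)
    ratio <- mean(f) / mean(m)
    inside[r] <- ratio > 1.005 && ratio < 1.020
  }
  expect_gte(mean(inside), 0.95)
})

test_that("bootstrap CIs cover 1.0 under zero true dimorphism", {
  set.seed(91)
  n_rep <- 100; n_boot <- 200
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    f <- stats::rlnorm(60, log(369), 0.03)
    m <- stats::rlnorm(60, log(369), 0.03)
    boots <- vapply(seq_len(n_boot), function(b)
      mean(sample(f, replace = TRUE)) / mean(sample(m, replace = TRUE)),
      numeric(1))
    ci <- stats::quantile(boots, c(0.025, 0.975))
    cover[r] <- ci[1] <= 1 && 1 <= ci[2]
  }
  expect_gte(mean(cover), 0.85)
  expect_lte(mean(cover), 1.0)
})
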