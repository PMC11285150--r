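test_that("centroid size matches closed forms and the direct formula", {
  sq <- landmark_config(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0)), "sq")
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)

  expect_warning(
    cs0 <- centroid_size(landmark_config(matrix(2, 5, 2), "deg")),
    "degenerate")
  expect_equal(cs0, 0)

  set.seed(7)
  xy <- rand_shape(7)
  ctr <- colMeans(xy)
  direct <- sqrt(sum(apply(xy, 1, function(p) sum((p - ctr)^2))))
  expect_equal(centroid_size(landmark_config(xy, "r")), direct,
               tolerance = 1e-12)
  # scale is applied exactly once
  expect_equal(centroid_size(landmark_config(xy, "r", scale = 0.1)),
               0.1 * direct, tolerance = 1e-12)
})

test_that("centroid size is invariant under rotation and translation", {
  set.seed(12)
  for (rep in 1:10) {
    xy <- rand_shape(sample(4:12, 1))
    cs <- centroid_size(landmark_config(xy, "a"))
    xy2 <- sweep(rot2(xy, runif(1, 0, 2 * pi)), 2, rnorm(2, 0, 100), "+")
    expect_equal(centroid_size(landmark_config(xy2, "a")), cs,
                 tolerance = 1e-10)
  }
})

test_that("GPA removes rotation, translation and scale", {
  set.seed(21)
  base <- rand_shape(8)
  # two copies of one shape, one rotated 90 degrees and translated
  c1 <- landmark_config(base, "a")
  c2 <- landmark_config(sweep(rot2(base, pi / 2), 2, c(12, -3), "+"), "b")
  fit <- gpa_align(list(c1, c2))
  expect_lt(sqrt(sum((fit$aligned[, , 1] - fit$aligned[, , 2])^2)), 1e-10)

  # one shape at 5 scales: sizes in the given ratios, aligned identical
  sizes <- c(1, 2, 3.5, 5, 8)
  cfgs <- make_configs(base, sizes)
  fit <- gpa_align(cfgs)
  expect_equal(unname(fit$centroid_sizes / fit$centroid_sizes[1]), sizes,
               tolerance = 1e-8)
  for (i in 2:5)
    expect_lt(max(abs(fit$aligned[, , i] - fit$aligned[, , 1])), 1e-7)
  # every aligned configuration is centered with unit centroid size
  for (i in 1:5) {
    expect_lt(max(abs(colMeans(fit$aligned[, , i]))), 1e-10)
    expect_equal(sum(fit$aligned[, , i]^2), 1, tolerance = 1e-10)
  }
  # consensus is the coordinate-wise mean up to its unit-size scaling
  cons <- apply(fit$aligned, c(1, 2), mean)
  expect_equal(fit$consensus, cons / sqrt(sum(cons^2)), tolerance = 1e-8)
})

test_that("GPA rotations are locally optimal (grid-search check)", {
  set.seed(33)
  cfgs <- make_configs(rand_shape(7), sizes = runif(10, 1, 4),
                       noise_sd = 0.05)
  fit <- gpa_align(cfgs)
  angles <- seq(-pi, pi, length.out = 721)
  for (i in c(1, 4, 9)) {
    ssd <- vapply(angles, function(a)
      sum((rot2(fit$aligned[, , i], a) - fit$consensus)^2), numeric(1))
    ssd0 <- sum((fit$aligned[, , i] - fit$consensus)^2)
    expect_lte(ssd0, min(ssd) + 1e-6)
  }
})

test_that("GPA is equivariant under specimen permutation", {
  set.seed(44)
  cfgs <- make_configs(rand_shape(6), sizes = runif(6, 1, 3),
                       noise_sd = 0.02)
  fit1 <- gpa_align(cfgs)
  perm <- c(3, 1, 6, 2, 5, 4)
  fit2 <- gpa_align(cfgs[perm])
  expect_equal(unname(fit2$centroid_sizes),
               unname(fit1$centroid_sizes[perm]), tolerance = 1e-12)
  # aligned shapes agree up to the (arbitrary) global orientation:
  # inter-specimen Procrustes distances are permutation-equivariant
  flat <- function(fit) t(apply(fit$aligned, 3, as.numeric))
  D1 <- as.matrix(dist(flat(fit1)))
  D2 <- as.matrix(dist(flat(fit2)))
  expect_equal(D2, D1[perm, perm], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("GPA refuses mismatched landmark counts and degenerate shapes", {
  c1 <- landmark_config(rand_shape(5), "a")
  c2 <- landmark_config(rand_shape(6), "b")
  expect_error(gpa_align(list(c1, c2)), "landmark counts differ")
  expect_error(gpa_align(list(c1)), "at least 2")
  cdeg <- landmark_config(matrix(1, 5, 2), "d")
  expect_error(gpa_align(list(c1, cdeg)), "degenerate")
})

test_that("two-configuration alignment agrees with vegan's Procrustes", {
  set.seed(55)
  x <- rand_shape(9)
  y <- rot2(x, 0.7) + matrix(rnorm(18, 0, 0.1), 9, 2)
  cx <- sweep(x, 2, colMeans(x)); cx <- cx / sqrt(sum(cx^2))
  cy <- sweep(y, 2, colMeans(y)); cy <- cy / sqrt(sum(cy^2))
  ours <- sum((hyenamorph:::rotate_onto(cy, cx) - cx)^2)
  vg <- vegan::procrustes(cx, cy, scale = FALSE, symmetric = FALSE)
  expect_equal(ours, vg$ss, tolerance = 1e-8)
})

test_that("recovered centroid sizes track generating sizes at 1% noise", {
  set.seed(66)
  base <- rand_shape(10)
  sizes <- runif(40, 80, 120)
  cfgs <- make_configs(base, sizes, noise_sd = 0.01 * mean(sizes) /
                         sqrt(nrow(base)))
  fit <- gpa_align(cfgs)
  expect_gt(cor(unname(fit$centroid_sizes), sizes), 0.999)
})
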