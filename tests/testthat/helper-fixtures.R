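# shared generators for the test suite; everything is seed-explicit

# a random non-degenerate 2D shape with k landmarks
rand_shape <- function(k, sd = 1) {
  cbind(stats::rnorm(k, sd = sd), stats::rnorm(k, sd = sd))
}

# rotate a coordinate matrix by theta radians
rot2 <- function(xy, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy %*% R
}

# a list of landmark_config built from one base shape at given sizes,
# random rotations/translations, optional coordinate noise
make_configs <- function(base, sizes, noise_sd = 0, view = "ventral",
                         scale = 1, fixed = NULL) {
  lapply(seq_along(sizes), function(i) {
    xy <- sweep(base, 2, colMeans(base))
    xy <- xy / sqrt(sum(xy^2))
    xy <- sizes[i] * rot2(xy, stats::runif(1, 0, 2 * pi))
    xy <- sweep(xy, 2, stats::runif(2, -5, 5), "+")
    if (noise_sd > 0)
      xy <- xy + matrix(stats::rnorm(2 * nrow(base), 0, noise_sd),
                        nrow(base), 2)
    landmark_config(xy, sprintf("s%02d", i), view = view, scale = scale,
                    fixed = fixed)
  })
}

# exhaustive optimal 1-D classification cost: minimum within-class SS over
# all contiguous partitions of the sorted values into k classes
brute_force_jenks_cost <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  if (k == 1) return(ss(x))
  best <- Inf
  for (sp in splits) {
    bounds <- c(0, sp, n)
    cost <- sum(vapply(seq_len(k), function(j)
      ss(x[(bounds[j] + 1):bounds[j + 1]]), numeric(1)))
    if (cost < best) best <- cost
  }
  best
}

# path to the shipped density-table transcription
density_fixture_path <- function() {
  system.file("extdata", "density_studies.tsv", package = "hyenamorph",
              mustWork = TRUE)
}
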