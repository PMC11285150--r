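#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults are
#' the study conditions the pipeline is meant to emulate: 332 specimens
#' with sex counts 121 female / 125 male / 86 unknown, clustered sampling
#' dominated by an eastern cluster (weights 0.75 / 0.15 / 0.10 for
#' east / west / south), a female/male size ratio of 1.012, a -5% size
#' effect of high population density, 1% multiplicative size noise, 32
#' density census sites, and a stable-variogram density field (nugget
#' 0.439, partial sill 0.2855, range 1.928 degrees, shape 1.5) on the log
#' scale with a low/high boundary at 0.03 animals per km2. All generation
#' is seed-explicit: every `simulate_*` function requires a seed.
#'
#' @param n_specimens number of specimens.
#' @param sex_counts named integer vector `female`, `male`, `unknown`;
#'   used exactly when `n_specimens` equals their sum, otherwise as
#'   proportions.
#' @param cluster_weights,cluster_centers,cluster_sd clustered point
#'   process for collecting localities (east, west, south).
#' @param bbox sampling bounding box `c(lon_min, lon_max, lat_min,
#'   lat_max)`.
#' @param views named numeric vector: mean centroid size (mm) per view.
#' @param dimorphism target female/male centroid-size ratio.
#' @param density_effect multiplicative size effect of the high-density
#'   class (log scale; negative).
#' @param trend_fun smooth spatial size trend on the log scale.
#' @param size_noise log-scale SD of individual size.
#' @param digit_noise digitizing noise as a fraction of centroid size
#'   (spread over landmarks).
#' @param tps_scale physical units per image unit written to TPS files.
#' @param n_density_samples number of census sites.
#' @param dens_variogram [variogram_model] of the log-density field.
#' @param dens_meanlog mean log density.
#' @param dens_threshold low/high boundary (animals per km2) of the
#'   generating density class.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_specimens = 332L,
                       sex_counts = c(female = 121L, male = 125L,
                                      unknown = 86L),
                       cluster_weights = c(east = 0.75, west = 0.15,
                                           south = 0.10),
                       cluster_centers = list(east = c(35, -2),
                                              west = c(2, 9),
                                              south = c(23, -25)),
                       cluster_sd = c(east = 4, west = 3, south = 3),
                       bbox = c(-17, 47, -32, 15),
                       views = c(ventral = 369, lateral_cranium = 540,
                                 lateral_mandible = 576),
                       dimorphism = 1.012,
                       density_effect = log(0.95),
                       trend_fun = function(lon, lat)
                         0.010 * sin((lon - 15) / 12) +
                         0.010 * cos((lat + 8) / 10),
                       size_noise = 0.01,
                       digit_noise = 0.005,
                       tps_scale = 0.1,
                       n_density_samples = 32L,
                       dens_variogram = variogram_model(nugget = 0.05,
                                                        psill = 0.70,
                                                        range = 2,
                                                        shape = 1.5),
                       dens_meanlog = log(0.07),
                       dens_threshold = 0.03) {
  stopifnot(size_noise >= 0, digit_noise >= 0,
            all(cluster_weights > 0), dimorphism > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate specimen collecting localities
#'
#' Clustered point process mimicking museum sampling imbalance: each
#' specimen is attached to one of three regional clusters (dense east,
#' sparse west and south) and scattered around its center with a Gaussian
#' kernel, clipped to the bounding box. Sex labels follow the configured
#' counts (exactly when `n_specimens` matches their sum); unknown-sex
#' specimens carry a latent true sex, drawn 50/50, which the generator
#' uses for their size but the analysis never sees.
#'
#' @param config a [sim_config].
#' @param seed integer seed (mandatory).
#' @return data.frame with columns `specimen_id`, `sex`, `latent_sex`,
#'   `year`, `country`, `lon`, `lat`, `cluster`.
#' @export
simulate_localities <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(seed)
  n <- config$n_specimens
  if (n == 0L)
    return(data.frame(specimen_id = character(0), sex = character(0),
                      latent_sex = character(0), year = integer(0),
                      country = character(0), lon = numeric(0),
                      lat = numeric(0), cluster = character(0)))
  w <- config$cluster_weights / sum(config$cluster_weights)
  cl <- sample(names(w), n, replace = TRUE, prob = w)
  ctr <- do.call(rbind, config$cluster_centers[cl])
  sd <- config$cluster_sd[cl]
  lon <- pmin(pmax(stats::rnorm(n, ctr[, 1], sd), config$bbox[1]),
              config$bbox[2])
  lat <- pmin(pmax(stats::rnorm(n, ctr[, 2], sd), config$bbox[3]),
              config$bbox[4])
  sc <- config$sex_counts
  sex <- if (n == sum(sc)) {
    sample(rep(names(sc), sc))
  } else {
    sample(names(sc), n, replace = TRUE, prob = sc / sum(sc))
  }
  latent <- ifelse(sex == "unknown",
                   sample(c("female", "male"), n, replace = TRUE), sex)
  country <- c(east = "Kenya", west = "Nigeria",
               south = "Botswana")[cl]
  data.frame(specimen_id = sprintf("HM%04d", seq_len(n)),
             sex = factor(sex, levels = c("female", "male", "unknown")),
             latent_sex = latent,
             year = sample(1900:2006, n, replace = TRUE),
             country = country, lon = lon, lat = lat, cluster = cl,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a spatially structured density field
#'
#' Realizes a Gaussian random field for log population density with the
#' configured stable covariance (structured variance = partial sill,
#' independent nugget component added per point) jointly at census sample
#' sites and at arbitrary query points, so the truth at the queries is
#' available for interpolation-error assertions. When query points (the
#' specimen localities) are supplied, most census sites are placed as
#' jittered copies of randomly chosen specimen localities -- census
#' studies and museum collecting concentrate in the same protected areas. Densities are
#' `exp(meanlog + field)`; the generating low/high class is the truth
#' thresholded at `dens_threshold`.
#'
#' @param config a [sim_config].
#' @param seed integer seed (mandatory).
#' @param query_lon,query_lat query coordinates (e.g. specimen
#'   localities).
#' @return list with `samples` (data.frame `lon`, `lat`, `density`),
#'   `truth` (density at the queries), `class_true` (factor `low`/`high`),
#'   `meanlog`, `threshold`.
#' @export
simulate_density_field <- function(config = sim_config(), seed,
                                   query_lon = numeric(0),
                                   query_lat = numeric(0)) {
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(seed)
  vg <- config$dens_variogram
  ns <- config$n_density_samples
  # census sites: field studies happen in the same protected areas the
  # museum specimens came from, so when specimen localities are supplied
  # three quarters of the census sites are jittered specimen localities;
  # the remainder (and all sites, absent specimens) follow the cluster
  # process plus range-wide scatter
  n1 <- if (length(query_lon)) round(0.75 * ns) else ns %/% 2L
  if (length(query_lon)) {
    pick <- sample.int(length(query_lon), n1, replace = n1 > length(query_lon))
    base_lon <- query_lon[pick] + stats::rnorm(n1, 0, 0.3)
    base_lat <- query_lat[pick] + stats::rnorm(n1, 0, 0.3)
  } else {
    w <- config$cluster_weights / sum(config$cluster_weights)
    cl <- sample(names(w), n1, replace = TRUE, prob = w)
    ctr <- do.call(rbind, config$cluster_centers[cl])
    csd <- 1.5 * config$cluster_sd[cl]
    base_lon <- stats::rnorm(n1, ctr[, 1], csd)
    base_lat <- stats::rnorm(n1, ctr[, 2], csd)
  }
  slon <- c(base_lon, stats::runif(ns - n1, config$bbox[1], config$bbox[2]))
  slat <- c(base_lat, stats::runif(ns - n1, config$bbox[3], config$bbox[4]))
  slon <- pmin(pmax(slon, config$bbox[1]), config$bbox[2])
  slat <- pmin(pmax(slat, config$bbox[3]), config$bbox[4])
  lon <- c(slon, query_lon); lat <- c(slat, query_lat)
  m <- length(lon)
  # structured part: stable correlation, variance = partial sill
  if (vg$psill > 0) {
    d <- as.matrix(stats::dist(cbind(lon, lat)))
    C <- vg$psill * exp(-(d / vg$range)^vg$shape)
    ev <- eigen(C, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    zs <- ev$vectors %*% (sqrt(lam) * stats::rnorm(m))
  } else zs <- numeric(m)
  zn <- stats::rnorm(m, 0, sqrt(vg$nugget))
  logd <- config$dens_meanlog + as.vector(zs) + zn
  dens <- exp(logd)
  qi <- if (length(query_lon)) ns + seq_along(query_lon) else integer(0)
  list(samples = data.frame(lon = slon, lat = slat,
                            density = dens[seq_len(ns)]),
       truth = dens[qi],
       class_true = factor(ifelse(dens[qi] > config$dens_threshold,
                                  "high", "low"),
                           levels = c("low", "high")),
       meanlog = config$dens_meanlog, threshold = config$dens_threshold)
}

#' Landmark template for one skull view
#'
#' A stylized closed outline: 14 points on a view-specific superellipse,
#' of which 4 are sliding semilandmarks (with their neighbor triples).
#' The template is centered and scaled to unit centroid size.
#'
#' @param view view name.
#' @return list with `coords` (14 x 2, centroid size 1), `fixed`
#'   (logical), `sliders` (a [slider_table]).
#' @export
template_skull <- function(view = "ventral") {
  k <- 14L
  th <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  mod <- switch(view,
                ventral = 0.25 * cos(2 * th) + 0.08 * sin(3 * th),
                lateral_cranium = 0.35 * cos(2 * th) + 0.10 * cos(3 * th),
                lateral_mandible = 0.20 * cos(2 * th) + 0.15 * sin(th),
                stop("unknown view '", view, "'"))
  r <- 1 + mod
  xy <- cbind(r * cos(th), r * sin(th))
  xy <- sweep(xy, 2L, colMeans(xy))
  xy <- xy / sqrt(sum(xy^2))
  sliders <- slider_table(before = c(2L, 5L, 8L, 11L),
                          slider = c(3L, 6L, 9L, 12L),
                          after = c(4L, 7L, 10L, 13L))
  fixed <- rep(TRUE, k)
  fixed[sliders$slider] <- FALSE
  list(coords = xy, fixed = fixed, sliders = sliders)
}

#' Simulate landmark configurations for a set of specimens
#'
#' Per specimen, a true centroid size is drawn on the log scale,
#' `s = base * exp(b_sex 1[male] + b_dens 1[high] + trend(lon, lat) + e)`,
#' with `b_sex = -log(dimorphism)` applied to the *latent* sex and
#' `e ~ N(0, size_noise^2)`; the view template is scaled to `s`, rotated
#' by a uniform random angle, translated, and perturbed with digitizing
#' noise of SD `digit_noise * s / sqrt(k)` per coordinate. Coordinates are
#' stored in image units with the configured TPS scale factor, exactly as
#' a digitizing session would produce them.
#'
#' @param config a [sim_config].
#' @param records [simulate_localities()] output.
#' @param density_class factor `low`/`high` per specimen (the generating
#'   class).
#' @param view view name (must be a name of `config$views`).
#' @param seed integer seed (mandatory).
#' @return list with `configs` (list of [landmark_config]), `true_size`
#'   (numeric), `template` (the [template_skull()] used).
#' @export
simulate_landmarks <- function(config = sim_config(), records,
                               density_class, view = "ventral", seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(seed)
  tmpl <- template_skull(view)
  k <- nrow(tmpl$coords)
  n <- nrow(records)
  base <- config$views[[view]]
  b_sex <- -log(config$dimorphism)
  s <- base * exp(b_sex * (records$latent_sex == "male") +
                  config$density_effect * (density_class == "high") +
                  config$trend_fun(records$lon, records$lat) +
                  stats::rnorm(n, 0, config$size_noise))
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    thet <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(thet), sin(thet), -sin(thet), cos(thet)), 2L)
    xy <- s[i] * tmpl$coords %*% R
    xy <- sweep(xy, 2L, stats::runif(2, -50, 50), "+")
    xy <- xy + matrix(stats::rnorm(2 * k, 0,
                                   config$digit_noise * s[i] / sqrt(k)),
                      k, 2L)
    configs[[i]] <- landmark_config(xy / config$tps_scale,
                                    records$specimen_id[i], view = view,
                                    scale = config$tps_scale,
                                    fixed = tmpl$fixed)
  }
  list(configs = configs, true_size = s, template = tmpl)
}

#' Simulate gridded climate and land-cover covariates
#'
#' Smooth deterministic fields on a 1-degree grid over the configured
#' bounding box: annual mean temperature (degrees C) declining away from
#' the equator, annual precipitation (mm) peaking in the equatorial belt,
#' and a blocky integer land-cover field (codes 1-28) laid out so that
#' forest codes dominate the wet equatorial west, grassland/savanna codes
#' the east, and bare-ground codes the arid south-west.
#'
#' @param config a [sim_config].
#' @return named list of three [covariate_grid]s: `temperature`,
#'   `precipitation`, `landcover`.
#' @export
simulate_covariate_grids <- function(config = sim_config()) {
  bb <- config$bbox + c(-1, 1, -1, 1)   # one pad cell: points clipped to
  lon_c <- seq(bb[1] + 0.5, bb[2] - 0.5, by = 1)  # the bbox edge stay inside
  lat_c <- seq(bb[3] + 0.5, bb[4] - 0.5, by = 1)  # the half-open grid
  temp <- outer(lat_c, lon_c, function(la, lo)
    28 - 0.18 * abs(la) - 0.03 * (lo - 20))
  prec <- outer(lat_c, lon_c, function(la, lo)
    120 + 1400 * exp(-((la - 2) / 9)^2) * exp(-((lo - 18) / 30)^2))
  lc <- outer(lat_c, lon_c, function(la, lo) {
    wet <- 1400 * exp(-((la - 2) / 9)^2) * exp(-((lo - 18) / 30)^2)
    base <- ifelse(wet > 900, 1L,        # forest block
            ifelse(wet > 450, 7L,        # mixed block
            ifelse(wet > 150, 13L,       # grassland block
                   22L)))                # bare ground block
    base + (abs(floor(lo) + floor(la)) %% 6L)
  })
  list(temperature = covariate_grid(temp, bb[1], bb[3], 1),
       precipitation = covariate_grid(prec, bb[1], bb[3], 1),
       landcover = covariate_grid(lc, bb[1], bb[3], 1))
}

#' Simulate a complete synthetic dataset
#'
#' Chains the generators: localities, density field (sampled at census
#' sites, truth kept at specimen localities), landmark configurations for
#' every view, and covariate grids. Sub-seeds are derived from `seed` so
#' the whole bundle is reproducible from one integer.
#'
#' @param config a [sim_config].
#' @param seed integer seed (mandatory).
#' @return list of class `"sim_dataset"`: `records`, `density`
#'   (see [simulate_density_field()]), `landmarks` (named list per view of
#'   [simulate_landmarks()] output), `grids`, `config`, `seed`.
#' @export
simulate_hyena_dataset <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  records <- simulate_localities(config, seed = seed)
  density <- simulate_density_field(config, seed = seed + 1L,
                                    query_lon = records$lon,
                                    query_lat = records$lat)
  landmarks <- list()
  for (vi in seq_along(config$views)) {
    v <- names(config$views)[vi]
    landmarks[[v]] <- simulate_landmarks(config, records,
                                         density$class_true, view = v,
                                         seed = seed + 1L + vi)
  }
  structure(list(records = records, density = density,
                 landmarks = landmarks,
                 grids = simulate_covariate_grids(config),
                 config = config, seed = seed),
            class = "sim_dataset")
}

#' Write a synthetic dataset to disk in interchange formats
#'
#' Emits exactly the formats the readers consume -- TPS per view, CSV
#' specimen and slider tables, CSV density samples, ASCII grids -- making
#' the generator double as a compatibility test of the readers.
#'
#' @param dataset a [simulate_hyena_dataset()] result.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (v in names(dataset$landmarks)) {
    p <- file.path(dir, paste0(v, ".tps"))
    write_tps(dataset$landmarks[[v]]$configs, p)
    paths[[paste0("tps_", v)]] <- p
    ps <- file.path(dir, paste0(v, "_sliders.csv"))
    utils::write.csv(as.data.frame(dataset$landmarks[[v]]$template$sliders),
                     ps, row.names = FALSE)
    paths[[paste0("sliders_", v)]] <- ps
  }
  sp <- file.path(dir, "specimens.csv")
  utils::write.csv(dataset$records[c("specimen_id", "sex", "year",
                                     "country", "lon", "lat")],
                   sp, row.names = FALSE)
  paths$specimens <- sp
  dp <- file.path(dir, "density_samples.csv")
  utils::write.csv(dataset$density$samples, dp, row.names = FALSE)
  paths$density_samples <- dp
  for (g in names(dataset$grids)) {
    gp <- file.path(dir, paste0(g, ".asc"))
    write_ascii_grid(dataset$grids[[g]], gp)
    paths[[paste0("grid_", g)]] <- gp
  }
  invisible(paths)
}
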