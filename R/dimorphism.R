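#' Geographic region scheme
#'
#' Deterministic assignment of specimens to the three African regions used
#' in the dimorphism analysis. The published verbal boundaries (the Nile
#' and the East African lake system) are not machine-readable, so the
#' default scheme is a pair of half-plane rules -- southern below
#' `lat_south`, then eastern/western split at `lon_split` -- plus an
#' optional per-country override table, and an exclusion rule for
#' geographically isolated specimens (nearest neighbor farther than
#' `exclude_nn_km`). The whole scheme is user-replaceable; determinism is
#' preferred over cartographic fidelity.
#'
#' @param lon_split meridian separating eastern from western (default 29
#'   degrees E, approximating the Nile / western-rift line).
#' @param lat_south parallel separating southern (default -12 degrees,
#'   approximating the southern end of the lake system).
#' @param country_overrides named character vector: country -> region.
#' @param exclude_nn_km exclude specimens whose nearest neighbor is
#'   farther than this (default 2000 km).
#' @return object of class `"region_scheme"`.
#' @export
region_scheme <- function(lon_split = 29, lat_south = -12,
                          country_overrides = character(),
                          exclude_nn_km = 2000) {
  structure(list(lon_split = lon_split, lat_south = lat_south,
                 country_overrides = country_overrides,
                 exclude_nn_km = exclude_nn_km),
            class = "region_scheme")
}

#' Assign specimens to geographic regions
#'
#' Applies a [region_scheme] to a specimen table: country overrides first,
#' then the half-plane rules. Specimens whose nearest-neighbor
#' great-circle distance exceeds the scheme's exclusion threshold are
#' flagged `excluded` (with the distance recorded) rather than assigned --
#' the treatment given to a single isolated West-African specimen in the
#' source analysis.
#'
#' @param specimens data.frame with `lon`, `lat`, `country` columns.
#' @param scheme a [region_scheme] (default scheme if omitted).
#' @return the input with columns `region` (factor `eastern`, `western`,
#'   `southern`, `excluded`) and `nn_km` appended.
#' @export
assign_region <- function(specimens, scheme = region_scheme()) {
  stopifnot(inherits(scheme, "region_scheme"))
  lon <- specimens$lon; lat <- specimens$lat
  region <- ifelse(lat <= scheme$lat_south, "southern",
                   ifelse(lon >= scheme$lon_split, "eastern", "western"))
  if (length(scheme$country_overrides)) {
    hit <- specimens$country %in% names(scheme$country_overrides)
    region[hit] <- scheme$country_overrides[specimens$country[hit]]
  }
  nn <- nearest_neighbor_km(lon, lat)
  region[nn > scheme$exclude_nn_km] <- "excluded"
  specimens$region <- factor(region, levels = c("eastern", "western",
                                                "southern", "excluded"))
  specimens$nn_km <- nn
  specimens
}

#' Sexual-size-dimorphism ratio
#'
#' `ratio = mean(CS female) / mean(CS male)` for one skull view within one
#' scope (total sample or one region). Unknown-sex specimens are excluded
#' from the ratio but counted in the scope's n. A Welch two-sample t test
#' on log centroid size accompanies the ratio as a supplementary
#' comparison (the headline significance of sex in the source analysis
#' comes from the full regression, not from this test). If either sex
#' class is empty the ratio is returned as `NA` with a reason, never an
#' error -- small regional cells are expected.
#'
#' @param specimens data.frame with `sex`, `region` and a centroid-size
#'   column.
#' @param size_col name of the centroid-size column (default
#'   `"centroid_size"`).
#' @param scope `"total"` or one of the region levels.
#' @return list with `ratio`, `mean_female`, `mean_male`, `n_female`,
#'   `n_male`, `n_scope`, `mean`, `sd`, `welch_p`, `scope`, `note`.
#' @export
dimorphism_ratio <- function(specimens, size_col = "centroid_size",
                             scope = "total") {
  dat <- specimens[!is.na(specimens[[size_col]]), ]
  if (scope != "total") {
    if (!"region" %in% names(dat))
      stop("scoped ratios need a 'region' column (see assign_region())")
    dat <- dat[!is.na(dat$region) & dat$region == scope, ]
  } else if ("region" %in% names(dat)) {
    dat <- dat[is.na(dat$region) | dat$region != "excluded", ]
  }
  cs <- dat[[size_col]]
  f <- cs[dat$sex == "female"]; m <- cs[dat$sex == "male"]
  out <- list(scope = scope, mean = mean(cs), sd = stats::sd(cs),
              n_scope = length(cs), n_female = length(f),
              n_male = length(m),
              mean_female = if (length(f)) mean(f) else NA_real_,
              mean_male = if (length(m)) mean(m) else NA_real_,
              ratio = NA_real_, welch_p = NA_real_, note = "")
  if (!length(f) || !length(m)) {
    out$note <- "ratio undefined: empty sex class in scope"
    return(out)
  }
  out$ratio <- mean(f) / mean(m)
  if (length(f) >= 2 && length(m) >= 2)
    out$welch_p <- tryCatch(stats::t.test(log(f), log(m))$p.value,
                            error = function(e) NA_real_)
  out
}

#' Dimorphism summary table
#'
#' Applies [dimorphism_ratio()] over all scopes (total plus each region)
#' and views, mirroring the published summary layout: mean centroid size,
#' SD, n, female/male ratio and per-sex sample sizes.
#'
#' @param specimens data.frame with `sex`, `region` and one centroid-size
#'   column per view named `cs_<view>`.
#' @param views character vector of view names.
#' @return data.frame with columns `scope`, `view`, `mean`, `sd`, `n`,
#'   `ratio`, `n_female`, `n_male`.
#' @export
dimorphism_table <- function(specimens,
                             views = c("ventral", "lateral_cranium",
                                       "lateral_mandible")) {
  scopes <- c("total", "western", "eastern", "southern")
  rows <- list()
  for (sc in scopes) for (v in views) {
    col <- paste0("cs_", v)
    if (!col %in% names(specimens)) next
    r <- dimorphism_ratio(specimens, size_col = col, scope = sc)
    rows[[length(rows) + 1L]] <-
      data.frame(scope = sc, view = v, mean = r$mean, sd = r$sd,
                 n = r$n_scope, ratio = r$ratio,
                 n_female = r$n_female, n_male = r$n_male)
  }
  do.call(rbind, rows)
}
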