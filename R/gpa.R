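#' Generalized Procrustes superimposition
#'
#' Iterative generalized least-squares Procrustes alignment of a set of 2D
#' landmark configurations: each configuration is centered, scaled to unit
#' centroid size, and rotated onto the current consensus by the 2D
#' orthogonal Procrustes solution constrained to proper rotations
#' (determinant +1 -- photographs of skulls have fixed chirality, so
#' reflections are never admitted); the consensus is then recomputed and
#' the cycle repeats until its root-mean-square change falls below `tol`.
#'
#' Physical centroid sizes (image centroid size times the stored scale
#' factor) are recorded *before* the unit-size normalization; they are the
#' size variable carried through all downstream models.
#'
#' @param configs list of [landmark_config] objects with identical landmark
#'   counts, all of the same view.
#' @param max_iter maximum consensus updates (default 100).
#' @param tol convergence tolerance on the RMS consensus change
#'   (default 1e-8).
#' @return object of class `"gpa_fit"`: list with
#'   \describe{
#'     \item{aligned}{`k x 2 x n` array of aligned unit-size coordinates}
#'     \item{consensus}{`k x 2` mean shape (centered, unit centroid size)}
#'     \item{centroid_sizes}{named numeric, physical units}
#'     \item{iterations, final_change}{convergence record}
#'     \item{specimen_ids, view, fixed}{metadata carried from the inputs}
#'   }
#' @export
gpa_align <- function(configs, max_iter = 100L, tol = 1e-8) {
  if (length(configs) < 2L)
    stop("generalized Procrustes alignment needs at least 2 configurations")
  k <- nrow(configs[[1]]$coords)
  counts <- vapply(configs, function(cf) nrow(cf$coords), integer(1))
  if (any(counts != k))
    stop("landmark counts differ across configurations: ",
         paste(unique(counts), collapse = ", "))
  n <- length(configs)
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  cs <- numeric(n)
  arr <- array(NA_real_, c(k, 2L, n))
  for (i in seq_len(n)) {
    xy <- configs[[i]]$coords
    xy <- sweep(xy, 2L, colMeans(xy))
    size <- sqrt(sum(xy^2))
    if (size == 0)
      stop("degenerate configuration '", ids[i],
           "': all landmarks coincide")
    cs[i] <- size * configs[[i]]$scale
    arr[, , i] <- xy / size
  }
  names(cs) <- ids
  consensus <- arr[, , 1L]
  it <- 0L; change <- Inf
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n))
      arr[, , i] <- rotate_onto(arr[, , i], consensus)
    new_cons <- apply(arr, c(1L, 2L), mean)
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    change <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (change < tol) break
  }
  if (change >= tol)
    warning("GPA did not converge in ", max_iter,
            " iterations (last change ", format(change), ")")
  structure(list(aligned = arr, consensus = consensus,
                 centroid_sizes = cs, iterations = it,
                 final_change = change, specimen_ids = ids,
                 view = configs[[1]]$view,
                 fixed = configs[[1]]$fixed),
            class = "gpa_fit")
}

# optimal proper rotation of centered configuration x onto target y:
# closed form for 2D, maximizing tr(t(y) %*% x %*% R) over rotations.
rotate_onto <- function(x, y) {
  a <- sum(x * y)                                   # cos component
  b <- sum(x[, 1] * y[, 2] - x[, 2] * y[, 1])       # sin component
  r <- sqrt(a * a + b * b)
  if (r == 0) return(x)                             # orientation undefined
  cth <- a / r; sth <- b / r
  cbind(cth * x[, 1] - sth * x[, 2],
        sth * x[, 1] + cth * x[, 2])
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes fit: ", dim(x$aligned)[3], " specimens, ",
      dim(x$aligned)[1], " landmarks (", x$view, ")\n", sep = "")
  cat("  converged in ", x$iterations, " iterations (final change ",
      format(x$final_change, digits = 3), ")\n", sep = "")
  cat("  centroid size range: ",
      paste(format(range(x$centroid_sizes), digits = 6), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' Per-specimen centroid-size table from a Procrustes fit
#'
#' @param fit a [gpa_align()] result.
#' @return data.frame with columns `specimen_id`, `view`, `centroid_size`.
#' @export
centroid_size_table <- function(fit) {
  data.frame(specimen_id = fit$specimen_ids, view = fit$view,
             centroid_size = unname(fit$centroid_sizes),
             stringsAsFactors = FALSE)
}
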