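#' Thin-plate-spline bending-energy system
#'
#' Builds the standard 2D thin-plate-spline system for a reference shape:
#' the kernel matrix `K` with entries `U(r) = r^2 log(r^2)` on
#' inter-landmark distances (0 on the diagonal), bordered by the affine
#' block `Q = [1 | x | y]`, and the bending-energy matrix `Be` -- the
#' upper-left `k x k` block of the inverse of the bordered matrix. The
#' quadratic form `v' Be v` applied to target coordinates measures the
#' non-affine part of the deformation from the reference to the target:
#' it is exactly zero for any affine map of the reference.
#'
#' @param reference `k x 2` matrix (k >= 4, not all collinear).
#' @return object of class `"bending_energy_system"`: list with `reference`,
#'   `K` (kernel), `Be` (bending-energy matrix, symmetrized).
#' @export
bending_energy_matrix <- function(reference) {
  reference <- as.matrix(reference)
  k <- nrow(reference)
  if (k < 4L)
    stop("bending energy needs at least 4 reference landmarks")
  d2 <- as.matrix(stats::dist(reference))^2
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Li <- tryCatch(solve(L), error = function(e)
    stop("singular thin-plate-spline system: reference landmarks are ",
         "collinear or coincident"))
  Be <- Li[seq_len(k), seq_len(k), drop = FALSE]
  Be <- (Be + t(Be)) / 2
  structure(list(reference = reference, K = K, Be = Be),
            class = "bending_energy_system")
}

#' Bending energy of a deformation
#'
#' Evaluates the thin-plate-spline bending energy of the deformation taking
#' the system's reference shape onto `target`, summed over the x and y
#' coordinate fields: `sum_d t(v_d) Be v_d`. Because `Be` annihilates
#' affine fields, translation, rotation, scaling and shear of the reference
#' all yield zero.
#'
#' @param system a [bending_energy_matrix()] result.
#' @param target `k x 2` matrix of target coordinates.
#' @return non-negative scalar (up to numerical round-off).
#' @export
bending_energy <- function(system, target) {
  target <- as.matrix(target)
  if (!all(dim(target) == dim(system$reference)))
    stop("target dimensions do not match the reference")
  sum(diag(t(target) %*% system$Be %*% target))
}

#' Slide semilandmarks to minimize bending energy
#'
#' Removes the nuisance positional parameter of semilandmarks after an
#' initial Procrustes superimposition. Each pass: (1) the bending-energy
#' system of the current consensus is built; (2) for every specimen, each
#' semilandmark is displaced along its local tangent direction -- the chord
#' between its `before` and `after` neighbors in that specimen -- by the
#' amounts that minimize the bending energy of the deformation from the
#' consensus (a closed-form generalized-least-squares step, exact for this
#' quadratic criterion, so energy can only decrease within the pass);
#' (3) the superimposition is re-run and the consensus updated. Passes
#' repeat until the relative change in total bending energy drops below
#' `tol` or `max_iter` passes have run.
#'
#' @param fit a [gpa_align()] result.
#' @param sliders a [slider_table]; indices refer to the landmark order of
#'   the fitted configurations.
#' @param max_iter maximum sliding passes (default 10).
#' @param tol relative tolerance on the total bending energy change
#'   between passes (default 1e-6).
#' @param gpa_tol tolerance passed to the embedded re-superimpositions.
#' @return a `"gpa_fit"` augmented with `energy_trace`: a data.frame with
#'   one row per pass giving the total bending energy before and after
#'   sliding (both measured against that pass's consensus).
#' @export
slide_semilandmarks <- function(fit, sliders, max_iter = 10L, tol = 1e-6,
                                gpa_tol = 1e-8) {
  stopifnot(inherits(fit, "gpa_fit"))
  if (!nrow(sliders)) return(fit)
  k <- dim(fit$aligned)[1]; n <- dim(fit$aligned)[3]
  idx <- unlist(sliders[c("before", "slider", "after")], use.names = FALSE)
  if (any(idx < 1L | idx > k))
    stop("slider index out of range")
  if (!is.null(fit$fixed)) {
    bad <- sliders$slider[fit$fixed[sliders$slider]]
    if (length(bad))
      stop("landmark(s) ", paste(bad, collapse = ", "),
           " are flagged fixed but appear as sliders")
  }
  arr <- fit$aligned
  consensus <- fit$consensus
  m <- nrow(sliders)
  trace_pre <- trace_post <- numeric(0)
  prev_energy <- Inf
  for (pass in seq_len(max_iter)) {
    bes <- bending_energy_matrix(consensus)
    pre <- sum(vapply(seq_len(n), function(i)
      bending_energy(bes, arr[, , i]), numeric(1)))
    for (i in seq_len(n)) {
      xy <- arr[, , i]
      tan <- xy[sliders$after, , drop = FALSE] -
        xy[sliders$before, , drop = FALSE]
      len <- sqrt(rowSums(tan^2))
      if (any(len == 0))
        stop("zero-length tangent: slider neighbors coincide for specimen '",
             fit$specimen_ids[i], "'")
      tan <- tan / len
      # Ux, Uy: k x m selection of tangent components at slider rows
      Ux <- matrix(0, k, m); Uy <- matrix(0, k, m)
      Ux[cbind(sliders$slider, seq_len(m))] <- tan[, 1]
      Uy[cbind(sliders$slider, seq_len(m))] <- tan[, 2]
      A <- t(Ux) %*% bes$Be %*% Ux + t(Uy) %*% bes$Be %*% Uy
      b <- -(t(Ux) %*% bes$Be %*% xy[, 1] + t(Uy) %*% bes$Be %*% xy[, 2])
      tvec <- tryCatch(solve(A, b), error = function(e)
        solve(A + diag(1e-12, m), b))
      xy[sliders$slider, 1] <- xy[sliders$slider, 1] + tan[, 1] * tvec
      xy[sliders$slider, 2] <- xy[sliders$slider, 2] + tan[, 2] * tvec
      arr[, , i] <- xy
    }
    post <- sum(vapply(seq_len(n), function(i)
      bending_energy(bes, arr[, , i]), numeric(1)))
    trace_pre <- c(trace_pre, pre); trace_post <- c(trace_post, post)
    # re-superimpose the slid configurations
    cfgs <- lapply(seq_len(n), function(i)
      landmark_config(arr[, , i], fit$specimen_ids[i], view = fit$view,
                      scale = 1, fixed = fit$fixed))
    refit <- gpa_align(cfgs, tol = gpa_tol)
    arr <- refit$aligned
    consensus <- refit$consensus
    if (is.finite(prev_energy) &&
        abs(prev_energy - post) <= tol * max(prev_energy, .Machine$double.eps))
      break
    prev_energy <- post
  }
  fit$aligned <- arr
  fit$consensus <- consensus
  fit$energy_trace <- data.frame(pass = seq_along(trace_pre),
                                 energy_before = trace_pre,
                                 energy_after = trace_post)
  fit$sliding_passes <- length(trace_pre)
  fit
}
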