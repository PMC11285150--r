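#' AIC subset selection of the spatial component
#'
#' Finds the subset of candidate trend-surface terms minimizing the
#' Gaussian AIC of the OLS regression of centroid size on those terms
#' (plus intercept). No hierarchy/marginality constraint is imposed: the
#' interaction monomials compete on their own, so a model may retain
#' `X2Y3` without `X2` or `Y3`. The empty subset (intercept only) is a
#' legal winner for pure-noise responses.
#'
#' With at most `exhaustive_limit` candidates every subset is enumerated
#' (`2^m` fits via the QR of each submatrix); beyond the limit a
#' bidirectional stepwise search is started from both the null and the
#' global model and the better endpoint is taken, with the strategy
#' recorded on the result. Ties in AIC are broken toward fewer terms, then
#' lexicographically by term names.
#'
#' @param candidates numeric matrix of candidate columns
#'   (see [trend_design()]).
#' @param response centroid sizes.
#' @param exhaustive_limit largest candidate count for exhaustive search
#'   (default 15, i.e. 32768 fits).
#' @return object of class `"trend_selection"`: list with `selected`
#'   (character vector of term names), `aic`, `strategy`
#'   (`"exhaustive"` or `"stepwise"`), `candidates`, `global_aic`.
#' @export
select_spatial_model <- function(candidates, response,
                                 exhaustive_limit = 15L) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("term", seq_len(ncol(X)))
  m <- ncol(X)
  y <- response
  global_aic <- aic_of_subset(X, y)
  if (m <= exhaustive_limit) {
    strategy <- "exhaustive"
    best <- list(aic = aic_of_subset(X[, 0, drop = FALSE], y),
                 sel = integer(0))
    for (code in seq_len(2^m - 1L)) {
      sel <- which(bitwAnd(code, 2^(seq_len(m) - 1L)) > 0L)
      a <- aic_of_subset(X[, sel, drop = FALSE], y)
      if (a < best$aic - 1e-10 ||
          (abs(a - best$aic) <= 1e-10 && better_tie(sel, best$sel, colnames(X))))
        best <- list(aic = a, sel = sel)
    }
    sel <- best$sel; aic <- best$aic
  } else {
    strategy <- "stepwise"
    from_null <- stepwise_search(X, y, integer(0))
    from_global <- stepwise_search(X, y, seq_len(m))
    pick <- if (from_null$aic <= from_global$aic) from_null else from_global
    sel <- pick$sel; aic <- pick$aic
  }
  structure(list(selected = colnames(X)[sel], aic = aic,
                 strategy = strategy, candidates = colnames(X),
                 global_aic = global_aic),
            class = "trend_selection")
}

# tie-break: fewer terms, then lexicographic on the name vector
better_tie <- function(sel_new, sel_old, nm) {
  if (length(sel_new) != length(sel_old))
    return(length(sel_new) < length(sel_old))
  a <- paste(nm[sel_new], collapse = "|")
  b <- paste(nm[sel_old], collapse = "|")
  a < b
}

# bidirectional (add/drop) AIC descent from a starting subset
stepwise_search <- function(X, y, sel) {
  m <- ncol(X)
  aic <- aic_of_subset(X[, sel, drop = FALSE], y)
  repeat {
    moves <- list()
    for (j in setdiff(seq_len(m), sel))
      moves[[length(moves) + 1L]] <- list(sel = sort(c(sel, j)))
    for (j in sel)
      moves[[length(moves) + 1L]] <- list(sel = setdiff(sel, j))
    if (!length(moves)) break
    aics <- vapply(moves, function(mv)
      aic_of_subset(X[, mv$sel, drop = FALSE], y), numeric(1))
    best <- which.min(aics)
    if (aics[best] < aic - 1e-10) {
      aic <- aics[best]; sel <- moves[[best]]$sel
    } else break
  }
  list(sel = sel, aic = aic)
}

#' @export
print.trend_selection <- function(x, ...) {
  cat("Spatial model selection (", x$strategy, "): ",
      length(x$selected), " of ", length(x$candidates),
      " terms retained\n", sep = "")
  cat("  selected: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n", sep = "")
  cat(sprintf("  AIC %.3f (global model %.3f)\n", x$aic, x$global_aic))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, where `R2_j` comes from regressing column `j`
#' on all other columns (with intercept). Perfectly collinear columns are
#' reported as `Inf`. When `groups` is supplied (a factor mapping columns
#' to model terms, e.g. the dummy columns of one factor), the generalized
#' VIF of each group is computed from correlation-matrix determinants and
#' reported together with `GVIF^(1/(2 df))`, the df-adjusted value
#' comparable across terms of different dimension.
#'
#' @param design numeric matrix or data.frame of predictor columns
#'   (no intercept column).
#' @param groups optional factor/character of length `ncol(design)`.
#' @return without `groups`: named numeric vector of VIFs. With `groups`:
#'   data.frame with columns `term`, `gvif`, `df`, `gvif_adj`.
#' @export
vif <- function(design, groups = NULL) {
  X <- as.matrix(design)
  if (ncol(X) < 2L)
    stop("VIF needs at least 2 predictor columns")
  if (is.null(groups)) {
    out <- vapply(seq_len(ncol(X)), function(j) {
      fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      rss <- sum(fit$residuals^2)
      tss <- sum((X[, j] - mean(X[, j]))^2)
      if (rss <= tss * 1e-12) Inf else 1 / (rss / tss)
    }, numeric(1))
    names(out) <- colnames(X)
    return(out)
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(X))
    stop("'groups' must map every design column to a term")
  R <- stats::cor(X)
  detR <- det(R)
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    i <- which(groups == g)
    gvif <- det(R[i, i, drop = FALSE]) *
      det(R[-i, -i, drop = FALSE]) / detR
    data.frame(term = g, gvif = gvif, df = length(i),
               gvif_adj = gvif^(1 / (2 * length(i))))
  }))
  rownames(out) <- NULL
  out
}

#' Backward stepwise AIC reduction of a fitted size model
#'
#' Iteratively removes the single droppable term whose removal most
#' decreases the AIC, refitting after each removal, until no single
#' removal lowers AIC. Only spatial polynomial terms are droppable: the
#' biological and environmental terms (sex, temperature, precipitation,
#' density class, land cover) are protected and never enter the reduction
#' path -- multicollinearity among high-order geographic monomials is the
#' problem this step exists to address.
#'
#' @param design data.frame used to fit the full model.
#' @param response centroid sizes.
#' @param protected character vector of column names that may not be
#'   dropped.
#' @return list with `model` (the reduced [fit_ols()] fit), `path`
#'   (character vector of dropped terms in order; empty if the input was
#'   already AIC-minimal), `aic_path` (AIC after each drop, starting with
#'   the full model).
#' @export
backward_stepwise_aic <- function(design, response, protected = character()) {
  design <- as.data.frame(design)
  unknown <- setdiff(protected, names(design))
  if (length(unknown))
    stop("protected term(s) not in design: ", paste(unknown, collapse = ", "))
  current <- names(design)
  model <- fit_ols(design[current], response)
  path <- character(0)
  aic_path <- model$aic
  repeat {
    droppable <- setdiff(current, protected)
    if (!length(droppable)) break
    trial_aic <- vapply(droppable, function(tm)
      fit_ols(design[setdiff(current, tm)], response)$aic, numeric(1))
    best <- which.min(trial_aic)
    if (trial_aic[best] < model$aic - 1e-10) {
      current <- setdiff(current, droppable[best])
      path <- c(path, droppable[best])
      model <- fit_ols(design[current], response)
      aic_path <- c(aic_path, model$aic)
    } else break
  }
  list(model = model, path = path, aic_path = aic_path)
}
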