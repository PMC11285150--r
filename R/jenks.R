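#' Jenks natural-breaks classification
#'
#' Optimal 1-D classification: partitions the sorted values into `k`
#' contiguous classes minimizing the total within-class sum of squared
#' deviations, by the Fisher-Jenks dynamic program. Deterministic; ties in
#' cost are resolved by the dynamic program's canonical (left-most split)
#' solution.
#'
#' Breaks are reported GIS-style as data values: the minimum followed by
#' the maximum of each class, so `length(breaks) == k + 1` and value `v`
#' belongs to class `j` when `breaks[j] < v <= breaks[j + 1]` (lowest class
#' closed on the left).
#'
#' @param values numeric vector, `length(values) >= k`.
#' @param k number of classes.
#' @return object of class `"jenks_breaks"`: list with `breaks` (length
#'   k + 1), `k`, and `within_ss` (optimal total within-class SS).
#' @export
jenks_breaks <- function(values, k) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (k < 1L) stop("'k' must be at least 1")
  if (k > n) stop("more classes (", k, ") than values (", n, ")")
  # prefix sums for O(1) segment costs
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {  # within-SS of x[i..j], vectorized over i
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    len <- j - i + 1
    s2 - s^2 / len
  }
  # dp[m, j]: optimal cost of splitting x[1..j] into m classes
  dp <- matrix(Inf, k, n)
  split_at <- matrix(0L, k, n)
  dp[1, ] <- vapply(seq_len(n), function(j) seg_cost(1L, j), numeric(1))
  if (k > 1L) {
    for (m in 2:k) {
      for (j in m:n) {
        i <- m:j                       # class m covers x[i..j]
        cost <- dp[m - 1, i - 1] + seg_cost(i, j)
        best <- which.min(cost)
        dp[m, j] <- cost[best]
        split_at[m, j] <- i[best]
      }
    }
  }
  # backtrack class boundaries
  uppers <- integer(k)
  j <- n
  for (m in k:1) {
    uppers[m] <- j
    j <- if (m > 1L) split_at[m, j] - 1L else 0L
  }
  structure(list(breaks = c(x[1], x[uppers]), k = k,
                 within_ss = dp[k, n]),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat("Jenks natural breaks (k = ", x$k, "): ",
      paste(format(x$breaks, digits = 6), collapse = " | "),
      "\n  within-class SS = ", format(x$within_ss, digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' Assign values to Jenks classes
#'
#' @param values numeric vector.
#' @param breaks a [jenks_breaks] object (or a sorted numeric vector of
#'   k + 1 break values).
#' @return integer class indices in `1..k`.
#' @export
jenks_classify <- function(values, breaks) {
  b <- if (inherits(breaks, "jenks_breaks")) breaks$breaks else breaks
  cls <- findInterval(values, b, rightmost.closed = TRUE,
                      left.open = TRUE)
  cls[values <= b[1]] <- 1L
  cls[values > b[length(b)]] <- length(b) - 1L
  cls
}

#' Two-class density categorization
#'
#' Classifies interpolated population densities at specimen localities into
#' four Jenks classes, then collapses the upper three into a single `high`
#' class, keeping the lowest as `low` -- the reduction used when only the
#' lowest-density category shows a relationship with size. Reports the
#' value ranges and member counts of the two classes.
#'
#' @param density interpolated density for every specimen (> 0).
#' @return object of class `"density_classification"`: list with
#'   `class` (factor `low`/`high` per value, reference level `low`),
#'   `boundary` (upper edge of the low class), `jenks` (the k = 4 fit),
#'   `low_range`, `high_range`, `counts`.
#' @export
categorize_density <- function(density) {
  if (any(!is.finite(density)))
    stop("non-finite density value(s)")
  if (length(unique(density)) < 4L)
    stop("too few distinct density values for a 4-class Jenks split")
  jb <- jenks_breaks(density, 4L)
  cls4 <- jenks_classify(density, jb)
  cls <- factor(ifelse(cls4 == 1L, "low", "high"),
                levels = c("low", "high"))
  structure(list(class = cls, boundary = jb$breaks[2], jenks = jb,
                 low_range = range(density[cls == "low"]),
                 high_range = range(density[cls == "high"]),
                 counts = table(cls)),
            class = "density_classification")
}

#' @export
print.density_classification <- function(x, ...) {
  cat("Density classes (Jenks k = 4 reduced to 2):\n")
  cat(sprintf("  low : %.4g to %.4g (n = %d)\n", x$low_range[1],
              x$low_range[2], x$counts[["low"]]))
  cat(sprintf("  high: %.4g to %.4g (n = %d)\n", x$high_range[1],
              x$high_range[2], x$counts[["high"]]))
  invisible(x)
}

#' Size classes for mapping
#'
#' Splits centroid sizes into `k` Jenks classes (default 3:
#' small/medium/large) and reports per-class ranges and counts -- the
#' classified point table used to map geographic size variation.
#'
#' @param sizes centroid sizes.
#' @param k number of classes (default 3).
#' @param labels class labels, lowest first.
#' @return list with `class` (ordered factor per size), `table`
#'   (data.frame: class, min, max, n), `breaks`.
#' @export
size_classes <- function(sizes, k = 3L,
                         labels = c("small", "medium", "large")) {
  if (length(unique(sizes)) < k)
    stop("fewer than ", k, " distinct size values")
  if (length(labels) != k) labels <- paste0("class", seq_len(k))
  jb <- jenks_breaks(sizes, k)
  cls <- factor(labels[jenks_classify(sizes, jb)], levels = labels,
                ordered = TRUE)
  tab <- do.call(rbind, lapply(seq_len(k), function(j) {
    v <- sizes[as.integer(cls) == j]
    data.frame(class = labels[j],
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               n = length(v))
  }))
  list(class = cls, table = tab, breaks = jb)
}
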