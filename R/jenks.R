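#' Fisher-Jenks natural breaks
#'
#' Exact dynamic-programming optimization of the k-class partition of sorted
#' values minimizing the within-class sum of squared deviations. Breaks are
#' reported as the minimum value of each upper class, so a value equal to a
#' break belongs to the upper class (the half-open convention used when
#' printing grade intervals, e.g. grade II = b1 <= v < b2). Ties in the
#' optimum are broken deterministically toward the earliest split.
#'
#' For very large inputs the DP runs on a deterministic quantile sample
#' (`max_n` evenly spaced order statistics), the standard practice of GIS
#' classifiers; results are exact whenever `length(values) <= max_n`.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of classes (default 5).
#' @param max_n exact-DP size cap; larger inputs are quantile-sampled.
#' @return A `break_set`: list `k`, `breaks` (length k-1, ascending), `min`,
#'   `max`, `within_ss`.
#' @export
jenks_breaks <- function(values, k = 5, max_n = 4000) {
  x <- sort(values[is.finite(values)])
  if (length(unique(x)) < k) {
    stop(sprintf("only %d distinct values; choose k <= %d",
                 length(unique(x)), length(unique(x))))
  }
  if (k == 1) {
    return(structure(list(k = 1L, breaks = numeric(0), min = x[1],
                          max = x[length(x)],
                          within_ss = sum((x - mean(x))^2)),
                     class = "break_set"))
  }
  if (length(x) > max_n) {
    x <- sort(unique(c(
      stats::quantile(x, probs = seq(0, 1, length.out = max_n), names = FALSE,
                      type = 1))))
  }
  n <- length(x)
  S1 <- c(0, cumsum(x)); S2 <- c(0, cumsum(x^2))
  css <- function(i, j) {  # vectorized over i, within-class SS of x[i..j]
    s <- S1[j + 1] - S1[i]; s2 <- S2[j + 1] - S2[i]; len <- j - i + 1
    pmax(s2 - s^2 / len, 0)
  }
  D <- matrix(Inf, k, n)
  Tmat <- matrix(1L, k, n)
  D[1, ] <- vapply(seq_len(n), function(j) css(1, j), numeric(1))
  if (k >= 2) {
    for (m in 2:k) {
      for (j in m:n) {
        i <- m:j
        cand <- D[m - 1, i - 1] + css(i, j)
        best <- which.min(cand)  # first minimum: deterministic tie-break
        D[m, j] <- cand[best]
        Tmat[m, j] <- i[best]
      }
    }
  }
  starts <- integer(k)
  j <- n
  for (m in k:1) {
    starts[m] <- Tmat[m, j]
    j <- starts[m] - 1L
  }
  structure(list(k = as.integer(k), breaks = x[starts[-1]],
                 min = x[1], max = x[n], within_ss = D[k, n]),
            class = "break_set")
}

#' @export
print.break_set <- function(x, ...) {
  cat(sprintf("<break_set> k = %d over [%g, %g]; breaks: %s (within-class SS %.6g)\n",
              x$k, x$min, x$max, paste(signif(x$breaks, 6), collapse = ", "),
              x$within_ss))
  invisible(x)
}

#' Assign grade classes from a break set
#'
#' Half-open assignment: grade 1 for values below the first break, grade j
#' for b_(j-1) <= v < b_j, grade k for values at or above the last break.
#'
#' @param x a `park_raster` surface or a numeric vector.
#' @param breakset a `break_set`.
#' @return For a raster input, a `grade_map` (integer `park_raster` with the
#'   break set attached); for a vector, an integer vector of grades.
#' @export
apply_grades <- function(x, breakset) {
  grade <- function(v) {
    g <- findInterval(v, breakset$breaks) + 1L
    g[!is.finite(v)] <- NA_integer_
    g
  }
  if (inherits(x, "park_raster")) {
    v <- x$values
    g <- matrix(0L, nrow(v), ncol(v))
    ok <- v != x$nodata & is.finite(v)
    g[ok] <- grade(v[ok])
    out <- park_raster(g, cell_size = x$cell_size, xll = x$xll, yll = x$yll,
                       nodata = 0L, crs_tag = x$crs_tag)
    attr(out, "break_set") <- breakset
    class(out) <- c("grade_map", class(out))
    out
  } else {
    grade(x)
  }
}
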