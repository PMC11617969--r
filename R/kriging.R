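#' Empirical semivariogram
#'
#' Classical Matheron estimator: gamma_hat(h) = mean of (v_a - v_b)^2 / 2
#' over all sample pairs whose separation falls in the lag bin. Empty bins
#' are dropped.
#'
#' @param samples data frame / tibble with columns `x`, `y`, `value`.
#' @param n_lags number of equal-width distance bins.
#' @param max_lag largest separation considered; default half the maximum
#'   pairwise distance (half the region diameter).
#' @return Tibble: `lag` (bin midpoint), `gamma` (semivariance), `n_pairs`.
#' @export
empirical_semivariogram <- function(samples, n_lags = 12, max_lag = NULL) {
  stopifnot(all(c("x", "y", "value") %in% names(samples)))
  n <- nrow(samples)
  if (n < 2) stop("need at least 2 samples for a semivariogram")
  d <- stats::dist(cbind(samples$x, samples$y))
  if (max(d) == 0) stop("all samples are coincident")
  if (is.null(max_lag)) max_lag <- max(d) / 2
  gv <- stats::dist(samples$value)^2 / 2
  keep <- d > 0 & d <= max_lag
  bin <- ceiling(as.numeric(d[keep]) / (max_lag / n_lags))
  bin[bin < 1] <- 1L
  g <- tapply(as.numeric(gv[keep]), bin, mean)
  np <- tapply(as.numeric(gv[keep]), bin, length)
  mids <- (as.numeric(names(g)) - 0.5) * (max_lag / n_lags)
  tibble::tibble(lag = mids, gamma = as.numeric(g), n_pairs = as.integer(np))
}

# variogram families: gamma(h) for h > 0; gamma(0) = 0 by definition,
# the nugget acting as a discontinuity at the origin
.vgm_gamma <- function(h, family, nugget, psill, range) {
  g <- switch(family,
    spherical = ifelse(h >= range, psill,
                       psill * (1.5 * h / range - 0.5 * (h / range)^3)),
    exponential = psill * (1 - exp(-3 * h / range)),
    gaussian = psill * (1 - exp(-3 * (h / range)^2)),
    stop("unknown variogram family: ", family)
  )
  ifelse(h > 0, nugget + g, 0)
}

#' Evaluate a variogram model
#'
#' @param model a `variogram_model` from [fit_variogram()].
#' @param h nonnegative distances.
#' @return Semivariance gamma(h); 0 at h = 0.
#' @export
variogram_gamma <- function(model, h) {
  .vgm_gamma(h, model$family, model$nugget, model$psill, model$range)
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes sum n_pairs * (gamma_hat - gamma_model)^2 over nugget, partial
#' sill and range with a bounded quasi-Newton search started from a fixed
#' deterministic grid of initial values (no randomness), keeping the best
#' converged fit. A degenerate fit (non-finite objective or collapsed range)
#' falls back to a pure-nugget model with a warning.
#'
#' @param empirical an [empirical_semivariogram()] table (>= 3 bins).
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @return A `variogram_model`: list `family`, `nugget`, `psill`, `range`,
#'   `sse`, `fallback`.
#' @export
fit_variogram <- function(empirical, family = c("spherical", "exponential", "gaussian")) {
  family <- match.arg(family)
  emp <- empirical[is.finite(empirical$gamma), ]
  if (nrow(emp) < 3) stop("need at least 3 nonempty semivariogram bins")
  w <- emp$n_pairs
  gmax <- max(emp$gamma); hmax <- max(emp$lag)
  if (gmax == 0) {
    return(structure(list(family = family, nugget = 0, psill = 0,
                          range = hmax, sse = 0, fallback = FALSE),
                     class = "variogram_model"))
  }
  obj <- function(p) {
    g <- .vgm_gamma(emp$lag, family, p[1], p[2], p[3])
    sum(w * (emp$gamma - g)^2)
  }
  lower <- c(0, 0, hmax * 1e-3)
  upper <- c(gmax * 2, gmax * 3, hmax * 3)
  starts <- expand.grid(nugget = c(0, 0.25, 0.5) * min(emp$gamma[emp$gamma > 0], gmax),
                        psill = c(0.5, 1, 1.5) * gmax,
                        range = c(0.25, 0.5, 1) * hmax)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(as.numeric(starts[s, ]), lower), upper), obj,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    warning("variogram fit degenerate; falling back to pure-nugget model")
    nug <- sum(w * emp$gamma) / sum(w)
    return(structure(list(family = family, nugget = nug, psill = 0,
                          range = hmax, sse = obj(c(nug, 0, hmax)),
                          fallback = TRUE),
                     class = "variogram_model"))
  }
  structure(list(family = family, nugget = best$par[1], psill = best$par[2],
                 range = best$par[3], sse = best$value, fallback = FALSE),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g%s\n",
              x$family, x$nugget, x$psill, x$range,
              if (isTRUE(x$fallback)) " (pure-nugget fallback)" else ""))
  invisible(x)
}

#' Ordinary kriging weights at one location
#'
#' Solves the ordinary kriging system for a target location given sample
#' coordinates: semivariance matrix among the samples, Lagrange multiplier
#' row enforcing the unbiasedness constraint sum(w) = 1.
#'
#' @param coords n x 2 matrix of sample coordinates.
#' @param target length-2 numeric target location.
#' @param model a `variogram_model`.
#' @return List `weights` (length n, summing to 1) and `lagrange`.
#' @export
ok_weights <- function(coords, target, model) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  G <- .vgm_gamma(D, model$family, model$nugget, model$psill, model$range)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- sqrt((coords[, 1] - target[1])^2 + (coords[, 2] - target[2])^2)
  b <- c(.vgm_gamma(d0, model$family, model$nugget, model$psill, model$range), 1)
  sol <- solve(A, b)
  list(weights = sol[seq_len(n)], lagrange = sol[n + 1])
}

#' Ordinary kriging to a grid
#'
#' Local-neighborhood ordinary kriging: each target cell is predicted from
#' its `neighborhood` nearest samples. A singular system first retries with
#' the doubled neighborhood, then with all samples, and finally falls back to
#' inverse-distance weighting with a warning.
#'
#' @param samples data frame with `x`, `y`, `value` (non-coincident).
#' @param model a fitted `variogram_model`.
#' @param target a `park_raster` defining the output grid.
#' @param target_mask logical matrix: cells to predict (default: all).
#' @param neighborhood number of nearest samples per prediction.
#' @return A `park_raster` (float) with predictions in the masked cells and
#'   nodata elsewhere; attributes `model` and `n_samples`.
#' @export
krige <- function(samples, model, target, target_mask = NULL, neighborhood = 16) {
  samples <- samples[is.finite(samples$value), ]
  n <- nrow(samples)
  if (n < 2) stop("need at least 2 samples to krige")
  neighborhood <- min(neighborhood, n)
  nr <- nrow(target$values); nc <- ncol(target$values)
  if (is.null(target_mask)) target_mask <- matrix(TRUE, nr, nc)
  idx <- which(target_mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  ctr <- cell_centers(target, rows, cols)
  sx <- samples$x; sy <- samples$y; sv <- samples$value
  out <- matrix(-9999, nr, nc)
  pred_one <- function(ti) {
    dx <- sx - ctr[ti, 1]; dy <- sy - ctr[ti, 2]
    d2 <- dx * dx + dy * dy
    for (k in unique(c(neighborhood, min(2 * neighborhood, n), n))) {
      nb <- order(d2)[seq_len(k)]
      w <- tryCatch(
        ok_weights(cbind(sx[nb], sy[nb]), ctr[ti, ], model)$weights,
        error = function(e) NULL)
      if (!is.null(w) && all(is.finite(w))) return(sum(w * sv[nb]))
    }
    # inverse-distance fallback
    warning("singular kriging system; inverse-distance fallback used")
    nb <- order(d2)[seq_len(neighborhood)]
    if (d2[nb[1]] == 0) return(sv[nb[1]])
    wi <- 1 / d2[nb]
    sum(wi * sv[nb]) / sum(wi)
  }
  vals <- vapply(seq_len(nrow(ctr)), pred_one, numeric(1))
  out[idx] <- vals
  surf <- park_raster(out, cell_size = target$cell_size, xll = target$xll,
                      yll = target$yll, nodata = -9999, crs_tag = target$crs_tag)
  attr(surf, "model") <- model
  attr(surf, "n_samples") <- n
  surf
}
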