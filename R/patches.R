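#' Label the patches of one land-use class
#'
#' Connected-component labeling of all cells carrying `class_code` inside a
#' region, under 8- (default, the FRAGSTATS convention) or 4-adjacency.
#' Nodata and out-of-region cells break connectivity.
#'
#' @param raster land-use `park_raster`.
#' @param region_mask logical matrix (same shape) delimiting the landscape;
#'   `NULL` means the whole raster.
#' @param class_code the class to label.
#' @param connectivity 8 or 4.
#' @return List with `class_code`, `n_patches`, `patch_cells` (integer vector
#'   of per-patch cell counts), `labels` (integer matrix, 0 = background) and
#'   `connectivity`.
#' @export
label_patches <- function(raster, region_mask = NULL, class_code,
                          connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  on <- v == class_code & v != raster$nodata
  if (!is.null(region_mask)) on <- on & region_mask
  labels <- matrix(0L, nr, nc)
  idx <- which(on)
  if (!length(idx)) {
    return(list(class_code = class_code, n_patches = 0L,
                patch_cells = integer(0), labels = labels,
                connectivity = connectivity))
  }
  # vertex per foreground cell; edges between adjacent foreground cells
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))             # S, E
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))  # SE, SW
  efrom <- integer(0); eto <- integer(0)
  for (s in shifts) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- vid[j] > 0L
    efrom <- c(efrom, vid[idx[ok]][hit])
    eto <- c(eto, vid[j][hit])
  }
  g <- igraph::make_graph(rbind(efrom, eto), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(class_code = class_code, n_patches = comp$no,
       patch_cells = as.integer(comp$csize), labels = labels,
       connectivity = connectivity)
}

# isolation index N_i, isolated so alternative readings can be swapped in:
# N_i = (A / (2 * A_i)) * sqrt(n_i / A), dimensionless when areas share units
isolation_index <- function(n_i, A_i, A) (A / (2 * A_i)) * sqrt(n_i / A)

#' Per-class landscape metrics
#'
#' For every land-use class occurring in the region, computes the patch count
#' n_i, class area A_i, patch-number share M_i, area share L_i, fragmentation
#' C_i = n_i / A_i (patches per km^2), isolation
#' N_i = (A / 2 A_i) * sqrt(n_i / A), dominance D_i = (M_i + L_i) / 2, and the
#' disturbance index S_i = a C_i + b N_i + c D_i.
#'
#' The default scope is landscape-global: one metric row per class over the
#' whole region, so per-unit risk variation downstream comes from unit
#' composition. Weights default to (0.6, 0.3, 0.1), loading fragmentation
#' most heavily as the primary imprint of human disturbance.
#'
#' @param raster land-use `park_raster`.
#' @param region_mask logical matrix delimiting the landscape (e.g. the core
#'   protected area); `NULL` = whole raster.
#' @param catalog a `park_catalog`.
#' @param connectivity patch adjacency, 8 (default) or 4.
#' @param weights numeric (a, b, c) for C, N, D.
#' @param normalize_cnd min-max normalize C, N, D across classes before
#'   weighting (off by default; the plain weighted sum is the literal index).
#' @return Tibble: `code`, `name`, `n_i`, `A_i_km2`, `M_i`, `L_i`, `C_i`,
#'   `N_i`, `D_i`, `S_i`, plus attribute `landscape_area_km2`.
#' @export
class_metrics <- function(raster, region_mask = NULL, catalog,
                          connectivity = 8, weights = c(0.6, 0.3, 0.1),
                          normalize_cnd = FALSE) {
  stopifnot(length(weights) == 3)
  v <- raster$values
  region <- if (is.null(region_mask)) v != raster$nodata else
    region_mask & v != raster$nodata
  if (!any(region)) stop("region is empty: no non-nodata cells to measure")
  ca <- cell_area_km2(raster)
  A <- sum(region) * ca
  codes <- sort(unique(v[region]))
  n_i <- integer(length(codes)); A_i <- numeric(length(codes))
  for (j in seq_along(codes)) {
    lab <- label_patches(raster, region, codes[j], connectivity)
    n_i[j] <- lab$n_patches
    A_i[j] <- sum(lab$patch_cells) * ca
  }
  M_i <- n_i / sum(n_i)
  L_i <- A_i / A
  C_i <- n_i / A_i
  N_i <- isolation_index(n_i, A_i, A)
  D_i <- (M_i + L_i) / 2
  if (normalize_cnd) {
    mm <- function(x) if (diff(range(x)) == 0) rep(0, length(x)) else
      (x - min(x)) / diff(range(x))
    S_i <- weights[1] * mm(C_i) + weights[2] * mm(N_i) + weights[3] * mm(D_i)
  } else {
    S_i <- weights[1] * C_i + weights[2] * N_i + weights[3] * D_i
  }
  out <- tibble::tibble(
    code = codes,
    name = catalog$classes$name[match(codes, catalog$classes$code)],
    n_i = n_i, A_i_km2 = A_i, M_i = M_i, L_i = L_i,
    C_i = C_i, N_i = N_i, D_i = D_i, S_i = S_i
  )
  attr(out, "landscape_area_km2") <- A
  attr(out, "connectivity") <- connectivity
  attr(out, "weights") <- weights
  out
}
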