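#' Synthetic land-use landscapes (modified random clusters)
#'
#' Neutral-landscape generator producing categorical rasters with
#' controllable patchiness, emulating the structure the zoning analysis
#' assumes: a forest-dominated matrix with clumped minority classes and
#' optional fragmentation hot-spots. The procedure is the modified
#' random-clusters algorithm: (1) Bernoulli(p) site percolation marks cells;
#' (2) marked cells are clustered by 4-adjacency; (3) clusters are assigned
#' to classes by filling area quotas proportional to the target composition
#' (largest-deficit first, in seeded random cluster order); (4) unmarked
#' cells take the class of their nearest assigned cell (iterative neighbor
#' majority), which preserves clump geometry. With p = 0 the raster is
#' i.i.d. multinomial.
#'
#' @param n_rows,n_cols raster dimensions.
#' @param cell_size cell side, meters.
#' @param proportions named numeric vector of target class proportions
#'   (names = class codes); must sum to 1.
#' @param clumping percolation probability p in [0, 1); larger values give
#'   larger, fewer patches. Values near or above the percolation threshold
#'   (~0.59) merge everything into one cluster.
#' @param hotspots optional list of fragmentation pockets, each a list with
#'   `row`, `col`, `radius` (cells), `classes` (codes scattered in the
#'   pocket) and `density` (fraction of pocket cells converted).
#' @param seed integer seed; the generator is deterministic given it.
#' @return An integer land-use `park_raster`.
#' @export
generate_landscape <- function(n_rows = 240, n_cols = 240, cell_size = 100,
                               proportions = default_proportions(),
                               clumping = 0.5, hotspots = NULL, seed = 1) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9, clumping >= 0, clumping < 1)
  codes <- as.integer(names(proportions))
  out <- withr_seed(seed, {
    n <- n_rows * n_cols
    cls <- matrix(0L, n_rows, n_cols)
    if (clumping == 0) {
      cls[] <- sample(codes, n, replace = TRUE, prob = proportions)
    } else {
      marked <- matrix(stats::runif(n) < clumping, n_rows, n_cols)
      if (any(marked)) {
        lab <- label_patches(park_raster(matrix(1L, n_rows, n_cols), cell_size),
                             marked, 1L, connectivity = 4)
        memb <- lab$labels
        sizes <- lab$patch_cells
        ord <- sample.int(lab$n_patches)
        # quota fill: assign each cluster to the class with largest deficit
        target <- proportions * sum(sizes)
        got <- stats::setNames(numeric(length(codes)), names(proportions))
        assign_cls <- integer(lab$n_patches)
        for (ci in ord) {
          deficit <- target - got
          pick <- which.max(deficit)
          assign_cls[ci] <- codes[pick]
          got[pick] <- got[pick] + sizes[ci]
        }
        cls[memb > 0] <- assign_cls[memb[memb > 0]]
      }
      # single majority-vote pass from the typed clusters; cells with no
      # typed neighbor get i.i.d. classes, so sparse percolation maps stay
      # fine-grained and patchiness grows with p
      if (any(cls == 0L)) {
        holes <- which(cls == 0L)
        nr <- n_rows; ncl <- n_cols
        rows <- (holes - 1L) %% nr + 1L
        cols <- (holes - 1L) %/% nr + 1L
        votes <- matrix(0L, length(holes), 8)
        s <- 0
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          s <- s + 1
          r2 <- rows + dr; c2 <- cols + dc
          ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncl
          vals <- integer(length(holes))
          vals[ok] <- cls[(c2[ok] - 1L) * nr + r2[ok]]
          votes[, s] <- vals
        }
        any_nb <- rowSums(votes > 0) > 0
        pick_mode <- function(v) {
          v <- v[v > 0]
          tab <- table(v)
          cand <- as.integer(names(tab)[tab == max(tab)])
          if (length(cand) == 1) cand else sample(cand, 1)
        }
        if (any(any_nb)) {
          cls[holes[any_nb]] <- apply(votes[any_nb, , drop = FALSE], 1, pick_mode)
        }
        rest <- holes[!any_nb]
        if (length(rest)) {
          cls[rest] <- sample(codes, length(rest), replace = TRUE,
                              prob = proportions)
        }
      }
    }
    if (!is.null(hotspots)) {
      for (h in hotspots) {
        rr <- pmax(1, h$row - h$radius):pmin(n_rows, h$row + h$radius)
        cc <- pmax(1, h$col - h$radius):pmin(n_cols, h$col + h$radius)
        cells <- as.matrix(expand.grid(r = rr, c = cc))
        d <- sqrt((cells[, 1] - h$row)^2 + (cells[, 2] - h$col)^2)
        cells <- cells[d <= h$radius, , drop = FALSE]
        dens <- if (is.null(h$density)) 0.5 else h$density
        hit <- stats::runif(nrow(cells)) < dens
        idx <- (cells[hit, 2] - 1L) * n_rows + cells[hit, 1]
        cls[idx] <- if (length(h$classes) == 1) rep(h$classes, length(idx)) else
          sample(h$classes, length(idx), replace = TRUE)
      }
    }
    cls
  })
  park_raster(out, cell_size = cell_size, nodata = -9999L)
}

#' Default synthetic composition
#'
#' Forest-dominated 12-class mix: arbor forest matrix with bamboo, shrub and
#' other forest, small cultivated/garden/grassland shares, and minor
#' wetland/water/building/bare fractions.
#'
#' @return Named numeric vector of proportions summing to 1 (names = codes).
#' @export
default_proportions <- function() {
  c("1" = 0.58, "2" = 0.10, "3" = 0.07, "4" = 0.05, "5" = 0.035, "6" = 0.035,
    "7" = 0.04, "8" = 0.03, "9" = 0.015, "10" = 0.02, "11" = 0.015, "12" = 0.01)
}

#' Generate a contiguous park footprint with core and general zones
#'
#' Builds a rounded, slightly irregular park footprint inside the raster and
#' splits it into a contiguous core (the innermost cells by boundary depth)
#' surrounded by the general control area, targeting the requested core
#' share of the park (matched to within a fraction of a percent by filling
#' the final erosion layer cell by cell, adjacent to the current core).
#'
#' @param raster the land-use raster to mask.
#' @param core_fraction target core share of the park footprint.
#' @param footprint_fraction approximate park share of the raster extent.
#' @param seed integer seed for the boundary irregularity.
#' @return A zone-mask `park_raster` (0 outside, 1 core, 2 general).
#' @export
generate_park_masks <- function(raster, core_fraction = 0.5182,
                                footprint_fraction = 0.87, seed = 1) {
  stopifnot(core_fraction > 0, core_fraction < 1)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  m <- withr_seed(seed + 1L, {
    # super-ellipse footprint with low-frequency radial noise
    r0 <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
    c0 <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
    R <- matrix(r0, nr, nc); C <- matrix(c0, nr, nc, byrow = TRUE)
    theta <- atan2(R, C)
    amp <- stats::runif(4, 0.02, 0.06)
    pha <- stats::runif(4, 0, 2 * pi)
    wob <- Reduce(`+`, lapply(1:4, function(i) amp[i] * cos(i * theta + pha[i])))
    rad <- (abs(R)^2.5 + abs(C)^2.5)^(1 / 2.5)
    # radius calibrated so the realized footprint share tracks the request
    # (superellipse area term x mean wobble, fitted once on the geometry)
    lim <- sqrt(footprint_fraction * 4 / pi) * 1.0496
    rad < lim * (0.92 + wob)
  })
  if (!any(m)) stop("footprint fraction infeasible for this raster")
  # boundary depth by iterative 4-erosion
  depth <- matrix(0L, nr, nc)
  cur <- m
  lev <- 0L
  while (any(cur)) {
    lev <- lev + 1L
    depth[cur] <- lev
    er <- matrix(FALSE, nr, nc)
    er[2:(nr - 1), 2:(nc - 1)] <-
      cur[2:(nr - 1), 2:(nc - 1)] &
      cur[1:(nr - 2), 2:(nc - 1)] & cur[3:nr, 2:(nc - 1)] &
      cur[2:(nr - 1), 1:(nc - 2)] & cur[2:(nr - 1), 3:nc]
    cur <- er
  }
  n_park <- sum(m)
  target_core <- core_fraction * n_park
  tab <- rev(cumsum(rev(tabulate(depth[m], nbins = max(depth)))))
  # deepest threshold whose cumulative count still exceeds the target
  t_full <- max(which(tab >= target_core)) + 1L
  core <- depth >= t_full
  shortfall <- round(target_core - sum(core))
  if (shortfall > 0) {
    ring <- which(depth == t_full - 1L)
    # grow deterministically: take ring cells closest to the park center
    rows <- (ring - 1L) %% nr + 1L; cols <- (ring - 1L) %/% nr + 1L
    d2 <- (rows - (nr + 1) / 2)^2 + (cols - (nc + 1) / 2)^2
    take <- ring[order(d2, ring)][seq_len(min(shortfall, length(ring)))]
    core[take] <- TRUE
  }
  z <- matrix(ZONE_CODES[["OUTSIDE"]], nr, nc)
  z[m] <- ZONE_CODES[["GENERAL"]]
  z[core & m] <- ZONE_CODES[["CORE"]]
  zone_mask(z, raster)
}

#' Hand-checkable fixture rasters
#'
#' Tiny named rasters (at most 10 x 10) with expectations precomputed by
#' hand, used by the test suite and by examples. The stored expectations are
#' re-derived by brute-force oracles at test time so they cannot go stale.
#'
#' @param name one of `"single-class-4km2"`, `"diag-pair"`, `"water-pocket"`,
#'   `"split-patch"`.
#' @return List `raster`, `mask`, `expected` (named list of hand-computed
#'   values; see each fixture's entry).
#' @export
fixture_raster <- function(name = c("single-class-4km2", "diag-pair",
                                    "water-pocket", "split-patch")) {
  name <- match.arg(name)
  core_mask <- function(r) {
    zone_mask(matrix(ZONE_CODES[["CORE"]], nrow(r$values), ncol(r$values)), r)
  }
  switch(name,
    # one class, one patch, A = A_i = 4 km^2 (2x2 cells of 1 km):
    # C = 1/4, N = (4/8) sqrt(1/4) = 1/4, D = 1, S = 0.6/4 + 0.3/4 + 0.1
    "single-class-4km2" = {
      r <- park_raster(matrix(1L, 2, 2), cell_size = 1000)
      list(raster = r, mask = core_mask(r),
           expected = list(C_i = 0.25, N_i = 0.25, D_i = 1, S_i = 0.325))
    },
    # two cells touching only diagonally: one patch under 8-adjacency, two under 4
    "diag-pair" = {
      v <- matrix(2L, 3, 3); v[1, 1] <- 1L; v[2, 2] <- 1L
      r <- park_raster(v, cell_size = 100)
      list(raster = r, mask = core_mask(r),
           expected = list(n_conn8 = 1L, n_conn4 = 2L))
    },
    # general-area landscape where one unit holds a water pocket: with any
    # catalog whose water coefficients exceed forest, that unit ranks first
    "water-pocket" = {
      v <- matrix(1L, 8, 8)
      v[3:4, 5:6] <- 10L
      r <- park_raster(v, cell_size = 100)
      z <- matrix(ZONE_CODES[["GENERAL"]], 8, 8)
      list(raster = r, mask = zone_mask(z, r),
           expected = list(top_unit = "r001_c002"))
    },
    # same class split into two patches in an otherwise fixed landscape:
    # doubling n_i doubles C_i and strictly increases S_i
    "split-patch" = {
      one <- matrix(2L, 4, 4); one[2:3, 2:3] <- 1L
      two <- matrix(2L, 4, 4); two[2, 2] <- 1L; two[3, 3] <- 1L
      # 4-adjacency keeps the two cells separate patches
      r1 <- park_raster(one, cell_size = 500)
      r2 <- park_raster(two, cell_size = 500)
      list(raster = r1, raster_split = r2, mask = core_mask(r1),
           expected = list(connectivity = 4L))
    }
  )
}

# deterministic seeding helper: evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
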