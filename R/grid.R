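#' Tessellate a park into square assessment units
#'
#' Lays a regular grid of square assessment units (default 400 m, the common
#' landscape sampling rule of 2-5 times the mean patch grain) over the raster,
#' anchored at the north-west raster corner. Units wholly outside the park are
#' dropped; units straddling the boundary are retained with their in-park
#' area, so area is conserved exactly. Each unit's zone label is the majority
#' zone among its in-park cells (ties resolve to CORE, the lower zone code).
#'
#' @param raster land-use `park_raster`.
#' @param mask zone-mask `park_raster` (codes 0/1/2) aligned with `raster`.
#' @param cell_size_m unit side length; must be a positive multiple of the
#'   raster cell size.
#' @param min_area_fraction units with in-park area below this fraction of a
#'   full unit are flagged `sliver = TRUE`; they keep their values and zones
#'   but are excluded from interpolation sampling.
#' @return An `assessment_grid`: list with `units` (tibble: `unit_id`,
#'   `block_row`, `block_col`, `cx`, `cy`, `zone`, `A_k` km^2, `n_cells`,
#'   `sliver`) plus the per-cell block index and in-park mask needed by
#'   [unit_composition()].
#' @export
tessellate <- function(raster, mask, cell_size_m = 400, min_area_fraction = 0.25) {
  .check_aligned(raster, mask, "raster and mask")
  b <- cell_size_m / raster$cell_size
  if (b <= 0 || abs(b - round(b)) > 1e-9) {
    lower <- max(1, floor(b)) * raster$cell_size
    upper <- ceiling(b) * raster$cell_size
    stop(sprintf("unit size %g m is not a multiple of the raster cell size %g m (nearest valid: %g or %g m)",
                 cell_size_m, raster$cell_size, lower, upper))
  }
  b <- as.integer(round(b))
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  nrb <- (nr - 1L) %/% b + 1L
  row_block <- (seq_len(nr) - 1L) %/% b + 1L
  col_block <- (seq_len(nc) - 1L) %/% b + 1L
  # per-cell block id, in matrix layout
  blk <- matrix(row_block, nr, nc) +
    (matrix(col_block, nr, nc, byrow = TRUE) - 1L) * nrb
  in_park <- mask$values != ZONE_CODES[["OUTSIDE"]]
  if (!any(in_park)) stop("mask contains no park cells")

  park_blocks <- sort(unique(blk[in_park]))
  f <- factor(blk[in_park], levels = park_blocks)
  n_cells <- as.integer(table(f))
  core_cells <- as.integer(table(factor(
    blk[in_park & mask$values == ZONE_CODES[["CORE"]]], levels = park_blocks)))
  zone <- ifelse(core_cells * 2L >= n_cells, "CORE", "GENERAL")

  brow <- (park_blocks - 1L) %% nrb + 1L
  bcol <- (park_blocks - 1L) %/% nrb + 1L
  cs <- raster$cell_size
  cx <- raster$xll + (bcol - 0.5) * b * cs
  cy <- raster$yll + (nr - (brow - 0.5) * b) * cs
  A_k <- n_cells * cell_area_km2(raster)
  full_area <- b^2 * cell_area_km2(raster)
  units <- tibble::tibble(
    unit_id = sprintf("r%03d_c%03d", brow, bcol),
    block_row = brow, block_col = bcol,
    cx = cx, cy = cy, zone = zone,
    A_k = A_k, n_cells = n_cells,
    sliver = A_k < min_area_fraction * full_area
  )
  structure(
    list(units = units, block_size = b, unit_size_m = cell_size_m,
         n_row_blocks = nrb, raster_dim = c(nr, nc), cell_size = cs,
         block_index = blk, in_park = in_park, composition = NULL),
    class = "assessment_grid"
  )
}

#' @export
print.assessment_grid <- function(x, ...) {
  cat(sprintf("<assessment_grid> %d units of %g m (%d CORE, %d GENERAL)%s\n",
              nrow(x$units), x$unit_size_m,
              sum(x$units$zone == "CORE"), sum(x$units$zone == "GENERAL"),
              if (is.null(x$composition)) ", composition not yet computed" else ""))
  invisible(x)
}

# block ids of the units, in unit-table order
.unit_block_ids <- function(grid) {
  grid$units$block_row + (grid$units$block_col - 1L) * grid$n_row_blocks
}

#' Per-unit land-use composition
#'
#' Fills A_ki, the area of each land-use class inside each assessment unit,
#' as exact cell counts times cell area. Nodata cells contribute nothing, so
#' sum_i(A_ki) <= A_k with equality on nodata-free units.
#'
#' @param grid an `assessment_grid` from [tessellate()].
#' @param raster the land-use raster the grid was built from.
#' @param catalog a `park_catalog`; codes outside the legend raise an error.
#' @return The grid with `composition` set: a tibble `unit_id`, `code`,
#'   `A_ki` (km^2), one row per (unit, class present in unit).
#' @export
unit_composition <- function(grid, raster, catalog) {
  stopifnot(inherits(grid, "assessment_grid"))
  if (!all(dim(raster$values) == grid$raster_dim)) {
    stop("raster does not match the grid's source dimensions")
  }
  sel <- grid$in_park & raster$values != raster$nodata
  codes <- raster$values[sel]
  unknown <- setdiff(unique(codes), catalog$classes$code)
  if (length(unknown)) {
    stop("raster codes absent from catalog: ", paste(unknown, collapse = ", "))
  }
  ids <- .unit_block_ids(grid)
  counts <- table(factor(grid$block_index[sel], levels = ids),
                  factor(codes, levels = catalog$classes$code))
  comp <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(comp) <- c("block", "code", "n")
  comp <- comp[comp$n > 0, ]
  idx <- match(comp$block, as.character(ids))
  out <- tibble::tibble(
    unit_id = grid$units$unit_id[idx],
    code = as.integer(comp$code),
    A_ki = comp$n * cell_area_km2(raster)
  )
  out <- out[order(out$unit_id, out$code), ]
  grid$composition <- out
  grid
}

#' Export an assessment grid to CSV
#'
#' One row per unit with the per-class areas spread into `A_<code>` columns.
#'
#' @param grid an `assessment_grid` with composition filled.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  units <- as.data.frame(grid$units)
  if (!is.null(grid$composition)) {
    comp <- grid$composition
    wide <- stats::reshape(as.data.frame(comp), idvar = "unit_id",
                           timevar = "code", direction = "wide")
    names(wide) <- sub("^A_ki\\.", "A_", names(wide))
    wide[is.na(wide)] <- 0
    units <- merge(units, wide, by = "unit_id", all.x = TRUE, sort = FALSE)
  }
  utils::write.csv(units, path, row.names = FALSE)
  invisible(path)
}
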