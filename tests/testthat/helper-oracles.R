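# Independent brute-force oracles. These deliberately avoid the package's own
# algorithms: flood fill by explicit stack, Jenks by exhaustive enumeration,
# ERI/ESV by raw per-cell recomputation.

# patch count of `code` cells (within mask) by stack-based flood fill
oracle_patch_count <- function(values, mask, code, connectivity = 8) {
  nr <- nrow(values); nc <- ncol(values)
  on <- values == code & mask
  seen <- matrix(FALSE, nr, nc)
  nbrs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!on[r, c] || seen[r, c]) next
    count <- count + 1L
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(stack)) {
      cell <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (i in seq_len(nrow(nbrs))) {
        r2 <- cell[1] + nbrs[i, 1]; c2 <- cell[2] + nbrs[i, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            on[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  count
}

# exhaustive Fisher-Jenks: minimum within-class SS over all contiguous
# k-partitions of the sorted values, via enumeration of split points
oracle_jenks_ss <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ss(x))
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, j], n)
    tot <- 0
    for (m in seq_len(k)) tot <- tot + ss(x[(bounds[m] + 1):bounds[m + 1]])
    best <- min(best, tot)
  }
  best
}

# ERI of one assessment unit recomputed from raw cells
oracle_unit_eri <- function(raster, grid, unit_id, loss) {
  u <- grid$units[grid$units$unit_id == unit_id, ]
  b <- grid$block_size
  rows <- ((u$block_row - 1) * b + 1):min((u$block_row) * b, grid$raster_dim[1])
  cols <- ((u$block_col - 1) * b + 1):min((u$block_col) * b, grid$raster_dim[2])
  acc <- 0
  n_park <- 0
  ca <- cell_area_km2(raster)
  for (r in rows) for (c in cols) {
    if (!grid$in_park[r, c]) next
    n_park <- n_park + 1
    v <- raster$values[r, c]
    if (v == raster$nodata) next
    ri <- loss$R_i[match(v, loss$code)]
    if (is.na(ri)) ri <- 0
    acc <- acc + ca * ri
  }
  acc / (n_park * ca)
}

# ESV of one unit recomputed cell by cell
oracle_unit_esv <- function(raster, grid, unit_id, vc) {
  u <- grid$units[grid$units$unit_id == unit_id, ]
  b <- grid$block_size
  rows <- ((u$block_row - 1) * b + 1):min((u$block_row) * b, grid$raster_dim[1])
  cols <- ((u$block_col - 1) * b + 1):min((u$block_col) * b, grid$raster_dim[2])
  acc <- 0
  ca <- cell_area_km2(raster)
  for (r in rows) for (c in cols) {
    if (!grid$in_park[r, c]) next
    v <- raster$values[r, c]
    if (v == raster$nodata) next
    acc <- acc + ca * vc$vc_total[match(v, vc$code)]
  }
  acc
}

# small all-core world used by several tests
make_core_world <- function(values, cell_size = 100) {
  r <- park_raster(values, cell_size = cell_size)
  m <- zone_mask(matrix(1L, nrow(values), ncol(values)), r)
  list(raster = r, mask = m)
}

# a catalog whose single valuation group sums to a chosen equivalent total
catalog_with_total <- function(total_equivalents, unit_value = 231427) {
  ct <- default_catalog(unit_equivalent_value = unit_value)
  eq <- ct$equivalents
  eq["forest land", ] <- total_equivalents * eq["forest land", ] /
    sum(eq["forest land", ])
  ct$equivalents <- eq
  ct
}
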