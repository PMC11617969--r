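test_that("the generator is deterministic per seed", {
  a <- generate_landscape(n_rows = 60, n_cols = 60, seed = 7)
  b <- generate_landscape(n_rows = 60, n_cols = 60, seed = 7)
  c <- generate_landscape(n_rows = 60, n_cols = 60, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  # the generator leaves the caller's RNG stream untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_landscape(n_rows = 20, n_cols = 20, seed = 3))
  expect_identical(stats::runif(1), before)
})

test_that("zero clumping gives an i.i.d. multinomial raster", {
  p <- default_proportions()
  r <- generate_landscape(n_rows = 120, n_cols = 120, clumping = 0, seed = 5)
  freq <- table(factor(r$values, levels = names(p))) / length(r$values)
  expect_true(all(abs(as.numeric(freq) - p) < 0.03))
  # no spatial structure: a 10% class scatters into hundreds of specks
  # (the 58% matrix class percolates even when i.i.d., so test a minority)
  lab <- label_patches(r, NULL, 2L)
  expect_gt(lab$n_patches, 0.5 * sum(r$values == 2L))
})

test_that("clumping raises landscape-wide mean patch size", {
  mps <- function(r) {
    tc <- 0; tp <- 0
    for (cc in 1:12) {
      lab <- label_patches(r, NULL, cc)
      tc <- tc + sum(lab$patch_cells); tp <- tp + lab$n_patches
    }
    tc / tp
  }
  sizes <- sapply(c(0.15, 0.45), function(p) {
    mean(sapply(1:4, function(s) {
      mps(generate_landscape(n_rows = 60, n_cols = 60, clumping = p, seed = s))
    }))
  })
  expect_gt(sizes[2], sizes[1])
})

test_that("park masks hit the core share and keep the core enclosed", {
  r <- generate_landscape(n_rows = 150, n_cols = 150, seed = 2)
  m <- generate_park_masks(r, core_fraction = 0.5182, seed = 2)
  frac <- sum(m$values == 1L) / sum(m$values != 0L)
  expect_gte(frac, 0.508); expect_lte(frac, 0.528)

  # the core is one 8-connected region
  lab <- label_patches(park_raster(m$values, r$cell_size), NULL, 1L, 8)
  expect_equal(lab$n_patches, 1L)

  # every neighbor of a core cell is core or general, never outside
  core <- which(m$values == 1L, arr.ind = TRUE)
  nr <- nrow(m$values); nc <- ncol(m$values)
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    nb <- core + matrix(d, nrow(core), 2, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc
    expect_true(all(m$values[nb[ok, , drop = FALSE]] != 0L))
  }
})

test_that("fixture expectations are reproduced by the oracles", {
  fx <- fixture_raster("single-class-4km2")
  m <- class_metrics(fx$raster, fx$mask$values == 1L, default_catalog())
  expect_equal(m$C_i, fx$expected$C_i)
  expect_equal(m$D_i, fx$expected$D_i)

  dg <- fixture_raster("diag-pair")
  expect_equal(oracle_patch_count(dg$raster$values, dg$mask$values == 1L, 1L, 8),
               dg$expected$n_conn8)
  expect_equal(oracle_patch_count(dg$raster$values, dg$mask$values == 1L, 1L, 4),
               dg$expected$n_conn4)

  wp <- fixture_raster("water-pocket")
  g <- unit_composition(tessellate(wp$raster, wp$mask, 400), wp$raster,
                        default_catalog())
  vc <- coefficient_table(default_catalog())
  vals <- sapply(g$units$unit_id, function(u) oracle_unit_esv(wp$raster, g, u, vc))
  expect_equal(names(which.max(vals)), wp$expected$top_unit)

  expect_error(fixture_raster("nope"))
})

test_that("hotspots inject fragmented minority patches", {
  hs <- list(list(row = 30, col = 30, radius = 6, classes = c(5L, 12L), density = 0.5))
  r0 <- generate_landscape(n_rows = 60, n_cols = 60, seed = 4)
  r1 <- generate_landscape(n_rows = 60, n_cols = 60, seed = 4, hotspots = hs)
  win <- r1$values[24:36, 24:36]
  expect_gt(sum(win %in% c(5L, 12L)), sum(r0$values[24:36, 24:36] %in% c(5L, 12L)))
  # untouched far corner is identical
  expect_identical(r0$values[50:60, 50:60], r1$values[50:60, 50:60])
})
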