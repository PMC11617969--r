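test_that("ASCII grids round-trip integer and float rasters exactly", {
  v <- matrix(sample.int(12, 48, replace = TRUE), 6, 8)
  v[2, 3] <- -9999L
  r <- park_raster(v, cell_size = 100, xll = 1000, yll = 2000)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path, integer = TRUE)
  expect_identical(back$values, r$values)
  expect_equal(back$cell_size, 100)
  expect_equal(c(back$xll, back$yll), c(1000, 2000))
  expect_equal(readLines(path)[1:3], c("NCOLS 8", "NROWS 6", "XLLCORNER 1000"))

  f <- park_raster(matrix(stats::rnorm(20), 4, 5), cell_size = 50)
  pf <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(f, pf)
  expect_equal(read_ascii_grid(pf)$values, f$values)  # full double precision
})

test_that("read_landuse validates codes against the catalog", {
  ct <- default_catalog()
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(park_raster(matrix(2L, 4, 4), cell_size = 100), path)
  r <- read_landuse(path, ct)
  expect_identical(unique(as.vector(r$values)), 2L)
  expect_equal(length(r$values), 16)

  bad <- matrix(2L, 4, 4); bad[1, 1:2] <- 99L
  write_ascii_grid(park_raster(bad, cell_size = 100), path)
  expect_error(read_landuse(path, ct), "99: 2")
})

test_that("tessellation tiles the park into anchored square units", {
  w <- make_core_world(matrix(1L, 8, 8), cell_size = 100)
  g <- tessellate(w$raster, w$mask, 400)
  expect_equal(nrow(g$units), 4)
  expect_equal(g$units$A_k, rep(0.16, 4))
  expect_equal(g$units$zone, rep("CORE", 4))
  # deterministic ids from block coordinates
  expect_setequal(g$units$unit_id, c("r001_c001", "r001_c002", "r002_c001", "r002_c002"))

  # boundary units keep their reduced in-park area
  z <- matrix(0L, 8, 8); z[, 1:3] <- 2L
  m <- zone_mask(z, w$raster)
  g2 <- tessellate(w$raster, m, 400)
  expect_equal(nrow(g2$units), 2)
  expect_equal(g2$units$A_k, rep(4 * 3 * 0.01, 2))
  expect_true(all(g2$units$A_k < 0.16))
  expect_true(all(g2$units$zone == "GENERAL"))

  expect_error(tessellate(w$raster, w$mask, 250), "not a multiple.*200 or 300")
})

test_that("a ~586 km2 footprint at 400 m units yields about 3662 units", {
  # square-ish synthetic footprint of the same area as the study park grid:
  # 58600 cells of 100 m = 586 km2
  n <- 243
  z <- matrix(0L, n, n)
  z[1:242, 1:242] <- 1L
  extra <- 58600 - 242 * 242
  z[243, seq_len(extra)] <- 1L
  r <- park_raster(matrix(1L, n, n), cell_size = 100)
  g <- tessellate(r, zone_mask(z, r), 400)
  expect_equal(sum(g$units$A_k), 586)
  expect_lt(abs(nrow(g$units) - 3662) / 3662, 0.02)
})

test_that("unit composition is exact and conserves area", {
  v <- matrix(2L, 4, 4); v[1, 1:4] <- 9L
  w <- make_core_world(v, cell_size = 100)
  g <- unit_composition(tessellate(w$raster, w$mask, 400), w$raster, default_catalog())
  comp <- g$composition
  expect_equal(comp$A_ki[comp$code == 2], 0.12)
  expect_equal(comp$A_ki[comp$code == 9], 0.04)
  expect_equal(sum(comp$A_ki), sum(g$units$A_k))

  # conservation on a larger random landscape with partial edge units
  set.seed(42)
  v2 <- matrix(sample.int(12, 900, replace = TRUE), 30, 30)
  z2 <- matrix(0L, 30, 30)
  z2[4:27, 3:29] <- sample(c(1L, 2L), 24 * 27, replace = TRUE)
  r2 <- park_raster(v2, cell_size = 100)
  g2 <- unit_composition(tessellate(r2, zone_mask(z2, r2), 400), r2, default_catalog())
  expect_equal(sum(g2$composition$A_ki), sum(z2 != 0) * 0.01)
  expect_equal(sum(g2$units$A_k), sum(z2 != 0) * 0.01)
})

test_that("unit zone labels follow the majority rule with ties to CORE", {
  z <- matrix(0L, 4, 4)
  z[1:4, 1:2] <- 1L  # 8 core cells
  z[1:4, 3:4] <- 2L  # 8 general cells: tie
  r <- park_raster(matrix(1L, 4, 4), cell_size = 100)
  g <- tessellate(r, zone_mask(z, r), 400)
  expect_equal(g$units$zone, "CORE")
  z[1, 1] <- 2L  # now general majority
  g2 <- tessellate(r, zone_mask(z, r), 400)
  expect_equal(g2$units$zone, "GENERAL")
})
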