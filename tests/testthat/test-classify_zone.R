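test_that("Jenks breaks split the worked examples optimally", {
  b <- jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)
  expect_equal(b$breaks, 10)  # classes {1,2,3} and {10,11,12}
  expect_equal(b$within_ss, oracle_jenks_ss(c(1, 2, 3, 10, 11, 12), 2))

  b2 <- jenks_breaks(c(4, 5, 9, 10), k = 2)
  expect_equal(b2$breaks, 9)
  expect_equal(b2$within_ss, 1.0)

  b1 <- jenks_breaks(c(3, 1, 4, 1, 5), k = 1)
  expect_length(b1$breaks, 0)

  expect_error(jenks_breaks(c(1, 1, 2, 2), k = 3), "choose k <= 2")
})

test_that("the DP optimum equals the exhaustive-partition minimum", {
  set.seed(41)
  for (case in 1:40) {
    n <- sample(4:12, 1)
    k <- sample(2:min(4, n - 1), 1)
    x <- round(stats::runif(n, 0, 100), 1)
    if (length(unique(x)) < k) next
    b <- jenks_breaks(x, k)
    expect_equal(b$within_ss, oracle_jenks_ss(x, k), tolerance = 1e-9)
  }
})

test_that("breaks transform with positive affine maps, grades unchanged", {
  set.seed(42)
  x <- stats::rnorm(60)
  b <- jenks_breaks(x, 4)
  y <- 3.5 * x + 10
  b2 <- jenks_breaks(y, 4)
  expect_equal(b2$breaks, 3.5 * b$breaks + 10, tolerance = 1e-9)
  expect_equal(apply_grades(y, b2), apply_grades(x, b))
})

test_that("grade assignment follows the half-open printed convention", {
  brk <- structure(list(k = 5L, breaks = c(0.016, 0.063, 0.180, 0.431),
                        min = 0, max = 1), class = "break_set")
  expect_equal(apply_grades(0.016, brk), 2L)  # boundary value joins the upper class
  expect_equal(apply_grades(0.0159, brk), 1L)
  expect_equal(apply_grades(0.43, brk), 4L)
  expect_equal(apply_grades(0.431, brk), 5L)
  expect_equal(apply_grades(1.0, brk), 5L)    # the maximum closes the top class

  # raster dispatch keeps nodata out of the grading
  r <- park_raster(matrix(c(0.01, 0.08, -9999, 0.5), 2, 2), cell_size = 100)
  gm <- apply_grades(r, brk)
  expect_equal(as.vector(gm$values), c(1L, 3L, 0L, 5L))
})

test_that("four-zone synthesis applies the cuts per zone", {
  z <- matrix(c(1L, 1L, 2L, 0L), 2, 2)
  r <- park_raster(matrix(1L, 2, 2), cell_size = 100)
  mask <- zone_mask(z, r)
  eri <- park_raster(matrix(c(0.02, 0.01, -9999, -9999), 2, 2), cell_size = 100)
  esv <- park_raster(matrix(c(-9999, -9999, 71.10, -9999), 2, 2), cell_size = 100)
  zm <- four_zone_map(eri, esv, mask, eri_cut = 0.016, esv_cut = 71.10)
  expect_equal(zm$values[1, 1], FOUR_ZONE_CODES[["CHR"]])  # 0.02 >= 0.016
  expect_equal(zm$values[2, 1], FOUR_ZONE_CODES[["CLR"]])
  expect_equal(zm$values[1, 2], FOUR_ZONE_CODES[["GHE"]])  # boundary joins GHE
  expect_equal(zm$values[2, 2], FOUR_ZONE_CODES[["NONE"]])
  expect_equal(attr(zm, "eri_cut"), 0.016)

  bad <- park_raster(matrix(0, 3, 3), cell_size = 100)
  expect_error(four_zone_map(bad, esv, mask), "not aligned")
})

test_that("GHE equals the grade III-V area under the shared cut", {
  set.seed(43)
  nr <- 20; nc <- 20
  z <- matrix(2L, nr, nc); z[, 1:8] <- 1L
  r <- park_raster(matrix(1L, nr, nc), cell_size = 100)
  mask <- zone_mask(z, r)
  eri_v <- matrix(-9999, nr, nc); eri_v[z == 1L] <- stats::runif(sum(z == 1L))
  esv_v <- matrix(-9999, nr, nc); esv_v[z == 2L] <- stats::runif(sum(z == 2L), 50, 120)
  eri <- park_raster(eri_v, cell_size = 100)
  esv <- park_raster(esv_v, cell_size = 100)
  eb <- jenks_breaks(eri_v[z == 1L], 5)
  sb <- jenks_breaks(esv_v[z == 2L], 5)
  zm <- four_zone_map(eri, esv, mask, eri_breaks = eb, esv_breaks = sb)
  rep <- zone_report(zm, list(ERI = apply_grades(eri, eb),
                              ESV = apply_grades(esv, sb)))
  ghe <- rep$zones$area_km2[rep$zones$zone == "GHE"]
  esv_grades <- rep$grades[rep$grades$field == "ESV", ]
  expect_equal(ghe, sum(esv_grades$area_km2[esv_grades$grade %in% c("III", "IV", "V")]))
  # CHR mirrors grades II-V on the risk side
  chr <- rep$zones$area_km2[rep$zones$zone == "CHR"]
  eri_grades <- rep$grades[rep$grades$field == "ERI", ]
  expect_equal(chr, sum(eri_grades$area_km2[eri_grades$grade != "I"]))
  # exact partition of the park and percentages closing to 100
  expect_equal(sum(rep$zones$area_km2), rep$park_area_km2)
  expect_lt(abs(sum(rep$zones$percent) - 100), 0.02)
})

test_that("constant fields make zone shares equal mask shares", {
  z <- matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4)
  r <- park_raster(matrix(1L, 4, 4), cell_size = 100)
  mask <- zone_mask(z, r)
  eri <- park_raster(matrix(0.5, 4, 4), cell_size = 100)
  esv <- park_raster(matrix(80, 4, 4), cell_size = 100)
  zm <- four_zone_map(eri, esv, mask, eri_cut = 1, esv_cut = 10)
  rep <- zone_report(zm)
  expect_equal(rep$zones$percent[rep$zones$zone == "CLR"], 50)
  expect_equal(rep$zones$percent[rep$zones$zone == "GHE"], 50)
  expect_equal(sum(rep$zones$percent), 100)
})
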