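#' Four-zone map codes
#'
#' Integer codes of the zoning raster: 1 CHR (core, high risk), 2 CLR (core,
#' low risk), 3 GHE (general, high service value), 4 GLE (general, low
#' service value), 5 NONE (outside the park).
#' @export
FOUR_ZONE_CODES <- c(CHR = 1L, CLR = 2L, GHE = 3L, GLE = 4L, NONE = 5L)

#' Synthesize the CHR/CLR/GHE/GLE zoning map
#'
#' Core cells with ERI at or above the risk cut become CHR, the rest CLR;
#' general cells with ESV at or above the value cut become GHE, the rest GLE.
#' By default the cuts are taken from the grade break sets — the first ERI
#' break (grade I/II boundary) and the second ESV break (grade II/III
#' boundary) — so CHR corresponds to ERI grades II-V and GHE to ESV grades
#' III-V under the shared half-open convention; fixed numeric cuts can be
#' supplied instead.
#'
#' @param eri_surface float `park_raster` of ERI over the core area.
#' @param esv_surface float `park_raster` of ESV over the general area (may
#'   be `NULL` when the park has no general area).
#' @param mask zone mask aligned with the surfaces.
#' @param eri_breaks,esv_breaks `break_set`s used to resolve default cuts.
#' @param eri_cut,esv_cut numeric overrides for the cuts.
#' @return A `zoning_map`: integer `park_raster` of [FOUR_ZONE_CODES] with
#'   attributes `eri_cut` and `esv_cut`.
#' @export
four_zone_map <- function(eri_surface, esv_surface, mask,
                          eri_breaks = NULL, esv_breaks = NULL,
                          eri_cut = NULL, esv_cut = NULL) {
  .check_aligned(eri_surface, mask, "ERI surface and mask")
  if (!is.null(esv_surface)) .check_aligned(esv_surface, mask, "ESV surface and mask")
  if (is.null(eri_cut)) {
    if (is.null(eri_breaks)) stop("provide eri_breaks or a numeric eri_cut")
    eri_cut <- eri_breaks$breaks[1]
  }
  core <- mask$values == ZONE_CODES[["CORE"]]
  general <- mask$values == ZONE_CODES[["GENERAL"]]
  z <- matrix(FOUR_ZONE_CODES[["NONE"]], nrow(mask$values), ncol(mask$values))
  ev <- eri_surface$values
  z[core] <- ifelse(is.finite(ev[core]) & ev[core] != eri_surface$nodata &
                      ev[core] >= eri_cut,
                    FOUR_ZONE_CODES[["CHR"]], FOUR_ZONE_CODES[["CLR"]])
  if (any(general)) {
    if (is.null(esv_surface)) stop("mask has general cells but esv_surface is NULL")
    if (is.null(esv_cut)) {
      if (is.null(esv_breaks)) stop("provide esv_breaks or a numeric esv_cut")
      esv_cut <- esv_breaks$breaks[2]
    }
    sv <- esv_surface$values
    z[general] <- ifelse(is.finite(sv[general]) & sv[general] != esv_surface$nodata &
                           sv[general] >= esv_cut,
                         FOUR_ZONE_CODES[["GHE"]], FOUR_ZONE_CODES[["GLE"]])
  } else {
    esv_cut <- NA_real_
  }
  out <- park_raster(z, cell_size = mask$cell_size, xll = mask$xll,
                     yll = mask$yll, nodata = FOUR_ZONE_CODES[["NONE"]],
                     crs_tag = mask$crs_tag)
  attr(out, "eri_cut") <- eri_cut
  attr(out, "esv_cut") <- esv_cut
  class(out) <- c("zoning_map", class(out))
  out
}

#' Zone and grade area accounting
#'
#' Areas (cell counts times cell area) and percentages of the four zones over
#' the park footprint, plus per-grade areas within the core and general areas
#' when grade maps are supplied.
#'
#' @param zoning a `zoning_map`.
#' @param grademaps optional named list with elements `ERI` and/or `ESV`,
#'   each a `grade_map` aligned with the zoning.
#' @return A `zone_report`: list with `zones` (tibble `zone`, `area_km2`,
#'   `percent`), `grades` (tibble `field`, `grade`, `area_km2`, `percent`,
#'   percentages within that field's zone) and `park_area_km2`.
#' @export
zone_report <- function(zoning, grademaps = list()) {
  ca <- cell_area_km2(zoning)
  z <- zoning$values
  park_cells <- sum(z != FOUR_ZONE_CODES[["NONE"]])
  park_area <- park_cells * ca
  zones <- names(FOUR_ZONE_CODES)[1:4]
  counts <- unname(vapply(zones, function(zn) sum(z == FOUR_ZONE_CODES[[zn]]), numeric(1)))
  ztab <- tibble::tibble(zone = zones, area_km2 = counts * ca,
                         percent = round(counts / park_cells * 100, 2))
  gtab <- NULL
  for (field in names(grademaps)) {
    gm <- grademaps[[field]]
    .check_aligned(gm, zoning, "grade map and zoning")
    zone_sel <- if (field == "ERI") {
      z %in% FOUR_ZONE_CODES[c("CHR", "CLR")]
    } else {
      z %in% FOUR_ZONE_CODES[c("GHE", "GLE")]
    }
    g <- gm$values[zone_sel & gm$values != gm$nodata]
    k <- attr(gm, "break_set")$k
    cnt <- vapply(seq_len(k), function(j) sum(g == j), numeric(1))
    gtab <- rbind(gtab, tibble::tibble(
      field = field, grade = as.character(utils::as.roman(seq_len(k))),
      area_km2 = cnt * ca,
      percent = round(cnt / sum(cnt) * 100, 2)))
  }
  structure(list(zones = ztab, grades = gtab, park_area_km2 = park_area),
            class = "zone_report")
}

#' @export
print.zone_report <- function(x, ...) {
  cat(sprintf("<zone_report> park area %.2f km^2\n", x$park_area_km2))
  print(x$zones)
  if (!is.null(x$grades)) print(x$grades)
  invisible(x)
}
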