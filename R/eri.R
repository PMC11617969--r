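#' Per-class loss index
#'
#' The loss index of class i combines how vulnerable the class is (its rank
#' F_i in the 12-class legend) with how disturbed its landscape configuration
#' is (the disturbance index S_i): R_i = F_i x S_i. With `normalize_F` the
#' rank is first divided by the sum of all catalog ranks (78 for the default
#' 12-rank legend), which puts downstream risk values on a convenient scale;
#' the choice is a uniform rescaling and never changes orderings or grades.
#'
#' @param metrics a [class_metrics()] table for the intended region.
#' @param catalog a `park_catalog` carrying `vulnerability_rank`.
#' @param normalize_F divide F_i by the sum of catalog ranks (default TRUE).
#' @return Tibble: `code`, `name`, `F_i`, `F_hat`, `S_i`, `R_i`.
#' @export
loss_index <- function(metrics, catalog, normalize_F = TRUE) {
  m <- match(metrics$code, catalog$classes$code)
  if (anyNA(m)) {
    stop("classes absent from catalog: ",
         paste(metrics$code[is.na(m)], collapse = ", "))
  }
  F_i <- catalog$classes$vulnerability_rank[m]
  denom <- if (normalize_F) sum(catalog$classes$vulnerability_rank) else 1
  F_hat <- F_i / denom
  tibble::tibble(code = metrics$code, name = metrics$name,
                 F_i = F_i, F_hat = F_hat, S_i = metrics$S_i,
                 R_i = F_hat * metrics$S_i)
}

#' Ecological risk of one assessment unit
#'
#' ERI_k = sum_i (A_ki / A_k) R_i: the composition-weighted mean of the loss
#' indices of the classes present in the unit, hence always a convex
#' combination of R_i values.
#'
#' @param A_ki named numeric vector of class areas in the unit (names = codes).
#' @param A_k unit area (km^2), > 0.
#' @param loss a [loss_index()] table.
#' @return Scalar ERI_k.
#' @export
unit_eri <- function(A_ki, A_k, loss) {
  if (!isTRUE(A_k > 0)) stop("undefined unit: A_k must be > 0")
  m <- match(as.integer(names(A_ki)), loss$code)
  if (anyNA(m)) {
    stop("unit contains classes absent from the loss table: ",
         paste(names(A_ki)[is.na(m)], collapse = ", "))
  }
  sum(A_ki / A_k * loss$R_i[m])
}

#' Ecological risk field over the core protected area
#'
#' Runs the full risk chain for the core zone: landscape metrics over the
#' core region, loss indices, then one ERI value per CORE assessment unit.
#'
#' @param grid an `assessment_grid` with composition filled.
#' @param raster the land-use raster.
#' @param mask the zone mask (core cells define the landscape).
#' @param catalog a `park_catalog`.
#' @param connectivity,weights,normalize_F,normalize_cnd passed to
#'   [class_metrics()] / [loss_index()].
#' @return A `scalar_field` tibble over CORE units: `unit_id`, `cx`, `cy`,
#'   `zone`, `A_k`, `sliver`, `value` (= ERI_k); attributes `kind = "ERI"`,
#'   `loss_table`, `metrics`.
#' @export
eri_field <- function(grid, raster, mask, catalog, connectivity = 8,
                      weights = c(0.6, 0.3, 0.1), normalize_F = TRUE,
                      normalize_cnd = FALSE) {
  if (is.null(grid$composition)) stop("grid composition not computed; run unit_composition() first")
  core <- mask$values == ZONE_CODES[["CORE"]]
  if (!any(core)) stop("core region is empty")
  metrics <- class_metrics(raster, core, catalog, connectivity, weights,
                           normalize_cnd)
  loss <- loss_index(metrics, catalog, normalize_F)
  units <- grid$units[grid$units$zone == "CORE", ]
  comp <- grid$composition[grid$composition$unit_id %in% units$unit_id, ]
  r_of <- loss$R_i[match(comp$code, loss$code)]
  # classes present in core units but absent from the core landscape (edge
  # units whose majority zone is CORE can contain general-area-only classes)
  # carry no core loss index; score them with R_i = 0 and record the fact.
  missing <- unique(comp$code[is.na(r_of)])
  r_of[is.na(r_of)] <- 0
  num <- tapply(comp$A_ki * r_of, comp$unit_id, sum)
  value <- as.numeric(num[units$unit_id]) / units$A_k
  out <- tibble::tibble(units[c("unit_id", "cx", "cy", "zone", "A_k", "sliver")],
                        value = value)
  class(out) <- c("scalar_field", class(out))
  attr(out, "kind") <- "ERI"
  attr(out, "loss_table") <- loss
  attr(out, "metrics") <- metrics
  attr(out, "codes_outside_landscape") <- missing
  out
}
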