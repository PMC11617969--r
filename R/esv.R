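#' Ecosystem service value of one assessment unit
#'
#' ESV_k = sum_i A_ki x VC_i: class areas times per-unit-area service
#' coefficients, in wan yuan (RMB 10^4). The per-category breakdown uses the
#' category-restricted coefficient columns, so the four category values
#' partition ESV_k exactly.
#'
#' @param A_ki named numeric vector of class areas in the unit (names = codes).
#' @param vc_table a [coefficient_table()].
#' @return Named list: `ESV_k` plus one entry per service category (wan yuan).
#' @export
unit_esv <- function(A_ki, vc_table) {
  m <- match(as.integer(names(A_ki)), vc_table$code)
  if (anyNA(m)) {
    stop("no service coefficients for classes: ",
         paste(names(A_ki)[is.na(m)], collapse = ", "))
  }
  cats <- unique(unname(esv_subcategories()))
  out <- list(ESV_k = sum(A_ki * vc_table$vc_total[m]))
  for (ct in cats) {
    out[[ct]] <- sum(A_ki * vc_table[[paste0("cat_", ct)]][m])
  }
  out
}

#' Ecosystem service value field over the general control area
#'
#' One ESV value (and category breakdown) per GENERAL assessment unit.
#' Per-unit sums are accumulated over class areas sorted by class code, so
#' the result is independent of raster traversal order.
#'
#' @param grid an `assessment_grid` with composition filled.
#' @param raster the land-use raster (used only for an alignment check).
#' @param mask the zone mask.
#' @param catalog a `park_catalog`.
#' @return A `scalar_field` tibble over GENERAL units: `unit_id`, `cx`, `cy`,
#'   `zone`, `A_k`, `sliver`, `value` (= ESV_k, wan yuan) and one column per
#'   service category; attribute `kind = "ESV"`.
#' @export
esv_field <- function(grid, raster, mask, catalog) {
  if (is.null(grid$composition)) stop("grid composition not computed; run unit_composition() first")
  if (!any(mask$values == ZONE_CODES[["GENERAL"]])) stop("general region is empty")
  vc <- coefficient_table(catalog)
  units <- grid$units[grid$units$zone == "GENERAL", ]
  comp <- grid$composition[grid$composition$unit_id %in% units$unit_id, ]
  comp <- comp[order(comp$unit_id, comp$code), ]
  m <- match(comp$code, vc$code)
  if (anyNA(m)) {
    stop("no service coefficients for classes: ",
         paste(unique(comp$code[is.na(m)]), collapse = ", "))
  }
  agg <- function(coef) {
    s <- tapply(comp$A_ki * coef[m], comp$unit_id, sum)
    v <- as.numeric(s[units$unit_id])
    v[is.na(v)] <- 0
    v
  }
  out <- tibble::tibble(units[c("unit_id", "cx", "cy", "zone", "A_k", "sliver")],
                        value = agg(vc$vc_total))
  for (ct in unique(unname(esv_subcategories()))) {
    out[[ct]] <- agg(vc[[paste0("cat_", ct)]])
  }
  class(out) <- c("scalar_field", class(out))
  attr(out, "kind") <- "ESV"
  out
}

#' Four-category service value report
#'
#' Aggregates a field's per-category values into the standard report: value
#' in wan yuan and percentage per category, plus the total in wan yuan and in
#' RMB million. Percentages are rounded half-even to 2 decimals at this layer
#' only; upstream values stay exact.
#'
#' @param field an [esv_field()] result, or any data frame with the four
#'   category columns in wan yuan.
#' @return A `service_report`: tibble `category`, `value_wanyuan`, `percent`,
#'   with attributes `total_wanyuan` and `total_rmb_million`; if the total is
#'   zero, `percent` is `NA` and attribute `undefined_percentage` is TRUE.
#' @export
service_report <- function(field) {
  cats <- unique(unname(esv_subcategories()))
  miss <- setdiff(cats, names(field))
  if (length(miss)) stop("field lacks category columns: ", paste(miss, collapse = ", "))
  vals <- unname(vapply(cats, function(ct) sum(field[[ct]]), numeric(1)))
  total <- sum(vals)
  pct <- if (total > 0) round(vals / total * 100, 2) else rep(NA_real_, length(vals))
  out <- tibble::tibble(category = cats,
                        value_wanyuan = round(vals, 2),
                        percent = pct)
  class(out) <- c("service_report", class(out))
  attr(out, "total_wanyuan") <- round(total, 2)
  attr(out, "total_rmb_million") <- round(total / 100, 2)
  attr(out, "undefined_percentage") <- !(total > 0)
  out
}

#' @export
print.service_report <- function(x, ...) {
  cat(sprintf("<service_report> total %.2f wan yuan = RMB %.2f million\n",
              attr(x, "total_wanyuan"), attr(x, "total_rmb_million")))
  NextMethod()
}
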