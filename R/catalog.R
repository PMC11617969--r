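#' Land-use class catalogs
#'
#' A class catalog ties together the categorical legend of a land-use raster,
#' the ecological vulnerability rank of each class, the regrouping of the
#' 12-class legend into the 8 groups used for ecosystem-service valuation, and
#' the per-unit-area service coefficients of the equivalent-factor method.
#'
#' @name catalog
NULL

# service subcategories, grouped into the four standard categories
.ESV_SUBCATEGORIES <- c(
  food_production = "provisioning", raw_material = "provisioning",
  water_supply = "provisioning",
  gas_regulation = "regulating", climate_regulation = "regulating",
  environment_purification = "regulating", hydrological_regulation = "regulating",
  soil_conservation = "supporting", nutrient_cycling = "supporting",
  biodiversity = "supporting",
  aesthetic_landscape = "cultural"
)

.ESV_GROUPS <- c(
  "forest land", "irrigated field", "non-irrigated field", "grassland",
  "wetland", "water", "building land", "bare land"
)

#' Service subcategory / category layout
#'
#' @return Named character vector mapping the 11 service subcategories to
#'   their category (`provisioning`, `regulating`, `supporting`, `cultural`).
#' @export
esv_subcategories <- function() .ESV_SUBCATEGORIES

# Default per-unit-area equivalence factors (dimensionless equivalents),
# following the style of the Chinese national equivalent-factor tables.
# Rows are the 8 valuation groups; a park-specific table can replace this
# wholesale through the catalog config. All entries are constrained >= 0
# (published paddy water-supply entries can be negative; the default clamps
# at zero so the nonnegativity contract of the catalog holds).
.default_equivalents <- function() {
  m <- rbind(
    "forest land"         = c(0.29, 0.66, 0.34, 2.17, 6.50, 1.93, 4.74, 2.65, 0.20, 2.41, 1.06),
    "irrigated field"     = c(1.36, 0.09, 0.00, 1.11, 0.57, 0.17, 2.72, 0.01, 0.19, 0.21, 0.09),
    "non-irrigated field" = c(0.85, 0.40, 0.02, 0.67, 0.36, 0.10, 0.27, 1.03, 0.12, 0.13, 0.06),
    "grassland"           = c(0.38, 0.56, 0.31, 1.97, 5.21, 1.72, 3.82, 2.40, 0.18, 2.18, 0.96),
    "wetland"             = c(0.51, 0.50, 2.59, 1.90, 3.60, 3.60, 24.23, 2.31, 0.18, 7.87, 4.73),
    "water"               = c(0.80, 0.23, 8.29, 0.77, 2.29, 5.55, 102.24, 0.93, 0.07, 2.55, 1.89),
    "building land"       = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    "bare land"           = c(0.01, 0.03, 0.02, 0.11, 0.10, 0.31, 0.21, 0.13, 0.01, 0.12, 0.05)
  )
  colnames(m) <- names(.ESV_SUBCATEGORIES)
  m
}

#' Default 12-class catalog
#'
#' The shipped legend distinguishes four forest types plus garden plot,
#' grassland, two field types, wetland, water, building land and bare land.
#' Vulnerability ranks run from 1 (building land, least vulnerable as a
#' landscape element already converted by people) to 12 (bare land).
#' The default monetary unit equivalent value is 231427 yuan per km^2 of one
#' equivalence factor (one seventh of the average local food price per unit
#' area, supplied by statistics; here a config scalar).
#'
#' @param garden_plot_group valuation group for garden plot; the default
#'   `"forest land"` treats orchards as woody cover, `"non-irrigated field"`
#'   treats them as cropland.
#' @param unit_equivalent_value yuan per km^2 for one equivalence factor.
#' @return An object of class `park_catalog` with elements `classes`
#'   (a tibble: `code`, `name`, `vulnerability_rank`, `esv_group`),
#'   `equivalents` (group x subcategory matrix) and `unit_equivalent_value`.
#' @examples
#' cat <- default_catalog()
#' subset(cat$classes, name == "bare land")
#' @export
default_catalog <- function(garden_plot_group = c("forest land", "non-irrigated field"),
                            unit_equivalent_value = 231427) {
  garden_plot_group <- match.arg(garden_plot_group)
  classes <- tibble::tibble(
    code = 1:12,
    name = c("arbor forest land", "bamboo forest land", "shrubland",
             "other forest land", "irrigated field", "non-irrigated field",
             "garden plot", "grassland", "wetland", "water",
             "building land", "bare land"),
    vulnerability_rank = c(2L, 3L, 4L, 5L, 9L, 8L, 6L, 7L, 10L, 11L, 1L, 12L),
    esv_group = c("forest land", "forest land", "forest land", "forest land",
                  "irrigated field", "non-irrigated field", garden_plot_group,
                  "grassland", "wetland", "water", "building land", "bare land")
  )
  structure(
    list(classes = classes,
         equivalents = .default_equivalents(),
         unit_equivalent_value = unit_equivalent_value),
    class = "park_catalog"
  )
}

#' @export
print.park_catalog <- function(x, ...) {
  cat(sprintf("<park_catalog> %d classes, %d valuation groups, unit equivalent value %s yuan/km^2\n",
              nrow(x$classes), nrow(x$equivalents),
              format(x$unit_equivalent_value, big.mark = ",")))
  print(x$classes)
  invisible(x)
}

#' Validate a catalog
#'
#' Checks the structural invariants of a catalog and returns human-readable
#' violation messages instead of throwing, so configuration problems can be
#' reported in bulk.
#'
#' @param catalog a `park_catalog`.
#' @return Character vector of violations; `character(0)` if the catalog is valid.
#' @export
validate_catalog <- function(catalog) {
  v <- character(0)
  cl <- catalog$classes
  dup <- unique(cl$code[duplicated(cl$code)])
  for (d in dup) v <- c(v, sprintf("duplicate class code %s", d))
  bad_rank <- cl$code[!(cl$vulnerability_rank %in% 1:12)]
  for (b in bad_rank) v <- c(v, sprintf("vulnerability_rank outside 1..12 for class code %s", b))
  eq <- catalog$equivalents
  if (is.null(dim(eq))) {
    v <- c(v, "equivalents is not a matrix")
    return(v)
  }
  neg <- which(eq < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    for (r in seq_len(nrow(neg))) {
      v <- c(v, sprintf("negative equivalence factor at [%s, %s]",
                        rownames(eq)[neg[r, 1]], colnames(eq)[neg[r, 2]]))
    }
  }
  missing_grp <- setdiff(unique(cl$esv_group), rownames(eq))
  for (g in missing_grp) {
    codes <- cl$code[cl$esv_group == g]
    v <- c(v, sprintf("esv_group '%s' (classes %s) has no equivalents row",
                      g, paste(codes, collapse = ",")))
  }
  if (!isTRUE(catalog$unit_equivalent_value > 0)) {
    v <- c(v, "unit_equivalent_value must be > 0")
  }
  v
}

#' Per-class service coefficients VC_i
#'
#' Multiplies each class's equivalence-factor row by the monetary unit
#' equivalent value to give the service value per km^2 of that class,
#' expressed in wan yuan (RMB 10^4) per km^2, per subcategory, per category,
#' and in total.
#'
#' @param catalog a valid `park_catalog`.
#' @return Tibble with one row per class: `code`, `name`, `esv_group`, one
#'   column per subcategory, one `cat_<category>` column per category, and
#'   `vc_total` (all wan yuan / km^2).
#' @export
coefficient_table <- function(catalog) {
  viol <- validate_catalog(catalog)
  if (length(viol)) stop("invalid catalog: ", paste(viol, collapse = "; "))
  cl <- catalog$classes
  eq <- catalog$equivalents[cl$esv_group, , drop = FALSE]
  vc <- eq * catalog$unit_equivalent_value / 1e4  # yuan -> wan yuan
  rownames(vc) <- NULL
  out <- tibble::as_tibble(as.data.frame(vc))
  cats <- unique(unname(.ESV_SUBCATEGORIES))
  for (ct in cats) {
    cols <- names(.ESV_SUBCATEGORIES)[.ESV_SUBCATEGORIES == ct]
    out[[paste0("cat_", ct)]] <- unname(rowSums(vc[, cols, drop = FALSE]))
  }
  out$vc_total <- unname(rowSums(vc))
  tibble::tibble(code = cl$code, name = cl$name, esv_group = cl$esv_group, out)
}

#' Read / write a catalog config file
#'
#' Catalogs serialize to YAML with keys `classes`, `equivalents` and
#' `unit_equivalent_value`. Unknown top-level keys are rejected so typos fail
#' loudly. Round-trips are value-identical.
#'
#' @param path file path.
#' @param catalog a `park_catalog`.
#' @return `read_catalog` returns a `park_catalog`; `write_catalog` returns
#'   `path` invisibly.
#' @export
read_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("classes", "equivalents", "unit_equivalent_value")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown catalog keys: ", paste(unknown, collapse = ", "),
         " (expected ", paste(known, collapse = ", "), ")")
  }
  classes <- do.call(rbind, lapply(raw$classes, function(cl) {
    data.frame(code = as.integer(cl$code), name = cl$name,
               vulnerability_rank = as.integer(cl$vulnerability_rank),
               esv_group = cl$esv_group)
  }))
  eq_rows <- raw$equivalents
  eq <- do.call(rbind, lapply(eq_rows, function(r) unlist(r[names(.ESV_SUBCATEGORIES)])))
  rownames(eq) <- vapply(eq_rows, `[[`, "", "group")
  colnames(eq) <- names(.ESV_SUBCATEGORIES)
  structure(
    list(classes = tibble::as_tibble(classes), equivalents = eq,
         unit_equivalent_value = raw$unit_equivalent_value),
    class = "park_catalog"
  )
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  cl <- catalog$classes
  classes <- lapply(seq_len(nrow(cl)), function(i) {
    list(code = cl$code[i], name = cl$name[i],
         vulnerability_rank = cl$vulnerability_rank[i],
         esv_group = cl$esv_group[i])
  })
  eq <- catalog$equivalents
  equivalents <- lapply(rownames(eq), function(g) {
    c(list(group = g), as.list(eq[g, ]))
  })
  yaml::write_yaml(
    list(classes = classes, equivalents = equivalents,
         unit_equivalent_value = catalog$unit_equivalent_value),
    path, precision = 15
  )
  invisible(path)
}
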