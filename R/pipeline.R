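#' Run the risk-value zoning pipeline
#'
#' Orchestrates the full analysis: obtain a land-use raster and zone mask
#' (from files, or synthesized when no input paths are configured),
#' tessellate into assessment units, compute per-unit ERI over the core
#' protected area and ESV over the general control area, krige both fields
#' to surfaces (each strictly within its own zone; the two are never blended
#' across the boundary), grade each surface into `breaks.k` Jenks classes,
#' synthesize the CHR/CLR/GHE/GLE zoning map, and assemble the area and
#' service-value reports. Deterministic given the config (including its
#' seed). If the park has no general area, the ESV stages are skipped with a
#' message and the zoning map covers the core only.
#'
#' @param config a `pipeline_config` from [load_config()].
#' @param stages run only the leading stages up to this one; one of
#'   `"simulate"`, `"assess"`, `"interpolate"`, `"classify"`, `"zone"`,
#'   `"report"` (default: everything).
#' @param quiet suppress progress messages.
#' @return A list bundle: `config`, `catalog`, `raster`, `mask`, `grid`,
#'   `eri_field`, `esv_field`, `eri_surface`, `esv_surface`, `eri_breaks`,
#'   `esv_breaks`, `eri_grades`, `esv_grades`, `zoning`, `zone_report`,
#'   `service_report`, `timings`. When `config$out_dir` is set, all
#'   artifacts are also written there (ASCII grids, CSVs, resolved config).
#' @export
run_pipeline <- function(config = load_config(), stages = "report", quiet = FALSE) {
  stage_order <- c("simulate", "assess", "interpolate", "classify", "zone", "report")
  stages <- match.arg(stages, stage_order)
  last <- match(stages, stage_order)
  say <- function(...) if (!quiet) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  out <- list(config = config)

  t0 <- tic()
  out$catalog <- if (!is.null(config$input$catalog)) {
    read_catalog(config$input$catalog)
  } else {
    default_catalog()
  }
  viol <- validate_catalog(out$catalog)
  if (length(viol)) stop("stage catalog: ", paste(viol, collapse = "; "))

  if (!is.null(config$input$raster)) {
    out$raster <- read_landuse(config$input$raster, out$catalog)
    if (is.null(config$input$mask)) stop("stage input: raster given without a mask")
    out$mask <- read_ascii_grid(config$input$mask, integer = TRUE)
    say("read %d x %d raster from %s", nrow(out$raster$values),
        ncol(out$raster$values), config$input$raster)
  } else {
    sp <- config$synthetic
    hotspots <- sp$hotspots
    if (identical(hotspots, "default")) {
      hotspots <- .default_hotspots(sp$n_rows, sp$n_cols, config$seed)
    }
    out$raster <- generate_landscape(
      n_rows = sp$n_rows, n_cols = sp$n_cols, cell_size = sp$cell_size,
      proportions = unlist(sp$proportions), clumping = sp$clumping,
      hotspots = hotspots, seed = config$seed)
    out$mask <- generate_park_masks(out$raster, core_fraction = sp$core_fraction,
                                    footprint_fraction = sp$footprint_fraction,
                                    seed = config$seed)
    say("synthesized %d x %d landscape (seed %s): %d park cells",
        sp$n_rows, sp$n_cols, format(config$seed), sum(out$mask$values != 0))
  }
  timings["simulate"] <- tic() - t0
  if (last == 1) return(.write_bundle(out, timings, quiet))

  t0 <- tic()
  out$grid <- tessellate(out$raster, out$mask, config$grid$cell_size_m,
                         config$grid$min_area_fraction)
  out$grid <- unit_composition(out$grid, out$raster, out$catalog)
  say("tessellated into %d assessment units of %g m", nrow(out$grid$units),
      config$grid$cell_size_m)
  mt <- config$metrics
  out$eri_field <- eri_field(out$grid, out$raster, out$mask, out$catalog,
                             connectivity = mt$connectivity, weights = mt$weights,
                             normalize_F = mt$normalize_F,
                             normalize_cnd = mt$normalize_cnd)
  has_general <- any(out$mask$values == ZONE_CODES[["GENERAL"]])
  if (has_general) {
    out$esv_field <- esv_field(out$grid, out$raster, out$mask, out$catalog)
  } else {
    say("park has no general control area: ESV stages skipped")
  }
  timings["assess"] <- tic() - t0
  if (last == 2) return(.write_bundle(out, timings, quiet))

  t0 <- tic()
  krige_zone <- function(field, zone_code) {
    samples <- field[!field$sliver & is.finite(field$value), ]
    samples <- tibble::tibble(x = samples$cx, y = samples$cy, value = samples$value)
    emp <- empirical_semivariogram(samples, n_lags = config$variogram$n_lags,
                                   max_lag = config$variogram$max_lag)
    model <- fit_variogram(emp, family = config$variogram$family)
    zone_cells <- out$mask$values == zone_code
    krige(samples, model, out$raster, zone_cells,
          neighborhood = config$kriging$neighborhood)
  }
  out$eri_surface <- krige_zone(out$eri_field, ZONE_CODES[["CORE"]])
  if (has_general) {
    out$esv_surface <- krige_zone(out$esv_field, ZONE_CODES[["GENERAL"]])
  }
  timings["interpolate"] <- tic() - t0
  if (last == 3) return(.write_bundle(out, timings, quiet))

  t0 <- tic()
  surf_vals <- function(s) s$values[s$values != s$nodata]
  out$eri_breaks <- jenks_breaks(surf_vals(out$eri_surface), config$breaks$k)
  out$eri_grades <- apply_grades(out$eri_surface, out$eri_breaks)
  if (has_general) {
    out$esv_breaks <- jenks_breaks(surf_vals(out$esv_surface), config$breaks$k)
    out$esv_grades <- apply_grades(out$esv_surface, out$esv_breaks)
  }
  timings["classify"] <- tic() - t0
  if (last == 4) return(.write_bundle(out, timings, quiet))

  t0 <- tic()
  out$zoning <- four_zone_map(out$eri_surface,
                              if (has_general) out$esv_surface else NULL,
                              out$mask,
                              eri_breaks = out$eri_breaks,
                              esv_breaks = if (has_general) out$esv_breaks else NULL,
                              eri_cut = config$zoning$eri_cut,
                              esv_cut = config$zoning$esv_cut)
  timings["zone"] <- tic() - t0
  if (last == 5) return(.write_bundle(out, timings, quiet))

  t0 <- tic()
  gm <- list(ERI = out$eri_grades)
  if (has_general) gm$ESV <- out$esv_grades
  out$zone_report <- zone_report(out$zoning, gm)
  if (has_general) out$service_report <- service_report(out$esv_field)
  timings["report"] <- tic() - t0
  .write_bundle(out, timings, quiet)
}

# fragmentation hot-spots near the core/general border: cultivated, garden
# and bare patches, the classic disturbance signature at zone edges
.default_hotspots <- function(n_rows, n_cols, seed) {
  withr_seed(seed + 2L, {
    k <- 4
    ang <- stats::runif(k, 0, 2 * pi)
    # ~60-70% of the half-extent: near the core/general boundary by construction
    rad <- stats::runif(k, 0.55, 0.7)
    lapply(seq_len(k), function(i) {
      list(row = round(n_rows / 2 + rad[i] * n_rows / 2 * sin(ang[i])),
           col = round(n_cols / 2 + rad[i] * n_cols / 2 * cos(ang[i])),
           radius = round(min(n_rows, n_cols) * 0.04),
           classes = c(5L, 6L, 7L, 12L), density = 0.6)
    })
  })
}

.write_bundle <- function(out, timings, quiet) {
  out$timings <- timings
  dir <- out$config$out_dir
  if (is.null(dir)) return(out)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wp <- function(name) file.path(dir, name)
  write_config(out$config, wp("resolved_config.yml"))
  write_ascii_grid(out$raster, wp("landuse.asc"))
  write_ascii_grid(out$mask, wp("zone_mask.asc"))
  if (!is.null(out$grid)) write_grid_csv(out$grid, wp("assessment_grid.csv"))
  wf <- function(field, name) {
    if (!is.null(field)) utils::write.csv(as.data.frame(field), wp(name), row.names = FALSE)
  }
  wf(out$eri_field, "eri_units.csv")
  wf(out$esv_field, "esv_units.csv")
  if (!is.null(out$eri_surface)) write_ascii_grid(out$eri_surface, wp("eri_surface.asc"))
  if (!is.null(out$esv_surface)) write_ascii_grid(out$esv_surface, wp("esv_surface.asc"))
  if (!is.null(out$eri_grades)) write_ascii_grid(out$eri_grades, wp("eri_grades.asc"))
  if (!is.null(out$esv_grades)) write_ascii_grid(out$esv_grades, wp("esv_grades.asc"))
  if (!is.null(out$zoning)) write_ascii_grid(out$zoning, wp("zoning.asc"))
  if (!is.null(out$zone_report)) {
    utils::write.csv(as.data.frame(out$zone_report$zones), wp("zone_report.csv"),
                     row.names = FALSE)
    if (!is.null(out$zone_report$grades)) {
      utils::write.csv(as.data.frame(out$zone_report$grades), wp("grade_report.csv"),
                       row.names = FALSE)
    }
  }
  if (!is.null(out$service_report)) {
    utils::write.csv(as.data.frame(out$service_report), wp("service_report.csv"),
                     row.names = FALSE)
  }
  if (!quiet) message("artifacts written to ", dir)
  out
}
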