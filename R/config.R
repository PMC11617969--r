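#' Pipeline configuration
#'
#' Every numeric choice the analysis leaves open is an explicit config value
#' with a default, so each run's resolved configuration is a complete audit
#' of its assumptions. Configs load from YAML, merge over the defaults, and
#' reject unknown keys with a nearest-key suggestion.
#'
#' @return `default_config()` returns the full default configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    input = list(raster = NULL, mask = NULL, catalog = NULL),
    synthetic = list(
      n_rows = 240, n_cols = 240, cell_size = 100,
      clumping = 0.5, core_fraction = 0.5182, footprint_fraction = 0.87,
      proportions = as.list(default_proportions()),
      hotspots = "default"
    ),
    grid = list(cell_size_m = 400, min_area_fraction = 0.25),
    metrics = list(connectivity = 8, weights = c(0.6, 0.3, 0.1),
                   normalize_F = TRUE, normalize_cnd = FALSE),
    variogram = list(family = "spherical", n_lags = 12, max_lag = NULL),
    kriging = list(neighborhood = 16),
    breaks = list(k = 5),
    zoning = list(eri_cut = NULL, esv_cut = NULL),
    out_dir = NULL
  )
}

# recursive merge of user values over defaults, tracking the key path for
# unknown-key errors
.merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      sugg <- utils::adist(key, names(defaults))
      hint <- names(defaults)[which.min(sugg)]
      stop(sprintf("unknown config key '%s'%s", full,
                   if (min(sugg) <= 3) sprintf(" (did you mean '%s'?)", hint) else ""))
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]])) && key != "proportions") {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and resolve a pipeline configuration
#'
#' @param path optional YAML file; an empty or absent file yields the defaults.
#' @param overrides optional named list merged over the file values.
#' @return The resolved configuration list (class `pipeline_config`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- .merge_config(cfg, user)
  }
  if (length(overrides)) cfg <- .merge_config(cfg, overrides)
  w <- unlist(cfg$metrics$weights)
  if (length(w) != 3) stop("metrics.weights must have 3 entries (a, b, c)")
  if (abs(sum(w) - 1) > 1e-9) {
    warning(sprintf("disturbance weights sum to %.3f, not 1", sum(w)))
  }
  cfg$metrics$weights <- as.numeric(w)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Write the resolved configuration beside the outputs
#'
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
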