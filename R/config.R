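default_run_config <- function() {
  list(
    seed = 1L,
    pixel_size = 1.37,
    control = "control",
    geometry = list(lx = 1970, ly = 1430, x_centre = 985),
    solver = list(dx = 1, dt = 0.1, eps = 1e-6, max_picard_iters = 100L),
    edge = list(canny_low = NULL, canny_high = NULL, canny_sigma = sqrt(2),
                dilation_radius = 15L, min_vacant_component = 10000L,
                median_window = 3L, connectivity = 8L),
    estimation = list(a_sr = 3.789e4, fraction = 0.02,
                      bracket = c(0.01, 0.05), d_bounds = c(1, 1e4)),
    assay = list(D = 132, lambda = 5.07e-2, K = 1.13e-3, C0 = 6.84e-4,
                 le0 = 300, frame_interval = 2, duration = 46,
                 count_times = c(0, 8, 16, 24, 46), cell_radius_px = 12,
                 intensity_noise_sd = 0.03, count_noise = "poisson",
                 le_noise_sd = 10, n_replicates = 3L, n_subregions = 3L,
                 subregion_x = 60))
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base))
      stop(sprintf("unknown configuration key: %s", full), call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key %s must be a mapping", full),
             call. = FALSE)
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a declarative YAML configuration (geometry, pixel size, solver,
#' edge-detection, estimation and synthetic-assay settings plus the run
#' seed), fills unspecified values with the package defaults and rejects
#' unknown keys. Command-line flags override configuration values, and
#' every pipeline run writes the fully resolved configuration beside its
#' outputs so a run can be reproduced exactly.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @param overrides Named list merged over the file values.
#' @return Object of class `run_config` (a validated nested list).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("configuration file not found: %s", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  if (length(overrides) > 0) cfg <- merge_config(cfg, overrides)
  # construct the typed objects once so invalid values fail on load
  rc_geom(cfg); rc_solver(cfg); rc_edge(cfg)
  structure(cfg, class = "run_config")
}

rc_geom <- function(cfg)
  domain_geometry(cfg$geometry$lx, cfg$geometry$ly, cfg$geometry$x_centre)

rc_solver <- function(cfg)
  solver_config(cfg$solver$dx, cfg$solver$dt, cfg$solver$eps,
                cfg$solver$max_picard_iters)

rc_edge <- function(cfg)
  edge_params(cfg$edge$canny_low, cfg$edge$canny_high, cfg$edge$canny_sigma,
              cfg$edge$dilation_radius, cfg$edge$min_vacant_component,
              cfg$edge$median_window, cfg$edge$connectivity)

rc_assay <- function(cfg, seed = cfg$seed) {
  a <- cfg$assay
  assay_config(params = fk_params(a$D, a$lambda, a$K, a$C0),
               geom = rc_geom(cfg), le0 = a$le0,
               frame_interval = a$frame_interval, duration = a$duration,
               count_times = a$count_times, pixel_size = cfg$pixel_size,
               cell_radius_px = a$cell_radius_px,
               intensity_noise_sd = a$intensity_noise_sd,
               count_noise = a$count_noise, le_noise_sd = a$le_noise_sd,
               n_replicates = a$n_replicates, n_subregions = a$n_subregions,
               a_sr = cfg$estimation$a_sr, subregion_x = a$subregion_x,
               solver = rc_solver(cfg), seed = seed)
}

write_resolved_config <- function(cfg, out) {
  dir <- if (dir.exists(out)) out else dirname(out)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plain <- unclass(cfg)
  yaml::write_yaml(plain, file.path(dir, "resolved_config.yaml"))
  invisible(NULL)
}
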