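#' @importFrom purrr map map_dbl
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed %% 1000003L)
  for (i in ids) s <- (s * 1009 + as.double(i) * 101 + 7) %% 2147483629
  as.integer(s)
}

default_subregions <- function(a_sr, geom, n = 3, x_min = 60) {
  side <- sqrt(a_sr)
  gap <- (geom$ly - n * side) / (n + 1)
  tibble::tibble(
    subregion_id = seq_len(n),
    x_min = x_min, x_max = x_min + side,
    y_min = gap + (seq_len(n) - 1) * (side + gap),
    y_max = gap + (seq_len(n) - 1) * (side + gap) + side)
}

#' Configuration of a synthetic scratch assay
#'
#' Bundles the ground-truth mechanistic parameters, imaging protocol and
#' noise settings from which a fully reproducible synthetic assay is
#' generated. The defaults emulate a standard live-imaging protocol:
#' frames every 2 h for 46 h on a 1970 x 1430 um field of view, a
#' vertical scratch of half-width 300 um centred at 985 um, three
#' replicates, three counting subregions of area 3.789e4 um^2 behind the
#' scratch, Poisson cell-count noise and 10 um Gaussian noise on the
#' measured half-width.
#'
#' @param params Ground-truth [fk_params()]; defaults to control-condition
#'   estimates for PC-3 cells.
#' @param geom [domain_geometry()].
#' @param le0 Initial scratch half-width (um).
#' @param frame_interval Imaging interval (h).
#' @param duration Assay duration (h).
#' @param count_times Times (h) at which subregion cells are counted; the
#'   final entry supplies the confluent counts used for `K`.
#' @param pixel_size Rendered pixel size (um/px).
#' @param cell_radius_px Rendered cell radius at confluence (px); the
#'   default 12 px (about 16 um at 1.37 um/px) is the radius of a cell
#'   tiling the substrate at the default carrying capacity,
#'   `1/sqrt(pi * K)`. Cells below confluent density spread linearly up
#'   to twice this radius (contact-inhibited spreading).
#' @param intensity_noise_sd Gaussian pixel-noise standard deviation
#'   (intensity units, images in `[0, 1]`).
#' @param count_noise `"poisson"` for Poisson-distributed subregion
#'   counts, `"none"` for deterministic round-half-up counts.
#' @param le_noise_sd Gaussian noise sd (um) added to the clean
#'   half-width series.
#' @param n_replicates Number of identically prepared replicates.
#' @param n_subregions Number of counting subregions.
#' @param a_sr Subregion area (um^2).
#' @param subregion_x Left edge (um) of the counting subregions (placed
#'   well behind the scratch).
#' @param solver [solver_config()] used for the ground-truth forward
#'   solve.
#' @param seed Integer seed; mandatory, every stochastic output is
#'   reproducible from `(config, seed)`.
#' @return Object of class `assay_config`.
#' @export
assay_config <- function(params = fk_params(D = 132, lambda = 5.07e-2,
                                            K = 1.13e-3, C0 = 6.84e-4),
                         geom = domain_geometry(), le0 = 300,
                         frame_interval = 2, duration = 46,
                         count_times = c(0, 8, 16, 24, 46),
                         pixel_size = 1.37, cell_radius_px = 12,
                         intensity_noise_sd = 0.03,
                         count_noise = c("poisson", "none"),
                         le_noise_sd = 10, n_replicates = 3,
                         n_subregions = 3, a_sr = 3.789e4,
                         subregion_x = 60,
                         solver = solver_config(), seed) {
  count_noise <- match.arg(count_noise)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1)
    stop("an integer `seed` is mandatory for a synthetic assay", call. = FALSE)
  stopifnot(inherits(params, "fk_params"), inherits(geom, "domain_geometry"),
            inherits(solver, "solver_config"),
            frame_interval > 0, duration >= 0, pixel_size > 0,
            cell_radius_px >= 1, intensity_noise_sd >= 0, le_noise_sd >= 0,
            n_replicates >= 1, n_subregions >= 1, a_sr > 0)
  count_times <- sort(unique(pmin(count_times, duration)))
  structure(list(params = params, geom = geom, le0 = le0,
                 frame_interval = frame_interval, duration = duration,
                 count_times = count_times, pixel_size = pixel_size,
                 cell_radius_px = cell_radius_px,
                 intensity_noise_sd = intensity_noise_sd,
                 count_noise = count_noise, le_noise_sd = le_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 n_subregions = as.integer(n_subregions), a_sr = a_sr,
                 subregions = default_subregions(a_sr, geom, n_subregions,
                                                 subregion_x),
                 solver = solver, seed = as.integer(seed)),
            class = "assay_config")
}

frame_times <- function(config) {
  if (config$duration == 0) return(0)
  seq(0, config$duration, by = config$frame_interval)
}

#' Noise-free forward simulation of a synthetic assay
#'
#' Solves the Fisher-Kolmogorov model at the frame times of the imaging
#' protocol and extracts the clean half-width series from the density
#' profiles (detection threshold 2 % of `K`).
#'
#' @param config An [assay_config()].
#' @return List with `profiles` (an `fk_profiles` tibble) and `le_clean`
#'   (tibble with `t_h`, `le_um`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "assay_config"))
  times <- frame_times(config)
  profiles <- solve_fk(config$params, le0 = config$le0, geom = config$geom,
                       config = config$solver, output_times = times)
  le <- front_position(profiles, config$params, fraction = 0.02,
                       geom = config$geom)
  list(profiles = profiles,
       le_clean = tibble::tibble(t_h = times, le_um = le))
}

subregion_density <- function(profile_vec, x, sr) {
  sel <- x >= sr$x_min & x <= sr$x_max
  mean(profile_vec[sel])
}

#' Sample subregion cell counts from density profiles
#'
#' Draws the per-subregion, per-time cell counts that the counting stage
#' of the estimator consumes: `N ~ Poisson(C(t) * A_SR)` with `C(t)` the
#' profile density averaged over the subregion's x-extent, or the
#' round-half-up expected count when count noise is disabled. Warns if a
#' subregion overlaps the scratch at t = 0.
#'
#' @param profiles An `fk_profiles` tibble from [solve_fk()] or
#'   [simulate_truth()] covering the requested count times.
#' @param config An [assay_config()] (supplies subregions, count times,
#'   area and noise model).
#' @param seed Integer seed for the Poisson draws.
#' @return Tibble with columns `subregion_id`, `t_h`, `n_cells`.
#' @export
sample_counts <- function(profiles, config, seed = config$seed) {
  stopifnot(inherits(config, "assay_config"))
  srs <- config$subregions
  if (any(srs$x_max > config$geom$x_centre - config$le0 &
          srs$x_min < config$geom$x_centre + config$le0))
    warning("subregion overlaps the scratch at t = 0", call. = FALSE)
  grid <- tidyr::expand_grid(subregion_id = srs$subregion_id,
                             t_h = config$count_times)
  dens <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    p <- profiles[abs(profiles$t_h - grid$t_h[i]) < 1e-8, ]
    if (nrow(p) == 0)
      stop(sprintf("no profile at count time t = %g h", grid$t_h[i]),
           call. = FALSE)
    subregion_density(p$density, p$x_um,
                      srs[srs$subregion_id == grid$subregion_id[i], ])
  })
  mu <- dens * config$a_sr
  n <- if (config$count_noise == "poisson") {
    with_seed(seed, stats::rpois(length(mu), mu))
  } else {
    as.integer(floor(mu + 0.5))
  }
  tibble::tibble(subregion_id = grid$subregion_id, t_h = grid$t_h,
                 n_cells = as.integer(n))
}

disk_kernel <- function(r) {
  span <- ceiling(r) + 1L
  off <- seq(-span, span)
  d <- sqrt(outer(off^2, off^2, "+"))
  w <- pmin(pmax(r + 0.5 - d, 0), 1)  # hard disk with a 1-px soft rim
  list(off = off, w = w, span = span)
}

# Cell-centre placement for the virtual monolayer. Centres are laid down
# by stratified inverse-CDF sampling in x (mass coordinate) with a
# jittered low-discrepancy spread in y: window count means still match
# C(x) * area, but the pattern has the sub-Poisson regularity of a
# contact-inhibited monolayer rather than the large voids of a pure
# Poisson draw, which no settled epithelial sheet shows.
place_cells <- function(c_cols, ps, npx, npy) {
  mass_col <- c_cols * ps * ps * npy     # expected cells per pixel column
  total <- sum(mass_col)
  n <- round(total)
  if (n < 1) return(NULL)
  cdf <- cumsum(mass_col) / total
  u <- (seq_len(n) - stats::runif(n)) / n
  cx <- stats::approx(c(0, cdf), c(0, seq_len(npx)), xout = u,
                      ties = "ordered", rule = 2)$y
  phi <- (sqrt(5) - 1) / 2
  cy <- ((seq_len(n) * phi + stats::runif(n, -0.18, 0.18)) %% 1) * npy
  list(cx = cx, cy = cy, n = n)
}

#' Render one synthetic phase-contrast-like frame
#'
#' Virtual microscopy for pipeline testing: cell centres are laid down
#' with local mean counts matching the supplied density profile
#' (uniform in y) but with the sub-Poisson spatial regularity of a
#' contact-inhibited monolayer (stratified placement); each cell is a
#' bright disk whose radius follows contact-inhibited spreading around
#' `cell_radius_px`, with per-cell intensity variation (max-blended so
#' rims stay crisp where cells overlap), and Gaussian pixel noise over a
#' darker background. Deterministic given `frame_seed`. The drawn cell
#' centres are attached as the `"cells"` attribute of the result.
#'
#' @param profile Single-time density tibble (`x_um`, `density`) with
#'   nonnegative densities.
#' @param config An [assay_config()].
#' @param frame_seed Integer seed for this frame.
#' @return An `assay_image`: list with `pixels` (matrix, rows = y),
#'   `t`, `pixel_size` and `geom`.
#' @export
render_frame <- function(profile, config, frame_seed) {
  stopifnot(inherits(config, "assay_config"))
  dens <- profile_to_vec(profile)
  if (any(dens < 0)) stop("density profile must be nonnegative", call. = FALSE)
  ps <- config$pixel_size
  npx <- round(config$geom$lx / ps)
  npy <- round(config$geom$ly / ps)
  x_cols <- (seq_len(npx) - 0.5) * ps
  c_cols <- stats::approx(profile$x_um, dens, xout = x_cols, rule = 2)$y
  background <- 0.15
  res <- with_seed(frame_seed, {
    img <- matrix(background, nrow = npy, ncol = npx)
    cells <- NULL
    pl <- place_cells(c_cols, ps, npx, npy)
    if (!is.null(pl)) {
      # contact-inhibited spreading: crowded cells pack at the confluent
      # radius, sparse cells spread up to twice that (linearly)
      c_here <- stats::approx(x_cols, c_cols, xout = pmax(pmin(pl$cx, npx), 1) * ps - ps / 2,
                              rule = 2)$y
      r_px <- config$cell_radius_px *
        pmin(sqrt(config$params$K / pmax(c_here, 1e-12)), 2)
      r_int <- pmax(2L, as.integer(round(r_px)))
      amp <- stats::runif(pl$n, 0.45, 0.75)
      kerns <- lapply(seq_len(max(r_int)), function(r) disk_kernel(r))
      for (i in seq_len(pl$n)) {
        kern <- kerns[[r_int[i]]]
        ci <- round(pl$cx[i]); ri <- round(pl$cy[i])
        cols <- ci + kern$off; rows <- ri + kern$off
        okc <- cols >= 1 & cols <= npx; okr <- rows >= 1 & rows <= npy
        patch <- background + amp[i] * kern$w[okr, okc, drop = FALSE]
        sub <- img[rows[okr], cols[okc], drop = FALSE]
        img[rows[okr], cols[okc]] <- pmax(sub, patch)
      }
      cells <- tibble::tibble(x_px = pl$cx, y_px = pl$cy, r_px = r_px)
    }
    if (config$intensity_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, config$intensity_noise_sd)
    list(img = pmax(pmin(img, 1), 0), cells = cells)
  })
  t_h <- if ("t_h" %in% names(profile)) profile$t_h[1] else 0
  out <- assay_image(res$img, t = t_h, pixel_size = ps, geom = config$geom)
  attr(out, "cells") <- res$cells
  out
}

#' Generate a complete reproducible synthetic scratch assay
#'
#' Bundles the noise-free forward simulation, per-replicate subregion
#' counts, per-replicate noisy half-width series, and (optionally)
#' rendered image stacks into one object whose every stochastic artefact
#' is reproducible from `(config, seed)`.
#'
#' @param config An [assay_config()].
#' @param render If `TRUE`, also render a full image stack per replicate
#'   (slower; the tabular outputs alone are enough for the count- and
#'   edge-based estimators).
#' @return Object of class `synthetic_assay`: list with `config`,
#'   `profiles`, `le_clean`, `le_noisy` (per replicate), `counts` (per
#'   replicate), `frames` (list of stacks or `NULL`) and `ground_truth`.
#' @export
generate_assay <- function(config, render = FALSE) {
  stopifnot(inherits(config, "assay_config"))
  truth <- simulate_truth(config)
  reps <- seq_len(config$n_replicates)
  counts <- dplyr::bind_rows(lapply(reps, function(r)
    dplyr::mutate(
      sample_counts(truth$profiles, config, seed = derive_seed(config$seed, 1, r)),
      replicate_id = r, .before = 1)))
  le_noisy <- dplyr::bind_rows(lapply(reps, function(r) {
    noise <- if (config$le_noise_sd > 0)
      with_seed(derive_seed(config$seed, 2, r),
                stats::rnorm(nrow(truth$le_clean), 0, config$le_noise_sd))
    else 0
    tibble::tibble(replicate_id = r, t_h = truth$le_clean$t_h,
                   le_um = pmax(0, truth$le_clean$le_um + noise))
  }))
  frames <- NULL
  if (isTRUE(render)) {
    times <- frame_times(config)
    frames <- lapply(reps, function(r)
      lapply(seq_along(times), function(i)
        render_frame(profiles_at(truth$profiles, times[i]), config,
                     frame_seed = derive_seed(config$seed, 3, r, i))))
  }
  structure(list(config = config, profiles = truth$profiles,
                 le_clean = truth$le_clean, le_noisy = le_noisy,
                 counts = counts, frames = frames,
                 ground_truth = list(params = config$params,
                                     le0 = config$le0, seed = config$seed)),
            class = "synthetic_assay")
}

profiles_at <- function(profiles, t) {
  p <- profiles[abs(profiles$t_h - t) < 1e-8, ]
  if (nrow(p) == 0) stop(sprintf("no profile at t = %g h", t), call. = FALSE)
  p
}

#' @export
print.synthetic_assay <- function(x, ...) {
  cat(sprintf(
    "<synthetic_assay> %d replicate(s), %d frame time(s), seed %d\n",
    x$config$n_replicates, length(unique(x$le_clean$t_h)), x$config$seed))
  cat(sprintf("  truth: D = %.4g, lambda = %.4g, K = %.4g, C0 = %.4g, LE0 = %g um\n",
              x$ground_truth$params$D, x$ground_truth$params$lambda,
              x$ground_truth$params$K, x$ground_truth$params$C0,
              x$ground_truth$le0))
  invisible(x)
}
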