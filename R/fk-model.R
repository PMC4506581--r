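#' @useDynLib scratchfk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
NULL

fk_grid <- function(geom, config) {
  n <- round(geom$lx / config$dx) + 1L
  if (abs((n - 1L) * config$dx - geom$lx) > 1e-8 * geom$lx)
    stop("domain width lx must be an integer multiple of dx", call. = FALSE)
  seq(0, by = config$dx, length.out = n)
}

#' Scratch-wound initial condition
#'
#' Builds the step initial density profile for a vertical scratch of
#' half-width `le0` centred at `geom$x_centre`: the monolayer density `C0`
#' outside the scratch and zero inside. Grid nodes falling exactly on a
#' scratch boundary follow the half-open convention: the left boundary
#' node is vacant, the right boundary node is occupied.
#'
#' @param params An [fk_params()] object (only `C0` is used here).
#' @param le0 Initial scratch half-width (um), in `(0, lx/2)`.
#' @param geom A [domain_geometry()].
#' @param config A [solver_config()] (sets the grid spacing).
#' @return A tibble with columns `x_um`, `density`, `t_h` (all `t_h = 0`).
#' @examples
#' ic <- build_initial_condition(
#'   fk_params(132, 5.07e-2, 1.13e-3, 6.84e-4), le0 = 300)
#' range(ic$density)
#' @export
build_initial_condition <- function(params, le0,
                                    geom = domain_geometry(),
                                    config = solver_config()) {
  stopifnot(inherits(params, "fk_params"))
  if (!is.numeric(le0) || length(le0) != 1 || !is.finite(le0) ||
      le0 <= 0 || le0 >= geom$lx / 2)
    stop("invalid scratch geometry: `le0` must lie in (0, lx/2)", call. = FALSE)
  x <- fk_grid(geom, config)
  vac <- x >= (geom$x_centre - le0) & x < (geom$x_centre + le0)
  tibble::tibble(x_um = x,
                 density = ifelse(vac, 0, params$C0),
                 t_h = 0)
}

#' Solve a tridiagonal linear system (Thomas algorithm)
#'
#' Direct O(n) solve of `T x = rhs` where `T` is tridiagonal with
#' sub-diagonal `lower`, diagonal `diag` and super-diagonal `upper`.
#'
#' @param lower,upper Off-diagonal bands, length `n - 1` (length 0 for
#'   `n = 1`).
#' @param diag Main diagonal, length `n`.
#' @param rhs Right-hand side, length `n`.
#' @return The solution vector, length `n`.
#' @examples
#' thomas_solve(lower = c(1, 1), diag = c(2, 2, 2), upper = c(1, 1),
#'              rhs = c(1, 2, 3))
#' @export
thomas_solve <- function(lower, diag, upper, rhs) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  diag <- as.numeric(diag); rhs <- as.numeric(rhs)
  n <- length(diag)
  if (n == 1) {
    if (diag == 0) stop("singular tridiagonal system: zero pivot at row 1",
                        call. = FALSE)
    return(rhs / diag)
  }
  thomas_solve_cpp(lower, diag, upper, rhs)
}

profile_to_vec <- function(profile) {
  if (is.numeric(profile)) return(profile)
  stopifnot(is.data.frame(profile), all(c("x_um", "density") %in% names(profile)))
  profile$density
}

#' Advance a density profile by one implicit time step
#'
#' One backward-Euler step of the 1-D Fisher-Kolmogorov equation with
#' zero-flux boundaries. The nonlinear logistic reaction is handled by
#' Picard iteration, lagging only the quadratic density factor so each
#' inner solve is a tridiagonal linear system.
#'
#' @param profile A tibble with columns `x_um`, `density` (and optionally
#'   `t_h`) on a uniform grid.
#' @inheritParams build_initial_condition
#' @return A tibble of the same shape at time `t + dt`.
#' @export
backward_euler_step <- function(profile, params, config = solver_config()) {
  stopifnot(inherits(params, "fk_params"))
  x <- profile$x_um
  dxs <- diff(x)
  if (length(dxs) < 2 || max(abs(dxs - dxs[1])) > 1e-8 * dxs[1])
    stop("profile grid must be uniform with at least 3 nodes", call. = FALSE)
  t0 <- if ("t_h" %in% names(profile)) profile$t_h[1] else 0
  res <- fk_solve_cpp(profile$density, params$D, params$lambda, params$K,
                      dxs[1], config$dt, config$eps, config$max_picard_iters,
                      1L)
  tibble::tibble(x_um = x, density = res$profiles[, 1], t_h = t0 + config$dt)
}

snap_steps <- function(times, dt) {
  steps <- as.integer(round(times / dt))
  snapped <- steps * dt
  off <- abs(snapped - times) > 1e-8 * max(dt, 1)
  if (any(off))
    warning(sprintf("output times snapped to the solver step (dt = %g h): %s",
                    dt, paste(signif(times[off], 6), collapse = ", ")),
            call. = FALSE)
  list(steps = steps, times = snapped)
}

.fk_solve_mat <- function(c_init, params, config, steps) {
  fk_solve_cpp(c_init, params$D, params$lambda, params$K,
               config$dx, config$dt, config$eps, config$max_picard_iters,
               as.integer(steps))
}

#' Solve the 1-D Fisher-Kolmogorov equation
#'
#' Integrates the scratch-assay reaction-diffusion model
#' `dC/dt = D d^2C/dx^2 + lambda C (1 - C/K)` on `[0, lx]` with zero-flux
#' boundaries from the step initial condition of [build_initial_condition()]
#' (or a spatially uniform monolayer when `le0 = NULL`), using backward
#' Euler time stepping, Picard linearisation and the Thomas algorithm.
#' Requested output times are snapped to the nearest multiple of `dt`
#' (with a warning when the snap is non-trivial).
#'
#' @inheritParams build_initial_condition
#' @param le0 Initial scratch half-width (um), or `NULL` for a uniform
#'   initial monolayer at density `C0` (no scratch).
#' @param output_times Nonnegative, sorted times (h) at which to record the
#'   density profile.
#' @return A tibble of class `fk_profiles` in long format with columns
#'   `x_um`, `density`, `t_h`, plus attributes `params`, `geom`, `config`
#'   and `picard_iters`.
#' @examples
#' sol <- solve_fk(fk_params(132, 5.07e-2, 1.13e-3, 6.84e-4), le0 = 300,
#'                 output_times = c(0, 23, 46))
#' dplyr::count(sol, t_h)
#' @export
solve_fk <- function(params, le0 = NULL, geom = domain_geometry(),
                     config = solver_config(), output_times = seq(0, 46, by = 2)) {
  stopifnot(inherits(params, "fk_params"))
  if (length(output_times) < 1 || any(output_times < 0) ||
      is.unsorted(output_times))
    stop("output_times must be nonnegative and sorted", call. = FALSE)
  c_init <- if (is.null(le0)) {
    rep(params$C0, length(fk_grid(geom, config)))
  } else {
    build_initial_condition(params, le0, geom, config)$density
  }
  sn <- snap_steps(output_times, config$dt)
  res <- .fk_solve_mat(c_init, params, config, sn$steps)
  x <- fk_grid(geom, config)
  out <- tibble::tibble(
    x_um = rep(x, times = length(sn$steps)),
    density = as.vector(res$profiles),
    t_h = rep(sn$times, each = length(x)))
  structure(out,
            class = c("fk_profiles", class(out)),
            params = params, geom = geom, config = config,
            picard_iters = res$picard_iters)
}

#' Closed-form logistic growth
#'
#' Solution of the logistic equation `dC/dt = lambda C (1 - C/K)` with
#' `C(0) = C0`, the limit of the Fisher-Kolmogorov model in spatially
#' uniform subregions where the diffusion term vanishes.
#'
#' @param C0 Initial density (cells/um^2), `>= 0`.
#' @param K Carrying-capacity density (cells/um^2), `> 0`.
#' @param lambda Proliferation rate (/h).
#' @param t Time(s) (h), `>= 0`.
#' @return Density at time `t` (vectorised over `t`).
#' @examples
#' logistic_solution(6.84e-4, 1.13e-3, 5.07e-2, c(0, 24, 46))
#' @export
logistic_solution <- function(C0, K, lambda, t) {
  if (!is.numeric(K) || K <= 0)
    stop("carrying capacity `K` must be > 0", call. = FALSE)
  if (C0 < 0) stop("initial density `C0` must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("time `t` must be >= 0", call. = FALSE)
  K * C0 / (C0 - exp(-lambda * t) * (C0 - K))
}

front_from_vec <- function(C, x, thr, x_centre) {
  below <- C < thr
  if (!any(below)) return(0)
  if (all(below))
    stop("degenerate profile: density below the detection threshold everywhere",
         call. = FALSE)
  iL <- which(below)[1]
  iR <- which(below)[length(which(below))]
  xl <- if (iL == 1) x[1] else {
    x[iL - 1] + (C[iL - 1] - thr) / (C[iL - 1] - C[iL]) * (x[iL] - x[iL - 1])
  }
  n <- length(C)
  xr <- if (iR == n) x[n] else {
    x[iR] + (thr - C[iR]) / (C[iR + 1] - C[iR]) * (x[iR + 1] - x[iR])
  }
  mean(c(abs(xl - x_centre), abs(xr - x_centre)))
}

#' Model leading-edge position from a density profile
#'
#' Locates the left and right crossings of the detection threshold
#' `fraction * K` by linear interpolation between adjacent grid nodes and
#' returns the mean distance of the two crossings from the scratch centre
#' (the model half-width `L_E`). Automated edge detection corresponds to a
#' density of roughly 2 % of the carrying capacity, the default here.
#' Returns 0 when the profile is everywhere above the threshold (closed
#' scratch); a profile everywhere below the threshold is an error.
#'
#' @param profile A tibble with columns `x_um`, `density` and optionally
#'   `t_h`; with several times present, one value per time is returned.
#' @param params An [fk_params()] (supplies `K`).
#' @param fraction Detection threshold as a fraction of `K`, in `(0, 1)`.
#' @param geom A [domain_geometry()] (supplies the scratch centre).
#' @return Numeric vector of half-widths (um), one per time present.
#' @export
front_position <- function(profile, params, fraction = 0.02,
                           geom = domain_geometry()) {
  stopifnot(inherits(params, "fk_params"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  thr <- fraction * params$K
  if (!is.data.frame(profile))
    stop("`profile` must be a data frame with x_um and density", call. = FALSE)
  if ("t_h" %in% names(profile) && length(unique(profile$t_h)) > 1) {
    sp <- split(profile, profile$t_h)
    return(vapply(sp, function(p) front_from_vec(p$density, p$x_um, thr,
                                                 geom$x_centre),
                  numeric(1), USE.NAMES = FALSE))
  }
  front_from_vec(profile$density, profile$x_um, thr, geom$x_centre)
}

#' Cell doubling time
#'
#' `log(2) / lambda`, the time for the population to double at low
#' density.
#'
#' @param lambda Proliferation rate (/h), `> 0`.
#' @return Doubling time (h).
#' @examples
#' doubling_time(5.07e-2) # about 14 h
#' @export
doubling_time <- function(lambda) {
  if (!is.numeric(lambda) || any(lambda <= 0))
    stop("`lambda` must be > 0 to define a doubling time", call. = FALSE)
  log(2) / lambda
}

#' Average a two-dimensional density field over y
#'
#' Collapses a rectangular field `C(x, y)` on a uniform y-grid to the
#' one-dimensional profile `C(x)` by trapezoid-rule averaging over y —
#' exact whenever the field does not vary with y, which is the modelling
#' assumption for a vertical scratch.
#'
#' @param field Numeric matrix with rows indexing y and columns indexing x.
#' @return Numeric vector of length `ncol(field)`: the y-averaged profile.
#' @export
average_over_y <- function(field) {
  if (!is.matrix(field) || length(field) == 0)
    stop("`field` must be a non-empty numeric matrix", call. = FALSE)
  ny <- nrow(field)
  if (ny == 1) return(as.numeric(field[1, ]))
  w <- c(0.5, rep(1, ny - 2), 0.5)
  as.numeric(colSums(field * w) / sum(w))
}

trapz_mass <- function(C, dx) {
  n <- length(C)
  dx * (sum(C) - 0.5 * (C[1] + C[n]))
}
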