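#' @importFrom stats optimize sd rnorm rpois median quantile setNames
#' @importFrom dplyr %>% filter group_by summarise arrange mutate ungroup
NULL

check_counts <- function(counts, integer_counts = TRUE) {
  if (!is.data.frame(counts) || nrow(counts) == 0)
    stop("missing data: cell-count table is empty", call. = FALSE)
  if (!all(c("t_h", "n_cells") %in% names(counts)))
    stop("cell-count table needs columns `t_h` and `n_cells`", call. = FALSE)
  if (any(counts$n_cells < 0))
    stop("cell counts must be nonnegative", call. = FALSE)
  if (integer_counts &&
      any(abs(counts$n_cells - round(counts$n_cells)) > 1e-8))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  counts
}

density_estimate <- function(n, a_sr, at_time, parameter) {
  if (length(n) == 0)
    stop(sprintf("missing data: no cell counts at t = %g h", at_time),
         call. = FALSE)
  if (length(n) == 1)
    warning(sprintf("single cell count at t = %g h: sd set to 0", at_time),
            call. = FALSE)
  m <- mean(n) / a_sr
  if (m == 0)
    warning(sprintf("degenerate %s: all cell counts are zero", parameter),
            call. = FALSE)
  tibble::tibble(parameter = parameter,
                 mean = m,
                 sd = if (length(n) > 1) stats::sd(n) / a_sr else 0,
                 n_counts = length(n),
                 t_h = at_time)
}

#' Estimate the carrying-capacity density from confluent cell counts
#'
#' Carrying capacity is estimated as the mean cell count per subregion at
#' the final observation time (when the monolayer has grown to confluence)
#' divided by the subregion area: `K = <N> / A_SR`. The spread is the
#' sample standard deviation of the counts on the same scale.
#'
#' @param counts Tibble of subregion cell counts with columns `t_h`,
#'   `n_cells` and optionally `replicate_id`, `subregion_id`.
#' @param a_sr Subregion area (um^2); default 3.789e4.
#' @param at_time Time (h) of the confluent counts; defaults to the last
#'   time present.
#' @return One-row tibble with columns `parameter`, `mean`, `sd`,
#'   `n_counts`, `t_h` (densities in cells/um^2).
#' @examples
#' estimate_K(tibble::tibble(t_h = 46, n_cells = c(43, 42, 44)))
#' @export
estimate_K <- function(counts, a_sr = 3.789e4, at_time = NULL) {
  counts <- check_counts(counts)
  stopifnot(is.numeric(a_sr), a_sr > 0)
  if (is.null(at_time)) at_time <- max(counts$t_h)
  n <- counts$n_cells[abs(counts$t_h - at_time) < 1e-8]
  density_estimate(n, a_sr, at_time, "K")
}

#' Estimate the initial monolayer density from the first frame's counts
#'
#' As [estimate_K()], applied to the counts taken immediately after the
#' scratch is made (t = 0 h).
#'
#' @inheritParams estimate_K
#' @return One-row tibble as in [estimate_K()], with `parameter = "C0"`.
#' @examples
#' estimate_C0(tibble::tibble(t_h = 0, n_cells = c(26, 25, 27)))
#' @export
estimate_C0 <- function(counts, a_sr = 3.789e4) {
  counts <- check_counts(counts)
  stopifnot(is.numeric(a_sr), a_sr > 0)
  n <- counts$n_cells[abs(counts$t_h) < 1e-8]
  out <- density_estimate(n, a_sr, 0, "C0")
  out
}

warn_if_at_bound <- function(value, bounds, what) {
  span <- diff(bounds)
  if (value - bounds[1] < 1e-4 * span || bounds[2] - value < 1e-4 * span)
    warning(sprintf("%s estimate %.4g is at an optimiser bound [%g, %g]",
                    what, value, bounds[1], bounds[2]), call. = FALSE)
  value
}

#' Fit the proliferation rate by least squares on subregion densities
#'
#' For each experimental replicate, the observed subregion densities
#' (counts divided by `a_sr`, averaged over subregions at each time) are
#' matched against the closed-form logistic curve with `K` and `C0` held
#' fixed at their previously estimated values; `lambda` minimises the
#' unweighted sum of squared density residuals (bounded one-dimensional
#' least squares via Brent's method). The condition-level estimate is the
#' mean of the per-replicate values, with spread reported as the sample
#' standard deviation, following the sequential design in which each
#' parameter is estimated one at a time.
#'
#' @inheritParams estimate_K
#' @param k,c0 Fixed carrying capacity and initial density (cells/um^2).
#' @param bounds Search interval for `lambda` (/h).
#' @return Object of class `lambda_fit`: list with `lam_mean`, `lam_sd`,
#'   a per-replicate tibble `replicates` (`replicate_id`, `lambda`, `sse`,
#'   `n_times`), and the fixed `k`, `c0`.
#' @export
fit_lambda <- function(counts, k, c0, a_sr = 3.789e4,
                       bounds = c(1e-4, 1)) {
  # fractional counts are allowed here: subregion averaging produces them
  counts <- check_counts(counts, integer_counts = FALSE)
  stopifnot(is.numeric(k), k > 0, is.numeric(c0), c0 >= 0)
  if (!"replicate_id" %in% names(counts)) counts$replicate_id <- 1L
  obs <- counts %>%
    dplyr::group_by(.data$replicate_id, .data$t_h) %>%
    dplyr::summarise(density = mean(.data$n_cells) / a_sr, .groups = "drop")
  reps <- split(obs, obs$replicate_id)
  fit_one <- function(d) {
    if (length(unique(d$t_h)) < 2)
      stop("insufficient data: need counts at >= 2 distinct times per replicate",
           call. = FALSE)
    sse <- function(l)
      sum((d$density - logistic_solution(c0, k, l, d$t_h))^2)
    opt <- stats::optimize(sse, interval = bounds, tol = 1e-10)
    lam <- warn_if_at_bound(opt$minimum, bounds, "lambda")
    tibble::tibble(replicate_id = d$replicate_id[1], lambda = lam,
                   sse = opt$objective, n_times = length(unique(d$t_h)))
  }
  tab <- dplyr::bind_rows(lapply(reps, fit_one))
  structure(list(lam_mean = mean(tab$lambda),
                 lam_sd = if (nrow(tab) > 1) stats::sd(tab$lambda) else 0,
                 replicates = tab, k = k, c0 = c0, bounds = bounds),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("<lambda_fit> lambda = %.4g +/- %.4g /h (%d replicate%s)\n",
              x$lam_mean, x$lam_sd, nrow(x$replicates),
              if (nrow(x$replicates) == 1) "" else "s"))
  invisible(x)
}

check_le_series <- function(le_series) {
  if (!is.data.frame(le_series) || nrow(le_series) == 0)
    stop("missing data: leading-edge series is empty", call. = FALSE)
  if (!all(c("t_h", "le_um") %in% names(le_series)))
    stop("leading-edge series needs columns `t_h` and `le_um`", call. = FALSE)
  if (!"replicate_id" %in% names(le_series)) le_series$replicate_id <- 1L
  le_series
}

fit_d_one <- function(d, params, geom, config, fraction, d_bounds) {
  d <- dplyr::arrange(d, .data$t_h)
  if (nrow(d) < 3)
    stop("insufficient data: need >= 3 leading-edge time points per replicate",
         call. = FALSE)
  le0 <- d$le_um[1]
  if (le0 <= 0 || le0 >= geom$lx / 2)
    stop("invalid scratch geometry: first-frame half-width outside (0, lx/2)",
         call. = FALSE)
  c_init <- build_initial_condition(params, le0, geom, config)$density
  steps <- as.integer(round(d$t_h / config$dt))
  x <- fk_grid(geom, config)
  thr_par <- params
  sse <- function(log10_d) {
    p <- fk_params(10^log10_d, params$lambda, params$K, params$C0)
    res <- .fk_solve_mat(c_init, p, config, steps)
    le_mod <- apply(res$profiles, 2, front_from_vec, x = x,
                    thr = fraction * params$K, x_centre = geom$x_centre)
    sum((d$le_um - le_mod)^2)
  }
  opt <- stats::optimize(sse, interval = log10(d_bounds), tol = 2e-4)
  if (min(opt$minimum - log10(d_bounds[1]),
          log10(d_bounds[2]) - opt$minimum) < 1e-3)
    warning(sprintf(
      "diffusivity estimate %.4g um^2/h is at an optimiser bound [%g, %g]",
      10^opt$minimum, d_bounds[1], d_bounds[2]), call. = FALSE)
  tibble::tibble(replicate_id = d$replicate_id[1], fraction = fraction,
                 d = 10^opt$minimum, sse = opt$objective)
}

#' Fit the cell diffusivity from leading-edge time series
#'
#' With `lambda`, `K` and `C0` held fixed, each replicate's observed
#' half-width series `L_E(t)` is matched against the half-width extracted
#' from the numerical Fisher-Kolmogorov solution (detection threshold at
#' `fraction` of `K`, default 2 %); `D` minimises the unweighted sum of
#' squared residuals by bounded one-dimensional least squares on a log
#' scale. The condition-level `D` is the mean over replicates. The
#' reported interval `d_low`-`d_high` reruns the whole procedure with the
#' detection threshold at 1 % and 5 % of `K`: a lower threshold places the
#' model edge deeper into the scratch and so implies less spreading
#' (smaller `D`), a higher threshold implies more.
#'
#' @param le_series Tibble with columns `t_h`, `le_um` and optionally
#'   `replicate_id`; each replicate needs at least 3 time points. The
#'   model initial half-width is taken from each replicate's first frame.
#' @param params [fk_params()] carrying the fixed `lambda`, `K`, `C0`
#'   (the `D` slot is ignored).
#' @param geom,config Domain geometry and solver settings.
#' @param fraction Detection-threshold fraction of `K` for the point
#'   estimate (default 0.02).
#' @param bracket Fractions used for the lower/upper reruns
#'   (default `c(0.01, 0.05)`; `NULL` skips the reruns and collapses the
#'   interval onto the point estimate).
#' @param d_bounds Search interval for `D` (um^2/h).
#' @return Object of class `diffusivity_fit`: list with `d_mean`,
#'   `d_low`, `d_high`, `fraction`, and per-replicate tibble `replicates`
#'   (one row per replicate and threshold fraction).
#' @export
fit_D <- function(le_series, params, geom = domain_geometry(),
                  config = solver_config(), fraction = 0.02,
                  bracket = c(0.01, 0.05), d_bounds = c(1, 1e4)) {
  le_series <- check_le_series(le_series)
  stopifnot(inherits(params, "fk_params"))
  reps <- split(le_series, le_series$replicate_id)
  fracs <- unique(c(fraction, bracket))   # bracket = NULL skips the reruns
  tab <- dplyr::bind_rows(lapply(fracs, function(f)
    dplyr::bind_rows(lapply(reps, fit_d_one, params = params, geom = geom,
                            config = config, fraction = f,
                            d_bounds = d_bounds))))
  mean_at <- function(f) mean(tab$d[tab$fraction == f])
  d_mean <- mean_at(fraction)
  d_reps <- tab$d[tab$fraction == fraction]
  bracket_means <- vapply(bracket, mean_at, numeric(1))
  structure(list(d_mean = d_mean,
                 d_sd = if (length(d_reps) > 1) stats::sd(d_reps) else 0,
                 d_low = min(bracket_means, d_mean),
                 d_high = max(bracket_means, d_mean),
                 fraction = fraction, bracket = bracket,
                 replicates = tab),
            class = "diffusivity_fit")
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf("<diffusivity_fit> D = %.4g um^2/h (threshold interval %.4g-%.4g)\n",
              x$d_mean, x$d_low, x$d_high))
  invisible(x)
}

stage <- function(label, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e)
      stop(sprintf("%s stage: %s", label, conditionMessage(e)), call. = FALSE)),
    warning = function(w) {
      warning(sprintf("%s stage: %s", label, conditionMessage(w)),
              call. = FALSE)
      invokeRestart("muffleWarning")
    })
}

#' Sequential three-stage parameter estimation for one condition
#'
#' Runs the full sequential estimator on one experimental condition:
#' carrying capacity `K` from the confluent (final-time) counts, initial
#' density `C0` from the first-frame counts, proliferation rate `lambda`
#' by logistic least squares with `K` and `C0` fixed, and diffusivity `D`
#' by matching the observed leading-edge series to the Fisher-Kolmogorov
#' solution with all other parameters fixed. Any stage failure aborts
#' with a stage-labelled error.
#'
#' @param counts Subregion cell-count tibble spanning the assay (columns
#'   `t_h`, `n_cells`, optionally `replicate_id`, `subregion_id`); the
#'   final time supplies `K` and `t = 0` supplies `C0`.
#' @param le_series Leading-edge tibble as in [fit_D()].
#' @param a_sr Subregion area (um^2).
#' @param geom,config Domain geometry and solver settings.
#' @param condition Condition label carried into the summary.
#' @param fraction,bracket,d_bounds Passed to [fit_D()].
#' @return Object of class `condition_summary`: list with `condition`,
#'   the component estimates (`k`, `c0`, `lambda_fit`, `d_fit`) and the
#'   doubling time `t_d` (h).
#' @export
sequential_estimate <- function(counts, le_series, a_sr = 3.789e4,
                                geom = domain_geometry(),
                                config = solver_config(),
                                condition = "condition",
                                fraction = 0.02, bracket = c(0.01, 0.05),
                                d_bounds = c(1, 1e4)) {
  k_est <- stage("carrying-capacity", estimate_K(counts, a_sr))
  c0_est <- stage("initial-density", estimate_C0(counts, a_sr))
  lam <- stage("proliferation",
               fit_lambda(counts, k = k_est$mean, c0 = c0_est$mean,
                          a_sr = a_sr))
  d_fit <- stage("diffusivity", {
    if (is.null(le_series)) stop("leading-edge series missing", call. = FALSE)
    fit_D(le_series,
          fk_params(D = 1, lambda = lam$lam_mean, K = k_est$mean,
                    C0 = min(c0_est$mean, k_est$mean)),
          geom = geom, config = config, fraction = fraction,
          bracket = bracket, d_bounds = d_bounds)
  })
  structure(list(condition = condition, k = k_est, c0 = c0_est,
                 lambda_fit = lam, d_fit = d_fit,
                 t_d = if (lam$lam_mean > 0) log(2) / lam$lam_mean else NA_real_),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s\n", x$condition))
  cat(sprintf("  K      = %.4g +/- %.4g cells/um^2\n", x$k$mean, x$k$sd))
  cat(sprintf("  C0     = %.4g +/- %.4g cells/um^2\n", x$c0$mean, x$c0$sd))
  cat(sprintf("  lambda = %.4g +/- %.4g /h (doubling time %.3g h)\n",
              x$lambda_fit$lam_mean, x$lambda_fit$lam_sd, x$t_d))
  cat(sprintf("  D      = %.4g um^2/h (threshold interval %.4g-%.4g)\n",
              x$d_fit$d_mean, x$d_fit$d_low, x$d_fit$d_high))
  invisible(x)
}

summary_table <- function(summaries) {
  if (is.data.frame(summaries)) {
    stopifnot(all(c("condition", "K", "lambda", "D") %in% names(summaries)))
    return(summaries)
  }
  if (inherits(summaries, "condition_summary")) summaries <- list(summaries)
  dplyr::bind_rows(lapply(summaries, function(s)
    tibble::tibble(condition = s$condition, K = s$k$mean,
                   lambda = s$lambda_fit$lam_mean, D = s$d_fit$d_mean)))
}

#' Cross-condition variability of the estimated parameters
#'
#' For each of `K`, `lambda` and `D`, the maximum relative deviation (in
#' per cent) of any non-control condition's mean estimate from the
#' control: `100 * max_c |theta_c - theta_control| / theta_control`. This
#' is the summary used to judge which mechanisms a treatment acts on.
#'
#' @param summaries Either a data frame with columns `condition`, `K`,
#'   `lambda`, `D` (one row per condition) or a list of
#'   `condition_summary` objects.
#' @param control Label of the control condition (must be present).
#' @return Tibble with columns `parameter`, `max_rel_dev_pct`,
#'   `worst_condition`.
#' @examples
#' condition_variability(pc3_egf_estimates())
#' @export
condition_variability <- function(summaries, control = "control") {
  tab <- summary_table(summaries)
  if (!control %in% tab$condition)
    stop(sprintf("control condition '%s' not found", control), call. = FALSE)
  ctrl <- tab[tab$condition == control, ]
  rest <- tab[tab$condition != control, ]
  if (nrow(rest) == 0)
    stop("need at least one non-control condition", call. = FALSE)
  one <- function(par) {
    dev <- 100 * abs(rest[[par]] - ctrl[[par]]) / ctrl[[par]]
    i <- which.max(dev)
    tibble::tibble(parameter = par, max_rel_dev_pct = dev[i],
                   worst_condition = rest$condition[i])
  }
  dplyr::bind_rows(lapply(c("K", "lambda", "D"), one))
}

#' Published PC-3 EGF dose-response parameter estimates
#'
#' Reference table of mean Fisher-Kolmogorov parameter estimates for PC-3
#' prostate-cancer scratch assays under increasing epidermal growth
#' factor (EGF) concentrations, bundled with the package as a comparison
#' fixture for cross-condition variability summaries. Columns: condition
#' label, `K` (cells/um^2), `lambda` (/h), `D` (um^2/h), `C0`
#' (cells/um^2).
#'
#' @return A tibble with six rows (control and five EGF doses).
#' @examples
#' pc3_egf_estimates()
#' @export
pc3_egf_estimates <- function() {
  path <- system.file("extdata", "pc3_egf_estimates.csv",
                      package = "scratchfk", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
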