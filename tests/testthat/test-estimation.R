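test_that("carrying capacity and initial density follow mean count / area", {
  k <- estimate_K(tibble::tibble(t_h = 46, n_cells = c(43, 42, 44)))
  expect_equal(k$mean, 43 / 37890)
  expect_equal(k$sd, stats::sd(c(43, 42, 44)) / 37890)
  expect_equal(k$n_counts, 3)

  c0 <- estimate_C0(tibble::tibble(t_h = 0, n_cells = c(26, 25, 27)))
  expect_equal(c0$mean, 26 / 37890)

  # identical replicates: zero spread
  expect_equal(estimate_K(tibble::tibble(t_h = 46, n_cells = rep(41, 3)))$sd, 0)
  # all-zero counts warn about a degenerate carrying capacity
  expect_warning(estimate_K(tibble::tibble(t_h = 46, n_cells = c(0, 0, 0))),
                 "degenerate")
  # a single count warns and sets sd to 0
  expect_warning(k1 <- estimate_K(tibble::tibble(t_h = 46, n_cells = 40)),
                 "single")
  expect_equal(k1$sd, 0)
  expect_error(estimate_K(tibble::tibble(t_h = numeric(0),
                                         n_cells = integer(0))), "empty")
  expect_error(estimate_C0(tibble::tibble(t_h = 8, n_cells = 30)),
               "t = 0")
})

test_that("lambda is recovered exactly from noise-free logistic data", {
  a_sr <- 3.789e4
  k <- 1.13e-3; c0 <- 6.84e-4; lam_true <- 0.05
  tt <- c(0, 8, 16, 24, 46)
  counts <- tibble::tibble(
    t_h = tt, n_cells = logistic_solution(c0, k, lam_true, tt) * a_sr)
  fit <- fit_lambda(counts, k, c0, a_sr)
  expect_lt(abs(fit$lam_mean - lam_true), 1e-6)
  expect_equal(fit$lam_sd, 0)
})

test_that("a non-growing series drives lambda to its lower bound with a warning", {
  counts <- tibble::tibble(t_h = c(0, 8, 16, 24, 46), n_cells = rep(26, 5))
  expect_warning(fit <- fit_lambda(counts, 1.13e-3, 26 / 3.789e4),
                 "bound")
  expect_lt(fit$lam_mean, 2e-4)
  expect_error(fit_lambda(tibble::tibble(t_h = 0, n_cells = 26),
                          1.13e-3, 6.84e-4), "2 distinct times")
})

test_that("Poisson-sampled replicates recover lambda within five per cent in median", {
  a_sr <- 3.789e4
  k <- 1.13e-3; c0 <- 6.84e-4; lam_true <- 5.07e-2
  tt <- c(0, 8, 16, 24, 46)
  mu <- logistic_solution(c0, k, lam_true, tt) * a_sr
  set.seed(7)
  lams <- replicate(200, {
    counts <- tibble::tibble(
      t_h = rep(tt, 3),
      subregion_id = rep(1:3, each = 5),
      n_cells = stats::rpois(15, rep(mu, 3)))
    suppressWarnings(fit_lambda(counts, k, c0, a_sr)$lam_mean)
  })
  expect_lt(abs(stats::median(lams) - lam_true) / lam_true, 0.05)
})

test_that("diffusivity is recovered from clean leading-edge data", {
  p <- control_params()
  coarse <- solver_config(dx = 2, dt = 0.2)
  tt <- seq(0, 46, by = 2)
  sol <- solve_fk(p, le0 = 300, config = coarse, output_times = tt)
  le <- tibble::tibble(t_h = tt, le_um = front_position(sol, p))
  fit <- fit_D(le, p, config = coarse, bracket = NULL)
  expect_rel_error(fit$d_mean, p$D, 0.02)
  expect_equal(fit$d_low, fit$d_mean)
  expect_error(fit_D(le[1:2, ], p, config = coarse), "3 leading-edge")
})

test_that("noisy leading-edge replicates recover D within ten per cent in median", {
  p <- control_params()
  coarse <- solver_config(dx = 2, dt = 0.2)
  tt <- seq(0, 46, by = 2)
  sol <- solve_fk(p, le0 = 300, config = coarse, output_times = tt)
  le_clean <- front_position(sol, p)
  set.seed(11)
  le <- dplyr::bind_rows(lapply(1:20, function(r)
    tibble::tibble(replicate_id = r, t_h = tt,
                   le_um = pmax(0, le_clean + stats::rnorm(length(tt), 0, 10)))))
  fit <- fit_D(le, p, config = coarse, bracket = NULL)
  d_reps <- fit$replicates$d
  expect_lt(abs(stats::median(d_reps) - p$D) / p$D, 0.10)
})

test_that("the detection-threshold reruns bracket the point estimate monotonically", {
  p <- control_params()
  coarse <- solver_config(dx = 2, dt = 0.2)
  tt <- seq(0, 46, by = 2)
  sol <- solve_fk(p, le0 = 300, config = coarse, output_times = tt)
  le <- tibble::tibble(t_h = tt, le_um = front_position(sol, p))
  fit <- fit_D(le, p, config = coarse)
  d_at <- function(f) fit$replicates$d[fit$replicates$fraction == f]
  expect_lte(d_at(0.01), d_at(0.02))
  expect_lte(d_at(0.02), d_at(0.05))
  expect_lte(fit$d_low, fit$d_mean)
  expect_lte(fit$d_mean, fit$d_high)
})

test_that("the sequential estimator keeps earlier stages fixed and labels failures", {
  cfg <- small_cfg(count_noise = "none", le_noise_sd = 0)
  assay <- generate_assay(cfg)
  le <- dplyr::mutate(assay$le_clean, replicate_id = 1L)
  s <- suppressWarnings(
    sequential_estimate(assay$counts, le, a_sr = cfg$a_sr,
                        geom = cfg$geom, config = cfg$solver,
                        bracket = NULL))
  # sequentiality: each stage carries exactly the upstream estimates
  expect_equal(s$lambda_fit$k, s$k$mean)
  expect_equal(s$lambda_fit$c0, s$c0$mean)
  expect_equal(s$t_d, log(2) / s$lambda_fit$lam_mean)
  # tidiers expose the same values
  td <- tidy(s)
  expect_equal(td$estimate[td$term == "K"], s$k$mean)
  expect_equal(glance(s)$D, s$d_fit$d_mean)

  suppressWarnings(expect_error(
    sequential_estimate(assay$counts, NULL, a_sr = cfg$a_sr,
                        geom = cfg$geom, config = cfg$solver),
    "diffusivity stage"))
  bad <- dplyr::filter(assay$counts, t_h > 0)
  suppressWarnings(expect_error(
    sequential_estimate(bad, le, a_sr = cfg$a_sr, geom = cfg$geom,
                        config = cfg$solver),
    "initial-density stage"))
})

test_that("a non-proliferating assay still yields a diffusivity estimate", {
  cfg <- small_cfg(params = fk_params(100, 0, 1.13e-3, 6.84e-4),
                   count_noise = "none", le_noise_sd = 0)
  assay <- generate_assay(cfg)
  le <- dplyr::mutate(assay$le_clean, replicate_id = 1L)
  expect_warning(
    s <- sequential_estimate(assay$counts, le, a_sr = cfg$a_sr,
                             geom = cfg$geom, config = cfg$solver,
                             bracket = NULL),
    "bound")
  expect_true(is.finite(s$d_fit$d_mean))
})

test_that("cross-condition variability reproduces the reference percentages", {
  tab <- pc3_egf_estimates()
  vb <- condition_variability(tab)
  get <- function(p) vb$max_rel_dev_pct[vb$parameter == p]
  expect_lte(get("K"), 8)
  expect_equal(round(get("lambda")), 37)
  expect_equal(round(get("D")), 82)
  # all conditions equal to control: zero variability
  same <- tibble::tibble(condition = c("control", "a", "b"),
                         K = 1e-3, lambda = 0.05, D = 100)
  expect_true(all(condition_variability(same)$max_rel_dev_pct == 0))
  expect_error(condition_variability(tab, control = "nope"), "control")
  expect_error(condition_variability(tab[tab$condition == "control", ]),
               "non-control")
})
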