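test_that("assay configuration validates and requires a seed", {
  expect_error(assay_config(), "seed")
  cfg <- small_cfg()
  expect_s3_class(cfg, "assay_config")
  expect_equal(nrow(cfg$subregions), 3)
  # subregions have the configured area
  side <- sqrt(cfg$a_sr)
  expect_equal(cfg$subregions$x_max - cfg$subregions$x_min, rep(side, 3))
})

test_that("the noise-free forward simulation reproduces known closure behaviour", {
  # frozen dynamics: the half-width never moves
  cfg0 <- small_cfg(params = fk_params(0, 0, 1.13e-3, 6.84e-4))
  tr0 <- simulate_truth(cfg0)
  expect_true(all(abs(tr0$le_clean$le_um - cfg0$le0) <= 1))

  # control parameters on the full geometry: monotone closure to < 50 um
  cfg <- assay_config(seed = 1)
  tr <- simulate_truth(cfg)
  le <- tr$le_clean$le_um
  expect_true(all(diff(le) < 0 | le[-1] == 0))
  expect_lt(le[length(le)], 50)

  # doubling D (pure motility) accelerates closure
  cfgA <- small_cfg(params = fk_params(100, 0, 1.13e-3, 6.84e-4))
  cfgB <- small_cfg(params = fk_params(200, 0, 1.13e-3, 6.84e-4))
  leA <- simulate_truth(cfgA)$le_clean
  leB <- simulate_truth(cfgB)$le_clean
  at2 <- function(le) le$le_um[le$t_h == 2]
  expect_lt(at2(leB), at2(leA))
})

test_that("subregion counts follow the local density with the chosen noise model", {
  # deterministic mode rounds half up
  cfg <- small_cfg(count_noise = "none", count_times = 0)
  dens <- 42.8 / cfg$a_sr
  prof <- uniform_profile(dens, cfg$geom, cfg$solver)
  n <- sample_counts(prof, cfg)
  expect_true(all(n$n_cells == 43))

  # Poisson mode: mean of many draws matches C * A_SR within 3 sd
  cfgp <- small_cfg(a_sr = 3.789e4, subregion_x = 10, n_subregions = 1,
                    count_times = 0)
  mu <- 6.84e-4 * 3.789e4   # about 25.9 cells, inside the 20-30 band
  expect_gt(mu, 20); expect_lt(mu, 30)
  profp <- uniform_profile(6.84e-4, cfgp$geom, cfgp$solver)
  draws <- vapply(1:300, function(i)
    suppressWarnings(sample_counts(profp, cfgp, seed = i)$n_cells[1]),
    integer(1))
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(mu / 300))

  # reproducibility contract
  a <- suppressWarnings(sample_counts(profp, cfgp, seed = 5))
  b <- suppressWarnings(sample_counts(profp, cfgp, seed = 5))
  d <- suppressWarnings(sample_counts(profp, cfgp, seed = 6))
  expect_identical(a, b)
  expect_false(identical(a, d))

  # a subregion overlapping the scratch is flagged
  cfg_bad <- small_cfg(subregion_x = 150, count_times = 0)
  expect_warning(sample_counts(uniform_profile(dens, cfg_bad$geom),
                               cfg_bad), "overlaps the scratch")
})

test_that("rendered frames are deterministic and density-faithful", {
  cfg <- small_cfg()
  prof <- uniform_profile(cfg$params$K, cfg$geom, cfg$solver)
  f1 <- render_frame(prof, cfg, frame_seed = 3)
  f2 <- render_frame(prof, cfg, frame_seed = 3)
  f3 <- render_frame(prof, cfg, frame_seed = 4)
  expect_identical(f1$pixels, f2$pixels)
  expect_false(identical(f1$pixels, f3$pixels))

  # a zero-density profile renders background only
  f0 <- render_frame(uniform_profile(0, cfg$geom, cfg$solver), cfg, 3)
  expect_null(attr(f0, "cells"))
  expect_lt(max(f0$pixels), 0.15 + 5 * cfg$intensity_noise_sd)

  # local cell-count means match C * area: chi-square over 100 windows
  cfgK <- assay_config(seed = 2)
  profK <- uniform_profile(cfgK$params$K, cfgK$geom, cfgK$solver)
  frK <- render_frame(profK, cfgK, frame_seed = 11)
  cells <- attr(frK, "cells")
  npx <- round(cfgK$geom$lx / cfgK$pixel_size)
  npy <- round(cfgK$geom$ly / cfgK$pixel_size)
  wx <- cut(cells$x_px, seq(0, npx, length.out = 11))
  wy <- cut(cells$y_px, seq(0, npy, length.out = 11))
  obs <- as.vector(table(wx, wy))
  expected <- cfgK$params$K * (cfgK$geom$lx / 10) * (cfgK$geom$ly / 10)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, stats::qchisq(0.99, df = 99))
})

test_that("generated assays are byte-identical under one seed and differ across seeds", {
  cfg <- small_cfg(seed = 9, n_replicates = 3)
  a1 <- generate_assay(cfg)
  a2 <- generate_assay(cfg)
  expect_identical(a1$counts, a2$counts)
  expect_identical(a1$le_noisy, a2$le_noisy)
  a3 <- generate_assay(small_cfg(seed = 10, n_replicates = 3))
  expect_false(identical(a1$counts, a3$counts))
  # replicates share ground truth but differ in noise
  expect_equal(length(unique(a1$counts$replicate_id)), 3)
  c1 <- dplyr::filter(a1$counts, replicate_id == 1)$n_cells
  c2 <- dplyr::filter(a1$counts, replicate_id == 2)$n_cells
  expect_false(identical(c1, c2))
})

test_that("a zero-duration assay still supports the density stages", {
  cfg <- assay_config(duration = 0, count_noise = "none", le_noise_sd = 0,
                      n_replicates = 1, seed = 2)
  a <- generate_assay(cfg)
  expect_equal(unique(a$counts$t_h), 0)
  c0 <- estimate_C0(a$counts, cfg$a_sr)
  expect_rel_error(c0$mean, cfg$params$C0, 0.05)
})

test_that("rendered stacks round-trip through the edge pipeline at the calibrated threshold", {
  # the detected edge on rendered diffuse fronts corresponds to the
  # virtual microscope's calibrated density fraction (~13% of K), the
  # same kind of correspondence calibration that pins real imaging at 2%
  cfg <- assay_config(seed = 4)
  tr <- simulate_truth(cfg)
  for (tt in c(0, 10, 20, 30)) {
    pr <- scratchfk:::profiles_at(tr$profiles, tt)
    fr <- render_frame(pr, cfg, frame_seed = 100 + tt)
    le_det <- half_width(detect_vacant_region(fr)$a_vacant_um2)
    le_cal <- front_position(pr, cfg$params,
                             fraction = render_edge_fraction())
    expect_lt(abs(le_det - le_cal), 15)
  }
})
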