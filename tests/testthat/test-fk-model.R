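test_that("parameter constructors enforce their invariants", {
  expect_error(fk_params(-1, 0.05, 1e-3, 5e-4), "diffusivity")
  expect_error(fk_params(100, -0.1, 1e-3, 5e-4), "proliferation")
  expect_error(fk_params(100, 0.05, 0, 5e-4), "carrying capacity")
  expect_error(fk_params(100, 0.05, 1e-3, 2e-3), "C0")
  expect_error(domain_geometry(x_centre = 2000), "centre")
  expect_error(solver_config(dx = 0), "dx")
  expect_s3_class(control_params(), "fk_params")
})

test_that("scratch initial condition follows the half-open boundary convention", {
  p <- control_params()
  ic <- build_initial_condition(p, le0 = 300)
  at <- function(x) ic$density[ic$x_um == x]
  expect_equal(at(0), 6.84e-4)
  expect_equal(at(985), 0)
  expect_equal(at(1970), 6.84e-4)
  # left scratch boundary vacant, right boundary occupied
  expect_equal(at(685), 0)
  expect_equal(at(1285), 6.84e-4)

  # zero initial density gives an identically zero profile
  ic0 <- build_initial_condition(fk_params(1, 0, 1e-3, 0), le0 = 100)
  expect_true(all(ic0$density == 0))

  # node count inside the vacant interval [492.5, 1477.5), enumerated
  ic2 <- build_initial_condition(fk_params(1, 0, 1e-3, 1e-3), le0 = 492.5)
  n_expected <- sum(ic2$x_um >= 492.5 & ic2$x_um < 1477.5)
  expect_equal(sum(ic2$density == 0), n_expected)
  expect_equal(n_expected, 985)

  expect_error(build_initial_condition(p, le0 = 0), "geometry")
  expect_error(build_initial_condition(p, le0 = 985), "geometry")
})

test_that("Thomas solver agrees with dense solves and flags singular systems", {
  # identity
  expect_equal(thomas_solve(c(0, 0), c(1, 1, 1), c(0, 0), c(3, 1, 4)),
               c(3, 1, 4))
  # scalar system
  expect_equal(thomas_solve(numeric(0), 4, numeric(0), 8), 2)
  # 3x3 against a dense solve
  A <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
  expect_equal(thomas_solve(c(1, 1), c(2, 2, 2), c(1, 1), c(1, 2, 3)),
               as.numeric(solve(A, c(1, 2, 3))), tolerance = 1e-12)
  # random diagonally dominant systems against base solve()
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    lo <- stats::runif(n - 1, -1, 1)
    up <- stats::runif(n - 1, -1, 1)
    dg <- 2 + abs(c(0, lo)) + abs(c(up, 0)) + stats::runif(n)
    rhs <- stats::rnorm(n)
    A <- diag(dg)
    A[cbind(2:n, 1:(n - 1))] <- lo
    A[cbind(1:(n - 1), 2:n)] <- up
    x <- thomas_solve(lo, dg, up, rhs)
    expect_lt(max(abs(x - solve(A, rhs))) / max(abs(x)), 1e-10)
  }
  expect_error(thomas_solve(numeric(0), 0, numeric(0), 1), "singular")
})

test_that("one implicit step matches a scalar backward-Euler oracle", {
  p0 <- fk_params(0, 0, 1e-3, 5e-4)
  prof <- build_initial_condition(p0, 300)
  out <- backward_euler_step(prof, p0)
  expect_equal(out$density, prof$density)
  expect_equal(out$t_h[1], 0.1)

  # uniform profile: the PDE step must equal the scalar fixed-point
  # iteration for the implicit logistic update, computed independently
  p <- control_params()
  cfg <- solver_config()
  c0 <- 5e-4
  prof_u <- uniform_profile(c0)
  out_u <- backward_euler_step(prof_u, p, cfg)
  cp <- c0
  repeat {
    cn <- c0 / (1 - cfg$dt * p$lambda * (1 - cp / p$K))
    if (abs(cn - cp) < cfg$eps) { cp <- cn; break }
    cp <- cn
  }
  expect_equal(max(abs(out_u$density - cp)), 0, tolerance = 1e-12)

  # zero-flux step conserves trapezoid mass for a pure-diffusion step
  pd <- fk_params(500, 0, 1e-3, 6e-4)
  prof_s <- build_initial_condition(pd, 300)
  out_s <- backward_euler_step(prof_s, pd)
  m0 <- scratchfk:::trapz_mass(prof_s$density, 1)
  m1 <- scratchfk:::trapz_mass(out_s$density, 1)
  expect_lt(abs(m1 - m0), 10 * cfg$eps * m0)
})

test_that("full solve is exact for frozen dynamics and snaps output times", {
  p0 <- fk_params(0, 0, 1e-3, 5e-4)
  sol <- solve_fk(p0, le0 = 300, output_times = c(0, 5, 10))
  ic <- build_initial_condition(p0, 300)
  for (tt in c(0, 5, 10))
    expect_equal(sol$density[sol$t_h == tt], ic$density)
  expect_warning(solve_fk(p0, le0 = 300, output_times = c(0, 1.23)),
                 "snapped")
})

test_that("the default grid is in the converged regime", {
  p <- control_params()
  cfg_fine <- solver_config(dx = 0.5, dt = 0.05)
  tt <- c(10, 20, 30, 46)
  sol1 <- solve_fk(p, le0 = 300, output_times = tt)
  sol2 <- solve_fk(p, le0 = 300, output_times = tt, config = cfg_fine)
  # halving (dx, dt) moves the predicted half-width by under a micron
  le1 <- front_position(sol1, p)
  le2 <- front_position(sol2, p)
  expect_lt(max(abs(le1 - le2)), 1)
  # and the density field by about a tenth of a per cent of K
  for (t in tt) {
    c1 <- sol1$density[sol1$t_h == t]
    c2 <- sol2$density[sol2$t_h == t][seq(1, 2 * length(c1) - 1, by = 2)]
    expect_lt(max(abs(c1 - c2)), 1.5e-3 * p$K)
  }
})

test_that("logistic closed form matches an adaptive ODE integration", {
  expect_equal(logistic_solution(6.84e-4, 1.13e-3, 5.07e-2, 0), 6.84e-4)
  expect_equal(logistic_solution(1.13e-3, 1.13e-3, 5.07e-2, c(1, 10, 100)),
               rep(1.13e-3, 3))
  # monotone growth from below
  tt <- seq(0, 46, by = 2)
  cc <- logistic_solution(6.84e-4, 1.13e-3, 5.07e-2, tt)
  expect_true(all(diff(cc) > 0))
  # independent Runge-Kutta oracle
  skip_if_not_installed("deSolve")
  ode <- deSolve::ode(y = c(C = 6.84e-4), times = c(0, 24),
                      func = function(t, y, p)
                        list(p$lam * y * (1 - y / p$K)),
                      parms = list(lam = 5.07e-2, K = 1.13e-3),
                      rtol = 1e-12, atol = 1e-14)
  expect_equal(logistic_solution(6.84e-4, 1.13e-3, 5.07e-2, 24),
               unname(ode[2, "C"]), tolerance = 1e-9)
  expect_error(logistic_solution(1e-4, -1, 0.05, 1), "carrying capacity")
})

test_that("front position interpolates threshold crossings symmetrically", {
  p <- control_params()
  ic <- build_initial_condition(p, 300)
  expect_lt(abs(front_position(ic, p) - 300), 1)
  # confluent profile: scratch closed
  expect_equal(front_position(uniform_profile(p$K), p), 0)
  # profile below threshold everywhere is degenerate
  expect_error(front_position(uniform_profile(1e-8), p), "degenerate")

  # travelling-front profile: brute-force scan over every grid interval
  sol <- solve_fk(p, le0 = 300, output_times = 20)
  le <- front_position(sol, p)
  thr <- 0.02 * p$K
  C <- sol$density; x <- sol$x_um
  cross <- c()
  for (i in seq_len(length(C) - 1)) {
    if ((C[i] - thr) * (C[i + 1] - thr) < 0)
      cross <- c(cross, x[i] + (thr - C[i]) / (C[i + 1] - C[i]))
  }
  expect_equal(le, mean(abs(cross - 985)), tolerance = 1e-10)
})

test_that("doubling time follows ln(2)/lambda", {
  expect_equal(round(doubling_time(5.07e-2)), 14)
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(doubling_time(6.94e-2), log(2) / 6.94e-2)
  expect_error(doubling_time(0), "lambda")
})

test_that("y-averaging is a trapezoid mean and exact for y-independent fields", {
  f <- matrix(rep(c(1, 2, 3, 4), each = 5), nrow = 5)
  expect_equal(average_over_y(f), c(1, 2, 3, 4))
  # field equal to y itself: trapezoid mean of a linear ramp is Ly/2
  y <- seq(0, 10, length.out = 21)
  fy <- matrix(y, nrow = 21, ncol = 4)
  expect_equal(average_over_y(fy), rep(5, 4))
  # checkerboard of 0/K averages to K/2
  K <- 1.13e-3
  cb <- K * outer(1:11, 1:6, function(i, j) (i + j) %% 2)
  expect_equal(average_over_y(cb), rep(K / 2, 6))
  expect_error(average_over_y(matrix(numeric(0), 0, 0)), "non-empty")
})
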