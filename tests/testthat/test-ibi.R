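test_that("linear correction has the prescribed endpoints and slope", {
  alpha <- -0.001 * thermal_energy(330)
  grid <- tab_fn(0, 0.01, rep(0, 121), "potential")   # 0 .. 1.2 nm
  dU <- linear_correction(grid, alpha, r_cut = 1.0)
  x <- tab_grid(dU)
  expect_equal(dU$values[x == 0], alpha)
  expect_equal(dU$values[abs(x - 1.0) < 1e-12], 0)
  expect_equal(dU$values[abs(x - 0.5) < 1e-12], alpha / 2)
  expect_equal(dU$values[x > 1.0], rep(0, sum(x > 1.0)))
  expect_error(linear_correction(grid, alpha, r_cut = -1), "r_cut")
})

test_that("convergence metric is the weighted squared-deviation integral", {
  n <- 201; dx <- 0.005
  x <- (0:(n - 1)) * dx
  g1 <- tab_fn(0, dx, rep(1, n), "rdf")
  expect_equal(convergence_metric(g1, g1), 0)
  # constant unit deviation on [0, R]: integral of e^-r equals 1 - e^-R
  g2 <- tab_fn(0, dx, rep(2, n), "rdf")
  R <- x[n]
  expect_equal(convergence_metric(g2, g1), 1 - exp(-R), tolerance = 1e-4)
  expect_equal(convergence_metric(g1, g2), convergence_metric(g2, g1))
  g3 <- tab_fn(0, dx, rep(1, 100), "rdf")
  expect_error(convergence_metric(g1, g3), "grid")
})

test_that("IBI update has the exact fixed point and single-bin response", {
  n <- 110; dx <- 0.01
  x <- dx / 2 + (0:(n - 1)) * dx
  g <- tab_fn(dx / 2, dx, 1 + 0.8 * exp(-((x - 0.4) / 0.08)^2), "rdf")
  U0 <- pmf_from_rdf(g, 330, r_cut = 1.0)
  cfg <- ibi_config(use_linear_correction = FALSE, damping = 1,
                    smooth_window = 1L, iterate_pair = c("A", "B"))
  # fixed point: g_n = g_target leaves U untouched
  U1 <- ibi_update(U0, g, g, 330, cfg)
  expect_equal(U1$U, U0$U, tolerance = 1e-12)
  # single-bin perturbation by a factor e raises U there by exactly kB T
  gp <- g; gp$values[40] <- g$values[40] * exp(1)
  U2 <- ibi_update(U0, gp, g, 330, cfg)
  dU <- U2$U - U0$U
  expect_equal(dU[40], thermal_energy(330), tolerance = 1e-9)
  expect_equal(dU[-40], rep(0, n - 1), tolerance = 1e-12)
  # over-structured bin (g_n > g_target) always raises the potential
  expect_gt(U2$U[40], U0$U[40])
  expect_error(ibi_update(U0, tab_fn(0, 0.02, rep(1, 50), "rdf"), g, 330,
                          cfg), "grid")
})

test_that("damping scales the increment and the tail correction adds alpha", {
  n <- 110; dx <- 0.01
  g <- tab_fn(dx / 2, dx, rep(1, n), "rdf")
  U0 <- pmf_from_rdf(g, 330, r_cut = 1.0)
  gp <- g; gp$values[30:40] <- exp(1)   # factor-e bump away from the cutoff
  cfg <- ibi_config(use_linear_correction = FALSE, damping = 0.25,
                    smooth_window = 1L, iterate_pair = c("A", "B"))
  U1 <- ibi_update(U0, gp, g, 330, cfg)
  x <- tab_grid(U1)
  dU <- U1$U - U0$U
  expect_equal(dU[30:40], rep(0.25 * thermal_energy(330), 11),
               tolerance = 1e-9)
  expect_equal(dU[-(30:40)], rep(0, n - 11), tolerance = 1e-12)
  # with the correction on, the r = 0 limit gains alpha = -0.001 kT
  cfg2 <- ibi_config(use_linear_correction = TRUE, damping = 1,
                     smooth_window = 1L, iterate_pair = c("A", "B"))
  U2 <- ibi_update(U0, g, g, 330, cfg2)
  dU <- U2$U - U0$U
  alpha <- -0.001 * thermal_energy(330)
  slope <- (dU[20] - dU[10]) / (x[20] - x[10])
  expect_equal(slope, -alpha / 1.0, tolerance = 1e-6)
})

test_that("unsampled-bin increments are capped at +/- 2 kT", {
  n <- 110; dx <- 0.01
  x <- dx / 2 + (0:(n - 1)) * dx
  gt <- tab_fn(dx / 2, dx, rep(1, n), "rdf")
  U0 <- pmf_from_rdf(gt, 330, r_cut = 1.0)
  gn <- gt; gn$values[30] <- 0       # simulated hole
  cfg <- ibi_config(use_linear_correction = FALSE, damping = 1,
                    smooth_window = 1L, iterate_pair = c("A", "B"))
  U1 <- ibi_update(U0, gn, gt, 330, cfg)
  expect_equal(U1$U[30] - U0$U[30], -2 * thermal_energy(330),
               tolerance = 1e-9)
})

test_that("degenerate stopping runs exactly one simulation", {
  set.seed(51)
  sys <- build_lj_fluid(40)
  g_seed <- run_nvt(sys, sim_config(n_steps = 2000, seed = 1,
                                    sample_interval = 10))
  gt <- radial_distribution(g_seed$traj, "LJ", "LJ", 1.1, 0.02)
  cfg <- ibi_config(max_iters = 10, f_tol = Inf,
                    sim = sim_config(n_steps = 1000, seed = 1,
                                     sample_interval = 10),
                    base_seed = 9, iterate_pair = c("LJ", "LJ"))
  fit <- run_ibi(gt, sys, cfg)
  expect_length(fit$f_history, 1L)
  expect_equal(fit$best_iter, 0L)
  expect_s3_class(fit, "ibi_fit")
})

test_that("IBI runs are replayable bit for bit from their seeds", {
  set.seed(52)
  sys <- build_lj_fluid(40)
  run0 <- run_nvt(sys, sim_config(n_steps = 2000, seed = 2,
                                  sample_interval = 10))
  gt <- radial_distribution(run0$traj, "LJ", "LJ", 1.1, 0.02)
  cfg <- ibi_config(max_iters = 2, f_tol = 1e-12,
                    sim = sim_config(n_steps = 1000, sample_interval = 10),
                    base_seed = 5, iterate_pair = c("LJ", "LJ"))
  f1 <- run_ibi(gt, sys, cfg)
  f2 <- run_ibi(gt, sys, cfg)
  expect_identical(f1$f_history, f2$f_history)
  expect_identical(f1$potential$U, f2$potential$U)
})

test_that("fit accessors expose potential, residuals and predictions", {
  set.seed(53)
  sys <- build_lj_fluid(40)
  run0 <- run_nvt(sys, sim_config(n_steps = 2000, seed = 3,
                                  sample_interval = 10))
  gt <- radial_distribution(run0$traj, "LJ", "LJ", 1.1, 0.02)
  cfg <- ibi_config(max_iters = 1, f_tol = 1e-12,
                    sim = sim_config(n_steps = 1000, sample_interval = 10),
                    base_seed = 6, iterate_pair = c("LJ", "LJ"))
  fit <- run_ibi(gt, sys, cfg)
  co <- coef(fit)
  expect_named(co, c("r", "U", "F"))
  expect_equal(nrow(co), length(gt$values))
  expect_length(residuals(fit), length(gt$values))
  expect_equal(fitted(fit), fit$rdf$values)
  expect_equal(predict(fit, r = co$r[5]), co$U[5])
  expect_equal(predict(fit, r = co$r[5], what = "force"), co$F[5])
  s <- summary(fit)
  expect_s3_class(s, "summary.ibi_fit")
  expect_output(print(fit), "best iteration")
  # simulate() under the fitted potential is reproducible
  r1 <- simulate(fit, seed = 101, n_steps = 500)
  r2 <- simulate(fit, seed = 101, n_steps = 500)
  expect_identical(r1$traj$coords, r2$traj$coords)
})
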