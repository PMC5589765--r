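make_traj <- function(positions, lambda, spring_k = 150) {
  structure(list(times = seq_along(lambda), positions = positions,
                 lambda = lambda, seed = 0,
                 settings = thermo_settings(), k_bias = spring_k,
                 protocol = NULL),
            class = "toy_trajectory")
}

test_that("work integration reproduces closed-form limits", {
  lam <- seq(0, 1, by = 0.001)
  proto <- steering_protocol(spring_k = 150, lambda_start = 0,
                             lambda_end = 1)
  ## particle clamped at x = 0 while the spring is pulled to 1 A:
  ## W = (k/2) lambda^2 (exact for the trapezoid: integrand is linear)
  clamped <- integrate_work(make_traj(rep(0, length(lam)), lam), proto)
  expect_equal(clamped$work[length(lam)], 75)
  expect_equal(clamped$work, 150 / 2 * lam^2)
  ## particle tracking the bias center exactly: zero spring extension
  tracking <- integrate_work(make_traj(lam, lam), proto)
  expect_true(all(tracking$work == 0))
  ## static bias center: no switching, no work
  static <- integrate_work(make_traj(stats::rnorm(100, 0, 0.01),
                                     rep(0, 100)),
                           steering_protocol(lambda_start = 0,
                                             lambda_end = 1))
  expect_true(all(static$work == 0))
  ## mismatched protocol start
  expect_error(integrate_work(make_traj(lam, lam),
                              steering_protocol(lambda_start = 2,
                                                lambda_end = 3)),
               "mismatch")
})

test_that("Jarzynski estimate matches direct two-point evaluation", {
  kBT <- kb_kcal() * 300
  ## degenerate distribution: estimate equals the common work profile
  lam <- seq(0, 1, by = 0.25)
  w <- c(0, 0.5, 1, 1.5, 2)
  ws <- manual_workset(lam, cbind(w, w, w))
  expect_equal(jarzynski_estimate(ws)$dG, w)
  ## two works {0, kBT ln 2} -> dG = -kBT ln(3/4)
  ws2 <- manual_workset(c(0, 1), rbind(c(0, 0), c(0, kBT * log(2))))
  expect_equal(jarzynski_estimate(ws2)$dG[2], -kBT * log(3 / 4),
               tolerance = 1e-12)
  expect_equal(-kBT * log(3 / 4), 0.17149, tolerance = 1e-4)
  ## single profile allowed only with a warning
  ws1 <- manual_workset(lam, matrix(w, ncol = 1))
  expect_warning(f1 <- jarzynski_estimate(ws1), "single")
  expect_equal(f1$dG, w)
  expect_error(jarzynski_estimate(manual_workset(c(0, 1),
                                                 rbind(c(0, 0),
                                                       c(1, Inf)))),
               "finite")
})

test_that("log-sum-exp form agrees with naive exponential averaging", {
  set.seed(3)
  kBT <- kb_kcal() * 300
  W <- matrix(stats::runif(200, 0, 3), nrow = 10)
  ws <- manual_workset(seq_len(10), W)
  naive <- -kBT * log(rowMeans(exp(-W / kBT)))
  expect_equal(jarzynski_estimate(ws)$dG, naive, tolerance = 1e-10)
})

test_that("second law holds on generated work sets", {
  pot <- make_migration_potential("open")
  ws <- run_steered_set(pot, migration_protocol("solvent_to_docking"),
                        n_traj = 12, base_seed = 21)
  fep <- jarzynski_estimate(ws)
  expect_true(all(rowMeans(ws$works) - fep$dG >= -1e-9))
})

test_that("bootstrap MSE vanishes for identical works and is seeded", {
  lam <- seq(0, 1, by = 0.5)
  W <- matrix(rep(c(0, 1, 2), 8), nrow = 3)
  ws <- manual_workset(lam, W)
  err <- estimate_mse(ws, n_boot = 50, boot_seed = 4)
  expect_equal(err$mse, rep(0, 3))
  expect_true(all(err$mse >= err$bias^2))
  ## deterministic given boot_seed
  set.seed(99)
  Wr <- matrix(stats::rnorm(60, 5, 1), nrow = 3)
  e1 <- estimate_mse(manual_workset(lam, Wr), n_boot = 80, boot_seed = 7)
  e2 <- estimate_mse(manual_workset(lam, Wr), n_boot = 80, boot_seed = 7)
  expect_identical(e1, e2)
  ## small-N fallback warns
  expect_warning(ef <- estimate_mse(manual_workset(lam, Wr[, 1:3])),
                 "fallback")
  expect_equal(ef$mse, apply(Wr[, 1:3], 1, stats::var) / 3)
})

test_that("the resampler is unbiased for a linear statistic", {
  ## at very high temperature the Jarzynski average reduces to the
  ## arithmetic mean, whose bootstrap bias must vanish within MC error
  set.seed(11)
  W <- matrix(stats::rnorm(40 * 3, 5, 1), nrow = 3)
  ws <- manual_workset(seq_len(3), W, temperature = 3e8)
  err <- estimate_mse(ws, n_boot = 400, boot_seed = 2)
  mc_err <- 3 * sqrt(err$sigma2 / 400)
  expect_true(all(abs(err$bias) < pmax(mc_err, 0.02)))
})

test_that("estimated MSE does not grow with the number of pulls", {
  set.seed(17)
  ## common random numbers: each replicate draws one 40-pull set and the
  ## smaller sets are nested subsets, isolating the pure N-dependence
  mse_by_n <- vapply(1:20, function(r) {
    ## dispersion comparable to a mildly dissipative pull set
    w40 <- stats::rnorm(40, mean = 3, sd = 0.7)
    vapply(c(10, 20, 40), function(N)
      estimate_mse(manual_workset(c(0, 1), rbind(0, w40[1:N])),
                   n_boot = 120, boot_seed = r)$mse[2],
      numeric(1))
  }, numeric(3))
  avg <- rowMeans(mse_by_n)
  expect_true(all(diff(avg) <= 0))
})

test_that("quasi-static pulls recover the analytic profile", {
  pot <- make_migration_potential("closed")
  proto <- migration_protocol("solvent_to_docking", speed = 0.005)
  ws <- run_steered_set(pot, proto, n_traj = 6, base_seed = 11)
  fep <- jarzynski_estimate(ws)
  v <- eval_potential(pot, fep$coord)
  v <- v - v[1]
  expect_lt(max(abs(fep$dG - v)), 0.2)
  ## every individual slow pull approaches the reversible work
  expect_lt(max(abs(ws$works - v)), 0.5)
})

test_that("stitching is exact for identity, offset and noisy cases", {
  x <- seq(8, 3, by = -0.1)
  v <- sin(x) + 0.3 * x
  f1 <- free_energy_profile(x, v - v[1], mse = rep(0.01, length(x)))
  ## self-stitch is the identity
  s <- stitch_segments(f1, f1)
  expect_equal(s$coord, x)
  expect_equal(s$dG, f1$dG)
  expect_equal(attr(s, "shift"), 0)
  ## constant offset recovered exactly
  x2 <- seq(4, 1.5, by = -0.1)
  v2 <- (sin(x2) + 0.3 * x2) - (sin(8) + 0.3 * 8) + 3.2
  f2 <- free_energy_profile(x2, v2, mse = rep(0.01, length(x2)))
  s2 <- stitch_segments(f1, f2)
  expect_equal(attr(s2, "shift"), -3.2)
  truth <- sin(s2$coord) + 0.3 * s2$coord - (sin(8) + 0.3 * 8)
  expect_equal(s2$dG, truth, tolerance = 1e-9)
  expect_lte(attr(s2, "junction_gap"),
             max(sqrt(f1$mse)) + 1e-9)
  ## least-squares constant equals the mean pointwise difference
  set.seed(5)
  noise <- stats::rnorm(length(x2), 0, 0.05)
  f2n <- free_energy_profile(x2, v2 + noise, mse = rep(0.01, length(x2)))
  s3 <- stitch_segments(f1, f2n)
  ov <- x2[x2 >= 3 & x2 <= 4]
  d <- (v - v[1])[match(round(ov, 10), round(x, 10))] -
    (v2 + noise)[x2 >= 3 & x2 <= 4]
  expect_equal(attr(s3, "shift"), mean(d), tolerance = 1e-9)
  ## failure modes
  expect_error(stitch_segments(f1, free_energy_profile(c(1, 1.1, 1.2),
                                                       c(0, 0, 0))),
               "overlap")
})

test_that("the Morse augmentation has the stated well and limits", {
  p <- morse_params()
  expect_equal(p$r0, 1.8)
  expect_equal(p$a, 5.6)
  expect_equal(p$D, 10)
  expect_equal(morse_energy(1.8, p), -10)
  expect_equal(morse_energy(100, p), 0)
  expect_equal(morse_energy(1.8 + log(2) / 5.6, p), -7.5)
  expect_error(morse_params(r_max = 1.0), "r_max")

  r <- seq(1.5, 8, by = 0.1)
  fep <- free_energy_profile(r, rep(0, length(r)))
  aug <- add_morse(fep)
  expect_equal(aug$provenance, "morse-augmented")
  expect_equal(aug$dG[r > p$r_max], rep(0, sum(r > p$r_max)))
  expect_equal(min(aug$dG), -10, tolerance = 0.01)
})
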