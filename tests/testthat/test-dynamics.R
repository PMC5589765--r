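test_that("trajectories are bit-identical under the same seed", {
  pot <- potential_model(list(list(type = "harmonic", center = 0, k = 10)),
                         domain = c(-5, 5))
  st <- thermo_settings(friction = 100, timestep = 0.1, n_steps = 5e3)
  t1 <- langevin_trajectory(pot, 0.3, st, seed = 7)
  t2 <- langevin_trajectory(pot, 0.3, st, seed = 7)
  t3 <- langevin_trajectory(pot, 0.3, st, seed = 8)
  expect_identical(t1$positions, t2$positions)
  expect_false(identical(t1$positions, t3$positions))
  expect_error(langevin_trajectory(pot, 0.3, st), "seed")
})

test_that("harmonic-well sampling satisfies equipartition within 5%", {
  k_h <- 10
  pot <- potential_model(list(list(type = "harmonic", center = 0, k = k_h)),
                         domain = c(-5, 5))
  ## timestep such that the Euler-Maruyama variance bias k*dt/(2*gamma)
  ## stays below 0.5%
  st <- thermo_settings(friction = 50, timestep = 0.05, n_steps = 2e6,
                        save_stride = 5)
  tr <- langevin_trajectory(pot, 0, st, seed = 42)
  v <- stats::var(tr$positions[-(1:1000)])
  expect_equal(v, st$kBT / k_h, tolerance = 0.05)
})

test_that("near-zero temperature relaxes to the potential minimum", {
  pot <- potential_model(list(list(type = "harmonic", center = 1.2, k = 5)),
                         domain = c(-5, 5))
  st <- thermo_settings(temperature = 1e-8, friction = 50, timestep = 0.1,
                        n_steps = 2e4)
  tr <- langevin_trajectory(pot, -2, st, seed = 1)
  expect_equal(tr$positions[length(tr$positions)], 1.2, tolerance = 1e-4)
})

test_that("flat-potential MSD grows linearly with slope 2kBT/gamma", {
  pot <- potential_model(list(), domain = c(-2000, 2000))
  gam <- 100
  st <- thermo_settings(friction = gam, timestep = 0.1, n_steps = 2e5,
                        save_stride = 100)
  t_end <- st$n_steps * st$timestep
  x_end <- vapply(1:30, function(s)
    langevin_trajectory(pot, 0, st, seed = s)$positions[2001],
    numeric(1))
  expect_equal(mean(x_end^2) / t_end, 2 * st$kBT / gam, tolerance = 0.10)
})

test_that("runaway trajectories abort with a domain diagnostic", {
  downhill <- potential_model(list(list(type = "harmonic", center = 0,
                                        k = -20)), domain = c(-2, 2))
  st <- thermo_settings(friction = 50, timestep = 0.1, n_steps = 1e4)
  expect_error(langevin_trajectory(downhill, 1.5, st, seed = 3), "domain")
})

test_that("steered sets have one zero-anchored profile per trajectory", {
  pot <- make_migration_potential("closed")
  ws <- run_steered_set(pot, migration_protocol("solvent_to_docking"),
                        n_traj = 40, base_seed = 1)
  expect_equal(ncol(ws$works), 40)
  expect_true(all(ws$works[1, ] == 0))
  expect_equal(ws$lambda[1], 8.0)
  expect_equal(ws$lambda[length(ws$lambda)], 2.8)
  expect_error(run_steered_set(pot, n_traj = 1), "n_traj")
})

test_that("a stiff pull across a flat potential does ~zero work", {
  flat <- potential_model(list(), domain = c(0, 3))
  ## light friction keeps the mean dissipated work far below the 3*SE
  ## band of the pull-to-pull fluctuations
  st <- thermo_settings(friction = 50, timestep = 0.1)
  proto <- steering_protocol(spring_k = 150, speed = 0.25,
                             lambda_start = 1, lambda_end = 2,
                             segment = "flat-test")
  ws <- run_steered_set(flat, proto, n_traj = 40, settings = st,
                        base_seed = 5)
  w_end <- ws$works[nrow(ws$works), ]
  se <- stats::sd(w_end) / sqrt(length(w_end))
  expect_lt(abs(mean(w_end)), 3 * se + 50 * 2.5e-4 * 1)
})

test_that("default umbrella layout spans the gate range in 10 windows", {
  wins <- default_gate_windows()
  centers <- vapply(wins, `[[`, numeric(1), "center")
  expect_length(centers, 10)
  expect_equal(centers, seq(60, 160, length.out = 10))
  expect_equal(centers[2] - centers[1], 100 / 9, tolerance = 1e-12)
})

test_that("umbrella windows sample the biased Boltzmann distribution", {
  flat <- potential_model(list(), domain = c(0, 360), periodic = TRUE,
                          period = 360)
  k_umb <- 60  # kcal/mol/rad^2
  st <- thermo_settings(friction = 0.05, timestep = 0.2, n_steps = 4e5,
                        save_stride = 5, n_equil = 2000)
  us <- run_umbrella_set(flat, windows = list(list(center = 100,
                                                   k_umb = k_umb),
                                              list(center = 110,
                                                   k_umb = k_umb)),
                         settings = st, base_seed = 2)
  s <- us$windows[[1]]$samples
  expect_equal(mean(s), 100, tolerance = 0.01)
  target <- st$kBT / (k_umb * (pi / 180)^2)   # deg^2
  expect_equal(stats::var(s), target, tolerance = 0.05)
  expect_true(all(us$overlap_ok))
})

test_that("umbrella sets are deterministic in the base seed", {
  pot <- make_gate_potential("alpha", "R", "HID")
  st <- thermo_settings(friction = 0.05, timestep = 0.2, n_steps = 5e3,
                        save_stride = 10, n_equil = 500)
  u1 <- run_umbrella_set(pot, settings = st, base_seed = 9)
  u2 <- run_umbrella_set(pot, settings = st, base_seed = 9)
  expect_identical(u1$windows, u2$windows)
})
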