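kBT300 <- kb_kcal() * 300

## reference double-well gate potential used throughout
oracle_pot <- make_gate_potential("beta", "T", "HID")

test_that("WHAM on exact biased densities recovers the potential", {
  ## expected (non-integer) counts computed by direct numerical
  ## integration of the biased Boltzmann densities -- the independent
  ## oracle for the self-consistent solver
  bw <- 2
  bc <- seq(bw / 2, 360 - bw / 2, by = bw)
  centers <- c(95, 125)
  k_umb <- c(60, 60)
  v <- eval_potential(oracle_pot, bc)
  counts <- t(vapply(seq_along(centers), function(k) {
    d <- (bc - centers[k]) %% 360
    d[d > 180] <- d[d > 180] - 360
    p <- exp(-(v + 0.5 * k_umb[k] * (pi / 180)^2 * d^2) / kBT300)
    1e6 * p / sum(p)
  }, numeric(length(bc))))
  res <- wham_core(counts, bc, centers, k_umb, kBT300, tol = 1e-10)
  keep <- counts[1, ] + counts[2, ] > 1  # bins both windows can reach
  g <- -kBT300 * log(res$P[keep])
  dv <- v[keep]
  expect_lt(max(abs((g - mean(g)) - (dv - mean(dv)))), 1e-3)
  ## window free energies match direct integration of the biased densities
  th <- seq(0.05, 360, by = 0.1)
  vf <- eval_potential(oracle_pot, th)
  f_direct <- vapply(seq_along(centers), function(k) {
    d <- (th - centers[k]) %% 360
    d[d > 180] <- d[d > 180] - 360
    -kBT300 * log(sum(exp(-(vf + 0.5 * k_umb[k] * (pi / 180)^2 * d^2) /
                          kBT300)))
  }, numeric(1))
  expect_equal(res$f[2] - res$f[1], f_direct[2] - f_direct[1],
               tolerance = 1e-3)
})

test_that("WHAM on analytic draws reaches 0.15 kcal/mol RMSD", {
  set.seed(31)
  centers <- seq(60, 160, length.out = 10)
  draws <- lapply(centers, function(ct)
    boltzmann_draws(oracle_pot, ct, 60, 4000))
  us <- manual_umbrella(centers, rep(60, 10), draws)
  prof <- wham(us)
  v <- eval_potential(oracle_pot, prof$coord)
  err <- (prof$dG - mean(prof$dG)) - (v - mean(v))
  expect_lt(sqrt(mean(err^2)), 0.15)
})

test_that("duplicating every window leaves the WHAM profile unchanged", {
  set.seed(32)
  centers <- seq(80, 140, length.out = 4)
  draws <- lapply(centers, function(ct)
    boltzmann_draws(oracle_pot, ct, 60, 2000))
  u1 <- manual_umbrella(centers, rep(60, 4), draws)
  u2 <- manual_umbrella(rep(centers, each = 2), rep(60, 8),
                        rep(draws, each = 2))
  p1 <- wham(u1)
  p2 <- wham(u2)
  ## doubling the data halves the shot-noise bin cutoff, so compare on
  ## the shared support
  shared <- intersect(p1$coord, p2$coord)
  i1 <- match(shared, p1$coord); i2 <- match(shared, p2$coord)
  g1 <- p1$dG[i1] - mean(p1$dG[i1]); g2 <- p2$dG[i2] - mean(p2$dG[i2])
  expect_gt(length(shared), 30)
  expect_equal(g1, g2, tolerance = 1e-6)
})

test_that("rotating samples and centers rotates the profile exactly", {
  set.seed(33)
  centers <- seq(60, 160, length.out = 6)
  draws <- lapply(centers, function(ct)
    boltzmann_draws(oracle_pot, ct, 60, 1500))
  u1 <- manual_umbrella(centers, rep(60, 6), draws)
  u2 <- manual_umbrella(centers + 90, rep(60, 6),
                        lapply(draws, function(s) (s + 90) %% 360))
  p1 <- wham(u1)
  p2 <- wham(u2)
  expect_equal((p1$coord + 90) %% 360, p2$coord %% 360)
  expect_equal(p1$dG, p2$dG, tolerance = 1e-9)
})

test_that("a single unbiased window on a flat potential is flat", {
  flat <- potential_model(list(), domain = c(0, 360), periodic = TRUE,
                          period = 360)
  set.seed(34)
  n <- 5e4
  us <- manual_umbrella(100, 1e-12, list(stats::runif(n, 0, 360)))
  prof <- wham(us, bin_width = 5)
  ## flat within 3x the expected shot-noise range of ~180/5 multinomial
  ## bins: per-bin sd kBT/sqrt(n_bin), range factor sqrt(2 log B)
  B <- length(prof$coord)
  shot_range <- 2 * kBT300 / sqrt(n / B) * sqrt(2 * log(B))
  expect_lt(max(prof$dG) - min(prof$dG), 3 * shot_range)
})

test_that("WHAM refuses window sets without histogram overlap", {
  set.seed(35)
  us <- manual_umbrella(c(60, 160), c(3000, 3000),
                        list(stats::rnorm(500, 60, 1),
                             stats::rnorm(500, 160, 1)))
  expect_error(wham(us), "overlap")
})

test_that("profiles align to a common closed-state zero", {
  th <- seq(50, 170, by = 2)
  base <- 0.002 * (th - 60)^2
  p1 <- free_energy_profile(th, base - min(base[th >= 50 & th <= 80]))
  p2 <- free_energy_profile(th, base + 7)
  p3 <- free_energy_profile(th, -0.05 * th)
  out <- align_profiles(list(p1, p2, p3), closed_region = c(50, 80))
  ## already-zeroed profile unchanged; constant offsets are gauge
  expect_equal(out[[1]]$dG, p1$dG)
  expect_equal(out[[2]]$dG, out[[1]]$dG)
  for (p in out)
    expect_equal(min(p$dG[p$coord >= 50 & p$coord <= 80]), 0)
  expect_error(align_profiles(list(p1), closed_region = c(300, 320)),
               "closed region")
})

test_that("gate summaries classify symmetric, monotone and preset cases", {
  th <- seq(45, 175, by = 1)
  ## symmetric double well about 110: tie
  sym <- free_energy_profile(th, -3 * exp(-(th - 60)^2 / 200) -
                                 3 * exp(-(th - 160)^2 / 200))
  s1 <- summarize_gate(sym)
  expect_equal(s1$preferred, "tie")
  expect_equal(s1$dG_open, 0, tolerance = 1e-9)
  ## monotone decreasing: open preferred, zero barrier
  mono <- free_energy_profile(th, -0.04 * (th - 45))
  s2 <- summarize_gate(mono)
  expect_equal(s2$preferred, "open")
  expect_equal(s2$barrier_opening, 0)
  ## beta-R HIP preset end-to-end: open preferred
  pot <- make_gate_potential("beta", "R", "HIP")
  us <- run_umbrella_set(pot, base_seed = 37)
  s3 <- summarize_gate(wham(us), labels = list(subunit = "beta",
                                               state = "R",
                                               tautomer = "HIP"))
  expect_equal(s3$preferred, "open")
  expect_lt(s3$barrier_opening, 0.8)
})
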