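# shared fixture builders (everything generated in code)

# work-profile set with explicit work matrix, standard thermo
manual_workset <- function(lambda, works, temperature = 300) {
  structure(
    list(lambda = lambda, works = works,
         protocol = steering_protocol(lambda_start = lambda[1],
                                      lambda_end = lambda[length(lambda)]),
         thermo = thermo_settings(temperature = temperature),
         base_seed = NA),
    class = "work_profile_set")
}

# umbrella set with externally supplied samples (e.g. analytic draws)
manual_umbrella <- function(centers, k_umb, sample_list,
                            temperature = 300) {
  structure(
    list(windows = lapply(seq_along(centers), function(i)
           list(center = centers[i], k_umb = k_umb[i],
                samples = sample_list[[i]] %% 360)),
         thermo = thermo_settings(temperature = temperature,
                                  friction = 0.05),
         coord_name = "dihedral (deg)", base_seed = NA),
    class = "umbrella_set")
}

# inverse-CDF draws from the biased Boltzmann density of `pot` under a
# harmonic dihedral bias (center deg, k_umb kcal/mol/rad^2); independent of
# the Langevin engine, for oracle tests
boltzmann_draws <- function(pot, center, k_umb, n, kBT = 0.59616123,
                            grid_step = 0.25) {
  th <- seq(grid_step / 2, 360 - grid_step / 2, by = grid_step)
  d <- (th - center) %% 360
  d[d > 180] <- d[d > 180] - 360
  u_bias <- 0.5 * k_umb * (pi / 180)^2 * d^2
  w <- exp(-(eval_potential(pot, th) + u_bias) / kBT)
  cdf <- cumsum(w) / sum(w)
  u <- stats::runif(n)
  th[findInterval(u, cdf) + 1]
}
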