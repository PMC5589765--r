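#' Thermodynamic and integrator settings for the toy dynamics
#'
#' Settings for the overdamped Langevin (Euler--Maruyama) propagator. The
#' friction coefficient absorbs the particle mass, so its units are
#' kcal mol^-1 ps per (coordinate unit)^2: with a distance coordinate in
#' Angstrom the default `friction = 800` makes pulls at the default
#' steering speed mildly dissipative (mean dissipated work of 1-2 kT over a
#' migration segment), which is the regime the Jarzynski bias and error
#' machinery is meant to handle. For dihedral coordinates in degrees a much
#' smaller friction (about 0.05) gives comparable relaxation times; see
#' [run_umbrella_set()].
#'
#' @param temperature temperature in K.
#' @param friction friction coefficient, kcal mol^-1 ps / (coord unit)^2.
#' @param timestep integration step in ps.
#' @param n_steps number of production steps (fixed-length runs; steering
#'   runs derive their step count from the protocol instead).
#' @param save_stride save every `save_stride`-th step.
#' @param n_equil equilibration steps run before production/pulling.
#' @return Object of class `thermo_settings`; `kBT` (kcal/mol) is
#'   precomputed (about 0.5962 kcal/mol at 300 K).
#' @export
thermo_settings <- function(temperature = 300, friction = 800,
                            timestep = 0.2, n_steps = 1e5,
                            save_stride = 10, n_equil = 2000) {
  stopifnot(temperature > 0, timestep > 0, friction > 0,
            n_steps >= 1, save_stride >= 1, n_equil >= 0)
  structure(
    list(temperature = temperature, kB = KB_KCAL,
         kBT = KB_KCAL * temperature, friction = friction,
         timestep = timestep, n_steps = as.integer(n_steps),
         save_stride = as.integer(save_stride),
         n_equil = as.integer(n_equil)),
    class = "thermo_settings")
}

#' Steering protocol for a migration segment
#'
#' Defaults are the standard multiple-steered-dynamics protocol for ligand
#' migration along the Fe--O distance: a 150 kcal mol^-1 A^-2 harmonic
#' restraint pulled at 0.25 A/ns. The two named segments split the long
#' migration coordinate at the secondary docking site so the ligand stays on
#' the pathway; their profiles are later recombined with
#' [stitch_segments()].
#'
#' @param spring_k harmonic force constant, kcal mol^-1 A^-2.
#' @param speed pulling speed, A/ns.
#' @param lambda_start,lambda_end restraint-center endpoints, A.
#' @param segment label, `"solvent_to_docking"` or `"docking_to_iron"` (or
#'   any custom string).
#' @return Object of class `steering_protocol`.
#' @export
steering_protocol <- function(spring_k = 150, speed = 0.25,
                              lambda_start = 8.0, lambda_end = 2.8,
                              segment = "solvent_to_docking") {
  stopifnot(spring_k > 0, speed > 0, lambda_start != lambda_end)
  structure(
    list(spring_k = spring_k, speed = speed,
         lambda_start = lambda_start, lambda_end = lambda_end,
         segment = segment),
    class = "steering_protocol")
}

#' Preset steering protocols for the two migration segments
#'
#' @param segment which segment of the migration coordinate.
#' @param ... overrides passed to [steering_protocol()].
#' @return A [steering_protocol()].
#' @export
migration_protocol <- function(segment = c("solvent_to_docking",
                                           "docking_to_iron"), ...) {
  segment <- match.arg(segment)
  if (segment == "solvent_to_docking")
    steering_protocol(lambda_start = 8.0, lambda_end = 2.8,
                      segment = segment, ...)
  else
    steering_protocol(lambda_start = 3.6, lambda_end = 1.8,
                      segment = segment, ...)
}

#' Run one overdamped Langevin trajectory
#'
#' Euler--Maruyama integration of `dx = -(V' + bias')/gamma dt +
#' sqrt(2 kBT dt / gamma) dW`. The bias, when present, is harmonic in the
#' (minimal-image, for periodic coordinates) displacement from a center that
#' is either fixed (umbrella run) or moves linearly at the protocol speed
#' (steering run). Identical `(seed, settings)` give bit-identical
#' trajectories.
#'
#' @param potential a [potential_model()].
#' @param x0 initial coordinate, inside the potential domain.
#' @param settings a [thermo_settings()].
#' @param seed integer RNG seed (required: reproducibility contract).
#' @param bias optional `list(center=, k=)` static harmonic bias.
#' @param protocol optional [steering_protocol()]; overrides `bias` and
#'   `settings$n_steps` (the step count follows from span and speed).
#' @return Object of class `toy_trajectory` with `times` (ps), `positions`,
#'   `lambda` (instantaneous bias center, `NA` when unbiased) and `seed`.
#' @export
langevin_trajectory <- function(potential, x0, settings, seed,
                                bias = NULL, protocol = NULL) {
  stopifnot(inherits(potential, "potential_model"),
            inherits(settings, "thermo_settings"))
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  dom <- potential$domain
  if (!potential$periodic && (x0 < dom[1] || x0 > dom[2]))
    stop("x0 outside the potential domain")

  if (!is.null(protocol)) {
    speed_ps <- protocol$speed * 1e-3          # A/ns -> A/ps
    span <- protocol$lambda_end - protocol$lambda_start
    n_steps <- as.integer(ceiling(abs(span) / (speed_ps * settings$timestep)))
    lambda0 <- protocol$lambda_start
    lambda_rate <- sign(span) * speed_ps
    k_bias <- protocol$spring_k
  } else if (!is.null(bias)) {
    n_steps <- settings$n_steps
    lambda0 <- bias$center
    lambda_rate <- 0
    k_bias <- bias$k
  } else {
    n_steps <- settings$n_steps
    lambda0 <- NA_real_
    lambda_rate <- 0
    k_bias <- 0
  }

  set.seed(seed)
  res <- langevin_cpp(term_matrix(potential), x0, settings$kBT,
                      settings$friction, settings$timestep, n_steps,
                      settings$save_stride, potential$periodic,
                      potential$period, if (k_bias > 0) k_bias else 0,
                      if (is.na(lambda0)) 0 else lambda0, lambda_rate,
                      dom[1], dom[2])
  if (res$escaped >= 0)
    stop(sprintf(paste0("trajectory left the domain [%g, %g] by more than ",
                        "10%% of its span at step %d (x ~ %.3f); check ",
                        "friction/timestep"),
                 dom[1], dom[2], res$escaped, res$x_final))
  times <- seq(0, n_steps, by = settings$save_stride) * settings$timestep
  structure(
    list(times = times, positions = res$x,
         lambda = if (is.na(lambda0)) rep(NA_real_, length(times))
                  else res$lambda,
         seed = seed, settings = settings,
         k_bias = if (k_bias > 0) k_bias else NA_real_,
         protocol = protocol),
    class = "toy_trajectory")
}

## Equilibrate at a fixed bias center and return the end position.
## Continues the current RNG stream (callers set the seed).
equilibrate_at <- function(potential, center, k_bias, settings) {
  res <- langevin_cpp(term_matrix(potential), center, settings$kBT,
                      settings$friction, settings$timestep,
                      settings$n_equil, settings$n_equil,
                      potential$periodic, potential$period,
                      k_bias, center, 0,
                      potential$domain[1], potential$domain[2])
  if (res$escaped >= 0)
    stop("equilibration left the domain; check friction/timestep")
  res$x_final
}

#' Run a set of steered trajectories and collect work profiles
#'
#' Repeats the steering protocol `n_traj` times (default 40 pulls per
#' profile) from independently equilibrated starting configurations at the
#' initial restraint center, integrating the external work along the way.
#' Trajectory `i` uses seed `base_seed + i`. The per-trajectory work
#' profiles are interpolated onto a shared uniform restraint-center grid.
#'
#' @param potential migration [potential_model()].
#' @param protocol a [steering_protocol()].
#' @param n_traj number of pulls (>= 2).
#' @param settings a [thermo_settings()].
#' @param base_seed integer; trajectory `i` uses `base_seed + i`.
#' @param grid_step spacing of the shared work grid, A.
#' @return A `work_profile_set`: `lambda` (grid, in pull order), `works`
#'   (matrix, one column per trajectory, zero at the first grid point),
#'   `protocol`, `thermo`, `base_seed`.
#' @export
run_steered_set <- function(potential, protocol = migration_protocol(),
                            n_traj = 40, settings = thermo_settings(),
                            base_seed = 1, grid_step = 0.1) {
  stopifnot(n_traj >= 2)
  lam_grid <- seq(protocol$lambda_start, protocol$lambda_end,
                  by = sign(protocol$lambda_end - protocol$lambda_start) *
                       grid_step)
  works <- matrix(NA_real_, nrow = length(lam_grid), ncol = n_traj)
  failed <- integer(0)
  for (i in seq_len(n_traj)) {
    seed_i <- base_seed + i
    ok <- tryCatch({
      set.seed(seed_i)
      x0 <- equilibrate_at(potential, protocol$lambda_start,
                           protocol$spring_k, settings)
      ## continue the same RNG stream for the pull
      traj <- local({
        speed_ps <- protocol$speed * 1e-3
        span <- protocol$lambda_end - protocol$lambda_start
        n_steps <- as.integer(ceiling(abs(span) /
                                      (speed_ps * settings$timestep)))
        res <- langevin_cpp(term_matrix(potential), x0, settings$kBT,
                            settings$friction, settings$timestep, n_steps,
                            settings$save_stride, potential$periodic,
                            potential$period, protocol$spring_k,
                            protocol$lambda_start, sign(span) * speed_ps,
                            potential$domain[1], potential$domain[2])
        if (res$escaped >= 0) stop("trajectory escaped the domain")
        times <- seq(0, n_steps, by = settings$save_stride) *
          settings$timestep
        structure(list(times = times, positions = res$x,
                       lambda = res$lambda, seed = seed_i,
                       settings = settings, k_bias = protocol$spring_k,
                       protocol = protocol),
                  class = "toy_trajectory")
      })
      wp <- integrate_work(traj, protocol)
      works[, i] <- stats::approx(wp$lambda, wp$work, xout = lam_grid,
                                  rule = 2)$y
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failed <- c(failed, seed_i)
  }
  if (length(failed) > 0)
    stop("steered trajectories failed for seed(s): ",
         paste(failed, collapse = ", "))
  works[1, ] <- 0  # exact by construction; interpolation preserves it
  structure(
    list(lambda = lam_grid, works = works, protocol = protocol,
         thermo = settings, base_seed = base_seed),
    class = "work_profile_set")
}

#' @export
print.work_profile_set <- function(x, ...) {
  cat(sprintf(
    "<work_profile_set: %d trajectories, %d grid points, lambda %g -> %g A>\n",
    ncol(x$works), length(x$lambda), x$lambda[1],
    x$lambda[length(x$lambda)]))
  invisible(x)
}

#' Default umbrella window layout for the gate dihedral
#'
#' Ten consecutive windows with centers evenly spanning the closed (60
#' degrees) to open (about 160 degrees) conformations of the distal
#' histidine gate dihedral.
#'
#' @param n_windows number of windows.
#' @param from,to first and last window centers, degrees.
#' @param k_umb umbrella force constant, kcal mol^-1 rad^-2 (chosen so
#'   neighboring window histograms overlap well at the default spacing).
#' @return List of `list(center=, k_umb=)` windows.
#' @export
default_gate_windows <- function(n_windows = 10, from = 60, to = 160,
                                 k_umb = 60) {
  centers <- seq(from, to, length.out = n_windows)
  lapply(centers, function(ct) list(center = ct, k_umb = k_umb))
}

#' Run umbrella-sampling windows on a periodic gate potential
#'
#' Each window equilibrates at its center under the harmonic dihedral bias,
#' then samples the production run every `save_stride` steps. Window `i`
#' uses seed `base_seed + i`. Adjacent-window histogram overlap is checked
#' (2-degree bins); windows that share no occupied bin with a neighbor are
#' flagged, and [wham()] refuses such sets.
#'
#' @param potential periodic gate [potential_model()].
#' @param windows list of `list(center=, k_umb=)`, `k_umb` in
#'   kcal mol^-1 rad^-2; default [default_gate_windows()].
#' @param settings a [thermo_settings()] (degree-scale friction).
#' @param base_seed integer seed base.
#' @return An `umbrella_set`: per-window samples (degrees, wrapped to
#'   `[0, 360)`), bias parameters, thermo settings, and overlap diagnostics.
#' @export
run_umbrella_set <- function(potential, windows = default_gate_windows(),
                             settings = thermo_settings(friction = 0.05,
                                                        timestep = 0.2,
                                                        n_steps = 4e4,
                                                        save_stride = 10,
                                                        n_equil = 2000),
                             base_seed = 1) {
  stopifnot(length(windows) >= 2)
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ord <- order(centers)
  windows <- windows[ord]
  out <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    k_deg <- w$k_umb * (pi / 180)^2      # rad^-2 -> deg^-2
    set.seed(base_seed + i)
    x0 <- equilibrate_at(potential, w$center, k_deg, settings)
    res <- langevin_cpp(term_matrix(potential), x0, settings$kBT,
                        settings$friction, settings$timestep,
                        settings$n_steps, settings$save_stride,
                        potential$periodic, potential$period, k_deg,
                        w$center, 0, potential$domain[1],
                        potential$domain[2])
    samples <- res$x[-1] %% 360
    out[[i]] <- list(center = w$center, k_umb = w$k_umb, samples = samples)
  }
  uset <- structure(
    list(windows = out, thermo = settings,
         coord_name = "HE7 gate dihedral C-CA-CB-CG (deg)",
         base_seed = base_seed),
    class = "umbrella_set")
  uset$overlap_ok <- check_window_overlap(uset)
  if (!all(uset$overlap_ok))
    warning("adjacent umbrella windows without histogram overlap: pair(s) ",
            paste(which(!uset$overlap_ok), collapse = ", "))
  uset
}

## TRUE for each adjacent pair that shares at least one occupied 2-deg bin.
check_window_overlap <- function(uset, bin_width = 2) {
  breaks <- seq(0, 360, by = bin_width)
  hists <- lapply(uset$windows, function(w)
    tabulate(findInterval(w$samples, breaks, rightmost.closed = TRUE),
             nbins = length(breaks) - 1))
  n <- length(hists)
  vapply(seq_len(n - 1), function(i)
    any(hists[[i]] > 0 & hists[[i + 1]] > 0), logical(1))
}

#' @export
print.umbrella_set <- function(x, ...) {
  cat(sprintf("<umbrella_set: %d windows, centers %g..%g deg, %d samples each>\n",
              length(x$windows), x$windows[[1]]$center,
              x$windows[[length(x$windows)]]$center,
              length(x$windows[[1]]$samples)))
  invisible(x)
}
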