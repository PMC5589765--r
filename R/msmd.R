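#' Free energy profile container
#'
#' @param coord coordinate grid (A for migration, degrees for the gate),
#'   strictly monotone.
#' @param dG free energy, kcal/mol; zero at the reference point.
#' @param mse pointwise mean square error, kcal^2/mol^2 (its square root is
#'   the reported uncertainty); zeros when unknown.
#' @param n number of underlying trajectories/samples.
#' @param provenance one of `"jarzynski"`, `"wham"`, `"stitched"`,
#'   `"morse-augmented"`, `"analytic"`.
#' @param coord_name label for the coordinate axis.
#' @return Object of class `fep`.
#' @export
free_energy_profile <- function(coord, dG, mse = rep(0, length(coord)),
                                n = NA_integer_, provenance = "analytic",
                                coord_name = "coordinate") {
  stopifnot(length(coord) == length(dG), length(mse) == length(coord),
            all(diff(coord) > 0) || all(diff(coord) < 0))
  if (any(mse < 0)) stop("negative MSE")
  structure(
    list(coord = as.numeric(coord), dG = as.numeric(dG),
         mse = as.numeric(mse), n = n, provenance = provenance,
         coord_name = coord_name),
    class = "fep")
}

#' @export
print.fep <- function(x, ...) {
  cat(sprintf("<fep [%s]: %d points on %s in [%g, %g], dG range [%.2f, %.2f] kcal/mol>\n",
              x$provenance, length(x$coord), x$coord_name,
              min(x$coord), max(x$coord), min(x$dG), max(x$dG)))
  invisible(x)
}

#' Uncertainty of a free energy profile
#'
#' @param fep a [free_energy_profile()].
#' @return Pointwise uncertainty `sqrt(mse)`, kcal/mol.
#' @export
fep_uncertainty <- function(fep) sqrt(fep$mse)

#' Integrate the external work along a steered trajectory
#'
#' The moving harmonic restraint `U(x, lambda) = (k/2)(x - lambda)^2`
#' performs work `W(lambda1) = int_{lambda_start}^{lambda1}
#' dU/dlambda dlambda = int -k (x(lambda) - lambda) dlambda`; the integral
#' is accumulated by the trapezoidal rule over the saved frames.
#'
#' @param trajectory a steering [langevin_trajectory()] (or any
#'   `toy_trajectory` with a moving `lambda`).
#' @param protocol the [steering_protocol()] the trajectory was run under.
#' @return List with `lambda` (restraint center at each frame) and `work`
#'   (accumulated work, kcal/mol, zero at the first frame).
#' @export
integrate_work <- function(trajectory, protocol) {
  stopifnot(inherits(trajectory, "toy_trajectory"),
            inherits(protocol, "steering_protocol"))
  lam <- trajectory$lambda
  if (anyNA(lam))
    stop("trajectory carries no bias center; not a steering run")
  if (abs(lam[1] - protocol$lambda_start) > 1e-8)
    stop("trajectory/protocol mismatch: lambda starts at ", lam[1],
         " but protocol starts at ", protocol$lambda_start)
  x <- trajectory$positions
  f <- -protocol$spring_k * (x - lam)     # dU/dlambda
  dl <- diff(lam)
  w <- c(0, cumsum(0.5 * (f[-length(f)] + f[-1]) * dl))
  list(lambda = lam, work = w)
}

## Numerically stable log-mean-exp of -w/kBT per grid row.
log_mean_exp_neg <- function(W, kBT) {
  ## W: matrix grid x N; returns log( mean_i exp(-W_i/kBT) ) per row
  A <- -W / kBT
  m <- apply(A, 1, max)
  m + log(rowMeans(exp(A - m)))
}

#' Jarzynski free energy estimate from a work profile set
#'
#' Applies the Jarzynski equality pointwise on the shared restraint grid:
#' `dG(lambda) = -kBT log( (1/N) sum_i exp(-W_i(lambda)/kBT) )`, evaluated
#' in a log-sum-exp-stable form. The reference zero is the pull start,
#' where all works vanish. Finite-N exponential averaging is biased; see
#' [estimate_mse()] for the accompanying error model.
#'
#' @param works a `work_profile_set` from [run_steered_set()], or any list
#'   with `lambda`, `works` (matrix), and `thermo`.
#' @param mse optional precomputed pointwise MSE to attach.
#' @return A [free_energy_profile()] with provenance `"jarzynski"`.
#' @export
jarzynski_estimate <- function(works, mse = NULL) {
  W <- works$works
  if (!all(is.finite(W))) stop("non-finite work values")
  N <- ncol(W)
  if (N == 1) {
    warning("single work profile: Jarzynski estimate equals W_1")
    dG <- W[, 1]
  } else {
    kBT <- works$thermo$kBT
    dG <- -kBT * log_mean_exp_neg(W, kBT)
  }
  free_energy_profile(
    works$lambda, dG,
    mse = if (is.null(mse)) rep(0, length(works$lambda)) else mse,
    n = N, provenance = "jarzynski",
    coord_name = "Fe-O distance (A)")
}

#' Mean-square-error model for the Jarzynski estimator
#'
#' The statistical uncertainty of the exponentially averaged profile is
#' reported as the square root of `MSE = sigma^2(N) + B^2(N)`, where
#' `sigma^2` is the variance of the estimate and `B` the finite-N bias of
#' the Jarzynski estimator. Both components are obtained by bootstrap
#' resampling of the `N` work profiles: `sigma^2` is the bootstrap variance
#' of the pointwise estimate, and `B` the mean bootstrap estimate minus the
#' full-sample estimate. Deterministic given `boot_seed`.
#'
#' @param works a `work_profile_set`.
#' @param n_boot number of bootstrap resamples.
#' @param boot_seed RNG seed for the resampler.
#' @return List of class `error_estimate` with pointwise `sigma2`, `bias`,
#'   `mse`, plus `n`, `n_boot`, `boot_seed` and `fallback` flag.
#' @export
estimate_mse <- function(works, n_boot = 200, boot_seed = 1) {
  W <- works$works
  N <- ncol(W)
  kBT <- works$thermo$kBT
  if (N < 4) {
    warning("fewer than 4 work profiles: using analytic small-N fallback ",
            "var(W)/N with zero bias term")
    sigma2 <- apply(W, 1, stats::var) / N
    out <- list(sigma2 = sigma2, bias = rep(0, nrow(W)),
                mse = sigma2, n = N, n_boot = 0L, boot_seed = boot_seed,
                fallback = TRUE)
    class(out) <- "error_estimate"
    return(out)
  }
  full <- -kBT * log_mean_exp_neg(W, kBT)
  set.seed(boot_seed)
  boots <- matrix(NA_real_, nrow = nrow(W), ncol = n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(N, N, replace = TRUE)
    boots[, b] <- -kBT * log_mean_exp_neg(W[, idx, drop = FALSE], kBT)
  }
  sigma2 <- apply(boots, 1, stats::var)
  bias <- rowMeans(boots) - full
  out <- list(sigma2 = sigma2, bias = bias, mse = sigma2 + bias^2,
              n = N, n_boot = as.integer(n_boot), boot_seed = boot_seed,
              fallback = FALSE)
  class(out) <- "error_estimate"
  out
}

#' Jarzynski profile with bootstrap error bars
#'
#' Convenience wrapper: [jarzynski_estimate()] plus [estimate_mse()].
#'
#' @inheritParams estimate_mse
#' @return A [free_energy_profile()] with `mse` filled in.
#' @export
jarzynski_with_mse <- function(works, n_boot = 200, boot_seed = 1) {
  err <- estimate_mse(works, n_boot = n_boot, boot_seed = boot_seed)
  jarzynski_estimate(works, mse = err$mse)
}

#' Stitch two migration-segment profiles into one
#'
#' The two steering segments (solvent to docking site, docking site to
#' iron) are each referenced to their own start. The inner profile is
#' rigidly shifted by the least-squares constant that best matches the
#' outer profile over the overlap interval (by default the intersection of
#' the two grids, which the segment presets place around the docking-site
#' minimum), then the grids are merged at the overlap midpoint.
#' Uncertainties are carried through unchanged.
#'
#' @param fep_outer,fep_inner [free_energy_profile()]s sharing coordinate
#'   units; the outer one holds the reference zero.
#' @param overlap optional `c(lo, hi)` coordinate interval; default the
#'   intersection of the two grids.
#' @return A stitched [free_energy_profile()]; the junction mismatch is
#'   attached as attribute `junction_gap`.
#' @export
stitch_segments <- function(fep_outer, fep_inner, overlap = NULL) {
  co <- fep_outer$coord; ci <- fep_inner$coord
  if (is.null(overlap))
    overlap <- c(max(min(co), min(ci)), min(max(co), max(ci)))
  if (overlap[1] >= overlap[2]) stop("empty overlap interval")
  in_ov <- co >= overlap[1] & co <= overlap[2]
  if (sum(in_ov) < 3)
    stop("overlap contains fewer than 3 grid points of the outer profile")
  so <- order(ci)
  inner_on_outer <- stats::approx(ci[so], fep_inner$dG[so],
                                  xout = co[in_ov])$y
  if (anyNA(inner_on_outer))
    stop("inner profile does not cover the overlap interval")
  cshift <- mean(fep_outer$dG[in_ov] - inner_on_outer)

  mid <- mean(overlap)
  ## keep outer points on the far side of the junction, inner on the near
  ## side (orientation-agnostic: outer side = side containing its reference)
  outer_side <- sign(co[1] - mid)
  keep_o <- sign(co - mid) == outer_side | co == mid
  keep_i <- sign(ci - mid) != outer_side & ci != mid
  coord <- c(co[keep_o], ci[keep_i])
  dG <- c(fep_outer$dG[keep_o], fep_inner$dG[keep_i] + cshift)
  mse <- c(fep_outer$mse[keep_o], fep_inner$mse[keep_i])
  ord <- order(coord)
  if (co[1] > co[length(co)]) ord <- rev(ord)   # preserve pull order
  ## junction mismatch: profiles compared at the merge point
  g_o <- stats::approx(co[order(co)], fep_outer$dG[order(co)], xout = mid,
                       rule = 2)$y
  g_i <- stats::approx(ci[so], fep_inner$dG[so] + cshift, xout = mid,
                       rule = 2)$y
  out <- free_energy_profile(coord[ord], dG[ord], mse[ord],
                             n = fep_outer$n, provenance = "stitched",
                             coord_name = fep_outer$coord_name)
  attr(out, "shift") <- cshift
  attr(out, "junction_gap") <- abs(g_o - g_i)
  out
}

#' Morse parameters for the Fe--O bond-formation term
#'
#' Defaults: equilibrium distance 1.8 A, width parameter 5.6 A^-1, well
#' depth 10 kcal/mol; the term is zero-clamped beyond `r_max`
#' (default `r0 + 3/a`).
#'
#' @param r0 equilibrium Fe--O distance, A.
#' @param a width control parameter, A^-1.
#' @param D well depth, kcal/mol (positive).
#' @param r_max cutoff beyond which the term is zero.
#' @return List of class `morse_params`.
#' @export
morse_params <- function(r0 = 1.8, a = 5.6, D = 10, r_max = r0 + 3 / a) {
  stopifnot(a > 0, D > 0)
  if (r_max < r0) stop("r_max must not be smaller than r0")
  structure(list(r0 = r0, a = a, D = D, r_max = r_max),
            class = "morse_params")
}

#' Evaluate the (clamped) Morse bond term
#'
#' `V(r) = D (1 - exp(-a (r - r0)))^2 - D` up to `r_max`, zero beyond.
#'
#' @param r Fe--O distances, A.
#' @param params a [morse_params()].
#' @return Energies, kcal/mol.
#' @export
morse_energy <- function(r, params = morse_params()) {
  v <- params$D * (1 - exp(-params$a * (r - params$r0)))^2 - params$D
  v[r > params$r_max] <- 0
  v
}

#' Augment a migration profile with the Fe--O Morse bond term
#'
#' The classical migration profile carries no Fe--O bond formation; a Morse
#' term added at short distance qualitatively describes it.
#'
#' @param fep a migration [free_energy_profile()] (Fe--O distance axis).
#' @param params a [morse_params()].
#' @return The augmented profile, provenance `"morse-augmented"`.
#' @export
add_morse <- function(fep, params = morse_params()) {
  out <- free_energy_profile(fep$coord, fep$dG + morse_energy(fep$coord,
                                                              params),
                             fep$mse, n = fep$n,
                             provenance = "morse-augmented",
                             coord_name = fep$coord_name)
  attr(out, "morse") <- params
  out
}
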