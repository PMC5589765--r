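## Minimal-image angular displacement in degrees.
wrap_deg <- function(d) {
  d <- d %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' WHAM on binned histograms (core solver)
#'
#' Self-consistent iteration of the weighted-histogram equations for K
#' harmonically biased windows on a periodic angular coordinate:
#' `P_j = sum_k n_kj / sum_k N_k exp((f_k - c_kj)/kBT)` and
#' `f_k = -kBT log sum_j P_j exp(-c_kj/kBT)`, iterated until the largest
#' change in any window free energy `f_k` is below `tol`.
#'
#' Exposed separately from [wham()] so exact (expected-count) histograms
#' can be fed in directly; counts need not be integers.
#'
#' @param counts K x J matrix of (possibly fractional) bin counts.
#' @param bin_centers J bin centers, degrees.
#' @param centers K window centers, degrees.
#' @param k_umb K umbrella force constants, kcal mol^-1 rad^-2.
#' @param kBT thermal energy, kcal/mol.
#' @param tol convergence tolerance on window free energies, kcal/mol.
#' @param max_iter iteration cap.
#' @return List with unnormalized probabilities `P` per bin, window free
#'   energies `f`, `iterations`, `residual`.
#' @export
wham_core <- function(counts, bin_centers, centers, k_umb, kBT,
                      tol = 1e-6, max_iter = 1e5) {
  K <- length(centers)
  stopifnot(nrow(counts) == K, ncol(counts) == length(bin_centers),
            length(k_umb) == K)
  Nk <- rowSums(counts)
  nj <- colSums(counts)
  k_deg <- k_umb * (pi / 180)^2
  ## bias energy of bin j under window k
  C <- outer(seq_len(K), seq_along(bin_centers), function(k, j)
    0.5 * k_deg[k] * wrap_deg(bin_centers[j] - centers[k])^2)
  expC <- exp(-C / kBT)            # K x J
  f <- rep(0, K)
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- colSums(Nk * exp(f / kBT) * expC)   # length J
    P <- nj / denom
    f_new <- -kBT * log(as.vector(expC %*% P))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol || it >= max_iter) break
  }
  if (resid >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                 it, resid))
  list(P = P, f = f, iterations = it, residual = resid)
}

#' Reconstruct the gate-opening free energy profile by WHAM
#'
#' Histograms the per-window dihedral samples on a periodic grid and solves
#' the weighted-histogram equations. Bins never visited by any window are
#' dropped; the profile minimum is set to zero. A shot-noise uncertainty
#' `kBT / sqrt(n_j)` per bin is attached as the `mse` field.
#'
#' @param samples an `umbrella_set` from [run_umbrella_set()] (or any list
#'   of windows with `center`, `k_umb`, `samples` plus `thermo`).
#' @param bin_width histogram bin width, degrees.
#' @param tol,max_iter convergence controls, see [wham_core()].
#' @param min_count bins with fewer total counts are dropped from the
#'   profile.
#' @return A [free_energy_profile()] (provenance `"wham"`) over the sampled
#'   range; iteration diagnostics attached as attributes.
#' @export
wham <- function(samples, bin_width = 2, tol = 1e-6, max_iter = 1e5,
                 min_count = 5) {
  wins <- samples$windows
  if (is.null(samples$overlap_ok) && length(wins) > 1)
    samples$overlap_ok <- check_window_overlap(samples)
  if (!is.null(samples$overlap_ok) && !all(samples$overlap_ok))
    stop("umbrella windows without adjacent histogram overlap; ",
         "WHAM refuses: pair(s) ",
         paste(which(!samples$overlap_ok), collapse = ", "))
  breaks <- seq(0, 360, by = bin_width)
  bin_centers <- breaks[-1] - bin_width / 2
  counts <- t(vapply(wins, function(w)
    tabulate(findInterval(w$samples %% 360, breaks,
                          rightmost.closed = TRUE),
             nbins = length(bin_centers)),
    numeric(length(bin_centers))))
  res <- wham_core(counts, bin_centers,
                   vapply(wins, `[[`, numeric(1), "center"),
                   vapply(wins, `[[`, numeric(1), "k_umb"),
                   samples$thermo$kBT, tol = tol, max_iter = max_iter)
  nj <- colSums(counts)
  keep <- nj >= min_count & res$P > 0
  G <- -samples$thermo$kBT * log(res$P[keep])
  G <- G - min(G)
  out <- free_energy_profile(bin_centers[keep], G,
                             mse = (samples$thermo$kBT)^2 / nj[keep],
                             n = length(wins), provenance = "wham",
                             coord_name = samples$coord_name %||%
                               "dihedral (deg)")
  attr(out, "iterations") <- res$iterations
  attr(out, "residual") <- res$residual
  attr(out, "f_windows") <- res$f
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align gate profiles to a common closed-state zero
#'
#' Each profile is shifted so that its minimum inside the closed-state
#' region is exactly zero. Profiles remain mutually independent: this
#' alignment makes open/closed comparisons within each profile readable,
#' and explicitly does not make free energies comparable across profiles.
#'
#' @param profiles list of [free_energy_profile()]s.
#' @param closed_region `c(lo, hi)` degrees containing the closed minimum.
#' @return List of shifted profiles.
#' @export
align_profiles <- function(profiles, closed_region = c(50, 80)) {
  lapply(profiles, function(p) {
    in_r <- p$coord >= closed_region[1] & p$coord <= closed_region[2]
    if (!any(in_r))
      stop("profile does not cover the closed region [",
           closed_region[1], ", ", closed_region[2], "] deg")
    p$dG <- p$dG - min(p$dG[in_r])
    p
  })
}

#' Summarize open/closed preference and barrier of a gate profile
#'
#' Locates the closed and open minima of the binned profile, reports the
#' opening barrier (highest point between the two minima minus the closed
#' minimum), and classifies the preferred state. A tie is declared when the
#' open/closed difference is below the combined pointwise uncertainty of
#' the two minima (plus a numerical floor). If the profile is monotone over
#' the gate range the single basin wins with zero barrier.
#'
#' @param profile a [free_energy_profile()] on the gate dihedral.
#' @param labels optional `list(subunit=, state=, tautomer=)` carried
#'   through to the summary.
#' @param closed_region,open_region degree intervals searched for the two
#'   minima.
#' @return List of class `gate_summary` with `G_closed`, `G_open`,
#'   `dG_open`, `barrier_opening`, `preferred`, `labels`.
#' @export
summarize_gate <- function(profile, labels = NULL,
                           closed_region = c(45, 85),
                           open_region = c(135, 175)) {
  cc <- profile$coord
  if (length(cc) < 3) stop("degenerate profile")
  ic <- which(cc >= closed_region[1] & cc <= closed_region[2])
  io <- which(cc >= open_region[1] & cc <= open_region[2])
  if (length(ic) == 0 || length(io) == 0)
    stop("profile does not cover both gate regions")
  i_closed <- ic[which.min(profile$dG[ic])]
  i_open <- io[which.min(profile$dG[io])]
  G_closed <- profile$dG[i_closed]
  G_open <- profile$dG[i_open]
  between <- seq(min(i_closed, i_open), max(i_closed, i_open))
  barrier <- max(profile$dG[between]) - G_closed
  dG <- G_open - G_closed
  tol <- sqrt(profile$mse[i_closed] + profile$mse[i_open]) + 1e-9
  preferred <- if (abs(dG) < tol) "tie" else if (dG < 0) "open" else "closed"
  structure(
    list(G_closed = G_closed, G_open = G_open, dG_open = dG,
         barrier_opening = barrier, preferred = preferred,
         theta_closed = cc[i_closed], theta_open = cc[i_open],
         labels = labels),
    class = "gate_summary")
}

#' @export
print.gate_summary <- function(x, ...) {
  lab <- if (is.null(x$labels)) "" else
    paste0(" [", paste(unlist(x$labels), collapse = "/"), "]")
  cat(sprintf(
    "<gate_summary%s: dG(open-closed) = %+.2f kcal/mol, barrier = %.2f, preferred = %s>\n",
    lab, x$dG_open, x$barrier_opening, x$preferred))
  invisible(x)
}
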