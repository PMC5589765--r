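#' @useDynLib hemefep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Boltzmann constant in kcal mol^-1 K^-1
KB_KCAL <- 0.0019872041

#' Boltzmann constant used throughout the package
#'
#' @return The Boltzmann constant in kcal mol^-1 K^-1.
#' @export
kb_kcal <- function() KB_KCAL

#' Construct a one-dimensional model potential
#'
#' A potential is a sum of primitive terms evaluated on a single reaction
#' coordinate (an Fe--ligand distance in Angstrom, or a side-chain dihedral in
#' degrees). Supported terms:
#' \describe{
#'   \item{gaussian}{`height * exp(-(x - center)^2 / (2 width^2))`; wells are
#'     Gaussians with negative height.}
#'   \item{harmonic}{`(k/2) (x - center)^2`.}
#'   \item{morse}{`D (1 - exp(-a (x - r0)))^2 - D`.}
#'   \item{constant}{a flat offset.}
#' }
#' For periodic potentials (dihedrals, period 360 degrees) the displacement
#' `x - center` of gaussian and harmonic terms is wrapped to the minimal
#' image, so `V(x) == V(x + period)` holds exactly.
#'
#' @param terms list of terms, each a list with a `type` field plus the
#'   parameters above (`center`, `height`, `width`, `k`, `r0`, `a`, `D`,
#'   `value`).
#' @param domain numeric length-2, the coordinate interval the potential is
#'   meant for.
#' @param periodic logical; wrap displacements at `period`.
#' @param period period in coordinate units (360 for dihedrals in degrees).
#' @return An object of class `potential_model`.
#' @examples
#' v <- potential_model(list(list(type = "harmonic", center = 0, k = 10)),
#'                      domain = c(-5, 5))
#' eval_potential(v, 1)  # 5 kcal/mol
#' @export
potential_model <- function(terms = list(), domain = c(0, 1),
                            periodic = FALSE, period = 360) {
  stopifnot(is.list(terms), length(domain) == 2L, domain[1] < domain[2])
  known <- c("gaussian", "harmonic", "morse", "constant")
  for (tm in terms) {
    if (is.null(tm$type) || !tm$type %in% known)
      stop("unknown potential term type: ", deparse(tm$type))
  }
  structure(
    list(terms = terms, domain = as.numeric(domain),
         periodic = isTRUE(periodic), period = as.numeric(period)),
    class = "potential_model")
}

## Encode terms as the numeric matrix the C++ evaluator consumes.
## Rows: type code (0 gaussian, 1 harmonic, 2 morse, 3 constant), p1, p2, p3.
term_matrix <- function(pot) {
  if (length(pot$terms) == 0L)
    return(matrix(numeric(0), nrow = 4L, ncol = 0L))
  vapply(pot$terms, function(tm) {
    switch(tm$type,
      gaussian = c(0, tm$center, tm$height, tm$width),
      harmonic = c(1, tm$center, tm$k, 0),
      morse    = c(2, tm$r0, tm$a, tm$D),
      constant = c(3, tm$value, 0, 0))
  }, numeric(4))
}

#' Evaluate a model potential
#'
#' @param pot a [potential_model()].
#' @param x numeric vector of coordinate values.
#' @return Potential energy in kcal/mol at each `x`.
#' @export
eval_potential <- function(pot, x) {
  stopifnot(inherits(pot, "potential_model"))
  eval_potential_cpp(term_matrix(pot), as.numeric(x),
                     pot$periodic, pot$period)
}

#' Analytic derivative of a model potential
#'
#' @inheritParams eval_potential
#' @return dV/dx in kcal/mol per coordinate unit.
#' @export
potential_deriv <- function(pot, x) {
  stopifnot(inherits(pot, "potential_model"))
  eval_deriv_cpp(term_matrix(pot), as.numeric(x), pot$periodic, pot$period)
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<potential_model: %d term(s)%s, domain [%g, %g]>\n",
              length(x$terms),
              if (x$periodic) sprintf(", periodic %g", x$period) else "",
              x$domain[1], x$domain[2]))
  invisible(x)
}

#' Model potential for ligand migration along the Fe--O axis
#'
#' Presets emulating the two regimes of oxygen entry into a globin distal
#' pocket, on an Fe--O-distance-like coordinate with the solvent plateau at
#' zero energy at large distance. The `"closed"` gate preset has a single
#' migration barrier (default 5 kcal/mol, mid-range of the 4--6 kcal/mol
#' closed-gate regime) between the solvent plateau and a shallow distal well.
#' The `"open"` gate preset is essentially barrierless and has a hydrophobic
#' docking well of about -2 kcal/mol that draws the ligand inside.
#'
#' @param gate_state `"closed"` or `"open"`, or pass `terms` explicitly.
#' @param barrier closed-gate barrier height, kcal/mol (default 5).
#' @param well_depth docking/distal well depth, kcal/mol (negative).
#' @param terms optional explicit term list overriding the preset.
#' @param domain Fe--O distance interval in Angstrom.
#' @return A [potential_model()] on the migration coordinate.
#' @export
make_migration_potential <- function(gate_state = c("closed", "open"),
                                     barrier = NULL, well_depth = NULL,
                                     terms = NULL, domain = c(1.5, 9)) {
  if (!is.null(terms))
    return(potential_model(terms, domain = domain))
  gate_state <- match.arg(gate_state)
  if (gate_state == "closed") {
    if (is.null(barrier)) barrier <- 5.0
    if (is.null(well_depth)) well_depth <- -1.0
    tms <- list(
      list(type = "gaussian", center = 5.0, height = barrier, width = 0.8),
      list(type = "gaussian", center = 3.0, height = well_depth, width = 0.45))
  } else {
    if (is.null(barrier)) barrier <- 0.25
    if (is.null(well_depth)) well_depth <- -2.0
    tms <- list(
      list(type = "gaussian", center = 5.2, height = barrier, width = 0.7),
      list(type = "gaussian", center = 3.2, height = well_depth, width = 0.55))
  }
  pot <- potential_model(tms, domain = domain)
  pot$preset <- list(gate_state = gate_state, barrier = barrier,
                     well_depth = well_depth)
  pot
}

## Gate preset table: target free energy difference dG = G(open) - G(closed)
## and opening barrier (closed minimum -> top), kcal/mol. Trend-faithful
## emulation of the subunit/state/tautomer orderings: HIE most closed with the
## largest barrier, HIP most open with the smallest, beta more open than the
## matching alpha, and beta-R with small-to-no opening barrier.
GATE_PRESETS <- local({
  g <- expand.grid(subunit = c("alpha", "beta"), state = c("R", "T"),
                   tautomer = c("HID", "HIE", "HIP"),
                   stringsAsFactors = FALSE)
  key <- paste(g$subunit, g$state, g$tautomer, sep = ".")
  dg <- c(
    alpha.R.HID = 1.0,  beta.R.HID = -0.8,
    alpha.T.HID = 1.2,  beta.T.HID = 0.4,
    alpha.R.HIE = 2.2,  beta.R.HIE = 0.5,
    alpha.T.HIE = 2.5,  beta.T.HIE = 1.5,
    alpha.R.HIP = -0.5, beta.R.HIP = -2.5,
    alpha.T.HIP = -1.0, beta.T.HIP = -2.0)
  barrier <- c(
    alpha.R.HID = 2.4,  beta.R.HID = 0.25,
    alpha.T.HID = 2.5,  beta.T.HID = 2.0,
    alpha.R.HIE = 3.8,  beta.R.HIE = 0.60,
    alpha.T.HIE = 4.0,  beta.T.HIE = 3.5,
    alpha.R.HIP = 2.2,  beta.R.HIP = 0.10,
    alpha.T.HIP = 1.5,  beta.T.HIP = 1.2)
  g$dG_open <- unname(dg[key])
  g$barrier <- unname(barrier[key])
  g
})

#' Table of built-in gate presets
#'
#' @return Data frame with one row per (subunit, state, tautomer) preset and
#'   its target open-minus-closed free energy difference and opening barrier
#'   (kcal/mol).
#' @export
gate_preset_table <- function() GATE_PRESETS

#' Model potential for the distal-histidine gate dihedral
#'
#' Periodic double-well potential on the HisE7 side-chain dihedral
#' (C-Calpha-Cbeta-Cgamma), with the closed conformation near 60 degrees and
#' the open conformation near 160 degrees. Presets encode the qualitative,
#' tautomer- and subunit-dependent thermodynamics of gate opening: the
#' epsilon-protonated tautomer (HIE) is preferentially closed with the
#' highest opening barrier, the doubly protonated tautomer (HIP) prefers the
#' open state with the smallest barrier, beta subunits favor the open state
#' more than the matching alpha subunit, and beta-R presets are essentially
#' barrierless. See [gate_preset_table()] for the encoded targets.
#'
#' @param subunit `"alpha"` or `"beta"`.
#' @param state quaternary state, `"R"` or `"T"`.
#' @param tautomer histidine protonation state, `"HID"`, `"HIE"` or `"HIP"`.
#' @param terms optional explicit term list overriding the preset (still
#'   periodic with period 360).
#' @return A [potential_model()] on `[0, 360)` degrees; the preset targets
#'   are attached as the `preset` element.
#' @export
make_gate_potential <- function(subunit = c("alpha", "beta"),
                                state = c("R", "T"),
                                tautomer = c("HID", "HIE", "HIP"),
                                terms = NULL) {
  if (!is.null(terms))
    return(potential_model(terms, domain = c(0, 360),
                           periodic = TRUE, period = 360))
  subunit <- match.arg(subunit)
  state <- match.arg(state)
  tautomer <- match.arg(tautomer)
  row <- GATE_PRESETS[GATE_PRESETS$subunit == subunit &
                      GATE_PRESETS$state == state &
                      GATE_PRESETS$tautomer == tautomer, ]
  ## wells at 60 (closed) and 160 (open), transition-top region near 110,
  ## plus a high plateau bump opposite the gate so sampling stays on the
  ## 60..160 branch. Widths chosen so cross-talk between terms is < 0.03
  ## kcal/mol at the stationary points.
  dc <- row$barrier            # closed well depth below the top
  do <- row$barrier - row$dG_open
  tms <- list(
    list(type = "gaussian", center = 60,  height = -dc, width = 16),
    list(type = "gaussian", center = 160, height = -do, width = 16),
    list(type = "gaussian", center = 290, height = 6,   width = 35))
  pot <- potential_model(tms, domain = c(0, 360), periodic = TRUE,
                         period = 360)
  pot$preset <- list(subunit = subunit, state = state, tautomer = tautomer,
                     dG_open = row$dG_open, barrier = row$barrier)
  pot
}
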