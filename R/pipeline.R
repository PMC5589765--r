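#' Configuration for an end-to-end scenario run
#'
#' Bundles the scenario name, thermodynamic settings, protocol and seed for
#' [run_scenario()]. Every protocol field defaults to the standard study
#' conditions (150 kcal mol^-1 A^-2 spring, 0.25 A/ns pulls, 40
#' trajectories, Morse 1.8 A / 5.6 A^-1 / 10 kcal/mol, 10 gate windows
#' spanning 60-160 degrees, 300 K).
#'
#' @param scenario one of `"migration-closed"`, `"migration-open"`,
#'   `"gate"`, `"binding"`, `"geometry"`.
#' @param subunit,state,tautomer gate-preset labels (gate scenario only).
#' @param n_traj steered trajectories per segment.
#' @param seed base seed for all randomness in the run.
#' @param thermo a [thermo_settings()] (migration scenarios).
#' @param gate_thermo a [thermo_settings()] (gate scenario).
#' @param n_boot bootstrap resamples for the error model.
#' @param out_dir output directory for [run_scenario()].
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = c("migration-closed", "migration-open",
                                    "gate", "binding", "geometry"),
                       subunit = "beta", state = "R", tautomer = "HIP",
                       n_traj = 40, seed = 1,
                       thermo = thermo_settings(),
                       gate_thermo = thermo_settings(friction = 0.05,
                                                     timestep = 0.2,
                                                     n_steps = 4e4,
                                                     save_stride = 10,
                                                     n_equil = 2000),
                       n_boot = 200, out_dir = tempfile("hemefep_run_")) {
  scenario <- match.arg(scenario)
  structure(
    list(scenario = scenario, subunit = subunit, state = state,
         tautomer = tautomer, n_traj = n_traj, seed = seed,
         thermo = thermo, gate_thermo = gate_thermo, n_boot = n_boot,
         out_dir = out_dir),
    class = "run_config")
}

config_echo <- function(config) {
  th <- config$thermo
  c(sprintf("scenario=%s", config$scenario),
    sprintf("subunit=%s state=%s tautomer=%s", config$subunit,
            config$state, config$tautomer),
    sprintf("n_traj=%d seed=%d n_boot=%d", config$n_traj, config$seed,
            config$n_boot),
    sprintf("thermo: T=%g K friction=%g timestep=%g ps n_equil=%d",
            th$temperature, th$friction, th$timestep, th$n_equil),
    sprintf("gate_thermo: T=%g K friction=%g timestep=%g ps n_steps=%d",
            config$gate_thermo$temperature, config$gate_thermo$friction,
            config$gate_thermo$timestep, config$gate_thermo$n_steps))
}

#' Run an end-to-end analysis scenario
#'
#' Orchestrates simulate, estimate, stitch/augment, and summarize for one
#' scenario, writing a deterministic report bundle (profile and summary
#' TSVs plus a log with the full configuration echo) under
#' `config$out_dir`. Identical configurations give byte-identical TSV
#' outputs.
#'
#' Scenarios:
#' \describe{
#'   \item{migration-closed / migration-open}{two steered segments on the
#'     corresponding migration preset, Jarzynski + bootstrap MSE,
#'     stitching, Morse augmentation; summary reports barrier/well depths.}
#'   \item{gate}{umbrella windows on the chosen gate preset, WHAM,
#'     alignment to the closed-state zero, open/closed summary.}
#'   \item{binding}{binding-energy and mutant-shift tables plus the
#'     ordinal release ranking from the packaged dataset.}
#'   \item{geometry}{descriptor table from internally generated fixture
#'     structures at tense/relaxed alpha-subunit target geometries.}
#' }
#'
#' @param config a [run_config()].
#' @return List (invisibly) with the computed objects and `out_dir`;
#'   contents depend on the scenario.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(config$out_dir, "run.log")
  writeLines(c(sprintf("hemefep %s",
                       as.character(utils::packageVersion("hemefep"))),
               config_echo(config)), log)
  res <- switch(
    config$scenario,
    "migration-closed" = scenario_migration(config, "closed"),
    "migration-open" = scenario_migration(config, "open"),
    "gate" = scenario_gate(config),
    "binding" = scenario_binding(config),
    "geometry" = scenario_geometry(config))
  res$out_dir <- config$out_dir
  manifest <- file.path(config$out_dir, "MANIFEST")
  writeLines(sort(setdiff(list.files(config$out_dir), "MANIFEST")),
             manifest)
  invisible(res)
}

scenario_migration <- function(config, gate_state) {
  pot <- make_migration_potential(gate_state)
  ws_out <- run_steered_set(pot, migration_protocol("solvent_to_docking"),
                            n_traj = config$n_traj,
                            settings = config$thermo,
                            base_seed = config$seed)
  ws_in <- run_steered_set(pot, migration_protocol("docking_to_iron"),
                           n_traj = config$n_traj,
                           settings = config$thermo,
                           base_seed = config$seed + 1000)
  fep_out <- jarzynski_with_mse(ws_out, n_boot = config$n_boot,
                                boot_seed = config$seed)
  fep_in <- jarzynski_with_mse(ws_in, n_boot = config$n_boot,
                               boot_seed = config$seed + 1)
  stitched <- stitch_segments(fep_out, fep_in)
  final <- add_morse(stitched)

  write_workset_tsv(ws_out, file.path(config$out_dir,
                                      "works_solvent_to_docking.tsv"))
  write_workset_tsv(ws_in, file.path(config$out_dir,
                                     "works_docking_to_iron.tsv"))
  write_profile_tsv(stitched, file.path(config$out_dir,
                                        "fep_migration.tsv"))
  write_profile_tsv(final, file.path(config$out_dir,
                                     "fep_migration_morse.tsv"))

  plateau <- stitched$dG[1]
  classical <- stitched$dG[stitched$coord > morse_params()$r_max]
  summary <- data.frame(
    quantity = c("barrier_kcal", "well_depth_kcal", "max_uncertainty_kcal"),
    value = c(max(classical) - plateau, min(classical) - plateau,
              max(sqrt(stitched$mse))))
  utils::write.table(format(summary, digits = 6, trim = TRUE),
                     file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(workset_outer = ws_out, workset_inner = ws_in, fep = stitched,
       fep_morse = final, summary = summary)
}

scenario_gate <- function(config) {
  pot <- make_gate_potential(config$subunit, config$state, config$tautomer)
  uset <- run_umbrella_set(pot, settings = config$gate_thermo,
                           base_seed = config$seed)
  prof <- wham(uset)
  prof <- align_profiles(list(prof))[[1]]
  summ <- summarize_gate(prof, labels = list(subunit = config$subunit,
                                             state = config$state,
                                             tautomer = config$tautomer))
  write_umbrella_tsv(uset, file.path(config$out_dir, "umbrella.tsv"))
  write_profile_tsv(prof, file.path(config$out_dir, "fep_gate.tsv"))
  df <- data.frame(
    subunit = config$subunit, state = config$state,
    tautomer = config$tautomer, G_closed = summ$G_closed,
    G_open = summ$G_open, dG_open = summ$dG_open,
    barrier_opening = summ$barrier_opening, preferred = summ$preferred)
  utils::write.table(format(df, digits = 6, trim = TRUE),
                     file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(umbrella = uset, fep = prof, summary = summ)
}

scenario_binding <- function(config) {
  recs <- hb_binding_dataset()
  is_wt <- vapply(recs, function(r) r$variant == "wt", logical(1))
  shifts <- list()
  for (v in recs[!is_wt]) {
    wt <- Filter(function(r) r$subunit == v$subunit &&
                   r$state == v$state, recs[is_wt])[[1]]
    shifts[[paste(v$subunit, v$state, v$variant)]] <- mutant_shift(wt, v)
  }
  ranking <- koff_order(recs[is_wt])
  write_binding_tsv(recs, file.path(config$out_dir, "binding_records.tsv"))
  sdf <- do.call(rbind, lapply(shifts, function(s)
    data.frame(subunit = s$labels$subunit, state = s$labels$state,
               variant = s$labels$variant, ddE = s$ddE,
               effect = s$effect_class)))
  utils::write.table(format(sdf, digits = 6, trim = TRUE),
                     file.path(config$out_dir, "mutant_shifts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(format(ranking, digits = 6, trim = TRUE),
                     file.path(config$out_dir, "koff_ranking.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(records = recs, shifts = shifts, ranking = ranking)
}

scenario_geometry <- function(config) {
  ## fixtures at the tense/relaxed alpha-subunit target geometries
  specs <- list(
    alphaT = pocket_spec(dFe_O = 1.77, dO_O = 1.30, dFe_NHis = 2.20,
                         hf8_rot = 17, dHE7H_O1 = 2.43, dHE7H_O2 = 1.83),
    alphaR = pocket_spec(dFe_O = 1.77, dO_O = 1.30, dFe_NHis = 2.12,
                         hf8_rot = 6, dHE7H_O1 = 2.31, dHE7H_O2 = 2.14))
  descs <- lapply(names(specs), function(nm) {
    path <- file.path(config$out_dir, paste0("fixture_", nm, ".pdb"))
    write_fixture_pdb(specs[[nm]], path)
    pocket_descriptors(read_structure(path),
                       labels = list(subunit = "alpha",
                                     state = sub("alpha", "", nm)))
  })
  names(descs) <- names(specs)
  delta <- compare_states(descs$alphaT, descs$alphaR)
  ddf <- do.call(rbind, lapply(names(descs), function(nm) {
    d <- descs[[nm]]
    data.frame(structure = nm, dFe_O = d$dFe_O, dO_O = d$dO_O,
               dFe_NHis = d$dFe_NHis, HF8_rot_angle = d$HF8_rot_angle,
               dHE7H_O1 = d$dHE7H_O1, dHE7H_O2 = d$dHE7H_O2,
               dHF8Hd_LeuCO = d$dHF8Hd_LeuCO)
  }))
  utils::write.table(format(ddf, digits = 6, trim = TRUE),
                     file.path(config$out_dir, "descriptors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(format(delta, digits = 6, trim = TRUE),
                     file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(descriptors = descs, delta = delta)
}
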