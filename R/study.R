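# End-to-end drivers for the two credibility studies: the multi-patient
# mesh-convergence study (study 1) and the input-uncertainty robustness
# study (study 2). Both are deterministic given their seed and write plain
# CSV/JSON artifacts when an output directory is supplied.

#' Run study 1: multi-patient mesh convergence
#'
#' Generates a nested mesh family per patient, paces each member once at the
#' fixed apical site, and tabulates discretization errors of the normalized
#' apex-to-base activation time and the pseudo-ECG (scaled infinity norm and
#' cross-correlation lag) against the finest mesh, plus across-patient
#' coefficients of variation.
#'
#' @param specs list of [patient_spec()] (e.g. from [draw_cohort_specs()]).
#' @param edge_lengths strictly decreasing target edge lengths, cm.
#' @param config a [simulation_config()].
#' @param qcfg a [qoi_config()].
#' @param out_dir optional directory; when given, writes `error_table.csv`,
#'   `cov_table.csv` and `manifest.json`.
#' @return list with `errors` (error_table), `cov` (data.frame) and
#'   `manifest`.
#' @export
run_study_1 <- function(specs, edge_lengths = c(0.2, 0.1, 0.05),
                        config = study1_config(), qcfg = qoi_config(),
                        out_dir = NULL) {
  families <- lapply(specs, generate_mesh_family, edge_lengths = edge_lengths)
  errors <- run_convergence_study(families, config, qcfg)
  cov <- cov_table(errors)
  manifest <- list(study = "mesh_convergence",
                   n_patients = length(specs),
                   edge_lengths = edge_lengths,
                   seeds = vapply(specs, function(s) s$seed, integer(1)),
                   failed = attr(errors, "failed"),
                   config = config_fingerprint(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(errors, file.path(out_dir, "error_table.csv"))
    write_table(cov, file.path(out_dir, "cov_table.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(errors = errors, cov = cov, manifest = manifest)
}

#' Default simulation configuration for the convergence study
#'
#' Shorter window than the robustness study: the convergence QOIs
#' (activation time, depolarization-phase ECG) are fully formed once
#' activation completes, so the beat is truncated at 100 ms.
#'
#' @param ... overrides passed to [simulation_config()].
#' @export
study1_config <- function(...) {
  defaults <- list(duration = 100,
                   stimulus = list(center = NULL, radius = 0.15,
                                   amplitude = 1, start = 1, duration = 2))
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Run study 2: robustness of the near-vs-far pacing conclusion
#'
#' Full uncertainty-quantification pipeline on a synthetic cohort:
#' calibrates conductivity to the baseline conduction velocity, builds
#' border-zone variants (contracted / original / expanded) and conductivity
#' variants (low / baseline / high CV), simulates each patient paced near
#' and far from scar under every variant, computes HRGV panels, and runs the
#' scenario battery: systematic-bias tests, the worst-case combination
#' test, Monte-Carlo sampling over discrete variant assignments, and
#' normal-CV interpolation sampling.
#'
#' @param specs list of [patient_spec()].
#' @param edge_length single mesh resolution for the study, cm.
#' @param config baseline [simulation_config()]; its conductivity is
#'   retuned to `target_cv` at the study resolution before use.
#' @param qcfg a [qoi_config()].
#' @param pacing_distances `c(near, far)` distances from scar, cm.
#' @param contract_dist,expand_dist BZ perturbation distances, cm.
#' @param cv_factors CV factors for the conductivity variants.
#' @param target_cv baseline conduction velocity, cm/s.
#' @param rob_cfg a [robustness_config()] (its `cv_levels` is filled in
#'   from the calibration).
#' @param calibration calibration-slab arguments for
#'   [measure_planar_cv()]: list with `slab_extent` and `edge_length`.
#' @param out_dir optional output directory (`hrgv_panel.csv`,
#'   `robustness_report.json`, `robustness_report.csv`, `manifest.json`).
#' @return list with `bz_panel`, `cond_panel` ([hrgv_panel()]), `baseline`
#'   (the reproduction test), `report` (8 scenario entries), `cv_levels`,
#'   and `manifest`.
#' @export
run_study_2 <- function(specs, edge_length = 0.1,
                        config = simulation_config(), qcfg = qoi_config(),
                        pacing_distances = c(0.2, 2.0),
                        contract_dist = 0.05, expand_dist = 0.1,
                        cv_factors = c(0.8, 1.2), target_cv = 66,
                        rob_cfg = robustness_config(),
                        calibration = list(slab_extent = c(2.4, 0.2, 0.2),
                                           edge_length = edge_length),
                        out_dir = NULL) {
  # conductivity calibration at the study resolution
  base_cfg <- tune_conductivity_to_cv(
    target_cv, config, slab_extent = calibration$slab_extent,
    edge_length = calibration$edge_length)
  cvar <- conductivity_variants(
    base_cfg, cv_factors, baseline_cv = attr(base_cfg, "measured_cv"),
    slab_extent = calibration$slab_extent,
    edge_length = calibration$edge_length)
  cv_levels <- as.numeric(attr(cvar, "cv"))

  K <- length(specs)
  bz_near <- bz_far <- matrix(
    NA_real_, K, 3, dimnames = list(NULL, c("contracted", "original",
                                            "expanded")))
  cd_near <- cd_far <- matrix(
    NA_real_, K, 3, dimnames = list(NULL, c("low", "baseline", "high")))
  rows <- list()

  for (k in seq_len(K)) {
    sp <- specs[[k]]
    mesh <- generate_patient(sp, edge_length)
    sites <- select_pacing_sites(mesh, pacing_distances)
    variants <- bz_variants(mesh, contract_dist, expand_dist)
    one <- function(msh, cfg, site_node) {
      cfg$stimulus$center <- msh$nodes[site_node, ]
      cfg$stimulus$nodes <- NULL
      sol <- run_monodomain(msh, cfg)
      rmap <- repolarization_map(sol, qcfg)
      hrgv(repolarization_gradient(rmap, msh), msh, qcfg)
    }
    for (v in names(variants)) {
      bz_near[k, v] <- one(variants[[v]], base_cfg, sites[1])
      bz_far[k, v] <- one(variants[[v]], base_cfg, sites[2])
    }
    cd_near[k, "baseline"] <- bz_near[k, "original"]
    cd_far[k, "baseline"] <- bz_far[k, "original"]
    for (v in c("low", "high")) {
      cd_near[k, v] <- one(mesh, cvar[[v]], sites[1])
      cd_far[k, v] <- one(mesh, cvar[[v]], sites[2])
    }
    for (v in colnames(bz_near)) rows[[length(rows) + 1]] <- data.frame(
      patient_id = sp$patient_id, input = "border_zone", variant = v,
      hrgv_near = bz_near[k, v], hrgv_far = bz_far[k, v])
    for (v in colnames(cd_near)) rows[[length(rows) + 1]] <- data.frame(
      patient_id = sp$patient_id, input = "conductivity", variant = v,
      hrgv_near = cd_near[k, v], hrgv_far = cd_far[k, v])
  }
  bz_panel <- hrgv_panel(bz_near, bz_far)
  cond_panel <- hrgv_panel(cd_near, cd_far)

  alpha <- rob_cfg$alpha
  baseline <- systematic_scenario_test(bz_panel, "original", alpha)
  baseline$scenario <- "baseline_original"
  cfg_cv <- rob_cfg
  cfg_cv$cv_levels <- cv_levels
  report <- list(
    bz_contracted = systematic_scenario_test(bz_panel, "contracted", alpha),
    bz_expanded = systematic_scenario_test(bz_panel, "expanded", alpha),
    bz_worst_case = worst_case_test(bz_panel, alpha),
    bz_mc = list(scenario = "bz_mc_sampling",
                 fraction_significant =
                   as.numeric(mc_fraction_significant(bz_panel, rob_cfg)),
                 n_samples = rob_cfg$n_samples, seed = rob_cfg$seed),
    cond_low = systematic_scenario_test(cond_panel, "low", alpha),
    cond_high = systematic_scenario_test(cond_panel, "high", alpha),
    cond_mc = list(scenario = "cond_mc_sampling",
                   fraction_significant =
                     as.numeric(mc_fraction_significant(cond_panel, rob_cfg)),
                   n_samples = rob_cfg$n_samples, seed = rob_cfg$seed),
    cond_cv_normal = list(scenario = "cond_cv_normal_sampling",
                          fraction_significant =
                            as.numeric(cv_normal_sampling(cond_panel, cfg_cv)),
                          n_samples = rob_cfg$n_samples, seed = rob_cfg$seed))

  panel_df <- do.call(rbind, rows)
  manifest <- list(study = "bz_conductivity_robustness",
                   n_patients = K,
                   edge_length = edge_length,
                   pacing_distances = pacing_distances,
                   cv_levels = cv_levels,
                   alpha = alpha, n_samples = rob_cfg$n_samples,
                   seed = rob_cfg$seed,
                   patient_seeds = vapply(specs, function(s) s$seed,
                                          integer(1)),
                   config = config_fingerprint(base_cfg))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(panel_df, file.path(out_dir, "hrgv_panel.csv"))
    write_table(report_to_df(c(list(baseline = baseline), report)),
                file.path(out_dir, "robustness_report.csv"))
    jsonlite::write_json(
      list(baseline = baseline, scenarios = report, manifest = manifest),
      file.path(out_dir, "robustness_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(bz_panel = bz_panel, cond_panel = cond_panel, baseline = baseline,
       report = report, cv_levels = cv_levels, panel_df = panel_df,
       manifest = manifest)
}

# flatten a list of scenario entries to a data.frame for CSV output
report_to_df <- function(entries) {
  do.call(rbind, lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    data.frame(scenario = e$scenario,
               t = if (!is.null(e$t) && !is.na(e$t)) e$t else NA_real_,
               p = if (!is.null(e$p)) e$p else NA_real_,
               significant = if (!is.null(e$significant)) e$significant
                             else NA,
               fraction_significant =
                 if (!is.null(e$fraction_significant))
                   e$fraction_significant else NA_real_)
  }))
}

# stable scalar summary of a config for provenance manifests
config_fingerprint <- function(config) {
  list(conductivity_fiber = config$conductivity_fiber,
       conductivity_cross = config$conductivity_cross,
       bz_conductivity_scale = config$bz_conductivity_scale,
       dt = config$dt, duration = config$duration,
       cell = unclass(config$cell$healthy),
       cell_bz = unclass(config$cell$bz))
}

# deterministic CSV writer (fixed significant digits, no row names)
write_table <- function(df, path) {
  df2 <- as.data.frame(df)
  num <- vapply(df2, is.numeric, logical(1))
  df2[num] <- lapply(df2[num], function(x) formatC(x, digits = 12,
                                                   format = "g"))
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
}
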