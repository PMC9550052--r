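# Multi-patient mesh-convergence study: discretization-error metrics against
# the finest mesh of each patient's family, and across-patient coefficients
# of variation.

#' Scaled infinity-norm ECG error
#'
#' `E_x = max|phi_x - phi_h| / max|phi_h|`: the relative discretization
#' error of an ECG computed on a coarser mesh (`phi_x`) against the
#' high-resolution ground truth (`phi_h`). Invariant to a common scaling of
#' both traces.
#'
#' @param phi_x,phi_h numeric vectors (or `ecg_trace` objects) of equal
#'   length sampled at the same interval.
#' @return non-negative unitless error.
#' @export
ecg_relative_error <- function(phi_x, phi_h) {
  phi_x <- as_phi(phi_x); phi_h <- as_phi(phi_h)
  if (length(phi_x) != length(phi_h))
    stop("traces must have equal length")
  denom <- max(abs(phi_h))
  if (denom == 0)
    stop("reference trace is identically zero (undefined normalization)")
  max(abs(phi_x - phi_h)) / denom
}

as_phi <- function(x) {
  if (inherits(x, "ecg_trace") || is.data.frame(x)) x$phi else as.numeric(x)
}

#' ECG lag by cross-correlation
#'
#' Integer-sample shift maximizing the zero-padded (un-normalized,
#' dot-product) cross-correlation between two equally sampled traces,
#' converted to ms. Ties are broken toward the smallest absolute shift, then
#' toward the negative shift. A positive lag means `phi_x` is delayed
#' relative to `phi_h`.
#'
#' @param phi_x,phi_h traces of equal length and sampling.
#' @param max_shift maximum shift searched, in samples.
#' @param sampling_interval ms per sample; taken from the trace attribute
#'   when present.
#' @return lag in ms (an integer multiple of the sampling interval).
#' @export
ecg_lag <- function(phi_x, phi_h, max_shift = 25, sampling_interval = NULL) {
  if (is.null(sampling_interval))
    sampling_interval <- attr(phi_x, "sampling_interval")
  if (is.null(sampling_interval)) sampling_interval <- 1
  phi_x <- as_phi(phi_x); phi_h <- as_phi(phi_h)
  nl <- length(phi_x)
  if (length(phi_h) != nl) stop("traces must have equal length")
  if (max_shift >= nl) stop("max_shift must be smaller than the trace length")
  if (stats::var(phi_x) == 0 || stats::var(phi_h) == 0)
    stop("constant trace: cross-correlation lag undefined")
  shifts <- -max_shift:max_shift
  cc <- vapply(shifts, function(s) {
    # zero-padded alignment: phi_x delayed by s against phi_h
    if (s >= 0) sum(phi_x[(1 + s):nl] * phi_h[1:(nl - s)])
    else sum(phi_x[1:(nl + s)] * phi_h[(1 - s):nl])
  }, numeric(1))
  best <- max(cc)
  cand <- shifts[cc == best]
  cand <- cand[order(abs(cand), cand)][1]
  cand * sampling_interval
}

#' Run the multi-patient mesh-convergence study
#'
#' For each patient's mesh family (coarse -> fine), paces one beat at a
#' fixed physical apical site, extracts the normalized activation time at a
#' fixed basal probe point and the pseudo-ECG at a fixed electrode, then
#' computes per-resolution errors against the finest member as ground truth:
#' absolute error in normalized activation time (ms/cm), scaled
#' infinity-norm ECG error, and cross-correlation ECG lag (ms). Patients
#' whose simulation fails are flagged and excluded; the study continues.
#'
#' @param families list of `mesh_family` objects (one per patient).
#' @param config a [simulation_config()]; its stimulus `center` (or, if
#'   `NULL`, the apical default `(0, Ly/2, Lz/2)`) is a fixed physical
#'   location shared by all resolutions.
#' @param qcfg a [qoi_config()]; `base_probe_point` and
#'   `electrode_positions[[1]]` default to `(Lx, Ly/2, Lz/2)` and a point
#'   4 cm beyond the basal face.
#' @param max_shift lag search range in samples.
#' @return object of class `error_table`: data.frame with one row per
#'   (patient, non-finest resolution): `patient_id`, `resolution`,
#'   `activation_error` (ms/cm), `activation_diff` (signed),
#'   `ecg_relative_error`, `ecg_lag` (ms); attribute `failed` lists
#'   excluded patients.
#' @export
run_convergence_study <- function(families, config, qcfg = qoi_config(),
                                  max_shift = 25) {
  rows <- list()
  failed <- character(0)
  for (fam in families) {
    pid <- attr(fam, "patient_id")
    res <- try(convergence_one_patient(fam, config, qcfg, max_shift),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      warning(sprintf("patient %s failed and is excluded: %s", pid,
                      attr(res, "condition")$message))
      failed <- c(failed, pid)
    } else rows[[pid]] <- res
  }
  if (length(rows) < 1) stop("no patient completed the convergence study")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("error_table", "data.frame"), failed = failed)
}

convergence_one_patient <- function(fam, config, qcfg, max_shift) {
  hs <- attr(fam, "edge_lengths")
  ext <- fam[[1]]$extent
  stim_center <- config$stimulus$center
  if (is.null(stim_center)) stim_center <- c(0, ext[2] / 2, ext[3] / 2)
  probe <- qcfg$base_probe_point
  if (is.null(probe)) probe <- c(ext[1], ext[2] / 2, ext[3] / 2)
  electrode <- if (!is.null(qcfg$electrode_positions))
    qcfg$electrode_positions[[1]] else
    c(ext[1] / 2 + 4, ext[2] / 2, ext[3] / 2)  # "V1-like": 4 cm from centroid

  per_res <- lapply(fam, function(mesh) {
    cfg <- config
    cfg$stimulus$center <- stim_center
    cfg$stimulus$nodes <- NULL
    sol <- run_monodomain(mesh, cfg)
    if (!sol$meta$activated) stop("domain failed to activate")
    amap <- activation_map(sol, qcfg)
    d2 <- (mesh$nodes[, 1] - stim_center[1])^2 +
          (mesh$nodes[, 2] - stim_center[2])^2 +
          (mesh$nodes[, 3] - stim_center[3])^2
    pacing_node <- which.min(d2)
    nat <- normalized_activation_time(amap, mesh, pacing_node, probe)
    ecg <- pseudo_ecg(sol, mesh, electrode, cfg)
    list(nat = as.numeric(nat), ecg = ecg)
  })
  n_res <- length(per_res)
  ref <- per_res[[n_res]]
  do.call(rbind, lapply(seq_len(n_res - 1), function(i) {
    diff_nat <- per_res[[i]]$nat - ref$nat
    data.frame(patient_id = attr(fam, "patient_id"),
               resolution = hs[i],
               activation_error = abs(diff_nat),
               activation_diff = diff_nat,
               ecg_relative_error = ecg_relative_error(per_res[[i]]$ecg,
                                                       ref$ecg),
               ecg_lag = ecg_lag(per_res[[i]]$ecg, ref$ecg,
                                 max_shift = max_shift),
               stringsAsFactors = FALSE)
  }))
}

#' Coefficient of variation of a sample
#'
#' Sample standard deviation divided by the mean. `NA` when the mean is zero
#' (the lag metric is integer-valued and often all-zero across patients, so
#' an undefined COV must be representable).
#'
#' @param x numeric vector, length >= 2.
#' @return COV, or `NA` if `mean(x) == 0`.
#' @export
cov_of <- function(x) {
  if (length(x) < 2) stop("COV needs at least 2 patients")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' Across-patient COV summary of a convergence error table
#'
#' @param errors an `error_table` from [run_convergence_study()].
#' @return data.frame with one row per resolution and columns
#'   `cov_activation_error`, `cov_ecg_relative_error`, `cov_ecg_lag`
#'   (absolute-error COVs; `NA` where the mean error is zero).
#' @export
cov_table <- function(errors) {
  stopifnot(is.data.frame(errors))
  res <- sort(unique(errors$resolution), decreasing = TRUE)
  out <- do.call(rbind, lapply(res, function(r) {
    e <- errors[errors$resolution == r, ]
    if (nrow(e) < 2)
      stop("COV needs at least 2 patients per resolution")
    data.frame(resolution = r,
               cov_activation_error = cov_of(e$activation_error),
               cov_ecg_relative_error = cov_of(e$ecg_relative_error),
               cov_ecg_lag = cov_of(abs(e$ecg_lag)))
  }))
  rownames(out) <- NULL
  out
}
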