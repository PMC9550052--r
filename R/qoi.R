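# Quantities of interest extracted from a voltage solution: activation and
# repolarization maps, normalized activation time, pseudo-ECG, the
# repolarization-gradient field, and the high-repolarization-gradient volume
# (HRGV) near scar.

#' QOI extraction configuration
#'
#' @param activation_threshold upstroke detection threshold, mV.
#' @param repolarization_threshold voltage the membrane must return below to
#'   count as repolarized, mV (default -70).
#' @param gradient_threshold repolarization-gradient magnitude threshold for
#'   the HRGV, ms/cm (default 30; 25 is the conventional sensitivity
#'   alternative).
#' @param scar_proximity_radius radius of the "near scar" region the HRGV is
#'   restricted to, cm (default 1).
#' @param base_probe_point 3-vector (cm) where the normalized activation time
#'   is read (nearest mesh node); `NULL` to set per study.
#' @param electrode_positions list of 3-vectors (cm) of virtual unipolar
#'   electrodes; `NULL` to set per study.
#' @return list of class `qoi_config`.
#' @export
qoi_config <- function(activation_threshold = -20,
                       repolarization_threshold = -70,
                       gradient_threshold = 30,
                       scar_proximity_radius = 1.0,
                       base_probe_point = NULL,
                       electrode_positions = NULL) {
  stopifnot(gradient_threshold > 0, scar_proximity_radius > 0)
  structure(list(activation_threshold = activation_threshold,
                 repolarization_threshold = repolarization_threshold,
                 gradient_threshold = gradient_threshold,
                 scar_proximity_radius = scar_proximity_radius,
                 base_probe_point = base_probe_point,
                 electrode_positions = electrode_positions),
            class = "qoi_config")
}

# first time each column of V crosses `thr` in direction `dir` (+1 upward,
# -1 downward), linearly interpolated; NA where never crossed. `from` is a
# per-node earliest time (crossings before it are ignored).
first_crossing <- function(V, times, thr, dir = +1, from = NULL) {
  n <- ncol(V)
  if (!is.null(from)) from[is.na(from)] <- Inf
  res <- rep(NA_real_, n)
  pending <- rep(TRUE, n)
  for (s in seq_len(nrow(V) - 1)) {
    v0 <- V[s, ]; v1 <- V[s + 1, ]
    if (dir > 0) hit <- pending & v0 <= thr & v1 > thr
    else hit <- pending & v0 >= thr & v1 < thr
    if (!is.null(from)) hit <- hit & times[s] >= from
    if (any(hit)) {
      frac <- (thr - v0[hit]) / (v1[hit] - v0[hit])
      res[hit] <- times[s] + frac * (times[s + 1] - times[s])
      pending[hit] <- FALSE
    }
    if (!any(pending)) break
  }
  res
}

#' Activation map
#'
#' Per-node time of the first upward crossing of the activation threshold,
#' linearly interpolated between output samples; `NA` where the node never
#' activates.
#'
#' @param sol a `voltage_solution` from [run_monodomain()].
#' @param cfg a [qoi_config()].
#' @return numeric vector of activation times (ms) with `NA` sentinels.
#' @export
activation_map <- function(sol, cfg = qoi_config()) {
  first_crossing(sol$voltage, sol$times, cfg$activation_threshold, +1)
}

#' Repolarization map
#'
#' Per-node time at which the membrane voltage first returns below the
#' repolarization threshold after that node's activation; `NA` where the
#' node never activated or has not repolarized within the simulated window.
#'
#' @inheritParams activation_map
#' @return numeric vector of repolarization times (ms) with `NA` sentinels.
#' @export
repolarization_map <- function(sol, cfg = qoi_config()) {
  act <- activation_map(sol, cfg)
  rep_t <- first_crossing(sol$voltage, sol$times,
                          cfg$repolarization_threshold, -1, from = act)
  rep_t[is.na(act)] <- NA_real_
  rep_t
}

#' Normalized activation time at a probe point
#'
#' Activation time at the mesh node nearest `probe_point`, divided by the
#' Euclidean distance between that node and the pacing node — the
#' heart-size-normalized activation QOI of the convergence study (ms/cm).
#'
#' @param amap activation map from [activation_map()].
#' @param mesh the [labeled_mesh()] the solution was computed on.
#' @param pacing_node index of the paced node.
#' @param probe_point 3-vector, cm.
#' @return normalized activation time, ms/cm; attribute `probe_node`.
#' @export
normalized_activation_time <- function(amap, mesh, pacing_node, probe_point) {
  d2 <- (mesh$nodes[, 1] - probe_point[1])^2 +
        (mesh$nodes[, 2] - probe_point[2])^2 +
        (mesh$nodes[, 3] - probe_point[3])^2
  probe <- which.min(d2)
  dist <- sqrt(sum((mesh$nodes[probe, ] - mesh$nodes[pacing_node, ])^2))
  if (dist == 0)
    stop("probe point coincides with the pacing node (zero distance)")
  if (is.na(amap[probe]))
    stop("probe node never activated")
  out <- amap[probe] / dist
  attr(out, "probe_node") <- probe
  out
}

#' Pseudo-ECG at a virtual electrode
#'
#' Infinite-volume-conductor lead field: at each output time,
#' `phi(e) = -k * sum_elements vol * (sigma grad V) . grad(1/r)`, with `r`
#' the distance from the element centroid (single-point quadrature) to the
#' electrode, per-element constant `grad V` from the P1 interpolant, and
#' `k = 1` (units arbitrary but consistent; downstream error metrics are
#' invariant to `k`). Scar elements carry zero conductivity and do not
#' contribute.
#'
#' @param sol a `voltage_solution`.
#' @param mesh the [labeled_mesh()] it was computed on.
#' @param electrode 3-vector (cm), strictly outside the tissue.
#' @param config the [simulation_config()] used (for conductivities);
#'   defaults to unit isotropic conductivity weighting if omitted.
#' @return object of class `ecg_trace`: data.frame with `time` (ms) and
#'   `phi`.
#' @export
pseudo_ecg <- function(sol, mesh, electrode, config = NULL) {
  cen <- element_centroids(mesh)
  rx <- cen[, 1] - electrode[1]
  ry <- cen[, 2] - electrode[2]
  rz <- cen[, 3] - electrode[3]
  r2 <- rx^2 + ry^2 + rz^2
  edge <- mean_edge_length(mesh)
  if (min(r2) < (0.5 * edge)^2)
    stop("electrode lies inside or on the tissue mesh (r -> 0)")
  # grad(1/r) = -(x - e) / r^3 evaluated at the centroid
  inv_r3 <- r2^(-1.5)
  g1x <- -rx * inv_r3; g1y <- -ry * inv_r3; g1z <- -rz * inv_r3
  g <- p1_gradients(mesh)
  if (is.null(config))
    config <- simulation_config(conductivity_fiber = 1,
                                conductivity_cross = 1,
                                surface_to_volume = 1, capacitance = 1)
  D <- element_diffusivity(mesh, config)
  w <- g$vol
  el <- mesh$elems
  n_t <- nrow(sol$voltage)
  phi <- numeric(n_t)
  for (s in seq_len(n_t)) {
    v <- sol$voltage[s, ]
    vx <- rowSums(g$gx * matrix(v[el], ncol = 4))
    vy <- rowSums(g$gy * matrix(v[el], ncol = 4))
    vz <- rowSums(g$gz * matrix(v[el], ncol = 4))
    sx <- D[, "xx"] * vx + D[, "xy"] * vy + D[, "xz"] * vz
    sy <- D[, "xy"] * vx + D[, "yy"] * vy + D[, "yz"] * vz
    sz <- D[, "xz"] * vx + D[, "yz"] * vy + D[, "zz"] * vz
    phi[s] <- -sum(w * (sx * g1x + sy * g1y + sz * g1z))
  }
  structure(data.frame(time = sol$times, phi = phi),
            class = c("ecg_trace", "data.frame"),
            sampling_interval = sol$sampling_interval)
}

#' Repolarization-gradient magnitude per element
#'
#' Magnitude of the spatial gradient of repolarization time from the P1
#' (linear) interpolant of the nodal repolarization map — exact for nodal
#' data linear in space. Elements with any undefined nodal time are `NA`.
#'
#' @param rmap repolarization map from [repolarization_map()] (or any nodal
#'   field in ms).
#' @param mesh the [labeled_mesh()].
#' @return numeric vector of per-element gradient magnitudes, ms/cm.
#' @export
repolarization_gradient <- function(rmap, mesh) {
  g <- p1_gradients(mesh)
  tv <- matrix(rmap[mesh$elems], ncol = 4)
  gx <- rowSums(g$gx * tv); gy <- rowSums(g$gy * tv)
  gz <- rowSums(g$gz * tv)
  out <- sqrt(gx^2 + gy^2 + gz^2)
  out[rowSums(is.na(tv)) > 0] <- NA_real_
  out
}

#' High repolarization gradient volume (HRGV)
#'
#' Total volume of healthy or border-zone elements whose centroid lies
#' within `scar_proximity_radius` of the scar boundary surface and whose
#' repolarization-gradient magnitude exceeds `gradient_threshold` — the
#' arrhythmia-substrate surrogate of the robustness study. Zero when the
#' mesh has no scar (empty proximity region).
#'
#' @param grad per-element gradient magnitudes from
#'   [repolarization_gradient()].
#' @param mesh the [labeled_mesh()].
#' @param cfg a [qoi_config()].
#' @return HRGV in cm^3.
#' @export
hrgv <- function(grad, mesh, cfg = qoi_config()) {
  if (!any(mesh$tissue == TISSUE_SCAR)) return(0)
  vols <- element_volumes(mesh)
  excitable <- mesh$tissue != TISSUE_SCAR
  cen <- element_centroids(mesh)
  d <- rep(Inf, nrow(cen))
  d[excitable] <- dist_to_scar(mesh, cen[excitable, , drop = FALSE])
  sel <- excitable & d <= cfg$scar_proximity_radius &
    !is.na(grad) & grad > cfg$gradient_threshold
  sum(vols[sel])
}
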