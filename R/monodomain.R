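# Anisotropic monodomain reaction-diffusion solver: P1 tetrahedral finite
# elements with lumped mass, operator splitting (explicit reaction, backward
# Euler diffusion with a single Cholesky factorization). Scar elements carry
# zero conductivity and no reaction.

#' Simulation configuration
#'
#' Physical and numerical parameters for [run_monodomain()]. Conductivity is
#' transversely isotropic: `sigma = sigma_f f x f + sigma_c (I - f x f)` per
#' element, scaled by `bz_conductivity_scale` on border-zone elements and
#' zero on scar. The monodomain diffusivity is
#' `sigma / (surface_to_volume * capacitance)` (cm^2/ms with the unit
#' conventions below).
#'
#' @param conductivity_fiber fiber-direction conductivity, mS/cm.
#' @param conductivity_cross cross-fiber conductivity, mS/cm.
#' @param bz_conductivity_scale scale in (0, 1] applied to BZ elements.
#' @param surface_to_volume membrane surface-to-volume ratio chi, 1/cm.
#' @param capacitance membrane capacitance, uF/cm^2.
#' @param dt time step, ms.
#' @param duration simulated time, ms; must cover activation and
#'   repolarization for downstream map extraction.
#' @param output_interval sampling interval of the stored voltage, ms
#'   (rounded to a multiple of `dt`).
#' @param stimulus list with either `nodes` (explicit node indices) or
#'   `center` + `radius` (cm ball), and `amplitude` (normalized units/ms),
#'   `start` (ms), `duration` (ms).
#' @param cell a [cell_model()].
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(conductivity_fiber = 5.3,
                              conductivity_cross = 5.3 / 2.25,
                              bz_conductivity_scale = 0.1,
                              surface_to_volume = 1400,
                              capacitance = 1,
                              dt = 0.1, duration = 320, output_interval = 1,
                              stimulus = list(center = NULL, radius = 0.1,
                                              amplitude = 1, start = 1,
                                              duration = 2),
                              cell = cell_model()) {
  stopifnot(conductivity_fiber > 0, conductivity_cross > 0,
            bz_conductivity_scale > 0, bz_conductivity_scale <= 1,
            surface_to_volume > 0, capacitance > 0,
            dt > 0, duration > dt, output_interval >= dt,
            inherits(cell, "cell_model"))
  structure(list(conductivity_fiber = conductivity_fiber,
                 conductivity_cross = conductivity_cross,
                 bz_conductivity_scale = bz_conductivity_scale,
                 surface_to_volume = surface_to_volume,
                 capacitance = capacitance,
                 dt = dt, duration = duration,
                 output_interval = output_interval,
                 stimulus = stimulus, cell = cell),
            class = "simulation_config")
}

# P1 basis gradients per element: returns list(gx, gy, gz) of m x 4 matrices
# with the gradient of basis function j on element e, plus volumes.
p1_gradients <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  x <- matrix(nd[el, 1], ncol = 4)
  y <- matrix(nd[el, 2], ncol = 4)
  z <- matrix(nd[el, 3], ncol = 4)
  vol <- abs(tet_volumes(nd, el))
  gx <- matrix(0, nrow(el), 4); gy <- gx; gz <- gx
  idx <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  # gradient of basis i is (opposite-face normal) / (3 * vol / area) ... use
  # the cross-product form: grad_i = (x_b - x_d) x (x_c - x_d) / (6 V) with
  # (b, c, d) the opposite face ordered so the normal points toward node i.
  for (i in 1:4) {
    b <- idx[i, 1]; c_ <- idx[i, 2]; d <- idx[i, 3]
    ux <- x[, b] - x[, d]; uy <- y[, b] - y[, d]; uz <- z[, b] - z[, d]
    vx <- x[, c_] - x[, d]; vy <- y[, c_] - y[, d]; vz <- z[, c_] - z[, d]
    nx <- uy * vz - uz * vy
    ny <- uz * vx - ux * vz
    nz <- ux * vy - uy * vx
    # orient toward node i
    wx <- x[, i] - x[, d]; wy <- y[, i] - y[, d]; wz <- z[, i] - z[, d]
    s <- sign(nx * wx + ny * wy + nz * wz)
    gx[, i] <- s * nx / (6 * vol)
    gy[, i] <- s * ny / (6 * vol)
    gz[, i] <- s * nz / (6 * vol)
  }
  list(gx = gx, gy = gy, gz = gz, vol = vol)
}

# per-element 3x3 diffusivity tensors (cm^2/ms), rows = elements, columns =
# (xx, xy, xz, yy, yz, zz); scar elements get zero.
element_diffusivity <- function(mesh, config) {
  f <- mesh$fiber
  scale <- rep(1, nrow(f))
  scale[mesh$tissue == TISSUE_BZ] <- config$bz_conductivity_scale
  scale[mesh$tissue == TISSUE_SCAR] <- 0
  chi_cm <- config$surface_to_volume * config$capacitance
  sf <- config$conductivity_fiber / chi_cm
  sc <- config$conductivity_cross / chi_cm
  d <- sf - sc
  cbind(xx = scale * (sc + d * f[, 1]^2),
        xy = scale * d * f[, 1] * f[, 2],
        xz = scale * d * f[, 1] * f[, 3],
        yy = scale * (sc + d * f[, 2]^2),
        yz = scale * d * f[, 2] * f[, 3],
        zz = scale * (sc + d * f[, 3]^2))
}

# assemble the global stiffness matrix K (n x n, dgCMatrix) with per-element
# anisotropic diffusivity, and the lumped mass vector (plain volumes).
assemble_system <- function(mesh, config) {
  g <- p1_gradients(mesh)
  D <- element_diffusivity(mesh, config)
  m <- nrow(mesh$elems); n <- nrow(mesh$nodes)
  ent_i <- vector("list", 16); ent_j <- vector("list", 16)
  ent_x <- vector("list", 16)
  k <- 0
  for (a in 1:4) {
    # D * grad(phi_a)
    dgx <- D[, "xx"] * g$gx[, a] + D[, "xy"] * g$gy[, a] + D[, "xz"] * g$gz[, a]
    dgy <- D[, "xy"] * g$gx[, a] + D[, "yy"] * g$gy[, a] + D[, "yz"] * g$gz[, a]
    dgz <- D[, "xz"] * g$gx[, a] + D[, "yz"] * g$gy[, a] + D[, "zz"] * g$gz[, a]
    for (b in 1:4) {
      k <- k + 1
      ent_i[[k]] <- mesh$elems[, a]
      ent_j[[k]] <- mesh$elems[, b]
      ent_x[[k]] <- g$vol * (dgx * g$gx[, b] + dgy * g$gy[, b] +
                             dgz * g$gz[, b])
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ent_i), j = unlist(ent_j),
                            x = unlist(ent_x), dims = c(n, n))
  mass <- numeric(n)
  vol4 <- g$vol / 4
  for (a in 1:4) {
    acc <- rowsum(vol4, mesh$elems[, a])
    mass[as.integer(rownames(acc))] <- mass[as.integer(rownames(acc))] + acc
  }
  list(K = K, mass = mass, grads = g)
}

# resolve the stimulated node set from a config's stimulus spec
stimulus_nodes <- function(mesh, stim) {
  if (!is.null(stim$nodes)) return(as.integer(stim$nodes))
  if (is.null(stim$center))
    stop("stimulus needs either explicit nodes or a center")
  d2 <- (mesh$nodes[, 1] - stim$center[1])^2 +
        (mesh$nodes[, 2] - stim$center[2])^2 +
        (mesh$nodes[, 3] - stim$center[3])^2
  which(d2 <= stim$radius^2)
}

#' Solve the monodomain equations on a labeled mesh
#'
#' Operator-split time integration of the anisotropic monodomain model with
#' the configured cell model: explicit reaction substep (exact exponential
#' update of the recovery gate), then a backward-Euler diffusion solve using
#' one prefactored sparse Cholesky decomposition. Border-zone elements use
#' scaled conductivity and BZ membrane parameters; scar elements are removed
#' from diffusion and reaction, so scar-interior nodes stay at rest. The
#' computation is deterministic.
#'
#' @param mesh a [labeled_mesh()].
#' @param config a [simulation_config()].
#' @return object of class `voltage_solution`: list with `voltage` (time x
#'   node matrix, mV), `times` (ms), `node_count`, `sampling_interval`, and
#'   `meta` (stimulated nodes, activation flag).
#' @export
run_monodomain <- function(mesh, config) {
  stopifnot(inherits(mesh, "labeled_mesh"),
            inherits(config, "simulation_config"))
  n <- nrow(mesh$nodes)
  sys <- assemble_system(mesh, config)
  dt <- config$dt
  A <- Matrix::Diagonal(x = sys$mass) + dt * sys$K
  Ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"),
                         LDL = FALSE)

  # per-node membrane class: scar-interior nodes (touching only scar
  # elements) are inert; nodes touching any BZ element use BZ parameters.
  touches <- function(label) {
    el <- mesh$elems[mesh$tissue == label, , drop = FALSE]
    tab <- logical(n); tab[unique(as.vector(el))] <- TRUE; tab
  }
  t_h <- touches(TISSUE_HEALTHY); t_b <- touches(TISSUE_BZ)
  t_s <- touches(TISSUE_SCAR)
  inert <- t_s & !t_h & !t_b
  is_bz <- t_b & !inert
  cm <- config$cell
  par_of <- function(field) {
    v <- rep(cm$healthy[[field]], n)
    v[is_bz] <- cm$bz[[field]]
    v
  }
  tau_in <- par_of("tau_in"); tau_out <- par_of("tau_out")
  tau_open <- par_of("tau_open"); tau_close <- par_of("tau_close")
  u_gate <- cm$healthy$u_gate
  react <- !inert

  stim <- config$stimulus
  stim_nodes <- stimulus_nodes(mesh, stim)
  stim_nodes <- stim_nodes[react[stim_nodes]]
  if (!length(stim_nodes))
    stop("stimulus region is empty or entirely non-excitable")

  n_steps <- ceiling(config$duration / dt)
  every <- max(1L, as.integer(round(config$output_interval / dt)))
  out_idx <- seq(0L, n_steps, by = every)
  is_out <- logical(n_steps)
  is_out[out_idx[-1]] <- TRUE
  n_out <- length(out_idx)
  V <- matrix(cm$v_rest, nrow = n_out, ncol = n)
  u <- numeric(n); h <- rep(1, n)
  out_row <- 1L  # t = 0 already stored as rest

  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    du <- numeric(n)
    du[react] <- ms_rate(u[react], h[react], tau_in[react], tau_out[react])
    if (t >= stim$start && t < stim$start + stim$duration)
      du[stim_nodes] <- du[stim_nodes] + stim$amplitude
    h[react] <- ms_gate_update(u[react], h[react], dt, tau_open[react],
                               tau_close[react], u_gate)
    u_star <- u + dt * du
    u <- as.numeric(Matrix::solve(Ch, sys$mass * u_star, system = "A"))
    if (s %% 50L == 0L || s == n_steps) {
      if (anyNA(u) || !all(is.finite(u)) || max(abs(u)) > 5)
        stop(sprintf("numerical instability at step %d (t = %.2f ms)", s, t))
    }
    if (is_out[s]) {
      out_row <- out_row + 1L
      V[out_row, ] <- cm$v_rest + cm$v_amp * u
    }
  }
  activated <- any(V > cm$v_rest + 0.5 * cm$v_amp)
  structure(list(voltage = V, times = out_idx * dt, node_count = n,
                 sampling_interval = every * dt,
                 meta = list(stim_nodes = stim_nodes, activated = activated,
                             inert_nodes = which(inert))),
            class = "voltage_solution")
}

#' @export
print.voltage_solution <- function(x, ...) {
  cat(sprintf(
    "voltage_solution: %d nodes, %d samples at %.3g ms (%.4g to %.4g mV)%s\n",
    x$node_count, length(x$times), x$sampling_interval,
    min(x$voltage), max(x$voltage),
    if (!x$meta$activated) " [domain not activated]" else ""))
  invisible(x)
}

#' Planar conduction velocity on a homogeneous slab
#'
#' Builds an all-healthy slab with fibers along +x, stimulates the x = 0
#' face, and measures the wavefront speed between the activation times of
#' probe planes at fractions `probes[1]` and `probes[2]` of the slab length
#' (default 25% and 75%, excluding stimulus and boundary artifacts).
#'
#' @param config a [simulation_config()]; its stimulus timing/amplitude is
#'   reused, the stimulated nodes are overridden with the x = 0 face.
#' @param slab_extent slab dimensions, cm.
#' @param edge_length target mean edge length, cm.
#' @param probes two fractions of slab length in (0, 1).
#' @param activation_threshold mV.
#' @return conduction velocity in cm/s, with attributes `t_probe` (ms) and
#'   `mesh_nodes`.
#' @export
measure_planar_cv <- function(config, slab_extent = c(1.2, 0.1, 0.1),
                              edge_length = 0.025, probes = c(0.25, 0.75),
                              activation_threshold = -20) {
  sm <- slab_mesh(slab_extent, edge_length)
  m <- nrow(sm$elems)
  mesh <- labeled_mesh(sm$nodes, sm$elems, rep(TISSUE_HEALTHY, m),
                       fiber = matrix(rep(c(1, 0, 0), each = m), ncol = 3),
                       patient_id = "cv_slab", resolution_tag = edge_length,
                       extent = slab_extent)
  hx <- sm$spacing[1]
  cfg <- config
  # stimulate a thin physical band at x = 0 (thick enough to excite even at
  # high diffusivity), then cap the run: the wave only needs to cross once
  cfg$stimulus <- list(nodes = which(sm$nodes[, 1] <= max(1.5 * hx, 0.05)),
                       amplitude = config$stimulus$amplitude,
                       start = config$stimulus$start,
                       duration = config$stimulus$duration)
  cfg$duration <- min(config$duration, 80)
  sol <- run_monodomain(mesh, cfg)
  amap <- activation_map(sol, qoi_config(activation_threshold =
                                           activation_threshold))
  L <- slab_extent[1]
  x <- sm$nodes[, 1]
  win <- x >= probes[1] * L - 1e-9 & x <= probes[2] * L + 1e-9
  tt <- amap[win]
  if (all(is.na(tt)))
    stop(sprintf(
      "wavefront failed to reach the probe window [%.0f%%, %.0f%%] of slab length",
      100 * probes[1], 100 * probes[2]))
  if (anyNA(tt))
    stop("wavefront did not traverse the full probe window")
  # planar wave: activation is linear in x; CV is the inverse slope of the
  # least-squares fit over the probe window (robust to per-plane jitter)
  slope <- stats::cov(x[win], tt) / stats::var(x[win])
  if (slope <= 0) stop("non-increasing activation across the probe window")
  cv <- 1 / slope * 1000  # cm/ms -> cm/s
  attr(cv, "t_probe") <- range(tt)
  attr(cv, "mesh_nodes") <- nrow(sm$nodes)
  cv
}

#' Tune fiber conductivity to a target conduction velocity
#'
#' Finds `conductivity_fiber` such that [measure_planar_cv()] matches
#' `target_cv` within `tol` (relative), exploiting the square-root
#' CV-conductivity law of the monodomain model as the update rule
#' (`sigma <- sigma * (target/measured)^2`), and rescaling
#' `conductivity_cross` to preserve the configured anisotropy ratio exactly.
#'
#' @param target_cv cm/s.
#' @param config a [simulation_config()] supplying the starting conductivity
#'   and all other parameters.
#' @param tol relative tolerance on the re-measured CV (default 0.02).
#' @param max_iter iteration cap.
#' @param ... passed to [measure_planar_cv()] (slab geometry, edge length).
#' @return a `simulation_config` with tuned conductivities; attributes
#'   `measured_cv` (cm/s) and `iterations`.
#' @export
tune_conductivity_to_cv <- function(target_cv, config, tol = 0.02,
                                    max_iter = 8, ...) {
  stopifnot(target_cv > 0)
  ratio <- config$conductivity_fiber / config$conductivity_cross
  cfg <- config
  for (it in seq_len(max_iter)) {
    cv <- as.numeric(measure_planar_cv(cfg, ...))
    if (abs(cv - target_cv) / target_cv <= tol) {
      attr(cfg, "measured_cv") <- cv
      attr(cfg, "iterations") <- it
      return(cfg)
    }
    sf <- cfg$conductivity_fiber * (target_cv / cv)^2
    if (!is.finite(sf) || sf <= 0)
      stop(sprintf("conductivity update failed (last sigma_f = %.4g, measured CV = %.4g)",
                   cfg$conductivity_fiber, cv))
    cfg$conductivity_fiber <- sf
    cfg$conductivity_cross <- sf / ratio
  }
  stop(sprintf(
    "CV tuning did not converge in %d iterations (target %.3g, last measured %.3g cm/s)",
    max_iter, target_cv, cv))
}
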