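# Shared fixtures: small labeled meshes with analytically known geometry,
# fast simulation configs, and memoised expensive objects.

# all-healthy slab with fibers along +x
healthy_slab <- function(extent = c(0.8, 0.1, 0.1), h = 0.025,
                         fiber = c(1, 0, 0)) {
  sm <- slab_mesh(extent, h)
  m <- nrow(sm$elems)
  labeled_mesh(sm$nodes, sm$elems, rep(TISSUE_HEALTHY, m),
               fiber = matrix(rep(fiber, each = m), ncol = 3),
               patient_id = "slab", resolution_tag = h, extent = extent)
}

# slab with an axis-aligned scar block (x < x_scar) and optional BZ layer
# (x_scar <= x < x_bz); the requested planes are snapped to the nearest grid
# plane (attributes "x_scar"/"x_bz" record the snapped values) so each label
# boundary is an exact coordinate plane of the mesh.
layered_slab <- function(extent = c(1, 0.2, 0.2), h = 0.02,
                         x_scar = 0.3, x_bz = NA) {
  sm <- slab_mesh(extent, h)
  gx <- sort(unique(sm$nodes[, 1]))
  snap <- function(x) gx[which.min(abs(gx - x))]
  x_scar <- snap(x_scar)
  if (!is.na(x_bz)) x_bz <- snap(x_bz)
  cen <- (sm$nodes[sm$elems[, 1], ] + sm$nodes[sm$elems[, 2], ] +
          sm$nodes[sm$elems[, 3], ] + sm$nodes[sm$elems[, 4], ]) / 4
  tissue <- rep(TISSUE_HEALTHY, nrow(sm$elems))
  if (!is.na(x_bz)) tissue[cen[, 1] < x_bz] <- TISSUE_BZ
  tissue[cen[, 1] < x_scar] <- TISSUE_SCAR
  m <- nrow(sm$elems)
  mesh <- labeled_mesh(sm$nodes, sm$elems, tissue,
                       fiber = matrix(rep(c(1, 0, 0), each = m), ncol = 3),
                       patient_id = "layered", resolution_tag = h,
                       extent = extent)
  attr(mesh, "x_scar") <- x_scar
  attr(mesh, "x_bz") <- x_bz
  mesh
}

# short, fast simulation config for wave tests on small slabs
fast_config <- function(...) {
  defaults <- list(dt = 0.05, duration = 40, output_interval = 0.5,
                   stimulus = list(center = NULL, radius = 0.06,
                                   amplitude = 1, start = 1, duration = 1.5))
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# simulate a planar wave on a healthy slab; memoised across tests
planar_wave_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    mesh <- healthy_slab()
    cfg <- fast_config()
    cfg$stimulus <- list(nodes = which(mesh$nodes[, 1] < 0.01),
                         amplitude = 1, start = 1, duration = 1.5)
    sol <- run_monodomain(mesh, cfg)
    cache <<- list(mesh = mesh, cfg = cfg, sol = sol,
                   amap = activation_map(sol))
    cache
  }
})

# independent Student-t upper-tail probability via the incomplete-beta
# representation (textbook route, distinct from stats::pt's use inside the
# package functions being tested)
t_upper_tail_beta <- function(t, df) {
  x <- df / (df + t^2)
  half <- stats::pbeta(x, df / 2, 0.5) / 2
  if (t >= 0) half else 1 - half
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", actual, expected, tol))
}
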