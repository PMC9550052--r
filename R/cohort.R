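# Synthetic patient cohort: labeled slab geometries with an embedded scar
# core, a border-zone shell, transmurally rotating fibers, and nested mesh
# resolutions. Stands in for an image-derived ventricular cohort so that
# every label has a closed-form ground truth.

#' Patient geometry specification
#'
#' Analytic description of one synthetic patient: a myocardial slab of given
#' extent containing a spherical scar core of radius `scar_radius` at
#' `scar_center`, surrounded by a border-zone (BZ) shell of width
#' `bz_thickness`. Fibers rotate linearly with transmural (z) depth from
#' `fiber_rotation[1]` at the endocardial face to `fiber_rotation[2]` at the
#' epicardial face.
#'
#' @param patient_id identifier string.
#' @param domain_extent slab dimensions `c(Lx, Ly, Lz)` in cm; `Lz` is the
#'   wall thickness.
#' @param scar_center 3-vector, cm.
#' @param scar_radius scar core radius, cm (> 0).
#' @param bz_thickness BZ shell width, cm (>= 0).
#' @param fiber_rotation `c(endo_deg, epi_deg)` fiber helix angles.
#' @param seed integer seed recorded with the spec (geometry itself is
#'   deterministic; the seed documents provenance of drawn parameters).
#' @return object of class `patient_spec`.
#' @export
patient_spec <- function(patient_id, domain_extent, scar_center, scar_radius,
                         bz_thickness, fiber_rotation = c(-60, 60),
                         seed = 0L) {
  stopifnot(length(domain_extent) == 3, all(domain_extent > 0),
            length(scar_center) == 3, scar_radius > 0, bz_thickness >= 0,
            length(fiber_rotation) == 2)
  r_out <- scar_radius + bz_thickness
  lo <- scar_center - r_out
  hi <- scar_center + r_out
  # scar + BZ must fit inside the slab footprint in x and y; transmural
  # clipping in z is allowed (transmural scar), full protrusion is not.
  if (lo[1] < 0 || lo[2] < 0 || hi[1] > domain_extent[1] ||
      hi[2] > domain_extent[2])
    stop(sprintf(
      "infeasible geometry: scar + BZ (outer radius %.3f cm) extends beyond ",
      r_out), "the slab footprint in x/y")
  if (scar_center[3] < 0 || scar_center[3] > domain_extent[3])
    stop("infeasible geometry: scar center outside the wall")
  structure(list(patient_id = as.character(patient_id),
                 domain_extent = as.numeric(domain_extent),
                 wall_thickness = as.numeric(domain_extent[3]),
                 scar_center = as.numeric(scar_center),
                 scar_radius = as.numeric(scar_radius),
                 bz_thickness = as.numeric(bz_thickness),
                 fiber_rotation = as.numeric(fiber_rotation),
                 seed = as.integer(seed)),
            class = "patient_spec")
}

#' Generate one labeled patient mesh
#'
#' Meshes the patient slab at the requested resolution and labels elements by
#' centroid against the analytic geometry: inside the scar ball -> scar;
#' inside the surrounding shell of width `bz_thickness` -> border zone;
#' otherwise healthy. Fibers are assigned by the transmural rotation rule.
#' Fully deterministic given `(spec, target_edge_length)`.
#'
#' @param spec a [patient_spec()].
#' @param target_edge_length target mean tet edge length, cm; must resolve
#'   the wall with at least 2 elements.
#' @return a [labeled_mesh()].
#' @export
generate_patient <- function(spec, target_edge_length) {
  stopifnot(inherits(spec, "patient_spec"), target_edge_length > 0)
  h <- target_edge_length / KUHN_MEAN_EDGE_FACTOR
  if (round(spec$domain_extent[3] / h) < 2)
    stop("target_edge_length too coarse: fewer than 2 elements span the wall")
  sm <- slab_mesh(spec$domain_extent, target_edge_length)
  cen <- (sm$nodes[sm$elems[, 1], ] + sm$nodes[sm$elems[, 2], ] +
          sm$nodes[sm$elems[, 3], ] + sm$nodes[sm$elems[, 4], ]) / 4
  r <- sqrt((cen[, 1] - spec$scar_center[1])^2 +
            (cen[, 2] - spec$scar_center[2])^2 +
            (cen[, 3] - spec$scar_center[3])^2)
  tissue <- rep(TISSUE_HEALTHY, nrow(sm$elems))
  tissue[r < spec$scar_radius + spec$bz_thickness] <- TISSUE_BZ
  tissue[r < spec$scar_radius] <- TISSUE_SCAR
  mesh <- labeled_mesh(sm$nodes, sm$elems, tissue,
                       fiber = matrix(rep(c(1, 0, 0), each = nrow(sm$elems)),
                                      ncol = 3),
                       patient_id = spec$patient_id,
                       resolution_tag = target_edge_length,
                       extent = spec$domain_extent)
  assign_fibers(mesh, spec$fiber_rotation)
}

#' Rule-based transmural fiber assignment
#'
#' Sets every element's fiber to an in-plane (xy) unit vector whose angle
#' from the +x axis rotates linearly with normalized transmural depth
#' (z / wall thickness): `rotation[1]` degrees at z = 0 (endocardium) to
#' `rotation[2]` degrees at z = Lz (epicardium).
#'
#' @param mesh a [labeled_mesh()] with a slab `extent`.
#' @param rotation `c(endo_deg, epi_deg)`.
#' @return the mesh with its `fiber` slot replaced.
#' @export
assign_fibers <- function(mesh, rotation = c(-60, 60)) {
  stopifnot(inherits(mesh, "labeled_mesh"), length(rotation) == 2)
  if (is.null(mesh$extent) || mesh$extent[3] <= 0)
    stop("mesh has no transmural coordinate (zero or unknown wall thickness)")
  depth <- element_centroids(mesh)[, 3] / mesh$extent[3]
  ang <- (rotation[1] + depth * (rotation[2] - rotation[1])) * pi / 180
  mesh$fiber <- cbind(cos(ang), sin(ang), 0)
  mesh
}

#' Nested mesh-resolution family for one patient
#'
#' Generates the same analytic patient geometry at a decreasing sequence of
#' target edge lengths (coarsest first), for mesh-convergence studies.
#'
#' @param spec a [patient_spec()].
#' @param edge_lengths strictly decreasing vector of target mean edge
#'   lengths, cm; at least 2 entries.
#' @return object of class `mesh_family`: list of [labeled_mesh()] ordered
#'   coarse -> fine, with attribute `edge_lengths`.
#' @export
generate_mesh_family <- function(spec, edge_lengths) {
  stopifnot(inherits(spec, "patient_spec"))
  if (length(edge_lengths) < 2)
    stop("a convergence family needs at least 2 edge lengths")
  if (any(diff(edge_lengths) >= 0))
    stop("edge_lengths must be strictly decreasing (coarsest first)")
  fam <- lapply(edge_lengths, function(h) generate_patient(spec, h))
  structure(fam, class = "mesh_family", edge_lengths = edge_lengths,
            patient_id = spec$patient_id)
}

#' Pacing-site selection at prescribed distances from scar
#'
#' For each requested distance `d`, returns a node of the healthy region
#' whose Euclidean distance to the scar boundary surface is within tolerance
#' of `d` (default tolerance: the larger of 10% of `d` and one mean edge
#' length). Among admissible candidates the lowest node index is returned,
#' making the choice deterministic.
#'
#' @param mesh a [labeled_mesh()] with scar elements.
#' @param distances numeric vector of target distances, cm (>= 0).
#' @param tol optional explicit tolerance (cm), recycled over distances.
#' @return integer vector of node indices, one per distance.
#' @export
select_pacing_sites <- function(mesh, distances, tol = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  if (!any(mesh$tissue == TISSUE_SCAR))
    stop("mesh contains no scar elements")
  helems <- mesh$elems[mesh$tissue == TISSUE_HEALTHY, , drop = FALSE]
  hnodes <- sort(unique(as.vector(helems)))
  d_scar <- dist_to_scar(mesh, mesh$nodes[hnodes, , drop = FALSE])
  edge <- mean_edge_length(mesh)
  vapply(seq_along(distances), function(i) {
    d <- distances[i]
    tol_i <- if (is.null(tol)) max(0.1 * d, edge) else
      rep_len(tol, length(distances))[i]
    miss <- abs(d_scar - d)
    if (min(miss) > tol_i)
      stop(sprintf(
        "no healthy node within %.4f cm of distance %.3f cm from scar (achievable range: %.3f to %.3f cm)",
        tol_i, d, min(d_scar), max(d_scar)))
    # best-matching node; ties resolved toward the lowest node index
    hnodes[which(miss == min(miss))[1]]
  }, integer(1))
}

#' Border-zone thickness statistics
#'
#' For each BZ element centroid the thickness proxy is the distance to the
#' nearest point of the BZ-healthy interface plus the distance to the nearest
#' point of the scar boundary. Returns its mean and max over BZ elements,
#' comparable to cohort BZ-width statistics reported for image-derived
#' meshes.
#'
#' @param mesh a [labeled_mesh()].
#' @return list with `mean`, `max` (cm) and `n_bz`; `(0, 0)` with a warning
#'   when the mesh has no BZ.
#' @export
bz_thickness_stats <- function(mesh) {
  bz <- mesh$tissue == TISSUE_BZ
  if (!any(bz)) {
    warning("mesh has no BZ elements; returning zero thickness")
    return(list(mean = 0, max = 0, n_bz = 0L))
  }
  cen <- element_centroids(mesh)[bz, , drop = FALSE]
  tri_h <- interface_faces(mesh, bz, mesh$tissue == TISSUE_HEALTHY)
  tri_s <- region_boundary_faces(mesh, mesh$tissue == TISSUE_SCAR)
  d_h <- dist_to_surface(cen, mesh$nodes, tri_h)
  d_s <- dist_to_surface(cen, mesh$nodes, tri_s)
  thick <- d_h + d_s
  list(mean = mean(thick), max = max(thick), n_bz = sum(bz))
}

#' Draw a synthetic cohort of patient specifications
#'
#' Samples per-patient geometry parameters from uniform ranges using one
#' master seed (which spawns a per-patient seed), emulating the variability
#' of an image-derived cohort: scar core radii around 3 mm and BZ shells
#' averaging about 1.2 mm, embedded in a 3.2 x 1.2 x 0.3 cm wall segment.
#'
#' @param n_patients number of patients.
#' @param seed master seed (integer).
#' @param domain_extent slab dimensions shared by the cohort, cm.
#' @param scar_radius_range,bz_thickness_range uniform sampling ranges, cm.
#' @param scar_x_range,scar_y_range uniform ranges for the scar center, cm.
#' @param fiber_rotation endo/epi fiber angles, degrees.
#' @return list of [patient_spec()] of length `n_patients`.
#' @export
draw_cohort_specs <- function(n_patients, seed,
                              domain_extent = c(3.2, 1.6, 0.3),
                              scar_radius_range = c(0.30, 0.38),
                              bz_thickness_range = c(0.10, 0.16),
                              scar_x_range = c(0.8, 1.0),
                              scar_y_range = c(0.75, 0.85),
                              fiber_rotation = c(-60, 60)) {
  stopifnot(n_patients >= 1)
  seeds <- local_seed(seed, sample.int(2^31 - 1, n_patients))
  lapply(seq_len(n_patients), function(i) {
    par <- local_seed(seeds[i], list(
      r = stats::runif(1, scar_radius_range[1], scar_radius_range[2]),
      bz = stats::runif(1, bz_thickness_range[1], bz_thickness_range[2]),
      cx = stats::runif(1, scar_x_range[1], scar_x_range[2]),
      cy = stats::runif(1, scar_y_range[1], scar_y_range[2])))
    patient_spec(patient_id = sprintf("P%02d", i),
                 domain_extent = domain_extent,
                 scar_center = c(par$cx, par$cy, domain_extent[3] / 2),
                 scar_radius = par$r, bz_thickness = par$bz,
                 fiber_rotation = fiber_rotation, seed = seeds[i])
  })
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# any pre-existing state afterwards
local_seed <- function(seed, expr) {
  expr <- substitute(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval(expr, envir = parent.frame())
}
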