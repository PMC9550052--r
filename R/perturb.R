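# Input-uncertainty perturbations: morphological contraction/expansion of
# the border zone (personalized input) and conductivity variants at scaled
# conduction velocities (non-personalized input). All operators are pure:
# label reassignment only, no remeshing; the input mesh is never modified.

#' Contract the border zone
#'
#' Every BZ element whose centroid lies within `dist` of the BZ-healthy
#' interface surface is relabeled healthy, emulating an over-estimated BZ
#' segmentation. Scar is never altered. With no BZ (or no BZ-healthy
#' interface) the mesh is returned unchanged.
#'
#' @param mesh a [labeled_mesh()].
#' @param dist contraction distance, cm (>= 0); default 0.05 cm mirrors a
#'   0.5 mm segmentation-error bound.
#' @return a new [labeled_mesh()] with updated labels.
#' @export
contract_bz <- function(mesh, dist = 0.05) {
  stopifnot(inherits(mesh, "labeled_mesh"), dist >= 0)
  bz <- mesh$tissue == TISSUE_BZ
  if (!any(bz) || dist == 0) return(mesh)
  tri <- interface_faces(mesh, bz, mesh$tissue == TISSUE_HEALTHY)
  if (nrow(tri) == 0) return(mesh)
  cen <- element_centroids(mesh)[bz, , drop = FALSE]
  d <- dist_to_surface(cen, mesh$nodes, tri)
  relabel <- which(bz)[d <= dist]
  mesh$tissue[relabel] <- TISSUE_HEALTHY
  mesh
}

#' Expand the border zone
#'
#' Every healthy element whose centroid lies within `dist` of the boundary
#' surface of the combined BZ-plus-scar region is relabeled BZ, emulating an
#' under-estimated BZ segmentation. Scar is never altered.
#'
#' @param mesh a [labeled_mesh()].
#' @param dist expansion distance, cm (>= 0); default 0.1 cm mirrors a 1 mm
#'   segmentation-error bound.
#' @return a new [labeled_mesh()] with updated labels.
#' @export
expand_bz <- function(mesh, dist = 0.1) {
  stopifnot(inherits(mesh, "labeled_mesh"), dist >= 0)
  if (dist == 0) return(mesh)
  core <- mesh$tissue != TISSUE_HEALTHY
  if (!any(core)) return(mesh)
  tri <- region_boundary_faces(mesh, core)
  healthy <- mesh$tissue == TISSUE_HEALTHY
  cen <- element_centroids(mesh)[healthy, , drop = FALSE]
  d <- dist_to_surface(cen, mesh$nodes, tri)
  relabel <- which(healthy)[d <= dist]
  mesh$tissue[relabel] <- TISSUE_BZ
  mesh
}

#' Border-zone variant set for one patient
#'
#' @param mesh the original [labeled_mesh()].
#' @param contract_dist,expand_dist cm.
#' @return named list `contracted`, `original`, `expanded` of labeled
#'   meshes; the scar element set is identical across the three.
#' @export
bz_variants <- function(mesh, contract_dist = 0.05, expand_dist = 0.1) {
  list(contracted = contract_bz(mesh, contract_dist),
       original = mesh,
       expanded = expand_bz(mesh, expand_dist))
}

#' Conductivity variants at scaled conduction velocities
#'
#' Produces `low`, `baseline` and `high` simulation configurations whose
#' planar conduction velocities are `cv_factors[1]`, 1 and `cv_factors[2]`
#' times the baseline CV, by retuning the fiber conductivity with
#' [tune_conductivity_to_cv()] while preserving the fiber:cross anisotropy
#' ratio exactly. The baseline CV is measured from `config` itself (or
#' passed via `baseline_cv` to skip the measurement).
#'
#' @param config the baseline [simulation_config()].
#' @param cv_factors length-2 numeric, default `c(0.8, 1.2)`.
#' @param baseline_cv optional pre-measured baseline CV, cm/s.
#' @param tol relative CV tolerance for the tuner.
#' @param ... passed to [measure_planar_cv()] / [tune_conductivity_to_cv()]
#'   (calibration slab geometry and edge length).
#' @return named list `low`, `baseline`, `high` of `simulation_config`;
#'   attribute `cv` records the three target CVs (cm/s).
#' @export
conductivity_variants <- function(config, cv_factors = c(0.8, 1.2),
                                  baseline_cv = NULL, tol = 0.02, ...) {
  stopifnot(length(cv_factors) == 2, all(cv_factors > 0))
  if (is.null(baseline_cv))
    baseline_cv <- as.numeric(measure_planar_cv(config, ...))
  low <- tune_conductivity_to_cv(cv_factors[1] * baseline_cv, config,
                                 tol = tol, ...)
  high <- tune_conductivity_to_cv(cv_factors[2] * baseline_cv, config,
                                  tol = tol, ...)
  out <- list(low = low, baseline = config, high = high)
  attr(out, "cv") <- c(low = cv_factors[1] * baseline_cv,
                       baseline = baseline_cv,
                       high = cv_factors[2] * baseline_cv)
  out
}
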