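# Tetrahedral slab meshes and geometric queries.
#
# All lengths are in cm throughout the package (time ms, voltage mV,
# conductivity mS/cm).

# Tissue label codes used in the `tissue` slot of a labeled_mesh.
#' Tissue class codes
#'
#' Integer codes used for the per-element tissue classification of a
#' [labeled_mesh()]: `TISSUE_HEALTHY` (0), `TISSUE_BZ` (1, border zone) and
#' `TISSUE_SCAR` (2, non-excitable scar). The same codes are written to the
#' `tissue_class` cell-data array of exported `.vtu` files.
#'
#' @name tissue-codes
#' @export
TISSUE_HEALTHY <- 0L

#' @rdname tissue-codes
#' @export
TISSUE_BZ <- 1L

#' @rdname tissue-codes
#' @export
TISSUE_SCAR <- 2L

# Mean edge length of the Kuhn 6-tet decomposition of a cubic grid, in units
# of the grid spacing: per cube the unique edges are 3 axis edges, 3 face
# diagonals and 1 body diagonal.
KUHN_MEAN_EDGE_FACTOR <- (3 + 3 * sqrt(2) + sqrt(3)) / 7

#' Labeled tetrahedral mesh
#'
#' Container for a tetrahedral mesh with per-element tissue classification
#' and fiber direction; the package's representation of a personalized
#' ventricular anatomy.
#'
#' @param nodes numeric matrix, n x 3, node coordinates in cm.
#' @param elems integer matrix, m x 4, tetrahedra as 1-based node indices,
#'   positively oriented.
#' @param tissue integer vector of length m with values in
#'   `c(TISSUE_HEALTHY, TISSUE_BZ, TISSUE_SCAR)`.
#' @param fiber numeric matrix, m x 3, per-element unit fiber vectors.
#' @param patient_id short identifier string.
#' @param resolution_tag resolution label or nominal edge length (cm).
#' @param extent slab dimensions `c(Lx, Ly, Lz)` in cm (used for transmural
#'   coordinates and probe placement); may be `NULL` for foreign meshes.
#'
#' @return An object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(nodes, elems, tissue, fiber,
                         patient_id = "patient", resolution_tag = NA,
                         extent = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(elems) == 4)
  m <- nrow(elems)
  tissue <- as.integer(tissue)
  if (length(tissue) != m)
    stop("tissue must have one label per element")
  if (!all(tissue %in% c(TISSUE_HEALTHY, TISSUE_BZ, TISSUE_SCAR)))
    stop("tissue labels must be in {0 (healthy), 1 (BZ), 2 (scar)}")
  fiber <- as.matrix(fiber)
  if (nrow(fiber) != m || ncol(fiber) != 3)
    stop("fiber must be an m x 3 matrix")
  if (min(elems) < 1 || max(elems) > nrow(nodes))
    stop("element node indices out of range")
  mesh <- structure(
    list(nodes = nodes, elems = elems, tissue = tissue, fiber = fiber,
         patient_id = as.character(patient_id),
         resolution_tag = resolution_tag, extent = extent),
    class = "labeled_mesh")
  vols <- element_volumes(mesh)
  if (any(vols <= 0))
    stop("all element volumes must be positive")
  nrm <- sqrt(rowSums(fiber^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("fiber vectors must have unit norm (tol 1e-8)")
  mesh
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cnt <- tabulate(x$tissue + 1L, nbins = 3L)
  cat(sprintf(
    "labeled_mesh '%s' [%s]: %d nodes, %d tets (healthy %d, BZ %d, scar %d)\n",
    x$patient_id, as.character(x$resolution_tag),
    nrow(x$nodes), nrow(x$elems), cnt[1], cnt[2], cnt[3]))
  invisible(x)
}

#' Structured tetrahedral slab mesh
#'
#' Meshes the block `[0,Lx] x [0,Ly] x [0,Lz]` with a regular hexahedral grid
#' and splits every hex into 6 tetrahedra along the main diagonal (Kuhn
#' decomposition), which is conforming without parity flips. The grid spacing
#' is chosen so the *mean* edge length of the tetrahedralization matches
#' `target_edge_length`.
#'
#' @param extent `c(Lx, Ly, Lz)` in cm.
#' @param target_edge_length desired mean tet edge length, cm.
#' @return list with `nodes` (n x 3), `elems` (m x 4, positively oriented)
#'   and `spacing` (the hex grid spacing used).
#' @export
slab_mesh <- function(extent, target_edge_length) {
  stopifnot(length(extent) == 3, all(extent > 0), target_edge_length > 0)
  h <- target_edge_length / KUHN_MEAN_EDGE_FACTOR
  ndiv <- pmax(1L, as.integer(round(extent / h)))
  nx <- ndiv[1]; ny <- ndiv[2]; nz <- ndiv[3]
  gx <- seq(0, extent[1], length.out = nx + 1)
  gy <- seq(0, extent[2], length.out = ny + 1)
  gz <- seq(0, extent[3], length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz,
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL

  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  cubes <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L),
                       KEEP.OUT.ATTRS = FALSE)
  i <- cubes$i; j <- cubes$j; k <- cubes$k
  # Kuhn: for each permutation of the axes, the path corner -> corner+e1 ->
  # corner+e1+e2 -> opposite corner is one tetrahedron.
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  v7 <- nid(i + 1L, j + 1L, k + 1L)
  v0 <- nid(i, j, k)
  step <- function(i, j, k, axis) {
    if (axis == 1) list(i + 1L, j, k)
    else if (axis == 2) list(i, j + 1L, k)
    else list(i, j, k + 1L)
  }
  elems <- vector("list", 6L)
  for (p in seq_along(perms)) {
    ax <- perms[[p]]
    s1 <- step(i, j, k, ax[1])
    s2 <- step(s1[[1]], s1[[2]], s1[[3]], ax[2])
    elems[[p]] <- cbind(v0,
                        nid(s1[[1]], s1[[2]], s1[[3]]),
                        nid(s2[[1]], s2[[2]], s2[[3]]),
                        v7)
  }
  elems <- do.call(rbind, elems)
  dimnames(elems) <- NULL
  storage.mode(elems) <- "integer"

  # enforce positive orientation
  vols <- tet_volumes(nodes, elems)
  neg <- vols < 0
  if (any(neg)) elems[neg, c(3, 4)] <- elems[neg, c(4, 3)]
  list(nodes = nodes, elems = elems, spacing = extent / ndiv)
}

# signed tet volumes for raw node/element arrays
tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  c_ <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Element volumes of a labeled mesh
#' @param mesh a [labeled_mesh()].
#' @return numeric vector of tetrahedron volumes (cm^3).
#' @export
element_volumes <- function(mesh) {
  abs(tet_volumes(mesh$nodes, mesh$elems))
}

#' Element centroids of a labeled mesh
#' @param mesh a [labeled_mesh()].
#' @return m x 3 matrix of centroid coordinates (cm).
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 2], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 3], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 4], , drop = FALSE]) / 4
}

#' Mean edge length of a tetrahedral mesh
#' @param mesh a [labeled_mesh()] or a list with `nodes` and `elems`.
#' @return mean length (cm) over the unique edges.
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh$elems
  pairs <- rbind(e[, c(1, 2)], e[, c(1, 3)], e[, c(1, 4)],
                 e[, c(2, 3)], e[, c(2, 4)], e[, c(3, 4)])
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2])
  key <- lo + (hi - 1) * nrow(mesh$nodes)
  keep <- !duplicated(key)
  d <- mesh$nodes[hi[keep], , drop = FALSE] - mesh$nodes[lo[keep], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# All element faces as a 3-column matrix of node indices plus the owning
# element index. Faces are keyed by their sorted node triple.
element_faces <- function(mesh) {
  e <- mesh$elems
  m <- nrow(e)
  faces <- rbind(e[, c(2, 3, 4)], e[, c(1, 3, 4)],
                 e[, c(1, 2, 4)], e[, c(1, 2, 3)])
  owner <- rep.int(seq_len(m), 4L)
  srt <- t(apply(faces, 1, sort.int))
  n1 <- nrow(mesh$nodes) + 1
  key <- srt[, 1] + n1 * (srt[, 2] + n1 * srt[, 3])
  list(faces = faces, owner = owner, key = key)
}

#' Interface surface between two tissue regions
#'
#' Extracts the triangles shared by an element of `region_a` and an element
#' of `region_b` (both given as element index vectors or logical masks).
#'
#' @param mesh a [labeled_mesh()].
#' @param region_a,region_b element selections (logical mask over elements or
#'   integer element indices).
#' @return integer matrix, one row per interface triangle (node indices);
#'   zero rows when the regions do not touch.
#' @export
interface_faces <- function(mesh, region_a, region_b) {
  in_a <- as_elem_mask(mesh, region_a)
  in_b <- as_elem_mask(mesh, region_b)
  ef <- element_faces(mesh)
  ord <- order(ef$key)
  key <- ef$key[ord]; owner <- ef$owner[ord]
  dup <- which(key[-1] == key[-length(key)])
  o1 <- owner[dup]; o2 <- owner[dup + 1L]
  hit <- (in_a[o1] & in_b[o2]) | (in_a[o2] & in_b[o1])
  ef$faces[ord[dup][hit], , drop = FALSE]
}

#' Boundary surface of a tissue region
#'
#' Triangles of `region` elements that are not shared with another element of
#' the same region: the interface with other tissue plus any part of the
#' domain boundary the region touches.
#'
#' @inheritParams interface_faces
#' @param region element selection (logical mask or indices).
#' @return integer matrix of boundary triangles (node indices).
#' @export
region_boundary_faces <- function(mesh, region) {
  in_r <- as_elem_mask(mesh, region)
  ef <- element_faces(mesh)
  sel <- in_r[ef$owner]
  key <- ef$key[sel]
  faces <- ef$faces[sel, , drop = FALSE]
  # faces appearing once within the region are boundary faces
  keep <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  faces[keep, , drop = FALSE]
}

as_elem_mask <- function(mesh, region) {
  m <- nrow(mesh$elems)
  if (is.logical(region)) {
    stopifnot(length(region) == m)
    region
  } else {
    mask <- logical(m)
    mask[as.integer(region)] <- TRUE
    mask
  }
}

#' Distance from points to a triangulated surface
#'
#' Exact Euclidean distance from each query point to the nearest point of any
#' triangle in the surface (Ericson's closest-point-on-triangle algorithm,
#' vectorized over points).
#'
#' @param points q x 3 matrix of query points (cm).
#' @param nodes node coordinate matrix the triangles index into.
#' @param tris t x 3 integer matrix of triangle node indices.
#' @return numeric vector of q distances (cm).
#' @export
dist_to_surface <- function(points, nodes, tris) {
  points <- rbind(points)  # accept a single point as a vector
  if (nrow(tris) == 0) return(rep(Inf, nrow(points)))
  px <- points[, 1]; py <- points[, 2]; pz <- points[, 3]
  best <- rep(Inf, nrow(points))
  for (t in seq_len(nrow(tris))) {
    a <- nodes[tris[t, 1], ]; b <- nodes[tris[t, 2], ]; c_ <- nodes[tris[t, 3], ]
    # cheap lower bound: distance to vertex a minus triangle diameter
    diam <- sqrt(max(sum((b - a)^2), sum((c_ - a)^2), sum((c_ - b)^2)))
    dax <- px - a[1]; day <- py - a[2]; daz <- pz - a[3]
    da2 <- dax^2 + day^2 + daz^2
    cand <- sqrt(da2) - diam < best
    if (!any(cand)) next
    d2 <- point_triangle_dist2(px[cand], py[cand], pz[cand], a, b, c_)
    best[cand] <- pmin(best[cand], sqrt(d2))
  }
  best
}

# squared distance from points (vectors px,py,pz) to triangle (a,b,c)
point_triangle_dist2 <- function(px, py, pz, a, b, c_) {
  ab <- b - a; ac <- c_ - a; bc <- c_ - b
  apx <- px - a[1]; apy <- py - a[2]; apz <- pz - a[3]
  d1 <- ab[1] * apx + ab[2] * apy + ab[3] * apz
  d2 <- ac[1] * apx + ac[2] * apy + ac[3] * apz
  bpx <- px - b[1]; bpy <- py - b[2]; bpz <- pz - b[3]
  d3 <- ab[1] * bpx + ab[2] * bpy + ab[3] * bpz
  d4 <- ac[1] * bpx + ac[2] * bpy + ac[3] * bpz
  cpx <- px - c_[1]; cpy <- py - c_[2]; cpz <- pz - c_[3]
  d5 <- ab[1] * cpx + ab[2] * cpy + ab[3] * cpz
  d6 <- ac[1] * cpx + ac[2] * cpy + ac[3] * cpz
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d4 * d5

  n <- length(px)
  qx <- numeric(n); qy <- numeric(n); qz <- numeric(n)
  done <- logical(n)

  put <- function(idx, x, y, z) {
    qx[idx] <<- x; qy[idx] <<- y; qz[idx] <<- z; done[idx] <<- TRUE
  }
  # vertex regions
  r <- !done & d1 <= 0 & d2 <= 0
  if (any(r)) put(r, a[1], a[2], a[3])
  r <- !done & d3 >= 0 & d4 <= d3
  if (any(r)) put(r, b[1], b[2], b[3])
  r <- !done & d6 >= 0 & d5 <= d6
  if (any(r)) put(r, c_[1], c_[2], c_[3])
  # edge AB
  r <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(r)) {
    v <- d1[r] / (d1[r] - d3[r])
    put(r, a[1] + v * ab[1], a[2] + v * ab[2], a[3] + v * ab[3])
  }
  # edge AC
  r <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(r)) {
    w <- d2[r] / (d2[r] - d6[r])
    put(r, a[1] + w * ac[1], a[2] + w * ac[2], a[3] + w * ac[3])
  }
  # edge BC
  r <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(r)) {
    w <- (d4[r] - d3[r]) / ((d4[r] - d3[r]) + (d5[r] - d6[r]))
    put(r, b[1] + w * bc[1], b[2] + w * bc[2], b[3] + w * bc[3])
  }
  # interior
  r <- !done
  if (any(r)) {
    denom <- 1 / (va[r] + vb[r] + vc[r])
    v <- vb[r] * denom; w <- vc[r] * denom
    put(r, a[1] + v * ab[1] + w * ac[1],
           a[2] + v * ab[2] + w * ac[2],
           a[3] + v * ab[3] + w * ac[3])
  }
  (px - qx)^2 + (py - qy)^2 + (pz - qz)^2
}

#' Distance from points to the scar boundary surface
#'
#' Convenience wrapper: Euclidean distance to the triangulated boundary of
#' the scar region (interface with other tissue plus scar faces on the domain
#' boundary). Used for pacing-site selection and the "within 1 cm of scar"
#' proximity region of the HRGV.
#'
#' @param mesh a [labeled_mesh()] containing scar elements.
#' @param points q x 3 matrix of query points.
#' @return numeric vector of distances (cm); all `Inf` if the mesh has no
#'   scar.
#' @export
dist_to_scar <- function(mesh, points) {
  tris <- region_boundary_faces(mesh, mesh$tissue == TISSUE_SCAR)
  dist_to_surface(points, mesh$nodes, tris)
}
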