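test_that("patient generation is deterministic and labels partition the elements", {
  specs <- draw_cohort_specs(2, seed = 123)
  m1 <- generate_patient(specs[[1]], 0.12)
  m2 <- generate_patient(specs[[1]], 0.12)
  expect_identical(m1, m2)
  # repeated spec drawing from the same master seed is also identical
  specs_b <- draw_cohort_specs(2, seed = 123)
  expect_identical(specs, specs_b)
  for (mesh in list(m1, generate_patient(specs[[2]], 0.12))) {
    cnt <- tabulate(mesh$tissue + 1L, nbins = 3L)
    expect_equal(sum(cnt), nrow(mesh$elems))
    expect_true(all(cnt > 0))  # defaults embed scar + BZ in healthy tissue
  }
})

test_that("scar volume converges to the analytic ball volume", {
  r <- (0.5 * 3 / (4 * pi))^(1 / 3)  # ball of volume 0.5 cm^3
  sp <- patient_spec("ball", domain_extent = c(1.4, 1.4, 1.4),
                     scar_center = c(0.68, 0.71, 0.66), scar_radius = r,
                     bz_thickness = 0)
  mesh <- generate_patient(sp, 0.05)
  scar_vol <- sum(element_volumes(mesh)[mesh$tissue == TISSUE_SCAR])
  expect_lt(abs(scar_vol - 0.5) / 0.5, 0.10)
  expect_equal(sum(mesh$tissue == TISSUE_BZ), 0L)  # zero-width shell
  # volume error shrinks when the edge length halves
  coarse <- generate_patient(sp, 0.1)
  err_c <- abs(sum(element_volumes(coarse)[coarse$tissue == TISSUE_SCAR]) - 0.5)
  expect_lt(abs(scar_vol - 0.5), err_c)
  # grid-aligned block scar: labeled volume is exact at any resolution, so
  # halving the edge length can only keep or shrink the (zero) error
  for (h in c(0.08, 0.04)) {
    blk <- layered_slab(extent = c(1, 0.2, 0.2), h = h, x_scar = 0.3)
    xs <- attr(blk, "x_scar")
    expect_equal(sum(element_volumes(blk)[blk$tissue == TISSUE_SCAR]),
                 xs * 0.2 * 0.2, tolerance = 1e-12)
  }
})

test_that("mesh families refine consistently", {
  sp <- draw_cohort_specs(1, seed = 5)[[1]]
  fam <- generate_mesh_family(sp, c(0.2, 0.1))
  expect_s3_class(fam, "mesh_family")
  expect_gte(nrow(fam[[2]]$elems), 4 * nrow(fam[[1]]$elems))
  v1 <- sum(element_volumes(fam[[1]])[fam[[1]]$tissue == TISSUE_SCAR])
  v2 <- sum(element_volumes(fam[[2]])[fam[[2]]$tissue == TISSUE_SCAR])
  expect_lt(abs(v1 - v2) / v2, 0.15)
  expect_error(generate_mesh_family(sp, 0.1), "at least 2")
  expect_error(generate_mesh_family(sp, c(0.1, 0.2)), "strictly decreasing")
})

test_that("rule-based fibers rotate transmurally and stay unit-norm", {
  mesh <- healthy_slab(c(0.4, 0.4, 0.3), 0.05)
  flat <- assign_fibers(mesh, c(0, 0))
  expect_equal(flat$fiber,
               matrix(rep(c(1, 0, 0), each = nrow(flat$fiber)), ncol = 3),
               tolerance = 1e-12)
  rot <- assign_fibers(mesh, c(-60, 60))
  expect_equal(sqrt(rowSums(rot$fiber^2)), rep(1, nrow(rot$fiber)),
               tolerance = 1e-8)
  # elements near mid-wall have near-zero fiber angle
  depth <- element_centroids(mesh)[, 3] / 0.3
  mid <- which(abs(depth - 0.5) < 0.07)
  expect_gt(length(mid), 0)
  ang <- atan2(rot$fiber[mid, 2], rot$fiber[mid, 1]) * 180 / pi
  expect_true(all(abs(ang) < 120 * 0.07 + 1e-6))
  no_wall <- mesh; no_wall$extent <- NULL
  expect_error(assign_fibers(no_wall, c(-60, 60)), "transmural")
})

test_that("pacing sites honor prescribed scar distances (exhaustive oracle)", {
  sp <- patient_spec("p", domain_extent = c(2.4, 1.2, 0.3),
                     scar_center = c(0.6, 0.6, 0.15), scar_radius = 0.3,
                     bz_thickness = 0.1)
  mesh <- generate_patient(sp, 0.08)
  sites <- select_pacing_sites(mesh, c(0.2, 1.2))
  d_all <- dist_to_scar(mesh, mesh$nodes)
  edge <- mean_edge_length(mesh)
  for (i in seq_along(sites)) {
    d_target <- c(0.2, 1.2)[i]
    tol <- max(0.1 * d_target, edge)
    expect_lte(abs(d_all[sites[i]] - d_target), tol)
    # oracle: no healthy node is strictly closer to the target distance
    helems <- mesh$elems[mesh$tissue == TISSUE_HEALTHY, , drop = FALSE]
    hnodes <- sort(unique(as.vector(helems)))
    expect_equal(min(abs(d_all[hnodes] - d_target)),
                 abs(d_all[sites[i]] - d_target), tolerance = 1e-12)
  }
  # d = 0 returns a node on the scar boundary surface (no-BZ mesh, so
  # healthy tissue touches the scar directly)
  sp0 <- patient_spec("p0", domain_extent = c(2.4, 1.2, 0.3),
                      scar_center = c(0.6, 0.6, 0.15), scar_radius = 0.3,
                      bz_thickness = 0)
  m0 <- generate_patient(sp0, 0.08)
  s0 <- select_pacing_sites(m0, 0)
  expect_lt(dist_to_scar(m0, m0$nodes[s0, , drop = FALSE]), 1e-9)
  expect_error(select_pacing_sites(mesh, 50), "achievable")
  expect_error(select_pacing_sites(healthy_slab(), 0.1), "no scar")
})

test_that("BZ thickness statistics recover a uniform shell width", {
  sp <- patient_spec("shell", domain_extent = c(1.2, 1.2, 1.2),
                     scar_center = c(0.6, 0.6, 0.6), scar_radius = 0.25,
                     bz_thickness = 0.12)
  mesh <- generate_patient(sp, 0.05)
  st <- bz_thickness_stats(mesh)
  expect_lt(abs(st$mean - 0.12) / 0.12, 0.20)
  expect_gte(st$max, st$mean)
  no_bz <- generate_patient(
    patient_spec("nobz", c(1, 1, 1), c(0.5, 0.5, 0.5), 0.2, 0), 0.08)
  expect_warning(st0 <- bz_thickness_stats(no_bz), "no BZ")
  expect_equal(st0$mean, 0)
  expect_equal(st0$max, 0)
})

test_that("infeasible geometries are rejected with a diagnostic", {
  expect_error(patient_spec("bad", c(1, 1, 0.3), c(0.5, 0.5, 0.15),
                            scar_radius = 0.5, bz_thickness = 0.2),
               "infeasible")
  sp <- draw_cohort_specs(1, seed = 1)[[1]]
  expect_error(generate_patient(sp, 0.4), "coarse")
})
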