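test_that("paired one-sided t matches closed-form and textbook oracles", {
  res <- paired_t_one_sided(c(3, 4, 5), c(2, 2, 2))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  # closed-form Student-t upper tail at df = 2:
  # 1 - F(t) with F(t) = 1/2 + (t / (2*sqrt(2))) / sqrt(1 + t^2/2)
  t <- 2 * sqrt(3)
  p_closed <- 1 - (0.5 + (t / (2 * sqrt(2))) / sqrt(1 + t^2 / 2))
  expect_lt(abs(res$p - p_closed), 1e-8)
  expect_equal(res$p, 0.03709, tolerance = 1e-3)
  # antisymmetry: swapping x and y maps p -> 1 - p
  swapped <- paired_t_one_sided(c(2, 2, 2), c(3, 4, 5))
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, 1 - res$p, tolerance = 1e-12)
  # incomplete-beta route agrees to 1e-8 for df up to 30
  set.seed(10)
  for (K in c(3, 8, 15, 31)) {
    x <- rnorm(K, 0.4); y <- rnorm(K)
    r <- paired_t_one_sided(x, y)
    expect_lt(abs(r$p - t_upper_tail_beta(r$t, K - 1)), 1e-8)
  }
})

test_that("degenerate zero-variance differences follow the stated convention", {
  same <- paired_t_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$p, 0.5)
  up <- paired_t_one_sided(c(2, 3, 4), c(1, 2, 3))
  expect_true(up$degenerate)
  expect_equal(up$p, 0)
  dn <- paired_t_one_sided(c(1, 2, 3), c(2, 3, 4))
  expect_equal(dn$p, 1)
})

test_that("systematic scenario tests use exactly the named variant", {
  near <- cbind(contracted = c(5, 6, 7, 8, 9),
                original = c(3, 4, 5, 6, 7),
                expanded = c(2, 2, 2, 2, 2))
  far <- cbind(contracted = c(4, 5, 6, 7, 8),  # near - 1: constant positive
               original = c(2.2, 3.1, 4.4, 5.1, 6.3),
               expanded = c(2, 2, 2, 2, 2))
  panel <- hrgv_panel(near, far)
  res <- systematic_scenario_test(panel, "original", alpha = 0.01)
  oracle <- paired_t_one_sided(near[, "original"], far[, "original"])
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_lt(abs(res$p - t_upper_tail_beta(oracle$t, 4)), 1e-10)
  # constant positive differences: degenerate-positive, significant
  resc <- systematic_scenario_test(panel, "contracted", alpha = 0.01)
  expect_true(resc$degenerate)
  expect_true(resc$significant)
  # near == far: not significant
  rese <- systematic_scenario_test(panel, "expanded", alpha = 0.01)
  expect_false(rese$significant)
  expect_error(hrgv_panel(near, far[, 1:2]))
  expect_error(hrgv_panel(near, cbind(far[, 1:2], c(NA, 2, 2, 2, 2))),
               "incomplete")
})

test_that("worst-case extraction matches an exhaustive per-patient scan", {
  set.seed(4)
  near <- matrix(runif(15, 1, 4), 5, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  far <- matrix(runif(15, 0, 3), 5, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  panel <- hrgv_panel(near, far)
  res <- worst_case_test(panel, alpha = 0.01)
  x <- numeric(5); y <- numeric(5)
  for (k in 1:5) {
    x[k] <- max(near[k, 1], near[k, 2], near[k, 3])
    y[k] <- min(far[k, 1], far[k, 2], far[k, 3])
  }
  oracle <- paired_t_one_sided(x, y)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  # worst-case difference dominates every single-variant assignment
  for (v in 1:3) expect_true(all(x - y >= near[, v] - far[, v]))
  # identical variants collapse to the systematic test
  same <- hrgv_panel(near[, c(1, 1, 1)], far[, c(1, 1, 1)])
  expect_equal(worst_case_test(same)$t,
               systematic_scenario_test(same, 1)$t, tolerance = 1e-12)
})

test_that("Monte-Carlo sampling converges to the exhaustive fraction (K = 5)", {
  set.seed(9)
  near <- matrix(runif(15, 0.5, 2.5), 5, 3)
  far <- near - matrix(runif(15, -0.3, 0.9), 5, 3)
  far[far < 0] <- 0
  panel <- hrgv_panel(near, far)
  # exhaustive oracle written out locally over all 3^5 = 243 assignments
  grid <- expand.grid(v1 = 1:3, v2 = 1:3, v3 = 1:3, v4 = 1:3, v5 = 1:3)
  sig <- apply(grid, 1, function(a) {
    x <- near[cbind(1:5, a)]; y <- far[cbind(1:5, a)]
    paired_t_one_sided(x, y)$p < 0.01
  })
  exact <- mean(sig)
  expect_equal(exhaustive_fraction_significant(panel, 0.01), exact,
               tolerance = 1e-12)
  n <- 1e5
  frac <- mc_fraction_significant(panel, robustness_config(n_samples = n,
                                                           seed = 21))
  se <- sqrt(exact * (1 - exact) / n)
  expect_lt(abs(as.numeric(frac) - exact), 3 * se + 1e-12)
  expect_gt(exact, 0); expect_lt(exact, 1)  # fixture is genuinely mixed
  # determinism: same seed, same fraction
  frac2 <- mc_fraction_significant(panel, robustness_config(n_samples = n,
                                                            seed = 21))
  expect_identical(as.numeric(frac), as.numeric(frac2))
})

test_that("MC matches exhaustive enumeration on random small panels", {
  set.seed(30)
  for (rep in 1:20) {
    K <- sample(3:6, 1)
    near <- matrix(runif(3 * K, 0, 3), K, 3)
    far <- matrix(runif(3 * K, 0, 2.5), K, 3)
    panel <- hrgv_panel(near, far)
    exact <- exhaustive_fraction_significant(panel, 0.05)
    mc <- as.numeric(mc_fraction_significant(
      panel, robustness_config(alpha = 0.05, n_samples = 2e4, seed = rep)))
    se <- sqrt(max(exact * (1 - exact), 1e-12) / 2e4)
    expect_lt(abs(mc - exact), 3 * se + 0.005)
  }
})

test_that("normal-CV interpolation sampling behaves at grid nodes and in bulk", {
  # constant HRGV across CV levels: every sample reduces to the baseline test
  near <- matrix(rep(c(2, 3, 4, 5, 6), 3), 5, 3)
  far <- matrix(rep(c(1, 1.5, 2, 2.5, 3), 3), 5, 3)
  panel <- hrgv_panel(near, far)
  cfg <- robustness_config(n_samples = 500, seed = 3,
                           cv_levels = c(52.8, 66, 79.2))
  frac <- cv_normal_sampling(panel, cfg)
  base_p <- paired_t_one_sided(near[, 2], far[, 2])$p
  expect_equal(as.numeric(frac), as.numeric(base_p < 0.01))
  # affine HRGV-vs-CV panels: moderate-n run within 3 binomial SE of a
  # large-n run with a different seed
  set.seed(11)
  slope_n <- runif(5, -0.01, 0.01); slope_f <- runif(5, -0.01, 0.01)
  lv <- c(52.8, 66, 79.2)
  near_a <- outer(seq(2, 3, length.out = 5), rep(1, 3)) +
    outer(slope_n, lv - 66)
  far_a <- outer(seq(1.8, 2.6, length.out = 5), rep(1, 3)) +
    outer(slope_f, lv - 66)
  panel_a <- hrgv_panel(near_a, far_a)
  f1 <- as.numeric(cv_normal_sampling(
    panel_a, robustness_config(n_samples = 1e4, seed = 5, cv_levels = lv)))
  f2 <- as.numeric(cv_normal_sampling(
    panel_a, robustness_config(n_samples = 2e5, seed = 99, cv_levels = lv)))
  se <- sqrt(max(f2 * (1 - f2), 1e-12) / 1e4)
  expect_lt(abs(f1 - f2), 3 * se + 0.01)
  expect_error(cv_normal_sampling(
    panel_a, robustness_config(n_samples = 10, cv_levels = c(66, 60, 70))),
    "strictly increasing")
})

test_that("adding a constant to the near site weakly decreases p", {
  set.seed(12)
  near <- matrix(runif(15, 1, 2), 5, 3)
  far <- matrix(runif(15, 0.5, 1.8), 5, 3)
  p0 <- systematic_scenario_test(hrgv_panel(near, far), 1)$p
  p1 <- systematic_scenario_test(hrgv_panel(near + 0.5, far), 1)$p
  expect_lte(p1, p0)
})

test_that("assignment counting is exact integer arithmetic", {
  expect_identical(count_assignments(24, 3), 282429536481)
  expect_identical(count_assignments(0, 3), 1)
  expect_identical(count_assignments(5, 3), 243)
  expect_identical(count_assignments(6, 2), 64)
})
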