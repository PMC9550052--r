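# Scenario battery testing whether the cohort-level conclusion (HRGV greater
# pacing near scar than far) survives input uncertainty: systematic-bias
# tests, the worst-case combination test, Monte-Carlo sampling over discrete
# variant assignments, and continuous normal-CV sampling with interpolation.

#' One-sided paired t-test (greater)
#'
#' Tests `mean(x - y) > 0` with the paired Student t statistic,
#' `t = mean(d) / (sd(d) / sqrt(K))`, `p` the upper tail of t with K - 1
#' degrees of freedom. Zero-variance differences are degenerate and handled
#' by convention: p = 0 if `mean(d) > 0`, p = 1 if `mean(d) < 0`, p = 0.5 if
#' all differences are zero, with `degenerate = TRUE` in the result.
#'
#' @param x,y paired per-patient values, equal length K >= 2.
#' @return list with `t` (NA when degenerate), `p`, `df`, `degenerate`.
#' @export
paired_t_one_sided <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  K <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    m <- mean(d)
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    return(list(t = NA_real_, p = p, df = K - 1, degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(K))
  list(t = t, p = stats::pt(t, df = K - 1, lower.tail = FALSE),
       df = K - 1, degenerate = FALSE)
}

#' HRGV panel
#'
#' Per-patient HRGV (cm^3) for each input variant and each pacing site, the
#' complete grid the robustness scenarios draw from.
#'
#' @param near,far numeric K x V matrices (patients x variants) of HRGV
#'   values for the near-scar and far-from-scar pacing sites; identical
#'   dimnames.
#' @return object of class `hrgv_panel`.
#' @export
hrgv_panel <- function(near, far) {
  near <- as.matrix(near); far <- as.matrix(far)
  stopifnot(all(dim(near) == dim(far)), nrow(near) >= 2)
  if (anyNA(near) || anyNA(far))
    stop("panel is incomplete (missing HRGV cells)")
  if (any(near < 0) || any(far < 0)) stop("HRGV values must be >= 0")
  structure(list(near = near, far = far, K = nrow(near),
                 variants = colnames(near)), class = "hrgv_panel")
}

#' Robustness sampling configuration
#'
#' @param alpha significance level (default 0.01).
#' @param n_samples Monte-Carlo sample count (desk default 1e4; 1e6
#'   reproduces the full-scale sampling).
#' @param seed integer RNG seed.
#' @param cv_mean,cv_sd normal conduction-velocity model, cm/s (defaults 66
#'   and 6.6, so the low/high variants sit at a 95% interval).
#' @param cv_levels the three CVs (cm/s, strictly increasing) at which the
#'   conductivity panel was simulated; `NULL` until set by the study.
#' @return list of class `robustness_config`.
#' @export
robustness_config <- function(alpha = 0.01, n_samples = 1e4, seed = 1L,
                              cv_mean = 66, cv_sd = 6.6, cv_levels = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_samples >= 1, cv_sd > 0)
  structure(list(alpha = alpha, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), cv_mean = cv_mean, cv_sd = cv_sd,
                 cv_levels = cv_levels), class = "robustness_config")
}

#' Systematic-bias scenario test
#'
#' Paired near-vs-far test using a single named variant for every patient:
#' the "all patients biased the same way" scenario.
#'
#' @param panel an [hrgv_panel()].
#' @param variant column name or index of the variant to use.
#' @param alpha significance level.
#' @return list: `scenario`, `t`, `p`, `significant`, `degenerate`.
#' @export
systematic_scenario_test <- function(panel, variant, alpha = 0.01) {
  stopifnot(inherits(panel, "hrgv_panel"))
  res <- paired_t_one_sided(panel$near[, variant], panel$far[, variant])
  list(scenario = paste0("systematic_", variant), t = res$t, p = res$p,
       significant = res$p < alpha, degenerate = res$degenerate)
}

#' Worst-case combination test
#'
#' Paired test on the per-patient maximum near-site HRGV over variants
#' against the per-patient minimum far-site HRGV — a combination that could
#' never be attained jointly (different variants supply the two sites), used
#' as a conservative screen: if it were significant it is argued to cover
#' every variant assignment. Note the caveat: a paired t statistic is not
#' monotone in the per-patient differences (the difference variance can
#' grow), so that guarantee is heuristic; the result records it.
#'
#' @param panel an [hrgv_panel()].
#' @param alpha significance level.
#' @return list as in [systematic_scenario_test()] plus `caveat`.
#' @export
worst_case_test <- function(panel, alpha = 0.01) {
  stopifnot(inherits(panel, "hrgv_panel"))
  x <- apply(panel$near, 1, max)
  y <- apply(panel$far, 1, min)
  res <- paired_t_one_sided(x, y)
  list(scenario = "worst_case", t = res$t, p = res$p,
       significant = res$p < alpha, degenerate = res$degenerate,
       caveat = paste("max/min combination is not attainable jointly;",
                      "significance here does not formally bound all",
                      "variant assignments (t is not monotone in",
                      "per-patient differences)"))
}

# vectorized paired one-sided p-values over rows of difference matrix D
# (n_samples x K), applying the degenerate convention rowwise
row_paired_p <- function(D) {
  K <- ncol(D)
  m <- rowMeans(D)
  s2 <- (rowSums(D^2) - K * m^2) / (K - 1)
  s2[s2 < 0] <- 0
  s <- sqrt(s2)
  p <- numeric(nrow(D))
  deg <- s == 0
  p[deg & m > 0] <- 0
  p[deg & m < 0] <- 1
  p[deg & m == 0] <- 0.5
  nd <- !deg
  t <- m[nd] / (s[nd] / sqrt(K))
  p[nd] <- stats::pt(t, df = K - 1, lower.tail = FALSE)
  p
}

#' Monte-Carlo fraction of significant variant assignments
#'
#' Draws `cfg$n_samples` assignments of one variant per patient (independent
#' and uniform over the variants; the drawn variant supplies both the near
#' and the far value of that patient — one representation per patient per
#' sample), runs the paired near-vs-far test on each, and returns the
#' fraction significant at `cfg$alpha`. Reproducible from `cfg$seed`.
#'
#' @param panel an [hrgv_panel()].
#' @param cfg a [robustness_config()].
#' @return fraction in `[0, 1]`, with attributes `n_samples` and `seed`.
#' @export
mc_fraction_significant <- function(panel, cfg = robustness_config()) {
  stopifnot(inherits(panel, "hrgv_panel"))
  if (cfg$n_samples < 1) stop("n_samples must be >= 1")
  K <- panel$K; V <- ncol(panel$near)
  frac <- local_seed(cfg$seed, {
    n_sig <- 0
    chunk <- 100000L
    remaining <- cfg$n_samples
    while (remaining > 0) {
      nb <- min(chunk, remaining)
      assign_idx <- matrix(sample.int(V, nb * K, replace = TRUE), nb, K)
      col <- rep(seq_len(K), each = nb)
      D <- matrix(panel$near[cbind(col, as.vector(assign_idx))] -
                  panel$far[cbind(col, as.vector(assign_idx))], nb, K)
      n_sig <- n_sig + sum(row_paired_p(D) < cfg$alpha)
      remaining <- remaining - nb
    }
    n_sig / cfg$n_samples
  })
  structure(frac, n_samples = cfg$n_samples, seed = cfg$seed)
}

#' Exhaustive fraction of significant variant assignments
#'
#' Enumerates all `V^K` assignments (small cohorts only) and returns the
#' exact fraction significant — the oracle the Monte-Carlo estimate
#' converges to.
#'
#' @param panel an [hrgv_panel()].
#' @param alpha significance level.
#' @return exact fraction in `[0, 1]`.
#' @export
exhaustive_fraction_significant <- function(panel, alpha = 0.01) {
  stopifnot(inherits(panel, "hrgv_panel"))
  K <- panel$K; V <- ncol(panel$near)
  n_total <- V^K
  if (n_total > 2e6) stop("too many assignments to enumerate")
  grid <- as.matrix(expand.grid(rep(list(seq_len(V)), K)))
  col <- rep(seq_len(K), each = nrow(grid))
  D <- matrix(panel$near[cbind(col, as.vector(grid))] -
              panel$far[cbind(col, as.vector(grid))], nrow(grid), K)
  mean(row_paired_p(D) < alpha)
}

#' Normal conduction-velocity sampling with interpolation
#'
#' Per sample and patient, draws an independent CV from
#' `Normal(cv_mean, cv_sd^2)`, clamps it to the simulated CV range, and
#' piecewise-linearly interpolates the near- and far-site HRGV between the
#' three simulated CV levels (the same drawn CV feeds both sites of a
#' patient). Returns the fraction of samples whose paired near-vs-far test
#' is significant.
#'
#' @param panel an [hrgv_panel()] whose variant columns correspond, in
#'   order, to `cfg$cv_levels` (low, baseline, high).
#' @param cfg a [robustness_config()] with `cv_levels` set (strictly
#'   increasing).
#' @return fraction in `[0, 1]`, with attributes `n_samples` and `seed`.
#' @export
cv_normal_sampling <- function(panel, cfg) {
  stopifnot(inherits(panel, "hrgv_panel"),
            inherits(cfg, "robustness_config"))
  lv <- cfg$cv_levels
  if (is.null(lv) || length(lv) != ncol(panel$near))
    stop("cfg$cv_levels must give one CV per panel variant")
  if (any(diff(lv) <= 0)) stop("cv_levels must be strictly increasing")
  K <- panel$K
  frac <- local_seed(cfg$seed, {
    n_sig <- 0
    chunk <- 100000L
    remaining <- cfg$n_samples
    while (remaining > 0) {
      nb <- min(chunk, remaining)
      cv <- matrix(stats::rnorm(nb * K, cfg$cv_mean, cfg$cv_sd), nb, K)
      cv <- pmin(pmax(cv, lv[1]), lv[length(lv)])
      D <- matrix(0, nb, K)
      for (kk in seq_len(K)) {
        nr <- stats::approx(lv, panel$near[kk, ], xout = cv[, kk])$y
        fr <- stats::approx(lv, panel$far[kk, ], xout = cv[, kk])$y
        D[, kk] <- nr - fr
      }
      n_sig <- n_sig + sum(row_paired_p(D) < cfg$alpha)
      remaining <- remaining - nb
    }
    n_sig / cfg$n_samples
  })
  structure(frac, n_samples = cfg$n_samples, seed = cfg$seed)
}

#' Number of discrete variant assignments
#'
#' Exact integer count `v^K` of ways to assign one of `v` variants to each
#' of `K` patients independently (e.g. 3^24 = 282,429,536,481 for a
#' 24-patient cohort with three border-zone representations).
#'
#' @param K number of patients (>= 0).
#' @param v number of variants per patient (>= 1).
#' @return exact count as a double (exact up to 2^53).
#' @export
count_assignments <- function(K, v) {
  stopifnot(K >= 0, v >= 1, K == round(K), v == round(v))
  out <- 1
  for (i in seq_len(K)) out <- out * v
  if (out > 2^53) warning("count exceeds exact double-integer range")
  out
}
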