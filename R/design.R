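#' Exact two-sample t-test sample size
#'
#' Smallest integer n per group for which the exact two-sample t-test
#' (noncentral t, 2n - 2 degrees of freedom) attains the target power for a
#' given difference and common SD. The normal-approximation size
#' n = 2 (z_{1-a/2} + z_{pow})^2 (sd/delta)^2 is also reported; the
#' t-correction typically adds one or two animals at small n.
#'
#' @param delta Assumed treatment difference (outcome units, nonzero).
#' @param sd Common outcome SD (> 0).
#' @param power Target power in (0, 1).
#' @param alpha_two_sided Two-sided type I error rate.
#' @return A list with `n` (exact), `n_normal_approx`, and `achieved_power`
#'   at the exact n.
#' @examples
#' sample_size_two_arm(0.5, 0.4)$n # 12
#' @export
sample_size_two_arm <- function(delta, sd, power = 0.80,
                                alpha_two_sided = 0.05) {
  if (delta == 0) stop("'delta' must be nonzero")
  if (sd <= 0) stop("'sd' must be > 0")
  if (power <= alpha_two_sided || power >= 1) {
    stop("'power' must lie in (alpha, 1)")
  }
  za <- stats::qnorm(1 - alpha_two_sided / 2)
  zb <- stats::qnorm(power)
  n_norm <- ceiling(2 * (za + zb)^2 * (sd / abs(delta))^2)
  pow_at <- function(n) {
    df <- 2 * n - 2
    ncp <- abs(delta) / (sd * sqrt(2 / n))
    crit <- stats::qt(1 - alpha_two_sided / 2, df)
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  }
  n <- 2L
  while (pow_at(n) < power) n <- n + 1L
  list(n = n, n_normal_approx = n_norm, achieved_power = pow_at(n))
}

#' Posterior probability of superiority for a two-arm Gaussian comparison
#'
#' With flat priors on the arm means and the Jeffreys prior on the common
#' variance, the posterior of the group difference is a location-scale
#' Student-t centred at the observed difference with scale
#' s_p sqrt(2/n) and 2n - 2 degrees of freedom; Pr(sup) is its mass on the
#' beneficial side of zero. In the known-variance mode the posterior is
#' Gaussian and Pr(sup) = Phi(d / (sigma sqrt(2/n))).
#'
#' @param diff Observed difference in arm means, oriented so positive =
#'   benefit.
#' @param pooled_sd Pooled sample SD (or the known sigma).
#' @param n_per_arm Sample size per arm.
#' @param known_variance If `TRUE` use the Gaussian posterior with
#'   `pooled_sd` as the known sigma.
#' @return Probability in (0, 1). Vectorised over `diff` and `pooled_sd`.
#' @export
pr_sup_conjugate <- function(diff, pooled_sd, n_per_arm,
                             known_variance = FALSE) {
  se <- pooled_sd * sqrt(2 / n_per_arm)
  if (known_variance) stats::pnorm(diff / se)
  else stats::pt(diff / se, df = 2 * n_per_arm - 2)
}

#' Specification of the Bayesian superiority design
#'
#' @param delta Assumed treatment difference under the alternative (log10
#'   units for the Lac/NAA primary outcome).
#' @param sd Outcome SD.
#' @param n_per_arm Animals per arm.
#' @param superiority_threshold Declare success when Pr(sup) meets or exceeds
#'   this (default 0.95).
#' @param futility_threshold Stop for futility when Pr(sup) is at or below
#'   this (default 0.50).
#' @param alpha_one_sided One-sided type I error target for calibration.
#' @param n_sims Simulated trials for operating characteristics (>= 1000 for
#'   reported values).
#' @param seed Integer seed.
#' @return A validated list of class `design_spec`.
#' @export
design_spec <- function(delta = 0.5, sd = 0.4, n_per_arm = 12,
                        superiority_threshold = 0.95,
                        futility_threshold = 0.50,
                        alpha_one_sided = 0.025,
                        n_sims = 10000, seed = 1L) {
  if (sd <= 0) stop("invalid 'sd': must be > 0")
  if (n_per_arm < 2) stop("invalid 'n_per_arm': must be >= 2")
  for (nm in c("superiority_threshold", "futility_threshold", "alpha_one_sided")) {
    v <- get(nm)
    if (v <= 0 || v >= 1) stop(sprintf("invalid '%s': must be in (0, 1)", nm))
  }
  if (futility_threshold >= superiority_threshold) {
    stop("invalid thresholds: futility_threshold must be < superiority_threshold")
  }
  structure(list(delta = delta, sd = sd, n_per_arm = n_per_arm,
                 superiority_threshold = superiority_threshold,
                 futility_threshold = futility_threshold,
                 alpha_one_sided = alpha_one_sided,
                 n_sims = n_sims, seed = as.integer(seed)),
            class = "design_spec")
}

# vectorised simulation of per-trial Pr(sup): difference in arm means and
# pooled SD drawn from their exact sampling distributions
simulate_pr_sup <- function(n_sims, truth, sd, n_per_arm,
                            known_variance = FALSE) {
  df <- 2 * n_per_arm - 2
  d <- stats::rnorm(n_sims, mean = truth, sd = sd * sqrt(2 / n_per_arm))
  s <- if (known_variance) rep(sd, n_sims)
       else sd * sqrt(stats::rchisq(n_sims, df) / df)
  pr_sup_conjugate(d, s, n_per_arm, known_variance = known_variance)
}

#' Operating characteristics of the superiority/futility decision rule
#'
#' Monte-Carlo frequencies of the design's decisions at a single (final)
#' analysis: per simulated trial, Gaussian outcomes are drawn for both arms
#' and Pr(sup) computed from the flat-prior posterior
#' (see [pr_sup_conjugate()]). Reports, with Monte-Carlo standard errors:
#' the probability of stopping for futility under the null, power under
#' `truth = spec$delta`, and the type I error of the superiority rule under
#' the null.
#'
#' @param spec A `design_spec`.
#' @param truth Optional override of the alternative-hypothesis effect
#'   (defaults to `spec$delta`).
#' @param known_variance Use the Gaussian (known-sigma) posterior instead of
#'   the Student-t.
#' @param warn_only If `TRUE`, permit `n_sims < 1000` with a warning instead
#'   of an error.
#' @return A list of class `oc_result` with entries
#'   `p_stop_futility_null`, `power`, `type1`, each with an `mc_se`
#'   attribute, plus the spec used.
#' @export
simulate_oc <- function(spec, truth = spec$delta, known_variance = FALSE,
                        warn_only = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$n_sims < 1000) {
    msg <- "n_sims < 1000: operating characteristics too noisy to report"
    if (warn_only) warning(msg) else stop(msg)
  }
  set.seed(spec$seed)
  pr_null <- simulate_pr_sup(spec$n_sims, 0, spec$sd, spec$n_per_arm,
                             known_variance)
  pr_alt <- simulate_pr_sup(spec$n_sims, truth, spec$sd, spec$n_per_arm,
                            known_variance)
  with_se <- function(p) {
    attr(p, "mc_se") <- sqrt(p * (1 - p) / spec$n_sims)
    p
  }
  structure(list(
    p_stop_futility_null = with_se(mean(pr_null <= spec$futility_threshold)),
    power = with_se(mean(pr_alt >= spec$superiority_threshold)),
    type1 = with_se(mean(pr_null >= spec$superiority_threshold)),
    spec = spec, truth = truth, known_variance = known_variance
  ), class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  fmt <- function(p) sprintf("%.4f (MC SE %.4f)", p, attr(p, "mc_se"))
  cat("Operating characteristics (", x$spec$n_sims, " simulated trials, n = ",
      x$spec$n_per_arm, "/arm)\n", sep = "")
  cat("  P(stop futility | null):", fmt(x$p_stop_futility_null), "\n")
  cat("  Power at truth =", x$truth, ":", fmt(x$power), "\n")
  cat("  Type I error:", fmt(x$type1), "\n")
  invisible(x)
}

#' Calibrate the superiority threshold to a one-sided type I error target
#'
#' Finds the smallest threshold c on a 0.001 grid with simulated type I error
#' at or below `target_alpha`. Under the known-variance conjugate posterior
#' Pr(sup) is exactly Uniform(0,1) under the null, so c converges to
#' 1 - target_alpha; the Student-t posterior's heavier tails calibrate to a
#' slightly smaller c at small n.
#'
#' @param spec A `design_spec` (its `n_sims` and `seed` drive the
#'   simulation).
#' @param target_alpha One-sided type I error target in (0, 0.5).
#' @param known_variance Use the Gaussian posterior.
#' @return A list with `threshold`, `type1_at_threshold`, and `achievable`
#'   (the smallest attainable type I error on the grid).
#' @export
calibrate_threshold <- function(spec, target_alpha = spec$alpha_one_sided,
                                known_variance = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  if (target_alpha <= 0 || target_alpha >= 0.5) {
    stop("'target_alpha' must be in (0, 0.5)")
  }
  set.seed(spec$seed)
  pr_null <- simulate_pr_sup(spec$n_sims, 0, spec$sd, spec$n_per_arm,
                             known_variance)
  grid <- seq(0.5, 0.999, by = 0.001)
  type1 <- vapply(grid, function(c) mean(pr_null >= c), 0)
  ok <- type1 <= target_alpha
  if (!any(ok)) {
    stop(sprintf("target alpha %.4f unattainable; achievable floor %.4f",
                 target_alpha, min(type1)))
  }
  c_star <- grid[which(ok)[1L]]
  list(threshold = c_star, type1_at_threshold = type1[which(ok)[1L]],
       achievable = min(type1))
}
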