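test_that("exact t-test sizing matches the independent power calculation", {
  # independent oracle: stats::power.t.test solves the same noncentral-t
  # problem by root finding; our iteration must agree after rounding up
  for (case in list(c(0.5, 0.4), c(0.4, 0.4), c(0.3, 0.5), c(1, 0.6))) {
    ours <- sample_size_two_arm(case[1], case[2], power = 0.8,
                                alpha_two_sided = 0.05)
    oracle <- ceiling(power.t.test(delta = case[1], sd = case[2],
                                   power = 0.8, sig.level = 0.05)$n)
    expect_equal(ours$n, oracle)
    expect_gte(ours$achieved_power, 0.8)
  }
  expect_equal(sample_size_two_arm(0.5, 0.4)$n, 12)
  expect_equal(sample_size_two_arm(0.4, 0.4)$n, 17)
  expect_equal(sample_size_two_arm(0.4, 0.4)$n_normal_approx, 16)
})

test_that("sizing is monotone in the effect and validates inputs", {
  n_grid <- vapply(c(0.3, 0.4, 0.5, 0.6, 1), function(d) {
    sample_size_two_arm(d, 0.4)$n
  }, 0L)
  expect_true(all(diff(n_grid) <= 0))
  expect_error(sample_size_two_arm(0, 0.4), "nonzero")
  expect_error(sample_size_two_arm(0.5, -1), "sd")
  expect_error(sample_size_two_arm(0.5, 0.4, power = 0.01), "power")
})

test_that("conjugate Pr(sup) has its closed forms", {
  # known variance: Phi(d / se); unknown: Student-t CDF
  expect_equal(pr_sup_conjugate(0.3, 0.4, 12, known_variance = TRUE),
               pnorm(0.3 / (0.4 * sqrt(2 / 12))))
  expect_equal(pr_sup_conjugate(0.3, 0.4, 12),
               pt(0.3 / (0.4 * sqrt(2 / 12)), df = 22))
  expect_equal(pr_sup_conjugate(0, 1, 10), 0.5)
})

test_that("Pr(sup) is uniform under the null (probability integral transform)", {
  spec <- design_spec(n_sims = 10000, seed = 11)
  set.seed(spec$seed)
  pr <- piglettrials:::simulate_pr_sup(spec$n_sims, 0, spec$sd,
                                       spec$n_per_arm)
  ks <- suppressWarnings(ks.test(pr, "punif"))
  expect_gt(ks$p.value, 0.01)
  # known-variance mode: P(Pr_sup > c | null) = 1 - c exactly (up to MC error)
  set.seed(spec$seed)
  prk <- piglettrials:::simulate_pr_sup(spec$n_sims, 0, spec$sd,
                                        spec$n_per_arm, known_variance = TRUE)
  for (c0 in c(0.9, 0.95, 0.975)) {
    mc3 <- 3 * sqrt(c0 * (1 - c0) / spec$n_sims)
    expect_lt(abs(mean(prk > c0) - (1 - c0)), mc3)
  }
})

test_that("operating characteristics match their analytic benchmarks", {
  spec <- design_spec(delta = 0.5, sd = 0.4, n_per_arm = 12,
                      n_sims = 20000, seed = 5)
  oc <- simulate_oc(spec)
  # futility: Pr(sup) <= 0.5 iff observed difference <= 0 -> exactly 1/2
  expect_lt(abs(oc$p_stop_futility_null - 0.5),
            3 * attr(oc$p_stop_futility_null, "mc_se"))
  # power: noncentral-t closed form for the Pr(sup) >= 0.95 rule
  df <- 22; ncp <- 0.5 / (0.4 * sqrt(2 / 12))
  pow_theory <- 1 - pt(qt(0.95, df), df, ncp)
  expect_lt(abs(oc$power - pow_theory), 3 * attr(oc$power, "mc_se"))
  # type I error of the same rule: exactly 1 - 0.95 by uniformity
  expect_lt(abs(oc$type1 - 0.05), 3 * attr(oc$type1, "mc_se"))
})

test_that("power is monotone in the threshold and the truth", {
  powers_thr <- vapply(c(0.8, 0.9, 0.95, 0.99), function(thr) {
    simulate_oc(design_spec(superiority_threshold = thr, n_sims = 4000,
                            seed = 21))$power
  }, 0)
  expect_true(all(diff(powers_thr) < 0))
  powers_tr <- vapply(c(0.2, 0.5, 0.8), function(tr) {
    simulate_oc(design_spec(n_sims = 4000, seed = 21), truth = tr)$power
  }, 0)
  expect_true(all(diff(powers_tr) > 0))
  # boundary: a threshold of ~1 kills the type I error
  oc <- simulate_oc(design_spec(superiority_threshold = 0.9999,
                                n_sims = 2000, seed = 3))
  expect_equal(unclass(oc$type1), 0, ignore_attr = TRUE)
})

test_that("simulate_oc refuses under-sized simulations unless warned", {
  spec <- design_spec(n_sims = 200, seed = 1)
  expect_error(simulate_oc(spec), "n_sims")
  expect_warning(simulate_oc(spec, warn_only = TRUE), "n_sims")
})

test_that("threshold calibration hits the conjugate closed form", {
  spec <- design_spec(n_sims = 50000, seed = 13)
  # known variance: Pr(sup) uniform under the null, so c -> 1 - alpha
  cal <- calibrate_threshold(spec, target_alpha = 0.025,
                             known_variance = TRUE)
  expect_equal(cal$threshold, 0.975, tolerance = 0.003)
  # unknown variance: Pr(sup) = pt(t-stat, df) is also exactly uniform under
  # the null (probability integral transform), so c -> 1 - alpha here too
  cal_t <- calibrate_threshold(spec, target_alpha = 0.025)
  expect_equal(cal_t$threshold, 0.975, tolerance = 0.003)
  # monotone: tighter alpha, higher threshold
  cal_small <- calibrate_threshold(spec, target_alpha = 0.005)
  expect_gt(cal_small$threshold, cal$threshold)
  expect_error(calibrate_threshold(spec, target_alpha = 0.6), "target_alpha")
})

test_that("design specification rejects inconsistent thresholds", {
  expect_error(design_spec(futility_threshold = 0.96), "thresholds")
  expect_error(design_spec(sd = 0), "sd")
  expect_error(design_spec(superiority_threshold = 1.2), "superiority_threshold")
})
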