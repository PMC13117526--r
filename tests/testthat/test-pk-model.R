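test_that("micro constants are the standard CL/V reparameterization", {
  mc <- micro_constants(pk_params(3, 10, 0, 0))
  expect_equal(mc$k10, 0.3)
  expect_equal(mc$k12, 0)
  expect_true(mc$one_compartment)

  mc2 <- micro_constants(fixture_pk_params())
  expect_equal(mc2$k10, 0.8125)
  expect_equal(mc2$k12, 0.5)
  expect_equal(mc2$k21, 1 / 30, tolerance = 1e-12)

  expect_error(pk_params(3, 10, Q = 1, V2 = 0), "V2")
  expect_error(pk_params(-1, 10), "CL")
})

test_that("micro-to-macro round trip reproduces the inputs", {
  set.seed(4)
  for (rep in 1:10) {
    p <- pk_params(runif(1, 0.5, 5), runif(1, 1, 10),
                   runif(1, 0.1, 5), runif(1, 5, 100))
    mc <- micro_constants(p)
    ab <- disposition_rates(mc$k10, mc$k12, mc$k21)
    # invert: alpha*beta = k10*k21, alpha+beta = k10+k12+k21
    expect_equal(ab[["alpha"]] * ab[["beta"]], mc$k10 * mc$k21,
                 tolerance = 1e-10)
    expect_equal(ab[["alpha"]] + ab[["beta"]], mc$k10 + mc$k12 + mc$k21,
                 tolerance = 1e-10)
    # macro rates are the eigenvalue magnitudes of the disposition matrix
    A <- matrix(c(-(mc$k10 + mc$k12), mc$k21, mc$k12, -mc$k21), 2, 2,
                byrow = TRUE)
    ev <- sort(abs(eigen(A)$values))
    expect_equal(unname(sort(ab)), ev, tolerance = 1e-10)
  }
})

test_that("disposition rates degenerate cleanly to one compartment", {
  ab <- disposition_rates(0.3, 0, 0)
  expect_equal(ab[["alpha"]], 0.3)
  expect_equal(ab[["beta"]], 0)
})

test_that("infusion concentration matches the one-compartment closed form", {
  # end of a T-hour infusion at rate R0: C = (R0/CL)(1 - exp(-CL T / V1))
  CL <- 2; V1 <- 8; T_inf <- 1.5; dose <- 30; R0 <- dose / T_inf
  p <- pk_params(CL, V1)
  reg <- dose_regimen(0, T_inf, dose)
  expect_equal(pk_concentration(T_inf, reg, p),
               (R0 / CL) * (1 - exp(-CL * T_inf / V1)), tolerance = 1e-12)
  expect_equal(pk_concentration(0, reg, p), 0)
  expect_error(pk_concentration(-1, reg, p), "negative")
})

test_that("concentration is zero before the first dose and superposes doses", {
  p <- fixture_pk_params()
  reg3 <- regimen_azithromycin(2)
  expect_equal(pk_concentration(c(0, 0.5, 0.999), reg3, p), rep(0, 3))
  # superposition: the 3-dose profile equals the sum of shifted single doses
  tt <- seq(0, 72, by = 0.5)
  singles <- sapply(c(1, 24, 48), function(s) {
    pk_concentration(tt, dose_regimen(s, 1, 40), p)
  })
  expect_equal(pk_concentration(tt, reg3, p), rowSums(singles),
               tolerance = 1e-10)
})

test_that("closed form agrees with piecewise ODE integration", {
  p <- fixture_pk_params()
  reg <- regimen_azithromycin(2)
  tt <- seq(0, 72, by = 0.25)
  closed <- pk_concentration(tt, reg, p)
  ode <- pk_profile_ode(reg, p, tt)$conc_mg_per_L
  rel <- abs(closed - ode) / pmax(abs(closed), 1e-9)
  expect_lt(max(rel[closed > 1e-6]), 1e-6)
})

test_that("kinetics are linear and mass balance is exact", {
  p <- fixture_pk_params()
  tt <- seq(0, 60, by = 1)
  c1 <- pk_concentration(tt, dose_regimen(c(1, 24), 1, c(40, 40)), p)
  c2 <- pk_concentration(tt, dose_regimen(c(1, 24), 1, c(80, 80)), p)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)

  dp <- derived_params(p, fixture_single_dose())
  expect_equal(dp$auc_inf * p$CL, 40, tolerance = 1e-12)

  # AUC equals the numerically integrated curve extrapolated to infinity
  h <- 0.02
  grid <- seq(0, 400, by = h)
  cg <- pk_concentration(grid, fixture_single_dose(), p)
  auc_num <- sum((cg[-1] + cg[-length(cg)]) / 2) * h +
    cg[length(cg)] / dp$beta  # terminal log-linear tail
  expect_equal(auc_num, dp$auc_inf, tolerance = 1e-3)
})

test_that("increasing clearance strictly decreases AUC", {
  aucs <- vapply(c(1, 2, 4, 8), function(cl) {
    derived_params(pk_params(cl, 4, 2, 60), fixture_single_dose())$auc_inf
  }, 0)
  expect_true(all(diff(aucs) < 0))
})

test_that("derived parameters have the one-compartment closed forms", {
  p1 <- pk_params(2, 10)
  dp1 <- derived_params(p1, dose_regimen(0, 1, 20))
  expect_equal(dp1$t_half_beta, log(2) * 10 / 2, tolerance = 1e-12)
  # infusion peaks at the infusion end
  expect_equal(dp1$t_cmax, 1, tolerance = 1e-4)
})

test_that("noise-free PK samples equal predictions; zero stays zero", {
  p <- fixture_pk_params()
  reg <- regimen_azithromycin(2)
  s <- generate_pk_samples(p, reg, times = c(0.5, 2, 25, 49), cv_prop = 0)
  expect_equal(s$conc_mg_per_L,
               pk_concentration(c(0.5, 2, 25, 49), reg, p))
  expect_equal(s$conc_mg_per_L[1], 0)
  expect_error(generate_pk_samples(p, reg, times = -1), "negative")
})

test_that("proportional-error spread matches the configured CV", {
  p <- fixture_pk_params()
  reg <- regimen_azithromycin(2)
  tt <- rep(c(2, 25, 49), 2000)
  s <- generate_pk_samples(p, reg, tt, cv_prop = 0.2, seed = 8)
  pred <- pk_concentration(tt, reg, p)
  ratio_sd <- sd(s$conc_mg_per_L / pred - 1)
  # 3 MC SEs of a SD estimated from 6000 draws: 3 * 0.2 / sqrt(2*6000)
  expect_lt(abs(ratio_sd - 0.2), 3 * 0.2 / sqrt(2 * 6000))
})
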