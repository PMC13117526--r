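# correlated multi-column table with MCAR holes for imputation tests
make_missing_panel <- function(n = 40, rate = 0.1, seed = 1) {
  set.seed(seed)
  b <- rnorm(n)
  d <- data.frame(x1 = b + rnorm(n, 0, 0.5),
                  x2 = 0.8 * b + rnorm(n, 0, 0.5),
                  x3 = -0.5 * b + rnorm(n, 0, 0.5))
  full <- d
  for (j in seq_along(d)) d[[j]][runif(n) < rate] <- NA
  list(holed = d, full = full)
}

test_that("chained imputation is a no-op on complete data and deterministic", {
  p <- make_missing_panel(rate = 0)
  out <- impute_chained(p$holed, n_imputations = 3, seed = 5)
  expect_length(out, 3)
  for (m in out) expect_identical(m, p$holed)

  p2 <- make_missing_panel(rate = 0.15, seed = 2)
  a <- impute_chained(p2$holed, n_imputations = 2, seed = 9)
  b <- impute_chained(p2$holed, n_imputations = 2, seed = 9)
  expect_identical(a, b)
  c <- impute_chained(p2$holed, n_imputations = 2, seed = 10)
  expect_false(identical(a, c))
})

test_that("observed cells are never altered and imputations are unbiased under MCAR", {
  p <- make_missing_panel(n = 200, rate = 0.1, seed = 3)
  out <- impute_chained(p$holed, n_imputations = 10, seed = 4)
  for (m in out) {
    for (j in names(p$holed)) {
      obs <- !is.na(p$holed[[j]])
      expect_identical(m[[j]][obs], p$holed[[j]][obs])
      expect_false(anyNA(m[[j]]))
    }
  }
  # pooled means within 3 SEs of the complete-data means
  for (j in names(p$full)) {
    pooled <- mean(vapply(out, function(m) mean(m[[j]]), 0))
    se <- sd(p$full[[j]]) / sqrt(nrow(p$full))
    expect_lt(abs(pooled - mean(p$full[[j]])), 3 * se)
  }
})

test_that("degenerate imputation inputs are rejected", {
  d <- data.frame(x1 = c(NA, NA, NA, 1), x2 = 1:4)
  expect_error(impute_chained(d), "fewer than 2 observed")
})

test_that("Rubin pooling inflates variance and respects its identities", {
  est <- c(1.0, 1.2, 0.9, 1.1, 1.05)
  se <- rep(0.3, 5)
  pooled <- rubin_pool(est, se, df_com = 20)
  expect_equal(pooled$estimate, mean(est))
  expect_gte(pooled$se^2, pooled$within_var)  # total >= within variance
  expect_lt(pooled$df, 20)                    # missing data costs df
  # zero between-imputation variance reduces to the single fit
  same <- rubin_pool(rep(1, 5), rep(0.3, 5), df_com = 20)
  expect_equal(same$se, 0.3)
  expect_equal(same$df, 20)
})

test_that("BH adjustment never lowers a p-value and matches the hand-worked case", {
  # step-up by hand: (0.01, 0.02, 0.03, 0.04) over a family of 4 all
  # adjust to 0.04 (0.04*4/4, then the running minimum from the top)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(8)
  for (r in 1:20) {
    p <- runif(8)
    adj <- p.adjust(p, method = "BH")
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # discoveries are non-increasing as the FDR threshold tightens
    disc <- vapply(c(0.2, 0.1, 0.05, 0.01), function(q) sum(adj <= q), 0L)
    expect_true(all(diff(disc) <= 0))
  }
})

# small 8-region panel with a known uniform shift
make_ihc <- function(n = 12, shift = 0, missing = 0, seed = 1) {
  set.seed(seed)
  arm <- rep(c("vehicle", "treated"), each = n)
  sex <- rep(c("male", "female"), n)
  b <- rnorm(2 * n, 0, 50)
  d <- do.call(rbind, lapply(ihc_regions(), function(r) {
    mu <- 500 + b + ifelse(arm == "treated", shift, 0)
    data.frame(animal_id = sprintf("A%02d", 1:(2 * n)), arm = arm, sex = sex,
               region = r, density = pmax(rnorm(2 * n, mu, 60), 0))
  }))
  if (missing > 0) d$density[runif(nrow(d)) < missing] <- NA
  d
}

test_that("complete data makes the panel identical to the single-fit path", {
  ihc <- make_ihc(shift = 60, seed = 21)
  p5 <- fit_ihc_panel(ihc, n_imputations = 5, seed = 2)
  p1 <- fit_ihc_panel(ihc, n_imputations = 1, seed = 2)
  expect_equal(p5$regions$effect, p1$regions$effect, tolerance = 1e-12)
  expect_equal(p5$regions$p_raw, p1$regions$p_raw, tolerance = 1e-12)
  # and the pooled SE carries no between-imputation component
  expect_equal(p5$regions$pr_sup, p1$regions$pr_sup, tolerance = 0.02)
})

test_that("panel output respects the BH and credibility-interval contracts", {
  ihc <- make_ihc(shift = 40, missing = 0.08, seed = 5)
  panel <- fit_ihc_panel(ihc, seed = 3)
  expect_equal(nrow(panel$regions), 8)
  expect_true(all(panel$regions$p_bh >= panel$regions$p_raw))
  expect_true(all(panel$regions$cri_lo <= panel$regions$effect &
                    panel$regions$effect <= panel$regions$cri_hi))
  expect_s3_class(panel$overall, "posterior_summary")
})

test_that("a uniform +1 SD regional shift is detected with high probability", {
  hits <- vapply(1:25, function(r) {
    ihc <- make_ihc(n = 12, shift = 78, seed = 500 + r)  # ~1 SD of density
    fit_ihc_panel(ihc, n_imputations = 2, n_draws = 4000,
                  seed = r)$overall$pr_sup > 0.95
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("panel validation rejects empty and mostly-missing regions", {
  ihc <- make_ihc(seed = 9)
  ihc$density[ihc$region == "Hip"] <- NA
  expect_error(fit_ihc_panel(ihc), "no observed values")
  ihc2 <- make_ihc(seed = 9)
  idx <- which(ihc2$region == "THAL")
  ihc2$density[idx[1:20]] <- NA
  expect_error(fit_ihc_panel(ihc2), "50%")
})

test_that("TUNEL-style benefit direction flips the superiority side", {
  ihc <- make_ihc(shift = -60, seed = 33)
  up <- fit_ihc_panel(ihc, direction = "higher", seed = 1)
  down <- fit_ihc_panel(ihc, direction = "lower", seed = 1)
  expect_gt(down$overall$pr_sup, 0.9)
  expect_lt(up$overall$pr_sup, 0.1)
})
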