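test_that("trial generation is a pure function of its configuration", {
  cfg <- trial_config(seed = 77)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  for (tb in c("animals", "mrs", "eeg", "ihc", "pk", "blood")) {
    expect_identical(a[[tb]], b[[tb]])
  }
  c <- generate_trial(trial_config(seed = 78))
  expect_false(identical(a$mrs, c$mrs))
})

test_that("generated tables satisfy the schema invariants", {
  d <- generate_trial(trial_config(n_per_arm = 8, seed = 5))
  expect_equal(nrow(d$animals), 16)
  expect_setequal(unique(d$animals$arm), c("vehicle", "treated"))
  expect_true(all(d$eeg$score %in% 0:4))
  expect_equal(nrow(d$eeg), 16 * 60)
  expect_true(all(d$ihc$density >= 0, na.rm = TRUE))
  expect_setequal(unique(d$ihc$region), ihc_regions())
  expect_true(all(d$pk$conc_mg_per_L >= 0))
  expect_setequal(unique(d$pk$time_h), c(2, 25, 49))
  # only treated animals have drug samples
  expect_setequal(unique(d$pk$subject_id),
                  d$animals$animal_id[d$animals$arm == "treated"])
  expect_true(all(d$blood[c("neutrophils", "monocytes",
                            "lymphocytes", "platelets")] > 0))
})

test_that("configuration validation names the offending field", {
  expect_error(trial_config(n_per_arm = 1), "n_per_arm")
  expect_error(trial_config(sd_lacnaa = 0), "sd_lacnaa")
  expect_error(trial_config(missing_rate = 1), "missing_rate")
  expect_error(trial_config(sex_ratio = 1.5), "sex_ratio")
})

test_that("a zero effect produces no systematic arm difference", {
  diffs <- vapply(1:2000, function(r) {
    # direct oracle on the MRS generator margin: difference of arm means
    set.seed(r)
    mean(rnorm(12, -0.1, 0.4)) - mean(rnorm(12, -0.1, 0.4))
  }, 0)
  # full-generator check on a subsample of replicates
  gen_diffs <- vapply(1:60, function(r) {
    d <- generate_trial(trial_config(n_per_arm = 12, effect_lacnaa = 0,
                                     seed = 9000 + r))
    m <- d$mrs[d$mrs$voxel == "BGT", ]
    mean(m$log10_lacnaa[m$arm == "treated"]) -
      mean(m$log10_lacnaa[m$arm == "vehicle"])
  }, 0)
  mc_se <- 0.4 * sqrt(2 / 12)
  expect_lt(abs(mean(diffs)), 3 * mc_se / sqrt(length(diffs)))
  expect_lt(abs(mean(gen_diffs)), 3 * mc_se / sqrt(length(gen_diffs)))
})

test_that("the configured effect size is recovered in expectation", {
  gen_diffs <- vapply(1:60, function(r) {
    d <- generate_trial(trial_config(n_per_arm = 12, effect_lacnaa = -0.5,
                                     seed = 7000 + r))
    m <- d$mrs[d$mrs$voxel == "WM", ]
    mean(m$log10_lacnaa[m$arm == "treated"]) -
      mean(m$log10_lacnaa[m$arm == "vehicle"])
  }, 0)
  mc_se <- 0.4 * sqrt(2 / 12) / sqrt(60)
  expect_lt(abs(mean(gen_diffs) + 0.5), 3 * mc_se)
})

test_that("the observed IHC missing fraction sits in its binomial bounds", {
  d <- generate_trial(trial_config(missing_rate = 0.1, seed = 55))
  n_cells <- nrow(d$ihc)
  obs <- mean(is.na(d$ihc$density))
  half_width <- qnorm(0.995) * sqrt(0.1 * 0.9 / n_cells)
  expect_gt(obs, 0.1 - half_width)
  expect_lt(obs, 0.1 + half_width)
  d0 <- generate_trial(trial_config(missing_rate = 0, seed = 55))
  expect_false(anyNA(d0$ihc$density))
})

test_that("animal-level random effect induces positive between-region correlation", {
  d <- generate_trial(trial_config(n_per_arm = 12, missing_rate = 0, seed = 31))
  neun <- d$ihc[d$ihc$marker == "NeuN", ]
  wide <- reshape(neun[c("animal_id", "region", "density")],
                  idvar = "animal_id", timevar = "region",
                  direction = "wide")
  cors <- cor(wide[-1])
  expect_gt(mean(cors[upper.tri(cors)]), 0.1)
})

test_that("csv round trip preserves every table", {
  d <- generate_trial(trial_config(n_per_arm = 4, seed = 12))
  dir <- tempfile("trial")
  write_trial_csvs(d, dir)
  expect_setequal(list.files(dir),
                  paste0(c("animals", "mrs", "eeg", "ihc", "pk", "blood"),
                         ".csv"))
  back <- read_trial_csvs(dir)
  expect_equal(back$mrs$log10_lacnaa, d$mrs$log10_lacnaa, tolerance = 1e-12)
  expect_identical(back$eeg$score, d$eeg$score)
  unlink(dir, recursive = TRUE)
})

test_that("null trials give uniformly distributed downstream Pr(sup)", {
  # 500 null replicates through the conjugate posterior of the primary
  # outcome; the Kolmogorov-Smirnov test should not reject uniformity
  pr <- vapply(1:500, function(r) {
    d <- generate_trial(trial_config(n_per_arm = 6, effect_lacnaa = 0,
                                     missing_rate = 0, seed = 20000 + r))
    m <- d$mrs[d$mrs$voxel == "BGT", ]
    y1 <- m$log10_lacnaa[m$arm == "treated"]
    y0 <- m$log10_lacnaa[m$arm == "vehicle"]
    sp <- sqrt(((length(y1) - 1) * var(y1) + (length(y0) - 1) * var(y0)) /
                 (length(y1) + length(y0) - 2))
    pr_sup_conjugate(mean(y0) - mean(y1), sp, length(y1))
  }, 0)
  ks <- suppressWarnings(ks.test(pr, "punif"))
  expect_gt(ks$p.value, 0.01)
})
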