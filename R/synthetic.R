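#' Configuration of a synthetic two-arm piglet trial
#'
#' Defines the generating process of a synthetic neuroprotection study with
#' the statistical structure the downstream analyses assume: lognormal-scale
#' (Gaussian on log10) Lac/NAA per voxel, bounded ordinal aEEG background
#' trajectories with post-insult suppression and stochastic recovery,
#' correlated regional immunohistochemistry densities with
#' missing-completely-at-random cells, two-compartment infusion
#' pharmacokinetic samples with proportional error, and serial blood counts.
#' Defaults mirror the study conditions: 12 animals per arm, a 0.5 log10-unit
#' Lac/NAA reduction under treatment, SD 0.4.
#'
#' @param n_per_arm Animals per arm (>= 2; default 12).
#' @param effect_lacnaa Treated-minus-vehicle difference in log10 Lac/NAA
#'   (default -0.5; negative = benefit).
#' @param sd_lacnaa Between-animal SD of log10 Lac/NAA (default 0.4).
#' @param eeg_recovery_shift Added hourly recovery rate (score units/h) in
#'   the treated arm (default 0.01).
#' @param ihc_effects Named list per marker of the treated-arm mean shift in
#'   cells/mm2, applied uniformly over regions. Defaults give a moderate
#'   neuronal preservation and microgliosis signal.
#' @param ihc_region_sd Between-region SD of the regional baseline offsets.
#' @param ihc_animal_sd Animal-level random-effect SD inducing exchangeable
#'   between-region correlation (the correlation is
#'   `ihc_animal_sd^2 / (ihc_animal_sd^2 + ihc_resid_sd^2)`).
#' @param ihc_resid_sd Residual SD of regional densities.
#' @param missing_rate Fraction of IHC cells set missing completely at
#'   random, in `[0, 1)`.
#' @param sex_ratio Fraction of male animals (default 0.5).
#' @param pk_params `pk_params` population values for the treated arm's drug
#'   sampling.
#' @param seed Integer seed; every generated table is a pure function of the
#'   configuration including this seed.
#' @return A validated list of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = 12, effect_lacnaa = -0.5,
                         sd_lacnaa = 0.4, eeg_recovery_shift = 0.01,
                         ihc_effects = list(NeuN = 60, Iba1 = 40,
                                            TUNEL = -15, OLIG2 = 30),
                         ihc_region_sd = 40, ihc_animal_sd = 50,
                         ihc_resid_sd = 60,
                         missing_rate = 0.05, sex_ratio = 0.5,
                         pk_params = pk_params_default(), seed = 1L) {
  if (!is.numeric(n_per_arm) || n_per_arm < 2) {
    stop("invalid 'n_per_arm': must be an integer >= 2")
  }
  if (!is.numeric(sd_lacnaa) || sd_lacnaa <= 0) {
    stop("invalid 'sd_lacnaa': must be > 0")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("invalid 'missing_rate': must be in [0, 1)")
  }
  if (sex_ratio < 0 || sex_ratio > 1) {
    stop("invalid 'sex_ratio': must be in [0, 1]")
  }
  structure(list(n_per_arm = as.integer(n_per_arm),
                 effect_lacnaa = effect_lacnaa, sd_lacnaa = sd_lacnaa,
                 eeg_recovery_shift = eeg_recovery_shift,
                 ihc_effects = ihc_effects, ihc_region_sd = ihc_region_sd,
                 ihc_animal_sd = ihc_animal_sd, ihc_resid_sd = ihc_resid_sd,
                 missing_rate = missing_rate, sex_ratio = sex_ratio,
                 pk_params = pk_params, seed = as.integer(seed)),
            class = "trial_config")
}

#' The fixed eight-region vocabulary of the histology panel
#'
#' Cingulate gyrus, sensorimotor cortex, periventricular white matter,
#' internal capsule, hippocampus, caudate nucleus, putamen, thalamus.
#' @return Character vector of the 8 region codes.
#' @export
ihc_regions <- function() {
  c("cCTX", "sCTX", "PvWM", "IC", "Hip", "CAUD", "PTMN", "THAL")
}

#' Simulate one hourly aEEG background score trajectory
#'
#' Bounded latent-drift process: a latent background level starts suppressed
#' after the insult, drifts upward at `recovery_rate` score units per hour,
#' accumulates Gaussian disturbances, and is clamped to `[0, 4]` and rounded
#' to the integer score. The clamping reproduces the plateaus at 0
#' (isoelectric) and 4 (normal voltage) typical of such recordings.
#'
#' @param hours Length of the recording in hours (>= 6, one full epoch).
#' @param start_level Latent level at hour 1 (score units; default 0.5,
#'   a suppressed post-insult background).
#' @param recovery_rate Latent drift (score units/h), >= 0.
#' @param noise_sd SD of the hourly latent disturbance (score units).
#' @param seed Optional integer seed (`NULL` leaves the RNG state alone so
#'   callers can embed the series in a larger generation).
#' @return Integer vector of hourly scores in 0..4.
#' @export
generate_eeg_series <- function(hours = 60L, start_level = 0.5,
                                recovery_rate = 0.05, noise_sd = 0.5,
                                seed = NULL) {
  if (hours < 6) stop("'hours' must be >= 6 (one complete 6-h epoch)")
  if (!is.null(seed)) set.seed(seed)
  latent <- start_level + recovery_rate * (seq_len(hours) - 1) +
    cumsum(stats::rnorm(hours, 0, noise_sd))
  as.integer(round(pmin(pmax(latent, 0), 4)))
}

#' Simulate timed drug concentrations with proportional error
#'
#' Observations are the closed-form model concentrations perturbed
#' multiplicatively: obs = pred x (1 + e), e ~ Normal(0, cv_prop^2). A zero
#' model concentration (before the first dose) stays exactly zero.
#'
#' @param params `pk_params` for the subject.
#' @param regimen `dose_regimen`.
#' @param times Sampling times (h), all >= 0.
#' @param cv_prop Proportional error SD, >= 0.
#' @param seed Optional integer seed.
#' @return Data frame `time_h`, `conc_mg_per_L`.
#' @export
generate_pk_samples <- function(params, regimen, times, cv_prop = 0.2,
                                seed = NULL) {
  if (any(times < 0)) stop("negative sampling time")
  if (cv_prop < 0) stop("'cv_prop' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pred <- pk_concentration(times, regimen, params)
  eps <- stats::rnorm(length(times), 0, cv_prop)
  data.frame(time_h = times, conc_mg_per_L = pred * (1 + eps))
}

#' Generate a complete synthetic trial dataset
#'
#' Produces all per-animal tables used downstream. Identical configurations
#' (including the seed) give byte-identical datasets.
#'
#' @param config A `trial_config`.
#' @return A list of class `trial_dataset` with data frames:
#'   \describe{
#'     \item{animals}{`animal_id`, `arm`, `sex`, `weight_kg`}
#'     \item{mrs}{per animal x voxel (BGT, WM): `log10_lacnaa`}
#'     \item{eeg}{per animal x hour (1..60): `score` in 0..4}
#'     \item{ihc}{per animal x 8 regions x 4 markers: `density` (cells/mm2,
#'       `NA` where missing)}
#'     \item{pk}{treated animals only: `subject_id`, `time_h`,
#'       `conc_mg_per_L` at 2, 25 and 49 h post-insult}
#'     \item{blood}{per animal x timepoint (0, 6, 24, 48, 60 h):
#'       `neutrophils`, `monocytes`, `lymphocytes`, `platelets` (x10^9/L)}
#'   }
#' @export
generate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  n <- config$n_per_arm
  ids <- sprintf("P%02d", seq_len(2 * n))
  arm <- rep(c("vehicle", "treated"), each = n)
  sex <- ifelse(stats::runif(2 * n) < config$sex_ratio, "male", "female")
  weight <- pmax(stats::rnorm(2 * n, 2.0, 0.25), 1.2)
  animals <- data.frame(animal_id = ids, arm = arm, sex = sex,
                        weight_kg = round(weight, 2))

  # MRS: Gaussian on the log10 scale; post-insult elevation of Lac/NAA with a
  # slightly higher baseline in the deep grey voxel; treated arm shifted by
  # the configured effect in both voxels
  voxels <- c(BGT = -0.10, WM = -0.20)
  mrs <- do.call(rbind, lapply(names(voxels), function(v) {
    mu <- voxels[[v]] + ifelse(arm == "treated", config$effect_lacnaa, 0)
    data.frame(animal_id = ids, arm = arm, sex = sex, voxel = v,
               log10_lacnaa = stats::rnorm(2 * n, mu, config$sd_lacnaa))
  }))

  # aEEG: suppressed start, slow stochastic recovery; treated arm recovers
  # faster by the configured shift
  eeg <- do.call(rbind, lapply(seq_len(2 * n), function(i) {
    rate <- 0.05 + if (arm[i] == "treated") config$eeg_recovery_shift else 0
    data.frame(animal_id = ids[i], arm = arm[i], hour = 1:60,
               score = generate_eeg_series(60L, start_level = 0.5,
                                           recovery_rate = rate,
                                           noise_sd = 0.5))
  }))

  # IHC: animal random effect induces exchangeable between-region correlation
  markers <- names(config$ihc_effects)
  marker_base <- c(NeuN = 500, Iba1 = 220, TUNEL = 80, OLIG2 = 300)
  regions <- ihc_regions()
  region_off <- stats::rnorm(length(regions), 0, config$ihc_region_sd)
  names(region_off) <- regions
  ihc <- do.call(rbind, lapply(markers, function(m) {
    b_animal <- stats::rnorm(2 * n, 0, config$ihc_animal_sd)
    base <- if (m %in% names(marker_base)) marker_base[[m]] else 200
    do.call(rbind, lapply(seq_along(regions), function(r) {
      mu <- base + region_off[r] + b_animal +
        ifelse(arm == "treated", config$ihc_effects[[m]], 0)
      data.frame(animal_id = ids, arm = arm, sex = sex, marker = m,
                 region = regions[r],
                 density = pmax(stats::rnorm(2 * n, mu, config$ihc_resid_sd), 0))
    }))
  }))
  if (config$missing_rate > 0) {
    drop <- stats::runif(nrow(ihc)) < config$missing_rate
    ihc$density[drop] <- NA_real_
  }

  # PK: treated animals dosed 20 mg/kg over 1 h at 1, 24, 48 h; sampled at
  # the study's observation times with lognormal between-subject variability
  treated_idx <- which(arm == "treated")
  pp <- config$pk_params
  pk <- do.call(rbind, lapply(treated_idx, function(i) {
    reg <- regimen_azithromycin(weight = weight[i])
    eta <- stats::rnorm(2, 0, c(pp$omega[["CL"]], pp$omega[["V1"]]))
    subj <- pk_params(pp$CL * exp(eta[1]), pp$V1 * exp(eta[2]), pp$Q, pp$V2)
    samp <- generate_pk_samples(subj, reg, times = c(2, 25, 49),
                                cv_prop = pp$cv_prop)
    cbind(subject_id = ids[i], samp)
  }))

  # serial blood counts: lognormal around a post-insult inflammatory course
  tp <- c(0, 6, 24, 48, 60)
  neut_mu <- c(4, 9, 7, 5, 4.5)   # x10^9/L, neutrophilia peaking early
  mono_mu <- c(0.6, 1.0, 1.2, 0.9, 0.8)
  lymph_mu <- c(3.5, 2.0, 2.5, 3.0, 3.2)
  plt_mu <- c(350, 300, 280, 300, 320)
  b_blood <- stats::rnorm(2 * n, 0, 0.15)  # animal-level log-scale effect
  blood <- do.call(rbind, lapply(seq_along(tp), function(k) {
    data.frame(animal_id = ids, arm = arm, timepoint_h = tp[k],
               neutrophils = stats::rlnorm(2 * n, log(neut_mu[k]) + b_blood, 0.3),
               monocytes = stats::rlnorm(2 * n, log(mono_mu[k]) + b_blood, 0.3),
               lymphocytes = stats::rlnorm(2 * n, log(lymph_mu[k]) + b_blood, 0.25),
               platelets = stats::rlnorm(2 * n, log(plt_mu[k]) + b_blood, 0.2))
  }))

  rownames(mrs) <- rownames(eeg) <- rownames(ihc) <- rownames(blood) <- NULL
  if (!is.null(pk)) rownames(pk) <- NULL
  structure(list(animals = animals, mrs = mrs, eeg = eeg, ihc = ihc,
                 pk = pk, blood = blood, config = config),
            class = "trial_dataset")
}

#' Write a trial dataset as the canonical tidy CSV files
#'
#' One file per table: `animals.csv`, `mrs.csv`, `eeg.csv`, `ihc.csv`,
#' `pk.csv`, `blood.csv`, with the fixed column names documented in
#' [generate_trial()].
#'
#' @param dataset A `trial_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_trial_csvs <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("animals", "mrs", "eeg", "ihc", "pk", "blood")
  paths <- vapply(tables, function(tb) {
    path <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(dataset[[tb]], path, row.names = FALSE)
    path
  }, "")
  invisible(paths)
}

#' Read the canonical CSVs back into a trial dataset
#'
#' @param dir Directory containing the canonical CSV files.
#' @return A `trial_dataset` (without a generating `config`).
#' @export
read_trial_csvs <- function(dir) {
  tables <- c("animals", "mrs", "eeg", "ihc", "pk", "blood")
  out <- lapply(tables, function(tb) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) stop("missing input file: ", path)
    utils::read.csv(path)
  })
  names(out) <- tables
  out$config <- NULL
  structure(out, class = "trial_dataset")
}
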