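#' Validate the canonical input CSVs against their schemas
#'
#' Checks each present file for required columns, types and ranges: aEEG
#' scores integer in 0..4, densities and cell counts non-negative,
#' concentrations non-negative, arm labels in the vehicle/treated vocabulary,
#' IHC regions in the fixed 8-region vocabulary. Violations are reported, not
#' thrown.
#'
#' @param dir Directory holding the canonical CSVs (any subset of
#'   animals/mrs/eeg/ihc/pk/blood).
#' @return A data frame report with columns `file`, `check`, `ok`, `detail`;
#'   zero rows with `ok = FALSE` means a clean panel.
#' @export
validate_inputs <- function(dir) {
  req_cols <- list(
    animals = c("animal_id", "arm", "sex", "weight_kg"),
    mrs = c("animal_id", "arm", "voxel", "log10_lacnaa"),
    eeg = c("animal_id", "arm", "hour", "score"),
    ihc = c("animal_id", "arm", "sex", "marker", "region", "density"),
    pk = c("subject_id", "time_h", "conc_mg_per_L"),
    blood = c("animal_id", "arm", "timepoint_h", "neutrophils", "monocytes",
              "lymphocytes", "platelets"))
  rows <- list()
  note <- function(file, check, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(file = file, check = check,
                                             ok = ok, detail = detail)
  }
  for (tb in names(req_cols)) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) { note(tb, "present", FALSE, "file missing"); next }
    d <- utils::read.csv(path)
    missing_cols <- setdiff(req_cols[[tb]], names(d))
    note(tb, "columns", length(missing_cols) == 0L,
         paste(missing_cols, collapse = ", "))
    if (length(missing_cols)) next
    if ("arm" %in% names(d)) {
      bad <- setdiff(unique(d$arm), c("vehicle", "treated"))
      note(tb, "arm_labels", length(bad) == 0L, paste(bad, collapse = ", "))
    }
    if (tb == "eeg") {
      bad <- !is.na(d$score) &
        (d$score < 0 | d$score > 4 | d$score != round(d$score))
      note(tb, "score_range", sum(bad) == 0L,
           if (any(bad)) sprintf("%d scores outside 0..4", sum(bad)) else "")
    }
    if (tb == "ihc") {
      bad_r <- setdiff(unique(d$region), ihc_regions())
      note(tb, "region_vocabulary", length(bad_r) == 0L,
           paste(bad_r, collapse = ", "))
      neg <- !is.na(d$density) & d$density < 0
      note(tb, "density_nonneg", sum(neg) == 0L,
           if (any(neg)) sprintf("%d negative densities", sum(neg)) else "")
    }
    if (tb == "pk") {
      neg <- !is.na(d$conc_mg_per_L) & d$conc_mg_per_L < 0
      note(tb, "conc_nonneg", sum(neg) == 0L,
           if (any(neg)) sprintf("%d negative concentrations", sum(neg)) else "")
    }
    if (tb == "blood") {
      counts <- c("neutrophils", "monocytes", "lymphocytes", "platelets")
      neg <- vapply(counts, function(cl) sum(d[[cl]] < 0, na.rm = TRUE), 0L)
      note(tb, "counts_nonneg", sum(neg) == 0L,
           paste(names(neg)[neg > 0], collapse = ", "))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on one trial
#'
#' Orchestrates generate (or load) - score - analyze into one reproducible
#' run: the MRS Bayesian regression for both voxels, the aEEG mixed model,
#' the regional IHC panels per marker, SIRI from the blood counts (analysed
#' with the repeated-measures ANOVA), and the PK population fit. Each outcome
#' family is run independently; a failure in one is recorded in the manifest
#' and does not abort the others. All randomness is governed by `seed`.
#'
#' @param input_dir Directory of canonical CSVs; exactly one of `input_dir`
#'   and `synth_config` must be given.
#' @param synth_config A `trial_config` for synthetic generation.
#' @param out_dir Output directory for `results.csv` and `manifest.json`
#'   (`NULL` = no files written).
#' @param seed Integer master seed.
#' @param sampler Named list of sampler sizes (`n_draws` for the regression
#'   posteriors, `n_iter`/`n_warmup` per Gibbs chain, `n_chains`).
#' @param fit_pk Whether to run the population PK fit (pooled mode).
#' @return A list of class `pipeline_run`: `results` (tidy table: `outcome`,
#'   `effect`, `cri_lo`, `cri_hi`, `pr_sup`, `p_raw`, `p_bh`), `fits` (the
#'   underlying model objects), `manifest` (seeds, settings, per-stage
#'   status).
#' @export
run_pipeline <- function(input_dir = NULL, synth_config = NULL,
                         out_dir = NULL, seed = 1L,
                         sampler = list(n_draws = 8000, n_iter = 1500,
                                        n_warmup = 500, n_chains = 4),
                         fit_pk = TRUE) {
  if (is.null(input_dir) == is.null(synth_config)) {
    stop("exactly one of 'input_dir' or 'synth_config' must be supplied")
  }
  dataset <- if (!is.null(input_dir)) read_trial_csvs(input_dir)
             else generate_trial(synth_config)
  stages <- list()
  results <- list()
  fits <- list()
  run_stage <- function(name, expr) {
    r <- tryCatch(list(ok = TRUE, value = expr, error = NA_character_),
                  error = function(e) list(ok = FALSE, value = NULL,
                                           error = conditionMessage(e)))
    stages[[name]] <<- list(ok = r$ok, error = r$error)
    r$value
  }
  add_result <- function(outcome, effect, cri, pr_sup,
                         p_raw = NA_real_, p_bh = NA_real_) {
    results[[length(results) + 1L]] <<- data.frame(
      outcome = outcome, effect = effect, cri_lo = cri[1], cri_hi = cri[2],
      pr_sup = pr_sup, p_raw = p_raw, p_bh = p_bh)
  }

  for (v in c("BGT", "WM")) {
    fit <- run_stage(paste0("mrs_", v), fit_mrs_model(
      dataset$mrs, voxel = v, n_draws = sampler$n_draws,
      n_chains = sampler$n_chains, seed = seed))
    if (!is.null(fit)) {
      fits[[paste0("mrs_", v)]] <- fit
      add_result(paste0("mrs_lacnaa_", v), fit$point, fit$cri95, fit$pr_sup)
    }
  }

  eeg_fit <- run_stage("eeg", fit_eeg_model(
    dataset$eeg, n_iter = sampler$n_iter, n_warmup = sampler$n_warmup,
    n_chains = sampler$n_chains, seed = seed + 1L))
  if (!is.null(eeg_fit)) {
    fits$eeg <- eeg_fit
    add_result("eeg_overall", eeg_fit$overall$point, eeg_fit$overall$cri95,
               eeg_fit$overall$pr_sup)
  }

  markers <- unique(dataset$ihc$marker)
  for (m in markers) {
    dir_m <- if (identical(m, "TUNEL")) "lower" else "higher"
    panel <- run_stage(paste0("ihc_", m), fit_ihc_panel(
      dataset$ihc[dataset$ihc$marker == m, ], direction = dir_m,
      n_draws = sampler$n_draws, seed = seed + 2L))
    if (!is.null(panel)) {
      fits[[paste0("ihc_", m)]] <- panel
      add_result(paste0("ihc_", m, "_overall"), panel$overall$point,
                 panel$overall$cri95, panel$overall$pr_sup)
      for (i in seq_len(nrow(panel$regions))) {
        r <- panel$regions[i, ]
        add_result(paste0("ihc_", m, "_", r$region), r$effect,
                   c(r$cri_lo, r$cri_hi), r$pr_sup, r$p_raw, r$p_bh)
      }
    }
  }

  siri_fit <- run_stage("siri", {
    b <- dataset$blood
    b$value <- siri(b$neutrophils, b$monocytes, b$lymphocytes)
    b$timepoint <- b$timepoint_h
    fit_repeated(b)
  })
  if (!is.null(siri_fit)) fits$siri <- siri_fit

  if (fit_pk && !is.null(dataset$pk) && nrow(dataset$pk) > 0) {
    pk_fit <- run_stage("pk", {
      weights <- dataset$animals$weight_kg
      names(weights) <- dataset$animals$animal_id
      regs <- lapply(unique(dataset$pk$subject_id), function(id) {
        regimen_azithromycin(weight = unname(weights[id]))
      })
      names(regs) <- unique(dataset$pk$subject_id)
      fit_population(dataset$pk, regs, method = "pooled")
    })
    if (!is.null(pk_fit)) fits$pk <- pk_fit
  }

  results_df <- if (length(results)) do.call(rbind, results) else
    data.frame(outcome = character(), effect = numeric(),
               cri_lo = numeric(), cri_hi = numeric(), pr_sup = numeric(),
               p_raw = numeric(), p_bh = numeric())
  rownames(results_df) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("piglettrials")),
    seed = seed, sampler = sampler,
    input = if (!is.null(input_dir)) input_dir else "synthetic",
    synth_seed = if (!is.null(synth_config)) synth_config$seed else NA,
    stages = stages,
    results_hash = digest_table(results_df))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(results_df, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(results = results_df, fits = fits, manifest = manifest),
            class = "pipeline_run")
}

# stable content hash of a results table (platform-independent text digest)
digest_table <- function(df) {
  txt <- paste(utils::capture.output(
    utils::write.csv(format(df, digits = 12), row.names = FALSE)),
    collapse = "\n")
  # simple polynomial rolling hash over the serialized text; avoids an
  # external digest dependency (exact integer arithmetic below 2^53)
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 4294967291
  # h is a double below 2^32; format as hex via two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @export
print.pipeline_run <- function(x, ...) {
  ok <- vapply(x$manifest$stages, function(s) isTRUE(s$ok), TRUE)
  cat(sprintf("Pipeline run (seed %d): %d/%d stages ok\n",
              x$manifest$seed, sum(ok), length(ok)))
  print(utils::head(x$results, 20), digits = 4, row.names = FALSE)
  if (nrow(x$results) > 20) cat("...", nrow(x$results) - 20, "more rows\n")
  invisible(x)
}
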