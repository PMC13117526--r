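#' Repeated-measures mixed ANOVA for longitudinal panels
#'
#' The frequentist analysis used for physiology, biochemistry and cytokine
#' tables: a linear mixed model with fixed effects of treatment, time and
#' their interaction plus an animal-level random intercept. Group contrasts
#' are least-squares means per arm-by-time cell with 95% confidence intervals
#' for the treated-minus-vehicle difference and Satterthwaite-approximate
#' degrees of freedom (lme4/lmerTest fit, emmeans contrasts).
#'
#' @param table Data frame with columns `animal_id`, `arm`, `timepoint`,
#'   `value` (one row per animal and timepoint for a single analyte).
#' @return A list of class `repeated_fit`: `lsmeans` (per arm x time),
#'   `differences` (per time: estimate, `lower`, `upper`, `p`), `anova`
#'   (type III tests for treatment, time, interaction), and the fitted
#'   `model`.
#' @export
fit_repeated <- function(table) {
  stopifnot(all(c("animal_id", "arm", "timepoint", "value") %in% names(table)))
  d <- table[!is.na(table$value), ]
  d$arm <- factor(d$arm)
  d$timepoint <- factor(d$timepoint)
  if (nlevels(d$arm) < 2L) stop("both arms must be present")
  shared <- Reduce(intersect, lapply(split(d$timepoint, d$arm), unique))
  if (nlevels(d$timepoint) >= 2L && length(shared) < 2L) {
    stop("arms must share at least 2 timepoints")
  }
  tab <- table(d$animal_id, d$timepoint)
  if (any(tab > 1L)) stop("duplicate (animal, timepoint) rows")

  if (nlevels(d$timepoint) == 1L) {
    # single timepoint: the mixed model degenerates to a two-sample comparison
    fit <- stats::lm(value ~ arm, data = d)
    emm <- emmeans::emmeans(fit, ~ arm)
    diffs <- as.data.frame(confint(emmeans::contrast(emm, "revpairwise")))
    pvals <- as.data.frame(emmeans::contrast(emm, "revpairwise"))$p.value
    anova_tab <- stats::anova(fit)
  } else {
    fit <- lmerTest::lmer(value ~ arm * timepoint + (1 | animal_id), data = d)
    emm <- emmeans::emmeans(fit, ~ arm | timepoint,
                            lmer.df = "satterthwaite")
    contr <- emmeans::contrast(emm, "revpairwise", by = "timepoint")
    diffs <- as.data.frame(confint(contr))
    pvals <- as.data.frame(contr)$p.value
    anova_tab <- stats::anova(fit, type = 3)
  }
  diffs$p <- pvals
  structure(list(lsmeans = as.data.frame(emm),
                 differences = diffs,
                 anova = as.data.frame(anova_tab),
                 model = fit),
            class = "repeated_fit")
}

#' @export
print.repeated_fit <- function(x, ...) {
  cat("Repeated-measures mixed ANOVA\n")
  print(x$anova, digits = 4)
  cat("\nArm differences (LS means):\n")
  print(x$differences, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Log10-transform an analyte with detection-limit handling
#'
#' Replaces an analyte's values with their log10. Values at or below a
#' declared detection limit are first replaced by half that limit (the
#' conventional substitution) and flagged; nonpositive values with no
#' declared limit are an error rather than silent NaNs.
#'
#' @param table Data frame with a numeric `value` column.
#' @param detection_limit Optional positive detection limit in the analyte's
#'   units.
#' @return The table with `value` replaced by log10 values and a logical
#'   `below_detection` column.
#' @export
log10_analyte <- function(table, detection_limit = NULL) {
  stopifnot("value" %in% names(table))
  v <- table$value
  below <- rep(FALSE, length(v))
  if (!is.null(detection_limit)) {
    stopifnot(detection_limit > 0)
    below <- !is.na(v) & v <= detection_limit
    v[below] <- detection_limit / 2
  }
  if (any(!is.na(v) & v <= 0)) {
    stop("nonpositive values present and no detection limit declared")
  }
  table$value <- log10(v)
  table$below_detection <- below
  table
}
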