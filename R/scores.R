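#' Microglial ramification index for one sampling field
#'
#' Quantifies microglial process complexity from grid-based morphometry of
#' Iba1-stained sections. A 50 x 50 micrometre sampling grid with 3 horizontal
#' and 3 vertical lines is placed over a field of view; the number of
#' Iba1+ process crossings of the gridlines and the number of complete somata
#' inside the grid are counted. The index is
#' \deqn{RI = \frac{(\mathrm{intersections})^2}{\mathrm{somata}}.}
#' High values indicate ramified (resting) microglia; amoeboid activated
#' microglia with few processes score low.
#'
#' @param intersections Non-negative integer count of process-gridline
#'   crossings in the field.
#' @param somata Positive integer count of complete cell bodies within the
#'   grid. Fields with zero somata leave the index undefined and must be
#'   excluded upstream; passing 0 is an error, never a silent 0.
#' @return The ramification index (unitless, non-negative scalar).
#' @examples
#' ramification_index(4, 2) # 8
#' @export
ramification_index <- function(intersections, somata) {
  stopifnot(length(intersections) == 1L, length(somata) == 1L)
  if (is.na(intersections) || is.na(somata) ||
      intersections < 0 || intersections != round(intersections) ||
      somata != round(somata)) {
    stop("'intersections' and 'somata' must be non-negative integers")
  }
  if (somata < 1) {
    stop("ramification index undefined for a field with 0 somata; exclude the field")
  }
  intersections^2 / somata
}

#' Mean ramification index over the fields of one brain region
#'
#' Averages per-field ramification indices over the valid fields of a region.
#' Fields with zero somata are excluded (the per-field index is undefined
#' there). By convention 6 fields are assessed per region except the
#' hippocampus, present in a single section, where 3 fields are expected; a
#' mismatch produces a warning, not an error.
#'
#' @param fields A data frame with integer columns `intersections` and
#'   `somata`, one row per field.
#' @param region Region label; `"Hip"` switches the expected field count to 3.
#' @return A list with `mean_ri`, `n_fields` (valid fields used) and
#'   `n_excluded`.
#' @export
region_ri <- function(fields, region = NA_character_) {
  stopifnot(is.data.frame(fields),
            all(c("intersections", "somata") %in% names(fields)))
  valid <- !is.na(fields$somata) & fields$somata >= 1 & !is.na(fields$intersections)
  if (!any(valid)) stop("no valid fields (all have 0 somata or missing counts)")
  expected <- if (identical(region, "Hip")) 3L else 6L
  if (!is.na(region) && sum(valid) != expected) {
    warning(sprintf("region %s: %d valid fields, expected %d",
                    region, sum(valid), expected))
  }
  ri <- mapply(ramification_index,
               fields$intersections[valid], fields$somata[valid])
  list(mean_ri = mean(ri), n_fields = sum(valid), n_excluded = sum(!valid))
}

#' Systemic inflammation response index
#'
#' SIRI = neutrophils x monocytes / lymphocytes, all counts in 10^9 cells/L
#' from the same full blood count. Unitless (one factor of 10^9/L cancels).
#'
#' @param neutrophils,monocytes,lymphocytes Cell counts (x 10^9/L), each >= 0;
#'   lymphocytes must be > 0 or the index is undefined.
#' @return SIRI (numeric, vectorised over equal-length inputs).
#' @examples
#' siri(4, 1, 2) # 2
#' @export
siri <- function(neutrophils, monocytes, lymphocytes) {
  if (any(is.na(neutrophils) | is.na(monocytes) | is.na(lymphocytes)) ||
      any(neutrophils < 0) || any(monocytes < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (any(lymphocytes <= 0)) {
    stop("SIRI undefined when lymphocytes are 0")
  }
  neutrophils * monocytes / lymphocytes
}

#' Aggregate hourly aEEG background scores into 6-hour epochs
#'
#' Hourly background scores (0 = isoelectric .. 4 = continuous normal voltage)
#' are averaged over consecutive blocks of `epoch_h` hours. Missing hours are
#' dropped from their epoch mean and counted; a trailing partial block is
#' reported with `partial = TRUE` rather than silently merged.
#'
#' @param scores Numeric vector of hourly scores, each in 0..4 or `NA`.
#' @param epoch_h Epoch length in hours (default 6).
#' @return A data frame with one row per epoch: `epoch` (1-based index),
#'   `mean_score`, `n_hours` (non-missing hours contributing), `partial`.
#' @examples
#' aggregate_eeg(c(0, 1, 2, 3, 4, 4))
#' @export
aggregate_eeg <- function(scores, epoch_h = 6L) {
  if (length(scores) == 0L) stop("empty score sequence")
  if (length(scores) < epoch_h) stop("need at least one complete epoch")
  ok <- is.na(scores) | (scores >= 0 & scores <= 4 & scores == round(scores))
  if (!all(ok)) stop("scores must be integers in [0, 4] or NA")
  idx <- ceiling(seq_along(scores) / epoch_h)
  out <- do.call(rbind, lapply(unique(idx), function(e) {
    s <- scores[idx == e]
    data.frame(epoch = e,
               mean_score = if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE),
               n_hours = sum(!is.na(s)),
               partial = length(s) < epoch_h)
  }))
  rownames(out) <- NULL
  out
}

#' Classify aEEG background from voltage margins
#'
#' Rule-based background classification on the Hellstrom-Westas voltage
#' pattern scheme, mapped to the 0-4 background score: 4 = continuous normal
#' voltage, 3 = discontinuous normal voltage, 2 = burst suppression,
#' 1 = continuous low voltage, 0 = isoelectric/flat. The voltage cutoffs are
#' overridable because the criteria are defined by pattern descriptions rather
#' than a single canonical threshold table.
#'
#' @param lower_margin,upper_margin Lower and upper amplitude margins of the
#'   aEEG band (microvolts), `lower_margin <= upper_margin`.
#' @param burst_suppression Logical; a burst-suppression pattern overrides the
#'   margin rules (score 2) unless the trace is isoelectric.
#' @param cutoffs Named list of the rule thresholds (microvolts):
#'   `iso_upper` (below which the trace is isoelectric), `lower_normal`
#'   (lower margin above this = continuous), `upper_normal` (upper margin
#'   above this = normal voltage).
#' @return Integer score in 0..4.
#' @export
classify_background <- function(lower_margin, upper_margin,
                                burst_suppression = FALSE,
                                cutoffs = list(iso_upper = 2,
                                               lower_normal = 5,
                                               upper_normal = 10)) {
  if (is.na(lower_margin) || is.na(upper_margin) ||
      lower_margin < 0 || upper_margin < lower_margin) {
    stop("inconsistent voltage margins (need 0 <= lower <= upper)")
  }
  if (upper_margin < cutoffs$iso_upper) return(0L)
  if (isTRUE(burst_suppression)) return(2L)
  if (upper_margin > cutoffs$upper_normal) {
    if (lower_margin > cutoffs$lower_normal) return(4L) # continuous normal voltage
    return(3L)                                          # discontinuous
  }
  1L # continuous low voltage
}
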