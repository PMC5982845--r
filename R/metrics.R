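#' Align an estimated rate series with a reference series
#'
#' The reference is linearly interpolated onto the estimate's timestamps
#' within the overlapping time span; estimates outside the overlap are
#' dropped.
#'
#' @param est,ref [rate_series()] objects with overlapping spans.
#' @return data.frame with columns `time`, `est`, `ref`.
#' @export
align_series <- function(est, ref) {
  stopifnot(inherits(est, "rate_series"), inherits(ref, "rate_series"))
  tv_assert(length(est$times) > 0 && length(ref$times) > 0,
            "cannot align an empty series", "tv_alignment_error")
  lo <- max(min(est$times), min(ref$times))
  hi <- min(max(est$times), max(ref$times))
  keep <- est$times >= lo & est$times <= hi
  tv_assert(hi >= lo && any(keep), "series do not overlap in time", "tv_alignment_error")
  ref_at <- if (length(ref$times) == 1) rep(ref$rates, sum(keep)) else
    approx(ref$times, ref$rates, xout = est$times[keep])$y
  data.frame(time = est$times[keep], est = est$rates[keep], ref = ref_at)
}

#' Agreement statistics on aligned rate pairs
#'
#' `rmse()` is the root-mean-square difference; `relative_errors()` returns
#' `|est - ref| / ref` per pair; `eps90()` is the 90th percentile of those
#' relative errors (linear interpolation between order statistics) - the
#' conventional "spread of the error" summary.
#'
#' @param pairs data.frame from [align_series()] (columns `est`, `ref`).
#' @return `rmse()`: per-minute scalar; `relative_errors()`: numeric vector;
#'   `eps90()`: scalar.
#' @export
rmse <- function(pairs) {
  tv_assert(nrow(pairs) >= 1, "no pairs", "tv_degenerate_error")
  sqrt(mean((pairs$est - pairs$ref)^2))
}

#' @rdname rmse
#' @export
relative_errors <- function(pairs) {
  tv_assert(nrow(pairs) >= 1, "no pairs", "tv_degenerate_error")
  tv_assert(all(pairs$ref > 0), "reference rates must be positive", "tv_domain_error")
  abs(pairs$est - pairs$ref) / pairs$ref
}

#' @rdname rmse
#' @param rel_errors vector from [relative_errors()].
#' @export
eps90 <- function(rel_errors) {
  tv_assert(length(rel_errors) >= 1, "no errors", "tv_degenerate_error")
  quantile(rel_errors, 0.9, names = FALSE, type = 7)
}

#' Complement of the absolute normalized difference
#'
#' `CAND = 1 - |gt - ti| / gt`: an agreement score between a reference rate
#' and an estimate, 1 for perfect agreement. Complements the relative error
#' of the same pair exactly to 1.
#'
#' @param gt reference rate(s), > 0.
#' @param ti estimated rate(s).
#' @return Numeric vector of scores.
#' @export
cand <- function(gt, ti) {
  tv_assert(all(gt > 0), "reference rate must be > 0", "tv_domain_error")
  1 - abs(gt - ti) / gt
}

#' Bland-Altman agreement analysis
#'
#' Differences are `est - ref`; the bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 * sd` (sample SD, n-1 denominator).
#'
#' @param pairs data.frame with columns `est`, `ref` (>= 2 rows).
#' @return List: `bias`, `loa_low`, `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(pairs) {
  tv_assert(nrow(pairs) >= 2, "need at least two pairs", "tv_degenerate_error")
  diffs <- pairs$est - pairs$ref
  bias <- mean(diffs)
  s <- sd(diffs)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = nrow(pairs))
}

#' Aggregate a per-subject validation table
#'
#' Column-wise mean and sample SD of the numeric validation columns -
#' the "Mean +/- SD" bottom row of a study table.
#'
#' @param rows data.frame with columns `subject_id`, `mean_gt`, `mean_irt`,
#'   `rmse`, `eps_mean`, `eps90` (>= 2 rows).
#' @return data.frame with rows `mean` and `sd`.
#' @export
aggregate_validation <- function(rows) {
  tv_assert(nrow(rows) >= 2, "need at least two rows", "tv_degenerate_error")
  num <- rows[, c("mean_gt", "mean_irt", "rmse", "eps_mean", "eps90")]
  out <- rbind(mean = colMeans(num), sd = apply(num, 2, sd))
  as.data.frame(out)
}

#' Mean relative error of per-subject mean rates
#'
#' `mean over subjects of |mean_gt - mean_irt| / mean_gt`: the coarse
#' whole-recording comparison (as opposed to the instantaneous pairwise
#' errors summarized by [rmse()] and [eps90()]).
#'
#' @param rows validation data.frame as in [aggregate_validation()].
#' @return Dimensionless scalar.
#' @export
mean_rate_relative_error <- function(rows) {
  tv_assert(nrow(rows) >= 1, "empty table", "tv_degenerate_error")
  tv_assert(all(rows$mean_gt > 0), "mean_gt must be > 0", "tv_domain_error")
  mean(abs(rows$mean_gt - rows$mean_irt) / rows$mean_gt)
}

#' Full agreement summary between an estimate and a reference
#'
#' Convenience wrapper: aligns the series and returns the statistics used
#' throughout the validation - RMSE, mean relative error, 90th percentile
#' error, Bland-Altman bias and limits, and mean CAND.
#'
#' @param est,ref [rate_series()] objects.
#' @return Named list of scalars plus `n` pairs.
#' @export
validate_series <- function(est, ref) {
  pairs <- align_series(est, ref)
  rel <- relative_errors(pairs)
  ba <- if (nrow(pairs) >= 2) bland_altman(pairs) else
    list(bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_)
  list(n = nrow(pairs), rmse = rmse(pairs), eps_mean = mean(rel),
       eps90 = eps90(rel), bias = ba$bias, loa_low = ba$loa_low,
       loa_high = ba$loa_high, cand_mean = mean(cand(pairs$ref, pairs$est)))
}

#' Bundled per-subject validation tables
#'
#' Per-subject agreement summaries from a pilot study of 20 healthy adults
#' monitored with a calibrated thermal camera against contact references
#' (photoplethysmography for heart rate, piezoplethysmographic thoracic
#' effort for respiration): `rr_frontal` (16 subjects), `hr_frontal`
#' (18 subjects) and `hr_side` (16 subjects). Columns: `subject_id`,
#' `mean_gt`, `mean_irt` (per-minute), `rmse` (per-minute), `eps_mean`,
#' `eps90`.
#'
#' @param which one of `"rr_frontal"`, `"hr_frontal"`, `"hr_side"`.
#' @return data.frame.
#' @export
load_validation_table <- function(which = c("hr_frontal", "hr_side", "rr_frontal")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("pilot_", which, ".csv"),
                      package = "thermovitals", mustWork = TRUE)
  read.csv(path, comment.char = "#")
}
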