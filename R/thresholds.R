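#' Sensitivity/specificity sweep over GRS cutoffs
#'
#' For every distinct GRS value (plus -Inf/+Inf sentinels) as cutoff `c`,
#' evaluates the rule "predict responder iff GRS <= c". Boundary
#' conventions match the clinical reading of the score: responders captured
#' are those with GRS *at or below* the cutoff, while the nonresponder
#' column counts GRS *at or above* it, so ties at the cutoff count toward
#' both quoted proportions. Sensitivity equals the captured-responder
#' proportion; specificity is the share of nonresponders strictly above
#' the cutoff.
#'
#' @param grs numeric GRS vector.
#' @param labels binary vector (1/`TRUE` = responder).
#' @return data frame, one row per cutoff: `cutoff`, `sensitivity`,
#'   `specificity`, `responders_captured`, `nonresponders_at_or_above`.
#' @export
cutoff_sweep <- function(grs, labels) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(grs) == length(y))
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  cuts <- c(-Inf, sort(unique(grs)), Inf)
  g_r <- grs[y == 1]; g_nr <- grs[y == 0]
  out <- data.frame(
    cutoff = cuts,
    sensitivity = vapply(cuts, function(c) mean(g_r <= c), numeric(1)),
    specificity = vapply(cuts, function(c) mean(g_nr > c), numeric(1)),
    responders_captured = vapply(cuts, function(c) mean(g_r <= c),
                                 numeric(1)),
    nonresponders_at_or_above = vapply(cuts, function(c) mean(g_nr >= c),
                                       numeric(1)))
  rownames(out) <- NULL
  out
}

#' Tertile and median summary of a GRS distribution
#'
#' Returns the [cutoff_sweep()] rows at the bottom-tertile (33.3%), median
#' (50%) and top-tertile (66.7%) nearest-rank sample quantiles of the GRS —
#' the three candidate clinical cutoffs.
#'
#' @inheritParams cutoff_sweep
#' @return data frame of three rows with a leading `point` column
#'   (`bottom_tertile`, `median`, `top_tertile`) and a `grs_value` column.
#' @export
summary_points <- function(grs, labels) {
  stopifnot(length(grs) >= 3)
  if (length(unique(grs)) == 1)
    warning("constant GRS: summary points collapse to a single value")
  q <- stats::quantile(grs, probs = c(1 / 3, 1 / 2, 2 / 3), type = 1,
                       names = FALSE)
  sweep <- cutoff_sweep(grs, labels)
  rows <- sweep[match(q, sweep$cutoff), , drop = FALSE]
  cbind(point = c("bottom_tertile", "median", "top_tertile"),
        grs_value = q, rows[, -1, drop = FALSE], row.names = NULL)
}

#' Decision aid: classify a subject's GRS against a calibrated cutoff
#'
#' The rule labels a subject "likely responder" — i.e. likely to benefit
#' from the TG-lowering effect of the supplementation — when the GRS is at
#' or below the cutoff (ties side with treating). When the calibration
#' sweep is supplied, the rationale quotes the sensitivity and
#' captured-responder proportion at that cutoff.
#'
#' @param grs_value the subject's GRS.
#' @param cutoff calibrated GRS cutoff (e.g. from [summary_points()]).
#' @param sweep optional [cutoff_sweep()] table used for the rationale.
#' @return list with `classification` (`"likely-responder"` /
#'   `"likely-nonresponder"`), `grs_value`, `cutoff` and `rationale`.
#' @export
decision_aid <- function(grs_value, cutoff, sweep = NULL) {
  is_resp <- grs_value <= cutoff
  rationale <- sprintf("GRS %s is %s the cutoff %s (rule: likely responder iff GRS <= cutoff).",
                       format(grs_value), if (is_resp) "at or below" else "above",
                       format(cutoff))
  if (!is.null(sweep)) {
    row <- sweep[which.min(abs(sweep$cutoff - cutoff)), ]
    rationale <- paste0(
      rationale,
      sprintf(" At this cutoff, %.0f%% of actual responders are captured and sensitivity is %.0f%%.",
              100 * row$responders_captured, 100 * row$sensitivity))
  }
  list(classification = if (is_resp) "likely-responder"
                        else "likely-nonresponder",
       grs_value = grs_value, cutoff = cutoff, rationale = rationale)
}
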