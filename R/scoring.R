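#' Allele-based odds ratio between responders and nonresponders
#'
#' Compares the odds of carrying the minor allele between the two response
#' groups. The orientation is responder-odds over nonresponder-odds,
#' \deqn{OR = \frac{p_R/(1-p_R)}{p_{NR}/(1-p_{NR})},}
#' so that a minor allele enriched in nonresponders gives OR < 1; `flip`
#' inverts the ratio for the opposite convention. The 95% CI uses the
#' normal approximation on the log odds ratio and needs allele counts, so
#' it is only computed when the group sizes are supplied.
#'
#' @param maf_responders,maf_nonresponders minor-allele frequencies in each
#'   group, in `[0, 1)`.
#' @param n_responders,n_nonresponders optional subject counts per group
#'   (each contributes two alleles), enabling the CI.
#' @param flip if `TRUE`, return nonresponder-odds over responder-odds.
#' @param conf_level CI coverage (default 0.95).
#' @return list with `odds_ratio`, `ci_low`, `ci_high` and `status`
#'   (`"ok"`, `"infinite"` when the nonresponder MAF is 0, `"excluded"`
#'   when the responder MAF is 0 — such variants cannot enter a score).
#' @export
allele_odds_ratio <- function(maf_responders, maf_nonresponders,
                              n_responders = NULL, n_nonresponders = NULL,
                              flip = FALSE, conf_level = 0.95) {
  p_r <- maf_responders; p_nr <- maf_nonresponders
  stopifnot(p_r >= 0, p_r < 1, p_nr >= 0, p_nr < 1)
  if (p_r == 0)
    return(list(odds_ratio = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, status = "excluded"))
  if (p_nr == 0)
    return(list(odds_ratio = Inf, ci_low = NA_real_, ci_high = NA_real_,
                status = "infinite"))
  or <- (p_r / (1 - p_r)) / (p_nr / (1 - p_nr))
  if (flip) or <- 1 / or
  ci_low <- ci_high <- NA_real_
  if (!is.null(n_responders) && !is.null(n_nonresponders)) {
    counts <- c(p_r, 1 - p_r, p_nr, 1 - p_nr) *
      rep(2 * c(n_responders, n_nonresponders), each = 2)
    se <- sqrt(sum(1 / counts))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci_low <- or * exp(-z * se)
    ci_high <- or * exp(z * se)
  }
  list(odds_ratio = or, ci_low = ci_low, ci_high = ci_high, status = "ok")
}

#' Assign a risk score to a variant from its odds ratio
#'
#' A score of +1 marks variants whose minor allele is depleted in
#' responders (OR < 1, i.e. associated with higher post-supplementation
#' lipids); −1 marks the opposite (OR > 1). Variants with responder MAF 0,
#' a missing odds ratio, or OR exactly 1 are excluded (returned as `NA`)
#' and contribute nothing to any score.
#'
#' @param odds_ratio positive odds ratio(s) as from [allele_odds_ratio()].
#' @param maf_responders responder minor-allele frequency (recycled).
#' @return integer vector: `+1`, `-1`, or `NA` for excluded.
#' @export
assign_score <- function(odds_ratio, maf_responders) {
  n <- max(length(odds_ratio), length(maf_responders))
  or <- rep_len(odds_ratio, n)
  p_r <- rep_len(maf_responders, n)
  score <- rep(NA_integer_, n)
  ok <- !is.na(p_r) & p_r > 0 & !is.na(or) & or != 1
  score[ok & or < 1] <- 1L
  score[ok & or > 1] <- -1L
  score
}

#' Build the per-variant score table for a frequency panel
#'
#' For each variant, computes the responder/nonresponder odds ratio from
#' the group MAFs, applies the score rule, and carries weights. When the
#' panel already carries an `odds_ratio` column (e.g. a published table
#' whose ORs come from unrounded allele counts), those values take
#' precedence over the MAF-derived ones, since frequencies rounded for
#' printing can distort or even zero out the log odds.
#'
#' @param panel data frame with `variant_id`, `maf_responders`,
#'   `maf_nonresponders`, and optionally `odds_ratio`, `ci_low`, `ci_high`,
#'   `weight`.
#' @param n_responders,n_nonresponders optional group sizes for CIs on
#'   MAF-derived odds ratios.
#' @param flip passed to [allele_odds_ratio()].
#' @return data frame of score entries: `variant_id`, `maf_responders`,
#'   `maf_nonresponders`, `odds_ratio`, `ci_low`, `ci_high`, `score`
#'   (`NA` = excluded), `weight`.
#' @export
score_table <- function(panel, n_responders = NULL, n_nonresponders = NULL,
                        flip = FALSE) {
  stopifnot(all(c("variant_id", "maf_responders", "maf_nonresponders")
                %in% names(panel)))
  n <- nrow(panel)
  out <- data.frame(variant_id = panel$variant_id,
                    maf_responders = panel$maf_responders,
                    maf_nonresponders = panel$maf_nonresponders,
                    odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, score = NA_integer_,
                    weight = if (is.null(panel$weight)) 1 else panel$weight,
                    stringsAsFactors = FALSE)
  supplied <- if (is.null(panel$odds_ratio)) rep(NA_real_, n)
              else panel$odds_ratio
  for (i in seq_len(n)) {
    est <- allele_odds_ratio(panel$maf_responders[i],
                             panel$maf_nonresponders[i],
                             n_responders, n_nonresponders, flip = flip)
    out$odds_ratio[i] <- est$odds_ratio
    out$ci_low[i] <- est$ci_low
    out$ci_high[i] <- est$ci_high
    if (!is.na(supplied[i])) {
      out$odds_ratio[i] <- supplied[i]
      out$ci_low[i] <- if (is.null(panel$ci_low)) NA_real_ else panel$ci_low[i]
      out$ci_high[i] <- if (is.null(panel$ci_high)) NA_real_
                        else panel$ci_high[i]
    }
  }
  out$score <- assign_score(out$odds_ratio, out$maf_responders)
  out
}

#' Construct a named score set
#'
#' @param name score-set name (e.g. `"GRS31"`).
#' @param entries score-entry data frame as from [score_table()].
#' @return object of class `score_set`.
#' @export
new_score_set <- function(name, entries) {
  stopifnot(is.character(name), length(name) == 1,
            all(c("variant_id", "score") %in% names(entries)))
  if (anyDuplicated(entries$variant_id))
    stop("duplicated variant ids in score set '", name, "'")
  structure(list(name = name, entries = entries), class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("<score_set> ", x$name, ": ", nrow(x$entries), " entries (",
      sum(!is.na(x$entries$score)), " scored, ",
      sum(is.na(x$entries$score)), " excluded)\n", sep = "")
  invisible(x)
}

#' Build nested score sets from a base panel plus additions
#'
#' Each addition set is appended to the base independently, producing score
#' sets that are all supersets of the base (the GRS31 → GRS32/GRS38/GRS46
#' construction).
#'
#' @param base_set a `score_set` (the base panel).
#' @param additions list of score-entry data frames, one per derived set.
#' @param names character vector of derived-set names, parallel to
#'   `additions`.
#' @return named list of `score_set` objects (the base first).
#' @export
build_score_sets <- function(base_set, additions, names) {
  stopifnot(inherits(base_set, "score_set"),
            length(additions) == length(names))
  out <- stats::setNames(list(base_set), base_set$name)
  for (k in seq_along(additions)) {
    add <- additions[[k]]
    dup <- intersect(base_set$entries$variant_id, add$variant_id)
    if (length(dup))
      stop("variant(s) already in base set: ", paste(dup, collapse = ", "))
    cols <- union(names(base_set$entries), names(add))
    fill <- function(df) {
      for (col in setdiff(cols, names(df))) df[[col]] <- NA
      df[, cols, drop = FALSE]
    }
    merged <- rbind(fill(base_set$entries), fill(add))
    out[[names[k]]] <- new_score_set(names[k], merged)
  }
  out
}

#' Compute genetic risk scores for every subject
#'
#' The unweighted GRS sums `score * dosage` over the set's non-excluded
#' variants; the weighted GRS scales each term by the absolute per-variant
#' weight. Missing dosages at scored variants are mean-imputed per variant
#' by default.
#'
#' @param cohort a cohort carrying all non-excluded variants of the set.
#' @param score_set a `score_set`.
#' @param weighted if `TRUE`, use `score * |weight| * dosage`.
#' @param missing `"mean"` (impute the per-variant mean dosage) or
#'   `"zero"`.
#' @return named numeric vector of GRS values, one per subject.
#' @export
compute_grs <- function(cohort, score_set, weighted = FALSE,
                        missing = c("mean", "zero")) {
  missing <- match.arg(missing)
  entries <- score_set$entries[!is.na(score_set$entries$score), , drop = FALSE]
  if (nrow(entries) == 0)
    return(stats::setNames(rep(0, nrow(cohort$subjects)),
                           cohort$subjects$subject_id))
  d <- cohort_dosage(cohort, entries$variant_id)
  if (anyNA(d)) {
    fill <- if (missing == "mean") colMeans(d, na.rm = TRUE) else
      rep(0, ncol(d))
    fill[is.nan(fill)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- fill[idx[, 2]]
  }
  w <- entries$score
  if (weighted) {
    weight <- entries$weight
    weight[is.na(weight)] <- 1
    w <- w * abs(weight)
  }
  stats::setNames(as.numeric(d %*% w), cohort$subjects$subject_id)
}

#' GRS profiles over several score sets
#'
#' @param cohort a cohort.
#' @param score_sets named list of `score_set` objects.
#' @param weighted logical, recycled over score sets.
#' @param ... passed to [compute_grs()].
#' @return data frame: `subject_id` plus one GRS column per score set.
#' @export
grs_profiles <- function(cohort, score_sets, weighted = FALSE, ...) {
  weighted <- rep_len(weighted, length(score_sets))
  out <- data.frame(subject_id = cohort$subjects$subject_id,
                    stringsAsFactors = FALSE)
  for (k in seq_along(score_sets))
    out[[score_sets[[k]]$name]] <-
      unname(compute_grs(cohort, score_sets[[k]], weighted = weighted[k], ...))
  out
}

#' Write a score table TSV
#'
#' Columns mirror the published panel layout: variant, per-group MAFs,
#' odds ratio with CI, assigned score, weight.
#'
#' @param entries score-entry data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_score_table <- function(entries, path) {
  utils::write.table(entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
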