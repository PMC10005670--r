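#' Tally alleles and genotypes from a dosage vector
#'
#' @param dosages vector of minor-allele copy counts in \{0, 1, 2, NA\}.
#' @return list with `minor_count` (total minor-allele copies),
#'   `total_alleles` (2 x called genotypes) and `genotype_counts`
#'   (named: hom_major, het, hom_minor).
#' @export
allele_counts <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  stopifnot(all(d %in% 0:2))
  list(minor_count = as.integer(sum(d)),
       total_alleles = 2L * length(d),
       genotype_counts = c(hom_major = sum(d == 0), het = sum(d == 1),
                           hom_minor = sum(d == 2)))
}

#' Minor-allele frequency of a dosage vector
#'
#' @inheritParams allele_counts
#' @return minor-allele copies divided by called alleles.
#' @export
compute_maf <- function(dosages) {
  ac <- allele_counts(dosages)
  if (ac$total_alleles == 0L)
    stop("MAF undefined: all genotypes missing")
  ac$minor_count / ac$total_alleles
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the allele counts: the p-value sums
#' the probabilities of all heterozygote configurations no more probable
#' than the observed one (the convention of Wigginton, Cutler & Abecasis,
#' also PLINK's default). Probabilities follow the recurrence
#' \eqn{P(h+2)/P(h) = 4 n_{AA} n_{aa} / ((h+2)(h+1))} over heterozygote
#' counts `h` sharing the parity of the minor-allele count.
#'
#' @param genotype_counts length-3 vector `(hom_major, het, hom_minor)`.
#' @param midp logical; if `TRUE`, use the mid-p variant (observed
#'   configuration counted with weight 1/2).
#' @return p-value in (0, 1].
#' @seealso [hwe_chisq_test()] for the asymptotic version.
#' @export
hwe_exact_test <- function(genotype_counts, midp = FALSE) {
  gc <- as.integer(round(genotype_counts))
  stopifnot(length(gc) == 3, all(gc >= 0))
  n <- sum(gc)
  if (n == 0) stop("HWE test undefined for zero subjects")
  obs_het <- gc[2]
  rare <- 2L * min(gc[1], gc[3]) + gc[2]   # copies of the rarer allele
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # start near the distribution's mode and apply the two-sided recurrence
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  probs <- numeric(length(hets))
  names(probs) <- hets
  probs[as.character(mid)] <- 1
  h <- mid
  while (h >= 2L) {                       # downward: h -> h - 2
    a <- (rare - h) / 2; A <- n - h - a   # hom_rare, hom_common at h
    probs[as.character(h - 2L)] <-
      probs[as.character(h)] * h * (h - 1) / (4 * (a + 1) * (A + 1))
    h <- h - 2L
  }
  h <- mid
  while (h + 2L <= rare) {                # upward: h -> h + 2
    a <- (rare - h) / 2; A <- n - h - a
    if (a == 0 || A == 0) { probs[as.character(h + 2L)] <- 0; break }
    probs[as.character(h + 2L)] <-
      probs[as.character(h)] * 4 * a * A / ((h + 2) * (h + 1))
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  p_obs <- probs[as.character(obs_het)]
  in_tail <- probs <= p_obs * (1 + 1e-12)
  p <- sum(probs[in_tail])
  if (midp) p <- p - p_obs / 2
  min(1, max(p, .Machine$double.xmin))
}

#' Chi-squared test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test against the binomial genotype
#' expectation; offered as the asymptotic cross-check for
#' [hwe_exact_test()].
#'
#' @inheritParams hwe_exact_test
#' @return p-value.
#' @export
hwe_chisq_test <- function(genotype_counts) {
  gc <- as.numeric(genotype_counts)
  stopifnot(length(gc) == 3, all(gc >= 0))
  n <- sum(gc)
  if (n == 0) stop("HWE test undefined for zero subjects")
  p <- (2 * gc[3] + gc[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((gc - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Per-variant quality-control summary
#'
#' Computes, for every variant, the pooled and per-group minor-allele
#' frequencies, the exact Hardy-Weinberg p-value, the monomorphic flag and
#' the number of called subjects. Per-group MAFs use only subjects with a
#' definite responder/nonresponder label.
#'
#' @param cohort a labelled cohort (see [label_cohort()]).
#' @return data frame, one row per variant: `variant_id`, `maf_all`,
#'   `maf_responders`, `maf_nonresponders`, `hwe_p`, `monomorphic`,
#'   `n_called`.
#' @export
variant_qc <- function(cohort) {
  d <- cohort_dosage(cohort)
  y <- response_indicator(cohort$subjects)
  one <- function(j) {
    dos <- d[, j]
    ac <- allele_counts(dos)
    maf_all <- if (ac$total_alleles > 0) ac$minor_count / ac$total_alleles
               else NA_real_
    grp_maf <- function(sel) {
      v <- dos[sel]
      if (all(is.na(v))) NA_real_ else compute_maf(v)
    }
    data.frame(variant_id = colnames(d)[j],
               maf_all = maf_all,
               maf_responders = grp_maf(!is.na(y) & y == 1),
               maf_nonresponders = grp_maf(!is.na(y) & y == 0),
               hwe_p = hwe_exact_test(ac$genotype_counts),
               monomorphic = !is.na(maf_all) && maf_all == 0,
               n_called = sum(!is.na(dos)),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(ncol(d)), one))
  rownames(out) <- NULL
  out
}

#' Quality-control filter for a cohort's variant panel
#'
#' Excludes monomorphic variants (no carrier of the rare allele) and flags —
#' without excluding — variants whose exact Hardy-Weinberg p-value falls
#' below `hwe_alpha`. Exclusion here is monomorphism-driven only; departure
#' from HWE is surfaced for the analyst to judge.
#'
#' @param cohort a labelled cohort.
#' @param hwe_alpha flag level for the HWE test (default 0.05).
#' @return list with `cohort` (monomorphic variants removed), `qc` (the
#'   [variant_qc()] table plus an `hwe_flag` column), and `log` (data frame
#'   of excluded variants and reasons).
#' @export
qc_filter <- function(cohort, hwe_alpha = 0.05) {
  qc <- variant_qc(cohort)
  qc$hwe_flag <- !is.na(qc$hwe_p) & qc$hwe_p < hwe_alpha
  drop <- qc$variant_id[qc$monomorphic]
  log <- data.frame(variant_id = drop,
                    reason = rep("monomorphic (MAF = 0)", length(drop)),
                    stringsAsFactors = FALSE)
  keep <- setdiff(cohort$variants$variant_id, drop)
  cohort$variants <- cohort$variants[cohort$variants$variant_id %in% keep, ,
                                     drop = FALSE]
  rownames(cohort$variants) <- NULL
  cohort$dosage <- cohort$dosage[, setdiff(colnames(cohort$dosage), drop),
                                 drop = FALSE]
  list(cohort = cohort, qc = qc, log = log)
}

#' Write a QC report TSV
#'
#' One row per variant with all QC fields and a `reason` column for
#' exclusions.
#'
#' @param qc_result the list returned by [qc_filter()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_qc_report <- function(qc_result, path) {
  tab <- qc_result$qc
  tab$reason <- qc_result$log$reason[match(tab$variant_id,
                                           qc_result$log$variant_id)]
  tab$reason[is.na(tab$reason)] <- ""
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
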