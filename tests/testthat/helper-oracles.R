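# Independent oracles used across the suite. Each is deliberately written
# as the most direct (brute-force / closed-form) computation, not sharing
# code with the package.

# Exact HWE p-value by full enumeration of the conditional distribution
# over heterozygote counts, via log-factorials.
hwe_enumeration_oracle <- function(genotype_counts) {
  gc <- as.integer(genotype_counts)
  n <- sum(gc)
  het_obs <- gc[2]
  m <- 2L * min(gc[1], gc[3]) + gc[2]      # rarer-allele copies
  if (m == 0L) return(1)
  hets <- seq.int(m %% 2L, m, by = 2L)
  logp <- vapply(hets, function(h) {
    a <- (m - h) / 2          # hom for the rarer allele
    A <- n - h - a            # hom for the commoner allele
    lfactorial(n) - lfactorial(A) - lfactorial(h) - lfactorial(a) +
      h * log(2) + lfactorial(m) + lfactorial(2 * n - m) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[match(het_obs, hets)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# AUC by explicit enumeration of all positive-negative pairs, ties = 1/2.
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Welch t-test from the textbook formulas.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, p = 2 * pt(-abs(t), df))
}

# A small deterministic cohort built directly from parts (no RNG).
toy_cohort <- function() {
  subjects <- data.frame(
    subject_id = paste0("P", 1:6),
    age = c(25, 32, 41, 28, 35, 47),
    sex = c("female", "male", "male", "female", "female", "male"),
    bmi = c(26.1, 31.5, 29.0, 27.2, 33.8, 25.4),
    tg_baseline = c(2.0, 1.8, 1.5, 1.2, 1.0, 1.4),
    tg_post = c(1.5, 1.3, 1.2, 1.3, 1.2, 1.6),
    stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = c("rsA", "rsB"),
    chromosome = c("1", "2"),
    position = c(1000L, 2000L),
    major_allele = c("A", "C"),
    minor_allele = c("G", "T"),
    stringsAsFactors = FALSE)
  dosage <- matrix(c(0, 1, 2, 0, 1, NA,
                     2, 1, 0, 1, 0, 0),
                   nrow = 6, ncol = 2,
                   dimnames = list(subjects$subject_id, variants$variant_id))
  label_cohort(new_cohort(subjects, variants, dosage))
}

# Write the toy cohort's PLINK pair into a temp dir; returns the paths.
toy_plink_files <- function(cohort = toy_cohort()) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  ped <- file.path(dir, "toy.ped"); map <- file.path(dir, "toy.map")
  write_plink_text(cohort, ped, map)
  list(ped = ped, map = map, dir = dir)
}
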