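test_that("allele odds ratio reproduces the published mid-frequency values", {
  expect_equal(round(allele_odds_ratio(0.18, 0.23)$odds_ratio, 2), 0.73)
  expect_equal(round(allele_odds_ratio(0.12, 0.14)$odds_ratio, 2), 0.84)
  expect_equal(round(allele_odds_ratio(0.03, 0.05)$odds_ratio, 2), 0.59)
})

test_that("odds ratio degenerate and count-based cases behave", {
  for (p in c(0.01, 0.2, 0.49))
    expect_equal(allele_odds_ratio(p, p)$odds_ratio, 1)
  expect_identical(allele_odds_ratio(0, 0.1)$status, "excluded")
  expect_identical(allele_odds_ratio(0.1, 0)$status, "infinite")
  # 2x2 allele counts 9/151 vs 4/116: cross-product ratio
  p_r <- 9 / 160; p_nr <- 4 / 120
  est <- allele_odds_ratio(p_r, p_nr, n_responders = 80,
                           n_nonresponders = 60)
  expect_equal(est$odds_ratio, (9 * 116) / (151 * 4), tolerance = 1e-12)
  expect_true(est$ci_low <= est$odds_ratio && est$odds_ratio <= est$ci_high)
  # no counts -> no CI
  expect_true(is.na(allele_odds_ratio(0.1, 0.2)$ci_low))
})

test_that("antisymmetry: swapping groups inverts the OR and flips scores", {
  set.seed(21)
  for (rep in 1:50) {
    p1 <- runif(1, 0.01, 0.5); p2 <- runif(1, 0.01, 0.5)
    or_a <- allele_odds_ratio(p1, p2)$odds_ratio
    or_b <- allele_odds_ratio(p2, p1)$odds_ratio
    expect_equal(or_a, 1 / or_b, tolerance = 1e-12)
    s_a <- assign_score(or_a, p1); s_b <- assign_score(or_b, p2)
    if (!is.na(s_a)) expect_equal(s_a, -s_b)
  }
  # the flip flag gives the opposite printed convention
  expect_equal(allele_odds_ratio(0.18, 0.23, flip = TRUE)$odds_ratio,
               1 / allele_odds_ratio(0.18, 0.23)$odds_ratio)
})

test_that("score assignment follows the sign rule with exclusions", {
  expect_equal(assign_score(1.71, 0.06), -1L)
  expect_equal(assign_score(0.73, 0.18), 1L)
  expect_true(is.na(assign_score(2.5, 0)))       # responder MAF 0
  expect_true(is.na(assign_score(1, 0.1)))       # OR exactly 1
  expect_true(is.na(assign_score(NA, 0.1)))
})

test_that("score_table scores the published panel: 14 scored, 1 excluded", {
  entries <- score_table(fas_score_table())
  expect_equal(nrow(entries), 15)
  expect_equal(sum(!is.na(entries$score)), 14)
  expect_identical(entries$variant_id[is.na(entries$score)], "rs77542162")
  # the supplied (published) ORs take precedence and reproduce the
  # published score column exactly
  expect_identical(entries$score, as.integer(fas_score_table()$score))
})

test_that("GRS summation is the signed, optionally weighted dosage sum", {
  entries <- data.frame(variant_id = c("a", "b", "c"),
                        maf_responders = c(0.1, 0.2, 0),
                        maf_nonresponders = c(0.2, 0.1, 0.1),
                        score = c(1L, -1L, NA), weight = c(2, 0.5, 1))
  set <- new_score_set("toy", entries)
  co <- toy_cohort()
  co$variants <- data.frame(variant_id = c("a", "b", "c"),
                            chromosome = "1", position = 1:3,
                            major_allele = "A", minor_allele = "G")
  co$dosage <- matrix(c(2, 0, 1, 0, 0, 0,
                        1, 0, 0, 2, 0, 0,
                        2, 2, 2, 2, 2, 2),   # excluded: contributes nothing
                      nrow = 6,
                      dimnames = list(co$subjects$subject_id, c("a", "b", "c")))
  g <- compute_grs(co, set)
  expect_equal(unname(g), c(2 - 1, 0, 1, -2, 0, 0))
  gw <- compute_grs(co, set, weighted = TRUE)
  expect_equal(unname(gw), c(2 * 2 - 0.5, 0, 2, -1, 0, 0))
  # all weights 1: weighted equals unweighted
  set$entries$weight <- 1
  expect_equal(compute_grs(co, set, weighted = TRUE), compute_grs(co, set))
  # all-zero dosages give zero burden
  co$dosage[] <- 0
  expect_equal(unname(compute_grs(co, set)), rep(0, 6))
})

test_that("GRS is additive over disjoint score sets", {
  cfg <- generator_config(seed = 31, n_responders = 20,
                          n_nonresponders = 15)
  co <- generate_cohort(cfg)
  qc <- variant_qc(co)
  entries <- score_table(qc, 20, 15)
  half <- nrow(entries) %/% 2
  s_all <- new_score_set("all", entries)
  s_1 <- new_score_set("h1", entries[seq_len(half), ])
  s_2 <- new_score_set("h2", entries[-seq_len(half), ])
  expect_equal(compute_grs(co, s_all),
               compute_grs(co, s_1) + compute_grs(co, s_2))
})

test_that("nested score-set construction reproduces the panel sizes", {
  base_entries <- data.frame(
    variant_id = sprintf("base%02d", 1:31),
    maf_responders = 0.25, maf_nonresponders = 0.40,
    odds_ratio = 0.5, ci_low = NA, ci_high = NA,
    score = 1L, weight = 1)
  base <- new_score_set("GRS31", base_entries)
  tab <- score_table(fas_score_table())
  ann <- fas_annotation()
  tg_ids <- intersect(tab$variant_id,
                      ann$variant_id[!is.na(ann$phenotype) &
                                       ann$phenotype == "TG"])
  sets <- build_score_sets(
    base,
    additions = list(tab[tab$variant_id == "rs55707100", ],
                     tab[tab$variant_id %in% tg_ids, ],
                     tab),
    names = c("GRS32", "GRS38", "GRS46"))
  sizes <- vapply(sets, function(s) nrow(s$entries), numeric(1))
  expect_equal(unname(sizes), c(31, 32, 38, 46))
  # GRS46 carries the one excluded entry: 45 scoreable
  expect_equal(sum(!is.na(sets$GRS46$entries$score)), 45)
  # duplicates are rejected
  expect_error(build_score_sets(base, list(base_entries[1, ]), "dup"),
               "already in base")
})

test_that("missing dosages at scored variants are mean-imputed by default", {
  entries <- data.frame(variant_id = "a", maf_responders = 0.1,
                        maf_nonresponders = 0.3, score = 1L, weight = 1)
  set <- new_score_set("m", entries)
  co <- toy_cohort()
  co$variants <- data.frame(variant_id = "a", chromosome = "1",
                            position = 1L, major_allele = "A",
                            minor_allele = "G")
  co$dosage <- matrix(c(0, 2, NA, 1, 1, NA), ncol = 1,
                      dimnames = list(co$subjects$subject_id, "a"))
  g <- compute_grs(co, set)
  expect_equal(unname(g[3]), 1)                  # mean of 0,2,1,1
  expect_equal(unname(compute_grs(co, set, missing = "zero")[3]), 0)
  # a scored variant absent from the genotypes is an error naming it
  set2 <- new_score_set("m2", data.frame(variant_id = "ghost",
                                         maf_responders = 0.1,
                                         maf_nonresponders = 0.3,
                                         score = 1L, weight = 1))
  expect_error(compute_grs(co, set2), "ghost")
})
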