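test_that("stratified split keeps class balance and is deterministic", {
  labels <- rep(c(1, 0), c(80, 60))
  plan <- stratified_split(labels, fraction = 0.5, seed = 42)
  expect_equal(length(plan$train_ids), 70)
  expect_equal(length(plan$test_ids), 70)
  y <- setNames(labels, as.character(seq_along(labels)))
  expect_equal(sum(y[plan$train_ids]), 40)       # 40R + 30NR per half
  expect_equal(sum(y[plan$test_ids]), 40)
  expect_length(intersect(plan$train_ids, plan$test_ids), 0)
  # folds partition the training ids, stratified
  expect_setequal(names(plan$fold_assignment), plan$train_ids)
  per_fold_r <- tapply(y[names(plan$fold_assignment)], plan$fold_assignment,
                       sum)
  expect_true(max(per_fold_r) - min(per_fold_r) <= 1)
  # determinism
  plan2 <- stratified_split(labels, fraction = 0.5, seed = 42)
  expect_identical(plan, plan2)
  # degenerate fractions are rejected
  expect_error(stratified_split(labels, fraction = 1.0, seed = 1),
               "between 0 and 1")
  expect_error(stratified_split(c(1, 1, 1, 0), seed = 1), "at least 2")
})

test_that("AUC equals the pairwise-count oracle, with ties", {
  scores <- c(1, 2, 2, 3, 4, 4, 5, 6)
  labels <- c(0, 0, 1, 0, 1, 0, 1, 1)
  expect_equal(auc_roc(scores, labels)$auc,
               auc_pairwise_oracle(scores, labels))
  # perfectly separated
  expect_equal(auc_roc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))$auc, 1)
  # independence gives ~0.5
  set.seed(30)
  expect_lt(abs(auc_roc(rnorm(2000), rbinom(2000, 1, 0.5))$auc - 0.5), 0.05)
  # property sweep across sizes with heavy ties
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    s <- sample(0:5, n, replace = TRUE)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_identical(auc_roc(s, l)$auc, auc_pairwise_oracle(s, l))
  }
  # invariance under strictly monotone transform
  s <- rnorm(40); l <- c(0, 1, rbinom(38, 1, 0.5))
  expect_equal(auc_roc(s, l)$auc, auc_roc(exp(s), l)$auc)
  # constant scores degrade gracefully
  expect_warning(res <- auc_roc(rep(1, 10), c(0, 1, rep(0, 8))), "constant")
  expect_equal(res$auc, 0.5)
})

test_that("DeLong CI brackets the AUC and stays in [0,1]", {
  set.seed(33)
  s <- rnorm(60) + rep(c(0, 1), each = 30)
  l <- rep(c(0, 1), each = 30)
  res <- auc_roc(s, l)
  expect_true(res$ci_low <= res$auc && res$auc <= res$ci_high)
  expect_true(res$ci_low >= 0 && res$ci_high <= 1)
})

test_that("confusion metrics match direct counting", {
  expect_equal(confusion_metrics(c(1, 0, 1), c(1, 0, 1))[c(1, 3, 4)],
               list(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_equal(confusion_metrics(c(0, 1, 0), c(1, 0, 1))[c(1, 3, 4)],
               list(accuracy = 0, sensitivity = 0, specificity = 0))
  # constructed 2x2: TP=29 FN=11 TN=24 FP=6
  pred <- c(rep(1, 29), rep(0, 11), rep(0, 24), rep(1, 6))
  act <- c(rep(1, 40), rep(0, 30))
  cm <- confusion_metrics(pred, act)
  expect_equal(cm$accuracy, 53 / 70)
  expect_equal(cm$sensitivity, 29 / 40)
  expect_equal(cm$specificity, 24 / 30)
  # accuracy CI is the exact binomial interval
  expect_equal(cm$accuracy_ci,
               as.numeric(binom.test(53, 70)$conf.int))
  # no actual positives: sensitivity undefined
  expect_true(is.na(confusion_metrics(c(0, 1), c(0, 0))$sensitivity))
})

test_that("cross-validation is reproducible and perfect signals give
           perfect test accuracy", {
  co <- generate_cohort(generator_config(seed = 51, n_responders = 40,
                                         n_nonresponders = 30,
                                         base_panel_size = 10))
  # noiseless separating score: label-derived
  g <- setNames(ifelse(co$subjects$response == "responder", -5, 5) +
                  rnorm(70, sd = 0.1), co$subjects$subject_id)
  y <- as.integer(co$subjects$response == "responder")
  plan <- stratified_split(y, seed = 3, ids = co$subjects$subject_id)
  res <- cross_validate(co, g, plan)
  expect_equal(res$test$accuracy, 1)
  expect_equal(res$test$auc, 1)
  res2 <- cross_validate(co, g, plan)
  expect_identical(res, res2)
  # metrics are invariant under subject-id relabelling
  co2 <- co
  new_ids <- paste0("X", seq_len(70))
  co2$subjects$subject_id <- new_ids
  rownames(co2$dosage) <- new_ids
  g2 <- setNames(g, new_ids)
  plan2 <- plan
  plan2$train_ids <- new_ids[match(plan$train_ids,
                                   co$subjects$subject_id)]
  plan2$test_ids <- new_ids[match(plan$test_ids, co$subjects$subject_id)]
  names(plan2$fold_assignment) <-
    new_ids[match(names(plan$fold_assignment), co$subjects$subject_id)]
  res3 <- cross_validate(co2, g2, plan2)
  expect_equal(res3$test[c("accuracy", "auc", "sensitivity", "specificity")],
               res$test[c("accuracy", "auc", "sensitivity", "specificity")])
})

test_that("training metrics dominate test metrics on average (optimism)", {
  aucs <- vapply(1:15, function(s) {
    co <- generate_cohort(generator_config(
      seed = 100 + s, n_responders = 40, n_nonresponders = 30,
      base_panel_size = 8, base_maf_responders = 0.28,
      base_maf_nonresponders = 0.38))
    y <- as.integer(co$subjects$response == "responder")
    plan <- stratified_split(y, seed = s, ids = co$subjects$subject_id)
    res <- suppressWarnings(evaluate_pipeline(co, plan))
    c(res$train$auc, res$test$auc)
  }, numeric(2))
  expect_gt(mean(aucs[1, ]), mean(aucs[2, ]))
})
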