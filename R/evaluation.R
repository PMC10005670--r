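# internal: run expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Stratified train/test split with cross-validation folds
#'
#' Randomly splits labelled subjects into training and testing sets at the
#' given fraction, keeping the responder:nonresponder ratio of each part
#' within one subject of the overall ratio, and pre-assigns the training
#' subjects to `folds` stratified cross-validation folds. Deterministic
#' given `seed`.
#'
#' @param labels binary vector (1/`TRUE` = responder).
#' @param fraction training fraction, in (0, 1) (default 0.5).
#' @param seed integer seed.
#' @param ids subject ids parallel to `labels` (default positions).
#' @param folds number of CV folds (default 10).
#' @return object of class `split_plan`: `seed`, `train_ids`, `test_ids`,
#'   `fold_assignment` (named integer vector over the training ids),
#'   `folds`.
#' @export
stratified_split <- function(labels, fraction = 0.5, seed, ids = NULL,
                             folds = 10) {
  y <- as.integer(as.logical(labels))
  if (is.null(ids)) ids <- as.character(seq_along(y))
  stopifnot(length(ids) == length(y), !anyDuplicated(ids))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be strictly between 0 and 1")
  counts <- table(factor(y, levels = 0:1))
  if (any(counts < 2)) stop("each class needs at least 2 members")
  with_local_seed(seed, {
    n_total_train <- round(length(y) * fraction)
    # per-class training sizes: floors, then largest remainders
    raw <- as.numeric(counts) * fraction
    n_tr <- floor(raw)
    extra <- n_total_train - sum(n_tr)
    if (extra > 0) {
      ord <- order(raw - n_tr, decreasing = TRUE)
      n_tr[ord[seq_len(extra)]] <- n_tr[ord[seq_len(extra)]] + 1
    }
    train_ids <- character(0)
    for (cls in 0:1) {
      members <- ids[y == cls]
      take <- sample(members, n_tr[cls + 1])
      train_ids <- c(train_ids, take)
    }
    test_ids <- setdiff(ids, train_ids)
    # stratified fold assignment within training
    fold <- integer(0)
    for (cls in 0:1) {
      members <- sample(intersect(train_ids, ids[y == cls]))
      f <- rep_len(seq_len(folds), length(members))
      fold <- c(fold, stats::setNames(f, members))
    }
    structure(list(seed = seed, train_ids = train_ids, test_ids = test_ids,
                   fold_assignment = fold[train_ids], folds = folds),
              class = "split_plan")
  })
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' AUC is computed by the Mann-Whitney rank formula (ties counted one
#' half): the probability that a randomly chosen positive outscores a
#' randomly chosen negative. The 95% CI uses DeLong's method (via
#' \pkg{pROC}).
#'
#' @param scores numeric predictor; higher values should indicate the
#'   positive class.
#' @param labels binary vector (1/`TRUE` = positive class).
#' @param conf_level CI coverage (default 0.95).
#' @return list with `auc`, `ci_low`, `ci_high`.
#' @export
auc_roc <- function(scores, labels, conf_level = 0.95) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (length(unique(scores)) == 1) {
    warning("constant scores: AUC 0.5 with degenerate CI")
    return(list(auc = 0.5, ci_low = NA_real_, ci_high = NA_real_))
  }
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ci <- tryCatch(suppressWarnings({
    roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    as.numeric(pROC::ci.auc(roc, conf.level = conf_level,
                            method = "delong"))[c(1, 3)]
  }), error = function(e) c(NA_real_, NA_real_))
  list(auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[2]))
}

#' Accuracy, sensitivity and specificity of binary predictions
#'
#' Accuracy is the proportion of correct calls with an exact
#' (Clopper-Pearson) binomial CI; sensitivity is the proportion of actual
#' positives (responders) called positive; specificity the proportion of
#' actual negatives called negative. With no actual positives (negatives),
#' sensitivity (specificity) is `NA`.
#'
#' @param predicted,actual binary vectors of equal length
#'   (1/`TRUE` = responder).
#' @param conf_level CI coverage for accuracy (default 0.95).
#' @return list with `accuracy`, `accuracy_ci` (length 2), `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(predicted, actual, conf_level = 0.95) {
  p <- as.integer(as.logical(predicted))
  a <- as.integer(as.logical(actual))
  stopifnot(length(p) == length(a))
  n <- length(a)
  correct <- sum(p == a)
  ci <- as.numeric(stats::binom.test(correct, n,
                                     conf.level = conf_level)$conf.int)
  sens <- if (any(a == 1)) mean(p[a == 1] == 1) else NA_real_
  spec <- if (any(a == 0)) mean(p[a == 0] == 0) else NA_real_
  list(accuracy = correct / n, accuracy_ci = ci,
       sensitivity = sens, specificity = spec)
}

# internal: metric panel for predicted probabilities vs labels
metric_panel <- function(prob, y, threshold, tag) {
  cm <- confusion_metrics(prob >= threshold, y)
  auc <- if (length(unique(y)) == 2) auc_roc(prob, y)
         else list(auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  mcf <- if (length(unique(y)) == 2) {
    ll <- bernoulli_log_lik(y, prob)
    ll0 <- bernoulli_log_lik(y, rep(mean(y), length(y)))
    if (ll0 == 0) NA_real_ else max(0, 1 - ll / ll0)
  } else NA_real_
  structure(list(dataset_tag = tag, accuracy = cm$accuracy,
                 accuracy_ci = cm$accuracy_ci, auc = auc$auc,
                 auc_ci = c(auc$ci_low, auc$ci_high),
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 mcfadden = mcf, n = length(y)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> [%s, n=%d] accuracy %.3f [%.3f-%.3f]  AUC %.3f  sens %.3f  spec %.3f  McFadden %.3f\n",
    x$dataset_tag, x$n, x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2],
    x$auc, x$sensitivity, x$specificity, x$mcfadden))
  invisible(x)
}

#' Cross-validated and held-out evaluation of a GRS prediction model
#'
#' Follows the study protocol: within the training half of the split plan,
#' a logistic model (response ~ GRS, plus any clinical covariates) is fit
#' on 9/10 of the folds and evaluated on the held-out fold; the
#' cross-validation report averages the metric panel over folds. The final
#' model is then refit on the full training set and evaluated once on the
#' untouched test set, with DeLong (AUC) and Clopper-Pearson (accuracy)
#' confidence intervals. The classification threshold on the predicted
#' responder probability is 0.5 by default. Deterministic given the plan.
#'
#' @param cohort a labelled cohort.
#' @param grs a `score_set` (the GRS is computed from it) or a named
#'   numeric GRS vector indexed by subject id.
#' @param plan a [stratified_split()] plan over the cohort's labelled
#'   subjects.
#' @param covariates character vector of clinical covariates to add:
#'   any of `"age"`, `"sex"`, `"bmi"`, `"tg_baseline"` (default none).
#' @param threshold probability cutoff for calling a responder.
#' @return list with `cv` (fold-mean `metrics_report`), `train` and `test`
#'   reports, the final model `coefficients`, and `skipped_folds`.
#' @export
cross_validate <- function(cohort, grs, plan, covariates = character(0),
                           threshold = 0.5) {
  stopifnot(inherits(plan, "split_plan"))
  if (inherits(grs, "score_set")) grs <- compute_grs(cohort, grs)
  s <- cohort$subjects
  y_all <- response_indicator(s)
  keep <- !is.na(y_all)
  dat <- data.frame(subject_id = s$subject_id[keep], y = y_all[keep],
                    grs = unname(grs[s$subject_id[keep]]),
                    stringsAsFactors = FALSE)
  cov_map <- list(age = s$age, sex = as.numeric(s$sex == "male"),
                  bmi = s$bmi, tg_baseline = s$tg_baseline)
  bad <- setdiff(covariates, names(cov_map))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  for (cv_name in covariates) dat[[cv_name]] <- cov_map[[cv_name]][keep]
  rownames(dat) <- dat$subject_id
  miss_plan <- setdiff(c(plan$train_ids, plan$test_ids), dat$subject_id)
  if (length(miss_plan))
    stop("plan covers unlabelled/unknown subjects: ",
         paste(miss_plan, collapse = ", "))
  predictors <- c("grs", covariates)
  fit_on <- function(idx) fit_logistic(dat[idx, "y"],
                                       as.matrix(dat[idx, predictors,
                                                     drop = FALSE]))
  predict_fit <- function(fit, idx) {
    b <- fit$coefficients
    b[is.na(b)] <- 0
    X <- cbind(1, as.matrix(dat[idx, predictors, drop = FALSE]))
    stats::plogis(as.numeric(X %*% b))
  }

  skipped <- integer(0)
  fold_reports <- list()
  for (f in sort(unique(plan$fold_assignment))) {
    hold <- names(plan$fold_assignment)[plan$fold_assignment == f]
    train_f <- setdiff(plan$train_ids, hold)
    if (length(unique(dat[train_f, "y"])) < 2) {
      warning("fold ", f, " skipped: single-class training data")
      skipped <- c(skipped, f)
      next
    }
    fit_f <- fit_on(train_f)
    prob <- predict_fit(fit_f, hold)
    fold_reports[[length(fold_reports) + 1]] <-
      metric_panel(prob, dat[hold, "y"], threshold, "cv_fold")
  }
  cv <- if (length(fold_reports)) {
    avg <- function(fld) mean(vapply(fold_reports,
                                     function(r) r[[fld]], numeric(1)),
                              na.rm = TRUE)
    structure(list(dataset_tag = "cv_mean", accuracy = avg("accuracy"),
                   accuracy_ci = c(NA_real_, NA_real_), auc = avg("auc"),
                   auc_ci = c(NA_real_, NA_real_),
                   sensitivity = avg("sensitivity"),
                   specificity = avg("specificity"),
                   mcfadden = avg("mcfadden"),
                   n = length(plan$train_ids)),
              class = "metrics_report")
  } else NULL

  final <- fit_on(plan$train_ids)
  train_rep <- metric_panel(predict_fit(final, plan$train_ids),
                            dat[plan$train_ids, "y"], threshold, "train")
  test_rep <- metric_panel(predict_fit(final, plan$test_ids),
                           dat[plan$test_ids, "y"], threshold, "test")
  list(cv = cv, train = train_rep, test = test_rep,
       coefficients = final$coefficients, skipped_folds = skipped)
}

#' Leakage-free pipeline evaluation of a data-estimated GRS
#'
#' Runs the full scoring-plus-evaluation protocol without information
#' leaking from the test half into the score: per-variant odds ratios and
#' +1/-1 scores are estimated from the *training* subjects' group
#' frequencies only, the resulting GRS is computed for everyone, and
#' [cross_validate()] supplies the cross-validated and held-out metric
#' panels.
#'
#' @param cohort a labelled cohort.
#' @param plan a [stratified_split()] plan over the cohort's labelled
#'   subjects.
#' @param variant_ids variants to score (default: all in the cohort).
#' @param covariates passed to [cross_validate()].
#' @return the [cross_validate()] result, plus `entries` (the
#'   training-estimated score table) and `grs`.
#' @export
evaluate_pipeline <- function(cohort, plan, variant_ids = NULL,
                              covariates = character(0)) {
  if (is.null(variant_ids)) variant_ids <- cohort$variants$variant_id
  train <- subset_cohort(cohort, plan$train_ids)
  qc <- variant_qc(train)
  qc <- qc[qc$variant_id %in% variant_ids & !qc$monomorphic, , drop = FALSE]
  n_r <- sum(train$subjects$response == "responder", na.rm = TRUE)
  n_nr <- sum(train$subjects$response == "nonresponder", na.rm = TRUE)
  entries <- score_table(qc, n_r, n_nr)
  set <- new_score_set("pipeline", entries)
  grs <- compute_grs(cohort, set)
  res <- cross_validate(cohort, grs, plan, covariates = covariates)
  res$entries <- entries
  res$grs <- grs
  res
}

#' Train/test metric table across several score sets
#'
#' Runs [cross_validate()] for each score set under one split plan and
#' lays the results out as metrics x (score set, dataset) — the shape of
#' a predictive-performance comparison table.
#'
#' @inheritParams cross_validate
#' @param score_sets named list of `score_set` objects or of named GRS
#'   vectors.
#' @return data frame with columns `metric` then `<name>_train`,
#'   `<name>_test` per score set.
#' @export
evaluate_score_sets <- function(cohort, score_sets, plan,
                                covariates = character(0), threshold = 0.5) {
  metrics <- c("accuracy", "auc", "sensitivity", "specificity", "mcfadden")
  out <- data.frame(metric = c("Accuracy", "AUC-ROC", "Sensitivity",
                               "Specificity", "McFadden"),
                    stringsAsFactors = FALSE)
  for (nm in names(score_sets)) {
    res <- cross_validate(cohort, score_sets[[nm]], plan,
                          covariates = covariates, threshold = threshold)
    out[[paste0(nm, "_train")]] <-
      vapply(metrics, function(m) res$train[[m]], numeric(1))
    out[[paste0(nm, "_test")]] <-
      vapply(metrics, function(m) res$test[[m]], numeric(1))
  }
  out
}
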