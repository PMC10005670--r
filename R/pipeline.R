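#' Default nested score-set membership for a variant panel
#'
#' Builds the study's nested panels from the variant ids present: the base
#' set (all synthetic `base_snp_*` variants, standing in for the original
#' 31-SNP score), then that base plus rs55707100, plus the
#' TG-associated subset of the study panel, plus the full study panel.
#' Set names carry the total entry counts (GRS31, GRS32, ... at the
#' default sizes).
#'
#' @param variant_ids variant ids available after QC.
#' @param annotation annotation table with a `phenotype` column (default
#'   [fas_annotation()]).
#' @return named list of variant-id vectors.
#' @export
default_score_set_ids <- function(variant_ids, annotation = fas_annotation()) {
  base <- grep("^base_snp_", variant_ids, value = TRUE)
  study <- setdiff(variant_ids, base)
  tg <- intersect(study, annotation$variant_id[
    !is.na(annotation$phenotype) & annotation$phenotype == "TG"])
  sets <- list(base)
  names(sets) <- paste0("GRS", length(base))
  if ("rs55707100" %in% study) {
    sets[[paste0("GRS", length(base) + 1)]] <- c(base, "rs55707100")
  }
  if (length(tg)) {
    sets[[paste0("GRS", length(base) + length(tg))]] <- c(base, tg)
  }
  if (length(study)) {
    sets[[paste0("GRS", length(base) + length(study))]] <- c(base, study)
  }
  sets
}

#' Pipeline stage 1: simulate a cohort and write its fixture bundle
#'
#' @param out_dir output directory.
#' @param seed integer seed (ignored when `config` is supplied).
#' @param config optional [generator_config()] overriding the defaults.
#' @return invisibly, the written file paths.
#' @export
run_simulate <- function(out_dir, seed = 1L, config = NULL) {
  if (is.null(config)) config <- generator_config(seed = seed)
  cohort <- generate_cohort(config)
  message("simulate: seed ", config$seed, ", ", nrow(cohort$subjects),
          " subjects x ", nrow(cohort$variants), " variants -> ", out_dir)
  write_fixture_bundle(cohort, out_dir)
}

#' Pipeline stage 2: QC, odds-ratio scoring and GRS profiles
#'
#' Reads a fixture bundle (PLINK pair + phenotype and annotation TSVs),
#' labels subjects from their TG change when no label column is present,
#' removes monomorphic variants (flagging HWE failures), estimates
#' per-variant odds ratios from the labelled per-group frequencies,
#' assigns +1/-1 scores, assembles the nested score sets and computes all
#' GRS profiles. Writes `qc_report.tsv`, `score_table.tsv` and
#' `grs_profiles.tsv` into `out_dir`.
#'
#' @param input_dir directory holding `cohort.ped`, `cohort.map`,
#'   `phenotypes.tsv`, `annotation.tsv` (as written by [run_simulate()]).
#' @param out_dir output directory.
#' @param score_set_ids named list of variant-id vectors; default
#'   [default_score_set_ids()] on the post-QC panel.
#' @param weights optional data frame `variant_id`, `weight` for weighted
#'   scores.
#' @param hwe_alpha HWE flag level.
#' @return invisibly, a list with `cohort`, `qc`, `entries`, `score_sets`,
#'   `profiles`.
#' @export
run_build_grs <- function(input_dir, out_dir, score_set_ids = NULL,
                          weights = NULL, hwe_alpha = 0.05) {
  ann_path <- file.path(input_dir, "annotation.tsv")
  annotation <- if (file.exists(ann_path))
    utils::read.table(ann_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c(chromosome = "character")) else NULL
  phen <- read_phenotypes(file.path(input_dir, "phenotypes.tsv"))
  cohort <- read_plink_text(file.path(input_dir, "cohort.ped"),
                            file.path(input_dir, "cohort.map"),
                            annotation = annotation, phenotypes = phen)
  if (!"response" %in% names(cohort$subjects))
    cohort <- label_cohort(cohort)
  qcres <- qc_filter(cohort, hwe_alpha = hwe_alpha)
  if (nrow(qcres$log))
    message("build-grs: excluded ", nrow(qcres$log), " variant(s): ",
            paste(qcres$log$variant_id, collapse = ", "))
  cohort <- qcres$cohort
  n_r <- sum(cohort$subjects$response == "responder", na.rm = TRUE)
  n_nr <- sum(cohort$subjects$response == "nonresponder", na.rm = TRUE)
  keep_qc <- qcres$qc[qcres$qc$variant_id %in% cohort$variants$variant_id, ]
  entries <- score_table(keep_qc, n_r, n_nr)
  if (!is.null(weights))
    entries$weight <- weights$weight[match(entries$variant_id,
                                           weights$variant_id)]
  if (is.null(score_set_ids)) {
    ann_for_sets <- annotation %||% fas_annotation()
    score_set_ids <- default_score_set_ids(entries$variant_id, ann_for_sets)
  }
  missing_ids <- setdiff(unique(unlist(score_set_ids)), entries$variant_id)
  if (length(missing_ids))
    stop("score set(s) name unavailable variant(s): ",
         paste(missing_ids, collapse = ", "))
  score_sets <- lapply(names(score_set_ids), function(nm)
    new_score_set(nm, entries[entries$variant_id %in% score_set_ids[[nm]], ,
                              drop = FALSE]))
  names(score_sets) <- names(score_set_ids)
  if (all(is.na(entries$score)))
    warning("no scoreable variants: every odds ratio is excluded")
  profiles <- grs_profiles(cohort, score_sets)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_qc_report(qcres, file.path(out_dir, "qc_report.tsv"))
  write_score_table(entries, file.path(out_dir, "score_table.tsv"))
  utils::write.table(profiles, file.path(out_dir, "grs_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cohort = cohort, qc = qcres$qc, entries = entries,
                 score_sets = score_sets, profiles = profiles))
}

#' Pipeline stage 3: discrimination metrics and threshold reports
#'
#' Splits the labelled subjects 50/50 (stratified), runs tenfold
#' cross-validation in the training half for every GRS column, evaluates
#' the refit models on the test half, sweeps cutoffs for the primary GRS
#' and writes the decision-aid recommendation. Outputs in `out_dir`:
#' `metrics.tsv`, `roc_points.csv`, `cutoff_sweep.csv`,
#' `summary_points.tsv`, `decision_aid.json`.
#'
#' @param input_dir fixture-bundle directory (for `phenotypes.tsv`).
#' @param grs_dir directory holding `grs_profiles.tsv` (from
#'   [run_build_grs()]).
#' @param out_dir output directory.
#' @param seed integer seed for the split.
#' @param split_fraction training fraction (default 0.5).
#' @param folds CV folds (default 10).
#' @param covariates clinical covariates added to each model (see
#'   [cross_validate()]).
#' @param cutoff `"median"`, `"top_tertile"`, or a numeric GRS cutoff for
#'   the decision aid.
#' @param primary GRS column used for threshold analysis (default the
#'   first).
#' @return invisibly, a list with `plan`, `metrics`, `sweep`, `summary`,
#'   `aid`.
#' @export
run_evaluate <- function(input_dir, grs_dir, out_dir, seed = 1L,
                         split_fraction = 0.5, folds = 10,
                         covariates = character(0), cutoff = "top_tertile",
                         primary = NULL) {
  stopifnot(folds >= 2, split_fraction > 0, split_fraction < 1)
  phen <- read_phenotypes(file.path(input_dir, "phenotypes.tsv"))
  if (!"response" %in% names(phen)) {
    lab <- classify_response(phen$tg_baseline, phen$tg_post)
    phen$response <- as.character(lab)
  }
  profiles <- utils::read.table(file.path(grs_dir, "grs_profiles.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  grs_names <- setdiff(names(profiles), "subject_id")
  if (length(grs_names) == 0) stop("grs_profiles.tsv has no GRS columns")
  if (is.null(primary)) primary <- grs_names[1]
  if (!primary %in% grs_names)
    stop("missing GRS column for score set '", primary, "'")

  labelled <- phen$response %in% c("responder", "nonresponder")
  n_drop <- sum(!labelled)
  if (n_drop) message("evaluate: excluded ", n_drop,
                      " unclassified subject(s)")
  phen <- phen[labelled, , drop = FALSE]
  idx <- match(phen$subject_id, profiles$subject_id)
  if (anyNA(idx))
    stop("subjects missing from GRS profiles: ",
         paste(phen$subject_id[is.na(idx)], collapse = ", "))
  skel <- new_cohort(phen,
                     data.frame(variant_id = character(0)),
                     matrix(numeric(0), nrow = 0, ncol = 0))
  y <- as.integer(phen$response == "responder")
  message("evaluate: split seed ", seed, ", fraction ", split_fraction,
          ", ", folds, " folds")
  plan <- stratified_split(y, fraction = split_fraction, seed = seed,
                           ids = phen$subject_id, folds = folds)
  grs_vectors <- lapply(grs_names, function(nm)
    stats::setNames(profiles[[nm]][idx], phen$subject_id))
  names(grs_vectors) <- grs_names
  metrics <- evaluate_score_sets(skel, grs_vectors, plan,
                                 covariates = covariates)

  g <- grs_vectors[[primary]]
  sweep <- cutoff_sweep(g, y)
  summary <- summary_points(g, y)
  cut_val <- if (is.numeric(cutoff)) cutoff
             else summary$grs_value[match(cutoff, summary$point)]
  if (is.na(cut_val)) stop("unknown cutoff policy: ", cutoff)
  aid <- decision_aid(stats::median(g), cut_val, sweep)
  roc <- data.frame(cutoff = sweep$cutoff,
                    tpr = sweep$sensitivity,
                    fpr = 1 - sweep$specificity)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(format(metrics, digits = 6),
                     file.path(out_dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(roc, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep, file.path(out_dir, "cutoff_sweep.csv"),
                   row.names = FALSE)
  utils::write.table(summary, file.path(out_dir, "summary_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(aid, file.path(out_dir, "decision_aid.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(plan = plan, metrics = metrics, sweep = sweep,
                 summary = summary, aid = aid))
}
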