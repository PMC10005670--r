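#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the supplementation study the analysis pipeline is
#' built for: 80 extreme responders and 60 nonresponders; the packaged
#' 17-variant panel at its published per-group minor-allele frequencies
#' (two variants monomorphic); a 31-variant synthetic base panel whose
#' group-MAF separation emulates the discrimination of the original GRS31;
#' TG changes of -0.50 +/- 0.36 mmol/L in responders and +0.18 +/- 0.17
#' mmol/L in nonresponders; ages uniform on 18-50 years, BMI uniform on
#' 25-40 kg/m^2; log-normal baseline TG with a higher median in responders
#' (who started higher) than nonresponders.
#'
#' @param n_responders,n_nonresponders group sizes.
#' @param variant_panel data frame with `variant_id`, `maf_responders`,
#'   `maf_nonresponders` (default [fas_variant_panel()]).
#' @param base_panel_size number of synthetic base-panel variants.
#' @param base_maf_responders,base_maf_nonresponders group MAFs shared by
#'   every base-panel variant; set them equal for a null (no-signal) panel.
#' @param tg_change_responders,tg_change_nonresponders length-2 `(mean, sd)`
#'   of the TG change, mmol/L.
#' @param baseline_tg_median_responders,baseline_tg_median_nonresponders
#'   medians of the log-normal baseline TG, mmol/L.
#' @param baseline_tg_sdlog log-scale SD of baseline TG.
#' @param age_range,bmi_range uniform sampling ranges.
#' @param extreme_fraction minimum relative TG decrease required of
#'   responders (the extreme-responder selection); set 0 to disable.
#' @param tg_floor smallest admissible post-supplementation TG, mmol/L.
#' @param seed integer seed driving all randomness.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_responders = 80, n_nonresponders = 60,
                             variant_panel = fas_variant_panel(),
                             base_panel_size = 31,
                             base_maf_responders = 0.25,
                             base_maf_nonresponders = 0.40,
                             tg_change_responders = c(-0.50, 0.36),
                             tg_change_nonresponders = c(0.18, 0.17),
                             baseline_tg_median_responders = 1.70,
                             baseline_tg_median_nonresponders = 1.20,
                             baseline_tg_sdlog = 0.30,
                             age_range = c(18, 50),
                             bmi_range = c(25, 40),
                             extreme_fraction = 0.10,
                             tg_floor = 0.05,
                             seed = 1L) {
  cfg <- list(n_responders = n_responders,
              n_nonresponders = n_nonresponders,
              variant_panel = variant_panel,
              base_panel_size = base_panel_size,
              base_maf_responders = base_maf_responders,
              base_maf_nonresponders = base_maf_nonresponders,
              tg_change_responders = tg_change_responders,
              tg_change_nonresponders = tg_change_nonresponders,
              baseline_tg_median_responders = baseline_tg_median_responders,
              baseline_tg_median_nonresponders = baseline_tg_median_nonresponders,
              baseline_tg_sdlog = baseline_tg_sdlog,
              age_range = age_range, bmi_range = bmi_range,
              extreme_fraction = extreme_fraction, tg_floor = tg_floor,
              seed = as.integer(seed))
  stopifnot(cfg$n_responders > 0, cfg$n_nonresponders > 0,
            cfg$base_panel_size >= 0,
            cfg$base_maf_responders >= 0, cfg$base_maf_responders <= 0.5,
            cfg$base_maf_nonresponders >= 0,
            cfg$base_maf_nonresponders <= 0.5,
            cfg$tg_change_responders[2] > 0,
            cfg$tg_change_nonresponders[2] > 0,
            all(cfg$variant_panel$maf_responders >= 0),
            all(cfg$variant_panel$maf_responders <= 0.5),
            all(cfg$variant_panel$maf_nonresponders >= 0),
            all(cfg$variant_panel$maf_nonresponders <= 0.5))
  structure(cfg, class = "generator_config")
}

# internal: full generation panel = synthetic base variants + study panel,
# with annotation columns needed to write PLINK/VCF fixtures
generation_panel <- function(config) {
  panel <- config$variant_panel
  ann <- tryCatch(fas_annotation(), error = function(e) NULL)
  base <- if (config$base_panel_size > 0) {
    data.frame(variant_id = sprintf("base_snp_%02d",
                                    seq_len(config$base_panel_size)),
               maf_responders = config$base_maf_responders,
               maf_nonresponders = config$base_maf_nonresponders,
               chromosome = "1",
               position = 1000000L * seq_len(config$base_panel_size),
               major_allele = "A", minor_allele = "G",
               nearest_gene = NA_character_, phenotype = NA_character_,
               stringsAsFactors = FALSE)
  } else NULL
  study <- data.frame(variant_id = panel$variant_id,
                      maf_responders = panel$maf_responders,
                      maf_nonresponders = panel$maf_nonresponders,
                      stringsAsFactors = FALSE)
  if (!is.null(ann) && all(study$variant_id %in% ann$variant_id)) {
    idx <- match(study$variant_id, ann$variant_id)
    study$chromosome <- ann$chromosome[idx]
    study$position <- ann$position[idx]
    study$major_allele <- ann$major_allele[idx]
    study$minor_allele <- ann$minor_allele[idx]
    study$nearest_gene <- ann$nearest_gene[idx]
    study$phenotype <- ann$phenotype[idx]
  } else {
    study$chromosome <- "2"
    study$position <- 1000000L * seq_len(nrow(study))
    study$major_allele <- "A"
    study$minor_allele <- "G"
    study$nearest_gene <- NA_character_
    study$phenotype <- NA_character_
  }
  rbind(base, study[, names(base) %||% names(study), drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic responder/nonresponder cohort
#'
#' Group labels are fixed by the configured counts. Genotypes are drawn
#' independently per variant as Binomial(2, group MAF) — i.e. in
#' Hardy-Weinberg proportions within each group, with no linkage
#' disequilibrium. TG changes are drawn from the group's normal
#' distribution with rejection so that every generated responder satisfies
#' the classification rule (change <= -0.01 mmol/L, and at least the
#' configured relative decrease) and every nonresponder has change >= 0;
#' post-supplementation TG is floored at `tg_floor`. Deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return a labelled [new_cohort()] object of
#'   `n_responders + n_nonresponders` subjects.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    n_r <- config$n_responders; n_nr <- config$n_nonresponders
    n <- n_r + n_nr
    is_resp <- rep(c(TRUE, FALSE), c(n_r, n_nr))
    ids <- sprintf("S%03d", seq_len(n))

    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    bmi <- stats::runif(n, config$bmi_range[1], config$bmi_range[2])
    sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "male", "female")
    med <- ifelse(is_resp, config$baseline_tg_median_responders,
                  config$baseline_tg_median_nonresponders)
    tg_base <- stats::rlnorm(n, meanlog = log(med),
                             sdlog = config$baseline_tg_sdlog)

    draw_delta <- function(i) {
      par <- if (is_resp[i]) config$tg_change_responders
             else config$tg_change_nonresponders
      for (attempt in seq_len(10000)) {
        d <- stats::rnorm(1, par[1], par[2])
        ok <- if (is_resp[i]) {
          d <= -0.01 && (-d / tg_base[i]) >= config$extreme_fraction &&
            tg_base[i] + d >= config$tg_floor
        } else d >= 0
        if (ok) return(d)
      }
      stop("could not generate an admissible TG change for subject ", ids[i],
           "; the configured change distribution is incompatible with the ",
           "classification rule")
    }
    delta <- vapply(seq_len(n), draw_delta, numeric(1))
    subjects <- data.frame(subject_id = ids, age = age, sex = sex, bmi = bmi,
                           tg_baseline = tg_base, tg_post = tg_base + delta,
                           response = ifelse(is_resp, "responder",
                                             "nonresponder"),
                           stringsAsFactors = FALSE)

    panel <- generation_panel(config)
    dosage <- matrix(NA_real_, nrow = n, ncol = nrow(panel),
                     dimnames = list(ids, panel$variant_id))
    for (j in seq_len(nrow(panel))) {
      dosage[is_resp, j] <- stats::rbinom(n_r, 2, panel$maf_responders[j])
      dosage[!is_resp, j] <- stats::rbinom(n_nr, 2,
                                           panel$maf_nonresponders[j])
    }
    variants <- panel[, c("variant_id", "chromosome", "position",
                          "major_allele", "minor_allele", "nearest_gene",
                          "phenotype")]
    new_cohort(subjects, variants, dosage)
  })
}

#' Generate label-permuted null replicates of a cohort
#'
#' Returns `n_reps` copies of the cohort, identical except that the
#' response labels are independently permuted — the null stream used to
#' calibrate association tests and pipeline AUC. Deterministic given
#' `seed`.
#'
#' @param cohort a labelled cohort.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return list of `n_reps` cohorts.
#' @export
generate_null_pair <- function(cohort, n_reps, seed) {
  stopifnot(n_reps >= 1)
  with_local_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      perm <- sample(nrow(cohort$subjects))
      cohort$subjects$response <- cohort$subjects$response[perm]
      if ("extreme" %in% names(cohort$subjects))
        cohort$subjects$extreme <- cohort$subjects$extreme[perm]
      cohort
    })
  })
}

#' Write a cohort as a fixture bundle of standard files
#'
#' Emits six files into `directory`: the PLINK text pair
#' (`cohort.ped`/`cohort.map`), a VCF (`cohort.vcf`), the phenotype TSV
#' (`phenotypes.tsv`), the variant annotation TSV (`annotation.tsv`) and a
#' score-table TSV (`score_table.tsv`, computed from the cohort's labelled
#' per-group frequencies unless `score_entries` is supplied). All files
#' round-trip through the package's readers.
#'
#' @param cohort a labelled cohort.
#' @param directory output directory (created if needed).
#' @param score_entries optional score-entry data frame to write as-is.
#' @return invisibly, the named vector of file paths.
#' @export
write_fixture_bundle <- function(cohort, directory, score_entries = NULL) {
  if (nrow(cohort$subjects) == 0 || nrow(cohort$variants) == 0)
    stop("refusing to write an empty cohort")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(directory, "cohort.ped"),
             map = file.path(directory, "cohort.map"),
             vcf = file.path(directory, "cohort.vcf"),
             phenotypes = file.path(directory, "phenotypes.tsv"),
             annotation = file.path(directory, "annotation.tsv"),
             score_table = file.path(directory, "score_table.tsv"))
  write_plink_text(cohort, paths["ped"], paths["map"])
  write_vcf(cohort, paths["vcf"])
  write_phenotypes(cohort$subjects, paths["phenotypes"])
  utils::write.table(cohort$variants, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (is.null(score_entries)) {
    qc <- variant_qc(cohort)
    score_entries <- score_table(qc, sum(cohort$subjects$response ==
                                           "responder", na.rm = TRUE),
                                 sum(cohort$subjects$response ==
                                       "nonresponder", na.rm = TRUE))
  }
  write_score_table(score_entries, paths["score_table"])
  invisible(paths)
}
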