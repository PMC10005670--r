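#' Construct a cohort object
#'
#' A `cohort` bundles the three pieces of a supplementation-response study:
#' subject phenotypes, variant annotations, and a subjects x variants
#' minor-allele dosage matrix.
#'
#' @param subjects data frame with columns `subject_id`, `age`, `sex`
#'   (`"female"`/`"male"`), `bmi`, `tg_baseline`, `tg_post` and optionally
#'   `response` (`"responder"`, `"nonresponder"`, `"unclassified"`). TG is in
#'   mmol/L, age in years, BMI in kg/m^2.
#' @param variants data frame with columns `variant_id`, `chromosome`,
#'   `position`, `major_allele`, `minor_allele` and optionally
#'   `nearest_gene`, `phenotype`.
#' @param dosage numeric matrix of minor-allele copy counts in
#'   \{0, 1, 2, NA\}, with rownames = subject ids and colnames = variant ids.
#'
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(subjects, variants, dosage) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  dosage <- as.matrix(dosage)
  obj <- structure(
    list(subjects = subjects, variants = variants, dosage = dosage),
    class = "cohort"
  )
  validate_cohort(obj)
  obj
}

#' Validate a cohort object's invariants
#'
#' Checks id uniqueness, dosage range, matrix/annotation agreement and
#' physical bounds on phenotypes. Called by [new_cohort()]; exported so that
#' readers and the generator can re-check after manipulation.
#'
#' @param x a `cohort`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  s <- x$subjects; v <- x$variants; d <- x$dosage
  need_s <- c("subject_id", "age", "sex", "bmi", "tg_baseline", "tg_post")
  miss <- setdiff(need_s, names(s))
  if (length(miss))
    stop("subject table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(s$subject_id)) stop("duplicated subject ids")
  if (anyDuplicated(v$variant_id)) stop("duplicated variant ids")
  if (!all(s$sex %in% c("female", "male", NA)))
    stop("sex must be 'female' or 'male'")
  bad_tg <- stats::na.omit(c(s$tg_baseline, s$tg_post)) <= 0
  if (any(bad_tg)) stop("TG concentrations must be positive")
  if (!is.null(s$bmi) && any(stats::na.omit(s$bmi) <= 0))
    stop("BMI must be positive")
  vals <- d[!is.na(d)]
  if (!all(vals %in% 0:2)) stop("dosage entries must be 0, 1, 2 or NA")
  if (!all(rownames(d) %in% s$subject_id))
    stop("dosage rows not all present in subject table")
  if (!all(colnames(d) %in% v$variant_id))
    stop("dosage columns not all present in variant table")
  if ("position" %in% names(v) && any(stats::na.omit(v$position) < 1))
    stop("positions are 1-based and must be >= 1")
  if (all(c("major_allele", "minor_allele") %in% names(v)) &&
      any(v$major_allele == v$minor_allele, na.rm = TRUE))
    stop("major and minor allele must differ")
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  n_lab <- if ("response" %in% names(x$subjects))
    table(factor(x$subjects$response,
                 levels = c("responder", "nonresponder", "unclassified")))
  cat("<cohort> ", nrow(x$subjects), " subjects x ", nrow(x$variants),
      " variants\n", sep = "")
  if (!is.null(n_lab))
    cat("  responders: ", n_lab[["responder"]],
        "  nonresponders: ", n_lab[["nonresponder"]],
        "  unclassified: ", n_lab[["unclassified"]], "\n", sep = "")
  n_miss <- sum(is.na(x$dosage))
  cat("  missing dosages: ", n_miss, " (",
      signif(100 * n_miss / length(x$dosage), 3), "%)\n", sep = "")
  invisible(x)
}

#' Restrict a cohort to a subset of subjects
#'
#' @param cohort a cohort.
#' @param subject_ids ids to keep (order preserved as given).
#' @return the restricted cohort.
#' @export
subset_cohort <- function(cohort, subject_ids) {
  idx <- match(subject_ids, cohort$subjects$subject_id)
  if (anyNA(idx))
    stop("unknown subject id(s): ",
         paste(subject_ids[is.na(idx)], collapse = ", "))
  cohort$subjects <- cohort$subjects[idx, , drop = FALSE]
  rownames(cohort$subjects) <- NULL
  cohort$dosage <- cohort$dosage[match(subject_ids, rownames(cohort$dosage)),
                                 , drop = FALSE]
  cohort
}

# internal: dosage matrix aligned to the subject table's order
cohort_dosage <- function(cohort, variant_ids = NULL) {
  d <- cohort$dosage[match(cohort$subjects$subject_id, rownames(cohort$dosage)),
                     , drop = FALSE]
  if (!is.null(variant_ids)) {
    missing_v <- setdiff(variant_ids, colnames(d))
    if (length(missing_v))
      stop("variants absent from genotype data: ",
           paste(missing_v, collapse = ", "))
    d <- d[, variant_ids, drop = FALSE]
  }
  d
}

# internal: response labels as 1 = responder, 0 = nonresponder, NA otherwise
response_indicator <- function(subjects) {
  r <- rep(NA_real_, nrow(subjects))
  if ("response" %in% names(subjects)) {
    r[subjects$response == "responder"] <- 1
    r[subjects$response == "nonresponder"] <- 0
  }
  r
}
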