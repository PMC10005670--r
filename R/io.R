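#' Read genotypes from a PLINK text fileset (.ped/.map)
#'
#' Parses the whitespace-separated PLINK text format: six mandatory leading
#' columns per `.ped` row (family, individual, paternal and maternal id, sex
#' code, phenotype) followed by two allele columns per variant; four columns
#' per `.map` row (chromosome, variant id, genetic distance, position).
#' `"0"` alleles mark missing genotypes.
#'
#' Dosage is the count of minor-allele copies. The minor allele is taken
#' from `annotation` when supplied (so orientation is stable even if the
#' sample MAF crosses 0.5), otherwise the empirically rarer allele (ties
#' broken toward the alphabetically later allele).
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @param annotation optional data frame with `variant_id`, `major_allele`,
#'   `minor_allele` (e.g. [fas_annotation()]).
#' @param phenotypes optional subject table (see [read_phenotypes()]) merged
#'   by `subject_id`.
#' @return A [new_cohort()] object. Sex is decoded from the PLINK code
#'   (1 = male, 2 = female) when no phenotype table overrides it.
#' @export
read_plink_text <- function(ped_path, map_path, annotation = NULL,
                            phenotypes = NULL) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chromosome", "variant_id",
                                         "cm", "position"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  expect_width <- 6L + 2L * m
  widths <- lengths(fields)
  if (any(widths != expect_width))
    stop(".ped line ", which(widths != expect_width)[1],
         " has ", widths[widths != expect_width][1],
         " fields; expected ", expect_width)
  ped <- do.call(rbind, fields)
  ids <- ped[, 2]
  sex <- c("1" = "male", "2" = "female")[ped[, 5]]
  alleles <- ped[, -(1:6), drop = FALSE]
  ok <- alleles %in% c("A", "C", "G", "T", "0")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = FALSE)[1]
    stop(".ped line ", (bad - 1) %% nrow(alleles) + 1,
         ": allele '", alleles[bad], "' not in {A,C,G,T,0}")
  }
  a1 <- alleles[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- alleles[, seq(2, 2 * m, by = 2), drop = FALSE]

  dosage <- matrix(NA_real_, nrow = length(ids), ncol = m,
                   dimnames = list(ids, map$variant_id))
  major <- minor <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    called <- x1 != "0" & x2 != "0"
    mm <- variant_allele_pair(map$variant_id[j], c(x1[called], x2[called]),
                              annotation)
    major[j] <- mm[1]; minor[j] <- mm[2]
    dosage[called, j] <- (x1[called] == mm[2]) + (x2[called] == mm[2])
  }
  variants <- data.frame(variant_id = map$variant_id,
                         chromosome = map$chromosome,
                         position = map$position,
                         major_allele = major, minor_allele = minor,
                         stringsAsFactors = FALSE)
  build_cohort_from_parts(ids, sex, variants, dosage, phenotypes, annotation)
}

# internal: decide (major, minor) for one variant from annotation or counts
variant_allele_pair <- function(variant_id, observed, annotation) {
  if (!is.null(annotation) && variant_id %in% annotation$variant_id) {
    row <- annotation[match(variant_id, annotation$variant_id), ]
    return(c(toupper(row$major_allele), toupper(row$minor_allele)))
  }
  tab <- table(observed)
  if (length(tab) == 0) return(c(NA_character_, NA_character_))
  if (length(tab) == 1) {
    obs <- names(tab)
    other <- setdiff(c("A", "C", "G", "T"), obs)[1]
    return(c(obs, other))          # monomorphic: unseen allele is the minor
  }
  if (length(tab) > 2)
    stop("variant ", variant_id, " has more than two alleles")
  ord <- order(tab, names(tab))    # rarest first; ties -> alphabetically later
  c(names(tab)[ord[2]], names(tab)[ord[1]])
}

# internal: assemble cohort, merging an optional phenotype table
build_cohort_from_parts <- function(ids, sex, variants, dosage,
                                    phenotypes, annotation) {
  subjects <- data.frame(subject_id = ids, age = NA_real_, sex = unname(sex),
                         bmi = NA_real_, tg_baseline = NA_real_,
                         tg_post = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(phenotypes)) {
    idx <- match(ids, phenotypes$subject_id)
    if (anyNA(idx))
      stop("subjects missing from phenotype table: ",
           paste(ids[is.na(idx)], collapse = ", "))
    subjects <- phenotypes[idx, , drop = FALSE]
    rownames(subjects) <- NULL
  }
  if (!is.null(annotation)) {
    idx <- match(variants$variant_id, annotation$variant_id)
    for (col in intersect(c("nearest_gene", "phenotype"), names(annotation)))
      variants[[col]] <- annotation[[col]][idx]
  }
  new_cohort(subjects, variants, dosage)
}

#' Read genotypes from a VCF file
#'
#' Reads a VCF (v4.2, GT field, diploid biallelic records) via the `vcfR`
#' package and converts genotypes to minor-allele dosages. When `annotation`
#' marks the REF allele as the minor allele, the ALT count is flipped
#' (`2 - count`) with a warning; without annotation the rarer allele is
#' taken as minor. `./.` becomes missing.
#'
#' @inheritParams read_plink_text
#' @param vcf_path path to an (uncompressed or gzipped) VCF.
#' @return A [new_cohort()] object.
#' @export
read_vcf <- function(vcf_path, annotation = NULL, phenotypes = NULL) {
  stopifnot(file.exists(vcf_path))
  v <- suppressWarnings(vcfR::read.vcfR(vcf_path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic site(s) present; split them (e.g. `bcftools norm -m-`) first")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  alt_count <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                      dimnames = dimnames(gt))
  alt_count[gt == "0/0"] <- 0
  alt_count[gt %in% c("0/1", "1/0")] <- 1
  alt_count[gt == "1/1"] <- 2
  unknown <- !is.na(gt) & is.na(alt_count) & gt != "./."
  if (any(unknown))
    stop("unparsable GT value(s): ", paste(unique(gt[unknown]), collapse = ", "))

  ids <- colnames(gt)
  m <- nrow(fix)
  dosage <- t(alt_count)
  major <- toupper(fix$REF); minor <- toupper(fix$ALT)
  for (j in seq_len(m)) {
    vid <- fix$ID[j]
    flip <- FALSE
    if (!is.null(annotation) && vid %in% annotation$variant_id) {
      row <- annotation[match(vid, annotation$variant_id), ]
      if (toupper(fix$ALT[j]) == toupper(row$major_allele) &&
          toupper(fix$REF[j]) == toupper(row$minor_allele)) {
        flip <- TRUE
      } else if (toupper(fix$ALT[j]) != toupper(row$minor_allele)) {
        stop("variant ", vid, ": VCF alleles disagree with annotation")
      }
    } else {
      af <- mean(dosage[, j], na.rm = TRUE) / 2
      flip <- is.finite(af) && af > 0.5
    }
    if (flip) {
      warning("variant ", vid, ": ALT is the major allele; dosage flipped")
      dosage[, j] <- 2 - dosage[, j]
      major[j] <- toupper(fix$ALT[j]); minor[j] <- toupper(fix$REF[j])
    }
  }
  colnames(dosage) <- fix$ID
  variants <- data.frame(variant_id = fix$ID, chromosome = fix$CHROM,
                         position = as.integer(fix$POS),
                         major_allele = major, minor_allele = minor,
                         stringsAsFactors = FALSE)
  build_cohort_from_parts(ids, rep(NA_character_, length(ids)), variants,
                          dosage, phenotypes, annotation)
}

#' Read a subject phenotype table
#'
#' Tab-separated, one row per subject, header
#' `subject_id age sex bmi tg_baseline tg_post` with an optional `response`
#' column (carried through unchanged) and arbitrary extra columns
#' (preserved).
#'
#' @param tsv_path path to the TSV file.
#' @return data frame of typed subject records.
#' @export
read_phenotypes <- function(tsv_path) {
  stopifnot(file.exists(tsv_path))
  x <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "bmi", "tg_baseline", "tg_post")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("phenotype table lacks required column(s): ",
         paste(miss, collapse = ", "))
  x$subject_id <- as.character(x$subject_id)
  for (col in c("age", "bmi", "tg_baseline", "tg_post"))
    x[[col]] <- as.numeric(x[[col]])
  if (any(stats::na.omit(x$bmi) <= 0)) stop("BMI must be positive")
  if (any(stats::na.omit(c(x$tg_baseline, x$tg_post)) <= 0))
    stop("TG concentrations must be positive")
  if (!all(x$sex %in% c("female", "male", NA)))
    stop("sex must be 'female' or 'male'")
  x
}

#' Classify the triglyceride response to supplementation
#'
#' A subject is a responder when plasma TG fell
#' (`tg_post - tg_baseline <= responder_bound`, default −0.01 mmol/L) and a
#' nonresponder when TG was stable or rose (change `>= nonresponder_bound`,
#' default 0.00 mmol/L). Changes strictly between the two bounds are
#' `"unclassified"`. The returned vector carries an `"extreme"` attribute
#' flagging responders whose relative TG decrease was at least
#' `extreme_fraction` (default 10%), the criterion used to select extreme
#' responders into the study sample.
#'
#' @param tg_baseline,tg_post TG concentrations in mmol/L (vectors).
#' @param extreme_fraction minimum relative decrease for the extreme flag.
#' @param responder_bound,nonresponder_bound classification bounds on the
#'   TG change, in mmol/L.
#' @return character vector of labels with attribute `"extreme"` (logical).
#' @export
classify_response <- function(tg_baseline, tg_post, extreme_fraction = 0.10,
                              responder_bound = -0.01,
                              nonresponder_bound = 0) {
  if (length(tg_baseline) != length(tg_post))
    stop("tg_baseline and tg_post must have equal length")
  if (anyNA(tg_baseline) || anyNA(tg_post))
    stop("cannot classify: missing TG value(s)")
  stopifnot(responder_bound < nonresponder_bound)
  delta <- tg_post - tg_baseline
  lab <- rep("unclassified", length(delta))
  lab[delta <= responder_bound] <- "responder"
  lab[delta >= nonresponder_bound] <- "nonresponder"
  extreme <- lab == "responder" & (-delta / tg_baseline >= extreme_fraction)
  attr(lab, "extreme") <- extreme
  lab
}

#' Fill a cohort's response labels from its TG measurements
#'
#' @param cohort a [new_cohort()] object with complete TG columns.
#' @param ... passed to [classify_response()].
#' @return the cohort with `response` and `extreme` subject columns set.
#' @export
label_cohort <- function(cohort, ...) {
  lab <- classify_response(cohort$subjects$tg_baseline,
                           cohort$subjects$tg_post, ...)
  cohort$subjects$response <- as.character(lab)
  cohort$subjects$extreme <- attr(lab, "extreme")
  cohort
}

#' Write a cohort's genotypes as a PLINK text fileset
#'
#' @param cohort a cohort.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_plink_text <- function(cohort, ped_path, map_path) {
  v <- cohort$variants
  utils::write.table(
    data.frame(v$chromosome, v$variant_id, 0, v$position),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  d <- cohort_dosage(cohort)
  s <- cohort$subjects
  sex_code <- ifelse(is.na(s$sex), "0", ifelse(s$sex == "male", "1", "2"))
  all_rows <- vapply(seq_len(nrow(s)), function(i) {
    g <- vapply(seq_len(nrow(v)), function(j) {
      dij <- d[i, j]
      if (is.na(dij)) return("0 0")
      paste(c(rep(v$major_allele[j], 2 - dij), rep(v$minor_allele[j], dij)),
            collapse = " ")
    }, character(1))
    paste(c(s$subject_id[i], s$subject_id[i], "0", "0", sex_code[i], "-9", g),
          collapse = " ")
  }, character(1))
  writeLines(all_rows, ped_path)
  invisible(c(ped_path, map_path))
}

#' Write a cohort's genotypes as a minimal VCF v4.2
#'
#' REF is the major and ALT the minor allele, so ALT counts equal the stored
#' dosages; missing dosages become `./.`.
#'
#' @param cohort a cohort.
#' @param vcf_path output path.
#' @return invisibly, the path.
#' @export
write_vcf <- function(cohort, vcf_path) {
  v <- cohort$variants
  d <- cohort_dosage(cohort)
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    gt <- ifelse(is.na(d[, j]), "./.", gt_of[d[, j] + 1])
    paste(c(v$chromosome[j], v$position[j], v$variant_id[j],
            v$major_allele[j], v$minor_allele[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##source=omega3grs",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$subjects$subject_id),
                    collapse = "\t"))
  writeLines(c(header, body), vcf_path)
  invisible(vcf_path)
}

#' Write a subject phenotype table as TSV
#'
#' @param subjects subject data frame (e.g. `cohort$subjects`).
#' @param tsv_path output path.
#' @return invisibly, the path.
#' @export
write_phenotypes <- function(subjects, tsv_path) {
  utils::write.table(subjects, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}
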