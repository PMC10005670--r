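#' Packaged SNP annotation panel from the FAS fish-oil study
#'
#' The 17-variant panel genotyped in the Fatty Acid Sensor (FAS) Study:
#' 15 polymorphic SNPs identified in UK Biobank gene-by-fish-oil
#' interaction analyses (with chromosome, position, nearest gene, alleles,
#' pooled MAF, HWE p-value and associated lipid phenotype) plus the two
#' SNPs found monomorphic in FAS (rs147166404, rs530804537), whose
#' coordinates and alleles are synthetic placeholders (chromosome 0),
#' flagged in the `notes` column.
#'
#' @return data frame, one row per variant.
#' @export
fas_annotation <- function() {
  path <- system.file("extdata", "fas_snp_annotation.tsv",
                      package = "omega3grs", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", fill = TRUE,
                    quote = "", stringsAsFactors = FALSE,
                    colClasses = c(chromosome = "character"))
}

#' Packaged per-group allele frequencies and published scores
#'
#' The 15 polymorphic FAS-study variants with responder and nonresponder
#' minor-allele frequencies, the published odds ratios (computed by the
#' original analysts from unrounded allele counts) with 95% CIs, and the
#' published +1/−1 score column; rs77542162 (responder MAF 0) is the
#' excluded row.
#'
#' @return data frame, one row per variant.
#' @export
fas_score_table <- function() {
  path <- system.file("extdata", "fas_score_table.tsv",
                      package = "omega3grs", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Default generator panel: published frequencies plus monomorphic SNPs
#'
#' Joins [fas_score_table()]'s per-group MAFs with the two monomorphic
#' variants (both group MAFs 0) to form the 17-variant panel the study
#' genotyped, in annotation order.
#'
#' @return data frame: `variant_id`, `maf_responders`, `maf_nonresponders`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `score`.
#' @export
fas_variant_panel <- function() {
  ann <- fas_annotation()
  sc <- fas_score_table()
  idx <- match(ann$variant_id, sc$variant_id)
  out <- data.frame(variant_id = ann$variant_id,
                    maf_responders = sc$maf_responders[idx],
                    maf_nonresponders = sc$maf_nonresponders[idx],
                    odds_ratio = sc$odds_ratio[idx],
                    ci_low = sc$ci_low[idx],
                    ci_high = sc$ci_high[idx],
                    score = sc$score[idx],
                    stringsAsFactors = FALSE)
  mono <- is.na(idx)
  out$maf_responders[mono] <- 0
  out$maf_nonresponders[mono] <- 0
  out
}
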