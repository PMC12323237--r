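# benchmark_builder: labeled validation benchmarks from ClinVar-style
# clinical-significance tables and MPRA activity/skew tables, applying
# the exact whitelist, length, contig and threshold rules.

#' ClinVar-style filter policy
#'
#' Whitelist-only retention: records whose clinical significance is in
#' the pathogenic set are labeled 1, those in the benign set 0, and all
#' other significance values (uncertain, conflicting, ...) are dropped.
#' Variants longer than `max_allele_length` base pairs (boundary
#' inclusive) and mitochondrial variants are removed.
#'
#' @param pathogenic_labels significance values labeled 1.
#' @param benign_labels significance values labeled 0 (must be disjoint
#'   from the pathogenic set).
#' @param max_allele_length maximum InDel length in bp (default 50,
#'   inclusive).
#' @param drop_mito drop chrM records (default TRUE).
#' @param assembly assembly tag recorded for provenance (default
#'   "GRCh38").
#' @return a list of class `clinvar_filter_policy`.
#' @export
clinvar_filter_policy <- function(
    pathogenic_labels = c("Pathogenic", "Likely pathogenic",
                          "Pathogenic/Likely pathogenic"),
    benign_labels = c("Likely benign", "Benign", "Benign/Likely benign"),
    max_allele_length = 50L, drop_mito = TRUE, assembly = "GRCh38") {
  if (length(intersect(pathogenic_labels, benign_labels)) > 0L) {
    vp_stop("pathogenic and benign label sets must be disjoint")
  }
  structure(list(pathogenic_labels = pathogenic_labels,
                 benign_labels = benign_labels,
                 max_allele_length = as.integer(max_allele_length),
                 drop_mito = drop_mito, assembly = assembly),
            class = "clinvar_filter_policy")
}

#' Build a ClinVar-style benchmark
#'
#' Applies the policy's type/length/contig rules and the significance
#' whitelist; pathogenic records are labeled 1 and benign records 0, all
#' others dropped. Input order is preserved among retained records.
#'
#' @param records a variant table with a `significance` column.
#' @param policy a [clinvar_filter_policy()].
#' @return a [labeled_dataset()].
#' @export
build_clinvar_benchmark <- function(records, policy = clinvar_filter_policy()) {
  check_columns(records, "significance", "ClinVar-style table")
  len_ok <- nchar(records$ref) <= policy$max_allele_length &
    nchar(records$alt) <= policy$max_allele_length
  contig_ok <- if (policy$drop_mito) records$chrom != "chrM" else TRUE
  sig <- records$significance
  keep <- len_ok & contig_ok &
    sig %in% c(policy$pathogenic_labels, policy$benign_labels)
  out <- records[keep, , drop = FALSE]
  labeled_dataset(validate_variant_table(out, require_frequency = FALSE),
                  labels = as.integer(out$significance %in%
                                        policy$pathogenic_labels))
}

#' MPRA effect thresholds
#'
#' A variant has a gene-regulatory effect when its element shows
#' significant activity (`A_logP > 3` and `B_logP > 3`), a significant
#' allelic difference (`Skew_logP > 4`) and an absolute effect of at
#' least 1 (`|skewStat| >= 1`), in at least three of five cell types.
#' It is neutral when activity is significant at the stricter bound
#' (`A_logP > 4`, `B_logP > 4`), the allelic difference is not
#' significant (`Skew_logP < 2`) and the absolute effect is at most 0.15,
#' in at least four of five cell types — and its consequence is not a
#' splice or (non-)coding exonic effect. Strictness is exactly as
#' written: activity and skew significance strict, effect-size bounds
#' inclusive.
#'
#' @param regulatory,neutral lists of threshold values (see defaults).
#' @param n_cell_types number of assayed cell types (5).
#' @param neutral_excluded_consequences consequence labels barred from
#'   the neutral set: the coding partition plus splice and noncoding
#'   exonic labels.
#' @return a list of class `mpra_thresholds`.
#' @export
mpra_thresholds <- function(
    regulatory = list(activity_logp = 3, skew_logp = 4, abs_skew = 1,
                      min_cell_types = 3L),
    neutral = list(activity_logp = 4, skew_logp = 2, abs_skew = 0.15,
                   min_cell_types = 4L),
    n_cell_types = 5L,
    neutral_excluded_consequences = c(consequence_partition()$coding,
                                      "SPLICE_SITE", "CANONICAL_SPLICE",
                                      "NONCODING_CHANGE")) {
  structure(list(regulatory = regulatory, neutral = neutral,
                 n_cell_types = as.integer(n_cell_types),
                 neutral_excluded_consequences =
                   unique(neutral_excluded_consequences)),
            class = "mpra_thresholds")
}

#' Build an MPRA-derived regulatory benchmark
#'
#' Input is a long table with one row per variant-by-cell-type
#' measurement. Variants meeting the regulatory criterion in enough cell
#' types are labeled 1; variants meeting the neutral criterion in enough
#' cell types (and without a splice/coding-exonic consequence) are
#' labeled 0. Variants qualifying for both labels — conflicting
#' duplicates across experiments — are removed from both sets and their
#' count reported in the `n_conflicts` attribute.
#'
#' @param measurements data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `cell_type`, `A_logP`, `B_logP`, `Skew_logP`, `skewStat` and
#'   optionally `consequence`.
#' @param thresholds an [mpra_thresholds()].
#' @return a [labeled_dataset()] (columns chrom, pos, ref, alt plus
#'   consequence when given); attribute `n_conflicts`.
#' @export
build_mpra_benchmark <- function(measurements,
                                 thresholds = mpra_thresholds()) {
  check_columns(measurements,
                c("chrom", "pos", "ref", "alt", "cell_type", "A_logP",
                  "B_logP", "Skew_logP", "skewStat"), "MPRA table")
  measurements$chrom <- normalize_contig(measurements$chrom)
  key <- paste(measurements$chrom, measurements$pos, measurements$ref,
               measurements$alt, sep = ":")
  n_ct <- tapply(measurements$cell_type, key,
                 function(x) length(unique(x)))
  too_many <- names(n_ct)[n_ct > thresholds$n_cell_types]
  if (length(too_many) > 0L) {
    vp_stop("variant %s measured in more than %d cell types", too_many[1L],
            thresholds$n_cell_types)
  }
  reg_hit <- measurements$A_logP > thresholds$regulatory$activity_logp &
    measurements$B_logP > thresholds$regulatory$activity_logp &
    measurements$Skew_logP > thresholds$regulatory$skew_logp &
    abs(measurements$skewStat) >= thresholds$regulatory$abs_skew
  neu_hit <- measurements$A_logP > thresholds$neutral$activity_logp &
    measurements$B_logP > thresholds$neutral$activity_logp &
    measurements$Skew_logP < thresholds$neutral$skew_logp &
    abs(measurements$skewStat) <= thresholds$neutral$abs_skew
  reg_n <- tapply(reg_hit, key, sum)
  neu_n <- tapply(neu_hit, key, sum)
  uk <- unique(key)
  first <- match(uk, key)
  cq <- if ("consequence" %in% names(measurements)) {
    measurements$consequence[first]
  } else rep(NA_character_, length(uk))
  is_reg <- reg_n[uk] >= thresholds$regulatory$min_cell_types
  is_neu <- neu_n[uk] >= thresholds$neutral$min_cell_types &
    !(cq %in% thresholds$neutral_excluded_consequences)
  conflict <- is_reg & is_neu
  keep <- (is_reg | is_neu) & !conflict
  sel <- first[keep]
  records <- data.frame(chrom = measurements$chrom[sel],
                        pos = as.integer(measurements$pos[sel]),
                        ref = measurements$ref[sel],
                        alt = measurements$alt[sel],
                        ac = rep(NA_integer_, length(sel)),
                        an = rep(NA_integer_, length(sel)),
                        af = rep(NA_real_, length(sel)),
                        filter = rep("PASS", length(sel)),
                        stringsAsFactors = FALSE)
  if ("consequence" %in% names(measurements)) {
    records$consequence <- cq[keep]
  }
  out <- labeled_dataset(validate_variant_table(records,
                                                require_frequency = FALSE),
                         labels = as.integer(is_reg[keep]))
  attr(out, "n_conflicts") <- sum(conflict)
  out
}
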