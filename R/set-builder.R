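# set_builder: site filtering, frequency stratification, substitution-
# spectrum matched subsampling, and assembly of proxy-labeled training
# pairs (balanced with matching, or unbalanced with class weights).

#' Frequency thresholds for stratifying population variants
#'
#' Defaults follow the standing-variation stratification: variants with
#' MAF >= 0.001 are "frequent" (proxy-benign), variants with AC = 1 are
#' "singletons", the remainder below the MAF bound are "rare", and variants
#' with AF above 0.5 are excluded from analysis.
#'
#' @param maf_frequent MAF bound at/above which a variant is frequent
#'   (default 0.001, boundary inclusive).
#' @param singleton_ac allele count defining a singleton (default 1).
#' @param af_exclude_above variants with `af` strictly above this are
#'   excluded (default 0.5).
#' @return a list of class `frequency_thresholds`.
#' @export
frequency_thresholds <- function(maf_frequent = 0.001, singleton_ac = 1L,
                                 af_exclude_above = 0.5) {
  if (!(maf_frequent > 0 && maf_frequent < af_exclude_above &&
        af_exclude_above <= 1)) {
    vp_stop("need 0 < maf_frequent < af_exclude_above <= 1")
  }
  structure(list(maf_frequent = maf_frequent,
                 singleton_ac = as.integer(singleton_ac),
                 af_exclude_above = af_exclude_above),
            class = "frequency_thresholds")
}

#' Site filter policy
#'
#' Sites with unacceptable FILTER status (e.g. limited coverage), sites on
#' alternative haplotypes or unplaced contigs, and (by default) the
#' mitochondrial genome are dropped before stratification.
#'
#' @param allowed_contigs contigs to retain (default chr1-chr22, chrX,
#'   chrY).
#' @param pass_filters acceptable `filter` values (default "PASS").
#' @param drop_mito drop chrM even if listed (default TRUE).
#' @return a list of class `filter_policy`.
#' @export
filter_policy <- function(allowed_contigs = paste0("chr", c(1:22, "X", "Y")),
                          pass_filters = "PASS", drop_mito = TRUE) {
  if (length(allowed_contigs) == 0L) vp_stop("allowed_contigs is empty")
  structure(list(allowed_contigs = allowed_contigs,
                 pass_filters = pass_filters, drop_mito = drop_mito),
            class = "filter_policy")
}

#' Filter sites by contig and FILTER status
#'
#' Retains records lying on allowed contigs with an acceptable filter
#' status; the mitochondrial genome is dropped when `policy$drop_mito`.
#' Relative record order is preserved; an empty result is allowed.
#'
#' @param records a variant table.
#' @param policy a [filter_policy()].
#' @return the retained subset of `records`.
#' @export
filter_sites <- function(records, policy = filter_policy()) {
  keep <- records$chrom %in% policy$allowed_contigs &
    records$filter %in% policy$pass_filters
  if (policy$drop_mito) keep <- keep & records$chrom != "chrM"
  records[keep, , drop = FALSE]
}

#' Classify variants into frequency strata
#'
#' Applies, in order: `af > af_exclude_above` -> `excluded`; `ac ==
#' singleton_ac` -> `singleton`; `MAF < maf_frequent` -> `rare`; otherwise
#' `frequent`. The partition is exhaustive and exclusive. Records in the
#' singleton/rare decision region with missing `ac` raise an error because
#' singleton detection requires the allele count.
#'
#' @param records a variant table.
#' @param thresholds a [frequency_thresholds()].
#' @return factor with levels `singleton`, `rare`, `frequent`, `excluded`.
#' @export
classify_frequency <- function(records, thresholds = frequency_thresholds()) {
  af <- records$af
  if (anyNA(af)) vp_stop("af required for frequency classification")
  cls <- rep(NA_character_, nrow(records))
  cls[af > thresholds$af_exclude_above] <- "excluded"
  open <- is.na(cls)
  need_ac <- open & is.na(records$ac)
  if (any(need_ac)) {
    vp_stop("record %d: ac required for singleton detection",
            which(need_ac)[1L])
  }
  cls[open & records$ac == thresholds$singleton_ac] <- "singleton"
  open <- is.na(cls)
  m <- pmin(af, 1 - af)
  cls[open & m < thresholds$maf_frequent] <- "rare"
  cls[is.na(cls)] <- "frequent"
  factor(cls, levels = c("singleton", "rare", "frequent", "excluded"))
}

#' Split a variant table into frequency strata
#'
#' @param records a variant table.
#' @param thresholds a [frequency_thresholds()].
#' @return named list of variant tables: `singleton`, `rare`, `frequent`,
#'   `excluded`.
#' @export
stratify_by_frequency <- function(records,
                                  thresholds = frequency_thresholds()) {
  cls <- classify_frequency(records, thresholds)
  lapply(stats::setNames(levels(cls), levels(cls)),
         function(l) records[cls == l, , drop = FALSE])
}

# canonical class order: the 12 ordered SNV substitution classes
# (alphabetical), then deletion length classes 1..50, then insertions.
snv_classes <- function() {
  b <- c("A", "C", "G", "T")
  cls <- as.vector(outer(b, b, function(r, a) paste0(r, ">", a)))
  sort(cls[substr(cls, 1, 1) != substr(cls, 3, 3)])
}

indel_classes <- function(cap = 50L) {
  c(sprintf("del:%02d", seq_len(cap)), sprintf("ins:%02d", seq_len(cap)))
}

#' Substitution / InDel-length class of each record
#'
#' SNVs map to one of the 12 ordered `ref>alt` classes (no strand
#' collapsing). InDels map to `del:LL` / `ins:LL` with the length
#' difference capped at 50 (longer events pooled at 50).
#'
#' @param records a variant table.
#' @param cap InDel length cap (default 50).
#' @return character vector of class names.
#' @export
spectrum_class <- function(records, cap = 50L) {
  lr <- nchar(records$ref); la <- nchar(records$alt)
  out <- character(nrow(records))
  snv <- lr == 1L & la == 1L
  out[snv] <- paste0(records$ref[snv], ">", records$alt[snv])
  len <- pmin(abs(la - lr), cap)
  ins <- !snv & la > lr
  del <- !snv & la <= lr
  out[ins] <- sprintf("ins:%02d", len[ins])
  out[del] <- sprintf("del:%02d", len[del])
  out
}

#' Substitution-spectrum histogram
#'
#' Counts records per substitution class (12 ordered SNV classes) and per
#' InDel class (insertion/deletion crossed with length 1..50, longer
#' pooled at 50). The class counts sum to the number of records; this
#' histogram is the currency of matched subsampling.
#'
#' @param records a variant table.
#' @param cap InDel length cap (default 50).
#' @return named integer vector of class `spectrum_histogram`, ordered by
#'   the canonical class order.
#' @export
spectrum <- function(records, cap = 50L) {
  classes <- c(snv_classes(), indel_classes(cap))
  counts <- table(factor(spectrum_class(records, cap), levels = classes))
  structure(stats::setNames(as.integer(counts), classes),
            class = "spectrum_histogram")
}

#' @export
print.spectrum_histogram <- function(x, ...) {
  nz <- x[x > 0]
  cat(sprintf("spectrum_histogram: %d records, %d occupied classes\n",
              sum(x), length(nz)))
  if (length(nz) > 0) print(unclass(nz))
  invisible(x)
}

#' Largest-remainder apportionment
#'
#' Distributes `n` among classes proportionally to `proportions`, flooring
#' quotas and assigning leftover units by decreasing fractional remainder;
#' remainder ties are broken by class order (earlier class wins), making
#' the apportionment fully deterministic.
#'
#' @param n total to apportion.
#' @param proportions named non-negative numeric vector summing to ~1.
#' @return named integer vector summing exactly to `n`.
#' @export
largest_remainder <- function(n, proportions) {
  p <- proportions / sum(proportions)
  quota <- n * p
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  if (left > 0L) {
    rem <- quota - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

#' Spectrum-matched subsample
#'
#' Draws exactly `n` records from `pool` so that per-class counts equal
#' the largest-remainder apportionment of `n` by the target spectrum's
#' class proportions; within each class, selection is uniform without
#' replacement under `seed`. Deterministic for a fixed pool order and
#' seed. Classes required by the target but under-represented in the pool
#' raise an infeasibility error naming the deficient class.
#'
#' @param pool a variant table to sample from.
#' @param target a [spectrum()] histogram defining target proportions.
#' @param n requested sample size (`n <= nrow(pool)`).
#' @param seed RNG seed.
#' @return a variant table of exactly `n` records (pool order preserved).
#' @export
matched_sample <- function(pool, target, n, seed = 1L) {
  if (n > nrow(pool)) vp_stop("requested n (%d) exceeds pool size (%d)", n,
                              nrow(pool))
  tprop <- target[target > 0] / sum(target)
  alloc <- largest_remainder(n, tprop)
  pcls <- spectrum_class(pool)
  idx <- with_seed(seed, {
    sel <- integer(0)
    for (cl in names(alloc)) {
      if (alloc[[cl]] == 0L) next
      avail <- which(pcls == cl)
      if (length(avail) < alloc[[cl]]) {
        vp_stop("matching infeasible: class %s needs %d record(s), pool has %d",
                cl, alloc[[cl]], length(avail))
      }
      sel <- c(sel, if (length(avail) == 1L) avail else
        sample(avail, alloc[[cl]]))
    }
    sel
  })
  pool[sort(idx), , drop = FALSE]
}

#' Configuration of one proxy-labeled training pair
#'
#' @param identifier label such as `"fr"`, `"fs"`, `"hs-all"`, `"hfs"`.
#' @param benign_source one of `frequent`, `rare`, `human_derived`,
#'   `human_derived_plus_frequent`.
#' @param deleterious_source one of `rare`, `singleton`.
#' @param balanced subsample the deleterious source to the benign size
#'   (`TRUE`) or keep it whole with class weights (`FALSE`).
#' @param match_spectrum match substitution rates and InDel lengths of the
#'   deleterious subsample to the benign set (balanced pairs only).
#' @param seed RNG seed for all subsampling.
#' @return a list of class `pair_config`.
#' @export
pair_config <- function(identifier, benign_source, deleterious_source,
                        balanced = TRUE, match_spectrum = TRUE, seed = 1L) {
  benign_source <- match.arg(benign_source,
                             c("frequent", "rare", "human_derived",
                               "human_derived_plus_frequent"))
  deleterious_source <- match.arg(deleterious_source, c("rare", "singleton"))
  if (benign_source == deleterious_source) {
    vp_stop("benign and deleterious sources must differ")
  }
  structure(list(identifier = identifier, benign_source = benign_source,
                 deleterious_source = deleterious_source,
                 balanced = balanced, match_spectrum = match_spectrum,
                 seed = as.integer(seed)),
            class = "pair_config")
}

benign_records <- function(strata, human_derived, config) {
  switch(config$benign_source,
         frequent = strata$frequent,
         rare = strata$rare,
         human_derived = {
           if (is.null(human_derived)) {
             vp_stop("pair %s requires a human-derived cohort",
                     config$identifier)
           }
           human_derived
         },
         human_derived_plus_frequent = {
           if (is.null(human_derived)) {
             vp_stop("pair %s requires a human-derived cohort",
                     config$identifier)
           }
           common <- intersect(names(human_derived), names(strata$frequent))
           rbind(as.data.frame(human_derived)[common],
                 as.data.frame(strata$frequent)[common])
         })
}

#' Assemble a proxy-labeled training pair
#'
#' Benign records are labeled 0 and deleterious records 1. SNVs and InDels
#' are handled as separate matching universes. For a balanced pair, the
#' deleterious source is subsampled per universe to the benign count —
#' spectrum-matched to the benign set when `config$match_spectrum`,
#' uniformly otherwise; a deleterious pool smaller than the benign set is
#' an infeasibility error. For an unbalanced pair, the entire deleterious
#' source is retained unmatched and per-record weights are set so that the
#' summed weight per label class is equal (minority-class weight
#' `n_majority / n_minority`, majority weight 1).
#'
#' @param strata named list of variant tables from
#'   [stratify_by_frequency()].
#' @param config a [pair_config()].
#' @param human_derived optional human-derived variant table (required for
#'   `hs`/`hfs`-style pairs).
#' @param thresholds a [frequency_thresholds()] (recorded for provenance).
#' @return a [labeled_dataset()].
#' @export
build_training_pair <- function(strata, config, human_derived = NULL,
                                thresholds = frequency_thresholds()) {
  benign <- benign_records(strata, human_derived, config)
  delet <- strata[[config$deleterious_source]]
  if (is.null(benign) || nrow(benign) == 0L) {
    vp_stop("pair %s: benign source `%s` is empty", config$identifier,
            config$benign_source)
  }
  if (is.null(delet) || nrow(delet) == 0L) {
    vp_stop("pair %s: deleterious source `%s` is empty", config$identifier,
            config$deleterious_source)
  }
  common <- intersect(names(benign), names(delet))
  benign <- as.data.frame(benign)[common]
  delet <- as.data.frame(delet)[common]
  label_pair(benign, delet, balanced = config$balanced,
             match_spectrum = config$match_spectrum, seed = config$seed,
             identifier = config$identifier)
}

#' Label an explicit benign / deleterious record pair
#'
#' Lower-level worker behind [build_training_pair()], useful when the two
#' cohorts are supplied directly (e.g. human-derived vs simulated).
#' Applies the same balancing, matching and weighting rules.
#'
#' @param benign,deleterious variant tables.
#' @inheritParams build_training_pair
#' @param balanced,match_spectrum,seed see [pair_config()].
#' @param identifier label recorded in error messages.
#' @return a [labeled_dataset()].
#' @export
label_pair <- function(benign, deleterious, balanced = TRUE,
                       match_spectrum = TRUE, seed = 1L,
                       identifier = "pair") {
  if (balanced) {
    picked <- list()
    for (u in c("snv", "indel")) {
      b_u <- benign[if (u == "snv") is_snv(benign) else !is_snv(benign), ,
                    drop = FALSE]
      d_u <- deleterious[if (u == "snv") is_snv(deleterious) else
        !is_snv(deleterious), , drop = FALSE]
      if (nrow(b_u) == 0L) next
      if (nrow(d_u) < nrow(b_u)) {
        vp_stop("pair %s: deleterious %s pool (%d) smaller than benign set (%d)",
                identifier, u, nrow(d_u), nrow(b_u))
      }
      picked[[u]] <- if (match_spectrum) {
        matched_sample(d_u, spectrum(b_u), nrow(b_u), seed = seed +
                         (u == "indel"))
      } else {
        idx <- with_seed(seed + 2L * (u == "indel"),
                         sample(nrow(d_u), nrow(b_u)))
        d_u[sort(idx), , drop = FALSE]
      }
    }
    delet_sel <- do.call(rbind, unname(picked))
    records <- rbind(benign, delet_sel)
    labeled_dataset(validate_variant_table(records),
                    labels = rep(c(0L, 1L), c(nrow(benign), nrow(delet_sel))),
                    balanced = TRUE)
  } else {
    n_b <- nrow(benign); n_d <- nrow(deleterious)
    n_max <- max(n_b, n_d)
    records <- rbind(benign, deleterious)
    labeled_dataset(validate_variant_table(records),
                    labels = rep(c(0L, 1L), c(n_b, n_d)),
                    weights = rep(c(n_max / n_b, n_max / n_d), c(n_b, n_d)),
                    balanced = FALSE)
  }
}

#' Planned pair sizes from per-stratum counts
#'
#' Computes, without touching any records, the benign and deleterious
#' sizes a [build_training_pair()] call would produce from per-stratum
#' SNV/InDel counts: for a balanced pair the deleterious subsample equals
#' the benign count per variant type; for an unbalanced pair the entire
#' deleterious stratum is kept.
#'
#' @param counts data.frame with columns `stratum` (singleton, rare,
#'   frequent, human_derived), `snvs`, `indels`.
#' @param config a [pair_config()].
#' @return data.frame with rows `benign`, `deleterious` and columns
#'   `snvs`, `indels`.
#' @export
pair_plan <- function(counts, config) {
  check_columns(counts, c("stratum", "snvs", "indels"), "stratum counts")
  pick <- function(s) {
    row <- counts[counts$stratum == s, , drop = FALSE]
    if (nrow(row) == 0L) vp_stop("stratum `%s` absent from counts", s)
    c(snvs = sum(row$snvs), indels = sum(row$indels))
  }
  ben <- switch(config$benign_source,
                frequent = pick("frequent"), rare = pick("rare"),
                human_derived = pick("human_derived"),
                human_derived_plus_frequent = pick("human_derived") +
                  pick("frequent"))
  del_pool <- pick(config$deleterious_source)
  del <- if (config$balanced) ben else del_pool
  if (config$balanced && any(del_pool < ben)) {
    vp_stop("pair %s: deleterious pool smaller than benign set",
            config$identifier)
  }
  data.frame(role = c("benign", "deleterious"),
             snvs = c(ben[["snvs"]], del[["snvs"]]),
             indels = c(ben[["indels"]], del[["indels"]]))
}

#' Per-stratum SNV/InDel counts
#'
#' @param strata named list of variant tables (e.g. from
#'   [stratify_by_frequency()]).
#' @param human_derived optional human-derived variant table appended as
#'   stratum `human_derived`.
#' @return data.frame with columns `stratum`, `snvs`, `indels`.
#' @export
stratum_counts <- function(strata, human_derived = NULL) {
  strata <- strata[setdiff(names(strata), "excluded")]
  if (!is.null(human_derived)) strata$human_derived <- human_derived
  do.call(rbind, lapply(names(strata), function(s) {
    r <- strata[[s]]
    data.frame(stratum = s, snvs = sum(is_snv(r)), indels = sum(!is_snv(r)))
  }))
}

#' Summarize frequency strata and the frequent-stratum share
#'
#' Reports per-stratum SNV and InDel counts plus the share (in percent) of
#' the frequent stratum among all retained population variants (singleton
#' + rare + frequent; a human-derived stratum, when present, is reported
#' but not part of the denominator).
#'
#' @param counts data.frame with columns `stratum`, `snvs`, `indels`
#'   (e.g. from [stratum_counts()]).
#' @return list with elements `counts` (the table with a `total` column)
#'   and `frequent_share_percent`.
#' @export
stratum_summary <- function(counts) {
  check_columns(counts, c("stratum", "snvs", "indels"), "stratum counts")
  counts$total <- counts$snvs + counts$indels
  pop <- counts[counts$stratum %in% c("singleton", "rare", "frequent"), ,
                drop = FALSE]
  share <- 100 * sum(pop$total[pop$stratum == "frequent"]) / sum(pop$total)
  list(counts = counts, frequent_share_percent = share)
}
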