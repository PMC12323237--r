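# Fixtures built in code: toy variant tables, a small simulated study,
# and independent metric oracles used to cross-check the implementation.

# toy variant table of SNVs with controllable substitution classes
toy_variants <- function(classes, ac = 1L, an = 1000L, chrom = "chr1",
                         filter = "PASS") {
  n <- length(classes)
  variant_table(chrom = rep(chrom, length.out = n), pos = seq_len(n) * 10L,
                ref = substr(classes, 1, 1), alt = substr(classes, 3, 3),
                ac = rep(ac, length.out = n), an = rep(an, length.out = n),
                af = rep(ac, length.out = n) / rep(an, length.out = n),
                filter = rep(filter, length.out = n))
}

# small simulated study shared by several tests (cached per session)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- simulation_params(n_sites = 20000L, seed = 1L)
      sim <- simulate_population_variants(p)
      cache <<- list(params = p, variants = sim$variants, truth = sim$truth,
                     strata = stratify_by_frequency(sim$variants))
    }
    cache
  }
})

# independent AUROC oracle: explicit pair counting, ties worth 1/2
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# 12 substitution-class indicator columns for a variant table
class_indicator_features <- function(records) {
  cls <- factor(spectrum_class(records), levels = snv_classes())
  m <- vapply(levels(cls), function(l) as.numeric(cls == l),
              numeric(nrow(records)))
  colnames(m) <- levels(cls)
  m
}

# ClinVar-style toy table: 8 rows exercising every filter rule
clinvar_toy <- function() {
  df <- data.frame(
    chrom = c("chr1", "chr1", "chrM", "chr2", "chr3", "chr4", "chr5",
              "chr6"),
    pos = seq_len(8) * 100L,
    ref = c("A", paste(rep("A", 61), collapse = ""), "G", "T", "C", "A",
            "G", "T"),
    alt = c("G", "A", "A", "C", paste(rep("T", 4), collapse = ""), "C",
            "A", "G"),
    ac = NA_integer_, an = NA_integer_, af = NA_real_, filter = "PASS",
    significance = c("Pathogenic", "Benign", "Likely benign",
                     "Uncertain significance", "Benign/Likely benign",
                     "Pathogenic/Likely pathogenic", "Benign",
                     "Conflicting interpretations of pathogenicity"),
    stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

# one MPRA measurement row
mpra_row <- function(pos, cell_type, a, b, skew, stat, consequence = NA) {
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
             cell_type = cell_type, A_logP = a, B_logP = b,
             Skew_logP = skew, skewStat = stat, consequence = consequence,
             stringsAsFactors = FALSE)
}
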