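# synthetic_data: seeded generator of population variant tables,
# annotation matrices and validation labels carrying the statistical
# structure the method assumes — a truncated power-law site frequency
# spectrum, a latent deleterious state concentrated at low allele counts,
# frequency-class-dependent substitution spectra (the C-to-T skew between
# frequent and singleton variants), annotation columns with planted
# linear effects, missingness, and a variant-density-style leakage
# column. The hidden truth is returned as a sidecar table and never
# written into the variant table itself.

#' Default frequency-class substitution spectra
#'
#' Twelve ordered ref>alt class proportions per frequency class. The
#' C-to-T proportions (40.1 percent in the frequent class versus 29.8
#' percent among singletons) reproduce the skew observed between real
#' frequency strata; the remaining entries are stylized and chosen so
#' the classes are separable enough for leakage demonstrations while
#' leaving spectrum-matched subsampling feasible. The rare class is the
#' elementwise midpoint.
#'
#' @return named list of named numeric vectors (`frequent`, `rare`,
#'   `singleton`), each summing to 1 over [snv_classes()].
#' @export
default_spectra <- function() {
  cls <- snv_classes()
  build <- function(named) {
    p <- stats::setNames(rep((1 - sum(named)) / (12 - length(named)), 12),
                         cls)
    p[names(named)] <- named
    p
  }
  frequent <- build(c("C>T" = 0.401, "T>C" = 0.22, "A>G" = 0.04,
                      "G>A" = 0.04))
  singleton <- build(c("C>T" = 0.298, "T>C" = 0.13, "A>G" = 0.18,
                       "G>A" = 0.18))
  list(frequent = frequent, rare = (frequent + singleton) / 2,
       singleton = singleton)
}

#' Simulation parameters
#'
#' Defaults emulate, at desk scale, a large sequenced cohort: 142,312
#' haplotypes (2 x 71,156 individuals), a 1/i allele-count law truncated
#' at AF 0.5 for neutral sites, latent-deleterious sites (60 percent of
#' simulated sites — the generator deliberately over-samples the
#' selected fraction of the genome so that every frequency stratum
#' carries signal at small n) whose allele counts follow the steeper
#' 1/i^(alpha * rare_shift) law, and class-conditional substitution
#' spectra with the frequent-vs-singleton C-to-T skew.
#'
#' @param n_sites number of simulated sites.
#' @param an total allele number (haplotypes; default 142312).
#' @param sfs_exponent alpha in the allele-count law AC proportional to
#'   1/i^alpha (default 1).
#' @param deleterious_fraction share of sites with the latent
#'   deleterious state (default 0.6).
#' @param rare_shift multiplier on the SFS exponent for latent-
#'   deleterious sites, concentrating them at low allele counts
#'   (default 2).
#' @param spectrum_by_class substitution-class proportions per frequency
#'   class (default [default_spectra()]).
#' @param n_numeric_annotations total numeric annotation columns; the
#'   first `length(effect_sizes)` carry planted effects, the rest are
#'   pure-noise decoys (default 12).
#' @param n_categorical_annotations categorical columns with
#'   truth-dependent level frequencies (default 2).
#' @param effect_sizes linear effects of the latent state on the signal
#'   columns (default `c(1.5, 1.2, 1.0, 0.8, 0.6, 0.4)`).
#' @param noise_sd Gaussian noise standard deviation on numeric
#'   annotations (default 1).
#' @param missing_rate per-cell missingness probability (default 0.05).
#' @param density_leak_strength mean shift of the variant-density-style
#'   column for low-frequency (singleton/rare) variants (default 2).
#' @param label_noise probability that a validation label is replaced by
#'   a coin flip (default 0.05).
#' @param thresholds a [frequency_thresholds()] used to realize
#'   frequency classes during simulation.
#' @param seed RNG seed.
#' @return a list of class `simulation_params`.
#' @export
simulation_params <- function(n_sites = 100000L, an = 142312L,
                              sfs_exponent = 1, deleterious_fraction = 0.6,
                              rare_shift = 2,
                              spectrum_by_class = default_spectra(),
                              n_numeric_annotations = 12L,
                              n_categorical_annotations = 2L,
                              effect_sizes = c(1.5, 1.2, 1.0, 0.8, 0.6, 0.4),
                              noise_sd = 1, missing_rate = 0.05,
                              density_leak_strength = 2, label_noise = 0.05,
                              thresholds = frequency_thresholds(),
                              seed = 1L) {
  stopifnot(sfs_exponent > 0, an >= 2,
            deleterious_fraction >= 0, deleterious_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            label_noise >= 0, label_noise <= 1,
            length(effect_sizes) <= n_numeric_annotations)
  structure(list(n_sites = as.integer(n_sites), an = as.integer(an),
                 sfs_exponent = sfs_exponent,
                 deleterious_fraction = deleterious_fraction,
                 rare_shift = rare_shift,
                 spectrum_by_class = spectrum_by_class,
                 n_numeric_annotations = as.integer(n_numeric_annotations),
                 n_categorical_annotations =
                   as.integer(n_categorical_annotations),
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 density_leak_strength = density_leak_strength,
                 label_noise = label_noise, thresholds = thresholds,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a population variant table
#'
#' Sites draw a latent deleterious state, then an allele count from the
#' truncated power-law SFS (exponent `sfs_exponent` for neutral sites,
#' `sfs_exponent * rare_shift` for deleterious ones, truncated at AF
#' 0.5), then a substitution class conditional on the realized frequency
#' class. SNVs only. The latent truth is emitted as a separate sidecar
#' table and never enters the variant table.
#'
#' @param params a [simulation_params()].
#' @return list with `variants` (a `variant_table`) and `truth`
#'   (data.frame chrom, pos, ref, alt, deleterious).
#' @export
simulate_population_variants <- function(params = simulation_params()) {
  with_seed(params$seed, {
    n <- params$n_sites
    ac_max <- params$an %/% 2L
    truth <- stats::rbinom(n, 1L, params$deleterious_fraction)
    sfs_prob <- function(a) {
      p <- seq_len(ac_max)^(-a)
      p / sum(p)
    }
    ac <- integer(n)
    for (state in c(0L, 1L)) {
      idx <- which(truth == state)
      if (length(idx) == 0L) next
      a <- params$sfs_exponent * if (state == 1L) params$rare_shift else 1
      ac[idx] <- sample.int(ac_max, length(idx), replace = TRUE,
                            prob = sfs_prob(a))
    }
    af <- ac / params$an
    cls <- classify_frequency(
      data.frame(ac = ac, an = params$an, af = af), params$thresholds)
    sub <- character(n)
    for (fc in c("singleton", "rare", "frequent")) {
      idx <- which(cls == fc)
      if (length(idx) == 0L) next
      sp <- params$spectrum_by_class[[fc]]
      sub[idx] <- sample(names(sp), length(idx), replace = TRUE, prob = sp)
    }
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    pos <- sample.int(2^28, n) # unique positions; collisions impossible
    variants <- variant_table(chrom = chrom, pos = pos,
                              ref = substr(sub, 1, 1),
                              alt = substr(sub, 3, 3),
                              ac = ac, an = params$an, af = af,
                              filter = "PASS")
    truth_df <- data.frame(chrom = variants$chrom, pos = variants$pos,
                           ref = variants$ref, alt = variants$alt,
                           deleterious = truth)
    list(variants = variants, truth = truth_df)
  })
}

#' Annotation schema for simulated data
#'
#' @param params a [simulation_params()].
#' @return schema data.frame (column, kind, group, impute) covering the
#'   simulated signal, decoy, categorical and variant-density columns.
#' @export
simulated_annotation_schema <- function(params = simulation_params()) {
  n_sig <- length(params$effect_sizes)
  n_noise <- params$n_numeric_annotations - n_sig
  groups_sig <- rep(c("conservation_constraint", "epigenetic_regulatory"),
                    length.out = n_sig)
  rows <- list(
    data.frame(column = sprintf("signal_%02d", seq_len(n_sig)),
               kind = "numeric", group = groups_sig, impute = "median"),
    if (n_noise > 0)
      data.frame(column = sprintf("noise_%02d", seq_len(n_noise)),
                 kind = "numeric", group = "sequence_based",
                 impute = "median"),
    if (params$n_categorical_annotations > 0)
      data.frame(column = sprintf("cat_%02d",
                                  seq_len(params$n_categorical_annotations)),
                 kind = "categorical", group = "other", impute = "mode"),
    data.frame(column = "density", kind = "numeric",
               group = "variant_density", impute = "median"))
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Simulate an annotation matrix with planted effects
#'
#' Signal columns are `effect_size * latent_state + N(0, noise_sd)`;
#' decoy columns are pure noise; categorical columns have
#' truth-dependent level frequencies; one `variant_density`-tagged
#' column is shifted by `density_leak_strength` for low-frequency
#' (singleton/rare) variants, emulating the leakage risk of variant-
#' density annotations. Cells go missing independently at
#' `missing_rate`.
#'
#' @param variants a `variant_table` from
#'   [simulate_population_variants()].
#' @param truth the aligned sidecar truth table.
#' @param params a [simulation_params()].
#' @return an [annotation_matrix()].
#' @export
simulate_annotations <- function(variants, truth, params = simulation_params()) {
  stopifnot(nrow(variants) == nrow(truth))
  with_seed(params$seed + 1L, {
    n <- nrow(variants)
    t <- truth$deleterious
    schema <- simulated_annotation_schema(params)
    data <- list()
    n_sig <- length(params$effect_sizes)
    for (j in seq_len(n_sig)) {
      data[[sprintf("signal_%02d", j)]] <-
        params$effect_sizes[j] * t + stats::rnorm(n, 0, params$noise_sd)
    }
    for (j in seq_len(params$n_numeric_annotations - n_sig)) {
      data[[sprintf("noise_%02d", j)]] <- stats::rnorm(n, 0, params$noise_sd)
    }
    lv <- c("L1", "L2", "L3")
    p_neutral <- c(0.5, 0.3, 0.2); p_delet <- c(0.2, 0.3, 0.5)
    for (j in seq_len(params$n_categorical_annotations)) {
      x <- character(n)
      x[t == 0L] <- sample(lv, sum(t == 0L), replace = TRUE, prob = p_neutral)
      x[t == 1L] <- sample(lv, sum(t == 1L), replace = TRUE, prob = p_delet)
      data[[sprintf("cat_%02d", j)]] <- x
    }
    low_freq <- maf(variants) < params$thresholds$maf_frequent
    data[["density"]] <- params$density_leak_strength * as.numeric(low_freq) +
      stats::rnorm(n)
    data <- as.data.frame(data, stringsAsFactors = FALSE)
    if (params$missing_rate > 0) {
      for (col in names(data)) {
        miss <- stats::runif(n) < params$missing_rate
        data[[col]][miss] <- NA
      }
    }
    annotation_matrix(variants[c("chrom", "pos", "ref", "alt")], data, schema)
  })
}

#' Simulate ClinVar-like validation labels
#'
#' Samples `n_per_class` sites from the latent-deleterious pool as
#' pathogenic and `n_per_class` from the rest as benign, then corrupts
#' each label with probability `label_noise` by replacing it with a fair
#' coin flip. Requested exclusions (e.g. training rows) are honoured
#' before sampling; an eligible pool smaller than the request is an
#' error.
#'
#' @param variants a `variant_table`.
#' @param truth the aligned sidecar truth table.
#' @param params a [simulation_params()].
#' @param n_per_class sites sampled per truth class (default 2000).
#' @param label_noise overrides `params$label_noise` when given.
#' @param exclude optional variant table (or key data.frame) whose rows
#'   must not be selected.
#' @return a [labeled_dataset()]; attribute `truth` holds the latent
#'   state of the selected sites.
#' @export
simulate_validation_labels <- function(variants, truth,
                                       params = simulation_params(),
                                       n_per_class = 2000L,
                                       label_noise = NULL,
                                       exclude = NULL) {
  stopifnot(nrow(variants) == nrow(truth))
  rho <- label_noise %||% params$label_noise
  eligible <- rep(TRUE, nrow(variants))
  if (!is.null(exclude)) {
    eligible <- !(variant_key(variants) %in% variant_key(exclude))
  }
  with_seed(params$seed + 2L, {
    pick <- function(state) {
      pool <- which(eligible & truth$deleterious == state)
      if (length(pool) < n_per_class) {
        vp_stop("requested %d sites per class but only %d eligible for state %d",
                n_per_class, length(pool), state)
      }
      sort(sample(pool, n_per_class))
    }
    idx <- c(pick(1L), pick(0L))
    lab <- truth$deleterious[idx]
    flip <- stats::runif(length(idx)) < rho
    lab[flip] <- stats::rbinom(sum(flip), 1L, 0.5)
    out <- labeled_dataset(variants[idx, , drop = FALSE], labels = lab)
    attr(out, "truth") <- truth$deleterious[idx]
    out
  })
}
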