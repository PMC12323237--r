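# evaluation: ranking metrics (AUROC as the Mann-Whitney pairwise
# probability, AUPRC as average precision), consequence-stratified
# metrics with a coding/noncoding partition, the binned allele-frequency
# versus PHRED-score analysis, and rank correlations.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, ties counted half.
#' Computed from average ranks, so tied scores are handled exactly.
#'
#' @param scores numeric scores (higher = more deleterious).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    vp_stop("AUROC undefined: both classes required")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision form: records are sorted by descending score (ties
#' broken by stable input order); the precisions at the rank of each
#' positive are averaged over the number of positives. This step-wise
#' convention is conservative compared to trapezoidal PR interpolation.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L)
  if (n1 == 0L) vp_stop("AUPRC undefined: no positives")
  ord <- order(-scores, seq_along(scores)) # stable for ties
  ys <- y[ord]
  cum_pos <- cumsum(ys)
  prec <- cum_pos / seq_along(ys)
  sum(prec[ys == 1L]) / n1
}

#' Coding / noncoding consequence partition
#'
#' The VEP-style consequence labels aggregated as "coding" and
#' "noncoding" for partition-level evaluation.
#'
#' @return list with character vectors `coding` and `noncoding`.
#' @export
consequence_partition <- function() {
  list(coding = c("STOP_GAINED", "STOP_LOST", "CANONICAL_SPLICE",
                  "NON_SYNONYMOUS", "SYNONYMOUS", "FRAME_SHIFT", "INFRAME"),
       noncoding = c("INTRONIC", "REGULATORY", "SPLICE_SITE", "3PRIME_UTR",
                     "NONCODING_CHANGE", "DOWNSTREAM", "UPSTREAM",
                     "5PRIME_UTR", "INTERGENIC"))
}

#' Consequence-stratified ranking metrics
#'
#' AUROC/AUPRC per consequence label with at least one positive and one
#' negative (others reported as skipped), plus aggregated `coding` and
#' `noncoding` rows per the partition.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param consequences consequence label per record.
#' @param partition a [consequence_partition()]-style list.
#' @return data.frame `stratum`, `n`, `n_pos`, `auroc`, `auprc`,
#'   `skipped`.
#' @export
stratified_metrics <- function(scores, labels, consequences,
                               partition = consequence_partition()) {
  one <- function(name, idx) {
    y <- labels[idx]
    if (length(idx) == 0L || length(unique(y)) < 2L) {
      return(data.frame(stratum = name, n = length(idx),
                        n_pos = sum(y == 1), auroc = NA_real_,
                        auprc = NA_real_, skipped = TRUE))
    }
    data.frame(stratum = name, n = length(idx), n_pos = sum(y == 1),
               auroc = auroc(scores[idx], y), auprc = auprc(scores[idx], y),
               skipped = FALSE)
  }
  rows <- lapply(sort(unique(consequences)), function(cq) {
    one(cq, which(consequences == cq))
  })
  rows <- c(rows, lapply(names(partition), function(p) {
    one(p, which(consequences %in% partition[[p]]))
  }))
  do.call(rbind, rows)
}

#' Binned allele-frequency / PHRED-score analysis
#'
#' For each of fifty unit-width PHRED bins over (0, 50], samples up to
#' `cap` variants uniformly without replacement (after excluding
#' zero-frequency variants when configured) and reports the mean allele
#' frequency, the singleton fraction (allele count equal to the singleton
#' rule), and the sampled count. Bins whose available count is below the
#' cap pass their full content through, making the analysis deterministic
#' and seed-independent in that regime.
#'
#' @param scored a data.frame with columns `phred`, `af`, `ac`.
#' @param cap per-bin sample cap (default 100000).
#' @param exclude_zero_af drop records with `af == 0` first (default
#'   TRUE).
#' @param singleton_ac allele count defining a singleton (default 1).
#' @param seed RNG seed for per-bin subsampling.
#' @return data.frame `bin_lo`, `bin_hi`, `n_available`, `n_sampled`,
#'   `mean_af`, `singleton_fraction`.
#' @export
binned_af_analysis <- function(scored, cap = 100000L, exclude_zero_af = TRUE,
                               singleton_ac = 1L, seed = 1L) {
  check_columns(scored, c("phred", "af", "ac"), "scored variants")
  if (exclude_zero_af) scored <- scored[scored$af > 0, , drop = FALSE]
  bins <- data.frame(lo = 0:49, hi = 1:50)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
      lo <- bins$lo[i]; hi <- bins$hi[i]
      idx <- which(scored$phred > lo & scored$phred <= hi)
      avail <- length(idx)
      take <- if (avail > cap) sample(idx, cap) else idx
      data.frame(bin_lo = lo, bin_hi = hi, n_available = avail,
                 n_sampled = length(take),
                 mean_af = if (length(take) > 0) mean(scored$af[take]) else
                   NA_real_,
                 singleton_fraction = if (length(take) > 0)
                   mean(scored$ac[take] == singleton_ac) else NA_real_)
    }))
  })
}

#' Spearman rank correlation with large-sample p-value
#'
#' Spearman's rho computed as the Pearson correlation of average ranks;
#' the two-sided p-value uses the standard large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `rho` and `p_value`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) vp_stop("x and y lengths differ")
  if (length(x) < 3L) vp_stop("need at least 3 observations")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `r` and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) vp_stop("x and y lengths differ")
  if (length(x) < 3L) vp_stop("need at least 3 observations")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
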