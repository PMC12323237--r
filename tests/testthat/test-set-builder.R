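test_that("site filtering drops alt contigs, mitochondria and failed filters", {
  vt <- variant_table(
    chrom = c("chr1", "chr1", "chrM", "chr5_alt", "chrUn_x", "chr2"),
    pos = 1:6 * 10, ref = "A", alt = "G", af = 0.01,
    filter = c("PASS", "PASS", "PASS", "PASS", "PASS", "lowcov"))
  kept <- filter_sites(vt)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$chrom, c("chr1", "chr1"))
  # empty input and all-pass input
  expect_equal(nrow(filter_sites(vt[0, ])), 0L)
  clean <- variant_table("chr1", 1:3 * 10, "A", "G", af = 0.01)
  expect_equal(nrow(filter_sites(clean)), 3L)
})

test_that("frequency classification matches the stratum definitions", {
  rec <- function(ac, an) variant_table("1", 100, "A", "G", ac = ac,
                                        an = an, af = ac / an)
  expect_equal(as.character(classify_frequency(rec(1, 142312))), "singleton")
  expect_equal(as.character(classify_frequency(rec(100, 142312))), "rare")
  # MAF >= 0.001 boundary is inclusive
  at_boundary <- variant_table("1", 100, "A", "G", ac = 143L, an = 143000L,
                               af = 0.001)
  expect_equal(as.character(classify_frequency(at_boundary)), "frequent")
  above_half <- variant_table("1", 100, "A", "G", af = 0.6)
  expect_equal(as.character(classify_frequency(above_half)), "excluded")
  # high-frequency alleles are frequent by MAF even when af is close to 0.5
  expect_equal(as.character(classify_frequency(
    variant_table("1", 1, "A", "G", ac = 71140L, an = 142312L,
                  af = 71140 / 142312))), "frequent")
})

test_that("classification partitions every record exactly once", {
  study <- small_study()
  cls <- classify_frequency(study$variants)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), nrow(study$variants))
  strata <- study$strata
  expect_equal(sum(vapply(strata, nrow, 1L)), nrow(study$variants))
})

test_that("classification without ac errors only when ac is needed", {
  no_ac <- variant_table("1", 1, "A", "G", af = 0.01)
  expect_error(classify_frequency(no_ac), "ac required")
  excluded <- variant_table("1", 1, "A", "G", af = 0.9)
  expect_equal(as.character(classify_frequency(excluded)), "excluded")
})

test_that("spectrum bins substitutions and pools long InDels at 50", {
  vt <- toy_variants(c("A>G", "A>G", "C>T"))
  sp <- spectrum(vt)
  expect_equal(unname(sp["A>G"]), 2L)
  expect_equal(unname(sp["C>T"]), 1L)
  expect_equal(sum(sp), 3L)
  long_del <- variant_table("1", 1, paste(rep("A", 74), collapse = ""), "A",
                            af = 0.01)
  expect_equal(unname(spectrum(long_del)["del:50"]), 1L)
  ins3 <- variant_table("1", 1, "A", "ATTT", af = 0.01)
  expect_equal(unname(spectrum(ins3)["ins:03"]), 1L)
  expect_equal(sum(spectrum(vt[0, ])), 0L)
})

test_that("largest-remainder apportionment is exact and deterministic", {
  expect_equal(unname(largest_remainder(4, c(a = 0.5, b = 0.5))), c(2L, 2L))
  # remainder ties resolve to earlier classes
  expect_equal(unname(largest_remainder(5, c(a = 1, b = 1, c = 1) / 3)),
               c(2L, 2L, 1L))
  p <- c(x = 0.401, y = 0.299, z = 0.3)
  a <- largest_remainder(1000, p)
  expect_equal(sum(a), 1000L)
  expect_equal(unname(a["x"]), 401L)
})

test_that("matched sampling hits the target spectrum exactly", {
  set.seed(7)
  # pool with singleton-like C>T share, target with frequent-like share
  pool_cls <- sample(snv_classes(), 5000, replace = TRUE,
                     prob = default_spectra()$singleton)
  pool <- toy_variants(pool_cls)
  target_cls <- sample(snv_classes(), 5000, replace = TRUE,
                       prob = default_spectra()$frequent)
  target <- spectrum(toy_variants(target_cls))
  got <- matched_sample(pool, target, 1000, seed = 11)
  expect_equal(nrow(got), 1000L)
  got_sp <- spectrum(got)
  alloc <- largest_remainder(1000, target[target > 0] / sum(target))
  expect_equal(got_sp[names(alloc)], alloc,
               ignore_attr = TRUE)
  # matching exactness invariant: L1 distance <= occupied classes / n
  l1 <- sum(abs(got_sp / 1000 - target / sum(target)))
  expect_lte(l1, sum(target > 0) / 1000)
})

test_that("matched sampling is deterministic and degenerate cases work", {
  pool <- toy_variants(rep(c("A>G", "C>T"), each = 10))
  target <- spectrum(pool)
  a <- matched_sample(pool, target, 10, seed = 5)
  b <- matched_sample(pool, target, 10, seed = 5)
  expect_identical(a, b)
  # whole-pool request with matching spectrum returns the pool as a set
  all20 <- matched_sample(pool, target, 20, seed = 5)
  expect_setequal(paste(all20$pos), paste(pool$pos))
  expect_error(matched_sample(pool, target, 21, seed = 5), "exceeds pool")
  # infeasible class allocation names the deficient class
  skew_target <- spectrum(toy_variants(rep("G>A", 10)))
  expect_error(matched_sample(pool, skew_target, 10, seed = 5),
               "G>A")
})

test_that("matched sampling stays within the L1 bound on random cases", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    classes <- sample(snv_classes(), k)
    tprop <- as.numeric(stats::rgamma(k, 1)) + 0.05
    tprop <- tprop / sum(tprop)
    n <- sample(50:200, 1)
    # generous pool so every allocation is feasible
    pool <- toy_variants(rep(classes, each = max(n, 100)))
    target_counts <- largest_remainder(1000, stats::setNames(tprop, classes))
    target <- spectrum(toy_variants(rep(classes, times = target_counts)))
    got <- matched_sample(pool, target, n, seed = i)
    got_sp <- spectrum(got)
    l1 <- sum(abs(got_sp / n - target / sum(target)))
    expect_lte(l1, sum(target > 0) / n)
  }
})

test_that("balanced pairs equalize per-universe counts with matching", {
  study <- small_study()
  ds <- build_training_pair(study$strata,
                            pair_config("fr", "frequent", "rare", seed = 1))
  expect_true(attr(ds, "balanced"))
  expect_equal(sum(ds$label == 0), sum(ds$label == 1))
  benign_sp <- spectrum(ds[ds$label == 0, ])
  delet_sp <- spectrum(ds[ds$label == 1, ])
  # per-class counts match the largest-remainder apportionment of the target
  alloc <- largest_remainder(sum(benign_sp),
                             benign_sp[benign_sp > 0] / sum(benign_sp))
  expect_equal(delet_sp[names(alloc)], alloc, ignore_attr = TRUE)
})

test_that("pair building is deterministic for a fixed seed", {
  study <- small_study()
  cfg <- pair_config("fs", "frequent", "singleton", seed = 9)
  a <- build_training_pair(study$strata, cfg)
  b <- build_training_pair(study$strata, cfg)
  expect_identical(a, b)
  c <- build_training_pair(study$strata,
                           pair_config("fs", "frequent", "singleton",
                                       seed = 10))
  expect_false(identical(a$pos, c$pos))
})

test_that("unbalanced pairs weight classes to equal summed weight", {
  benign <- toy_variants(rep("A>G", 10), ac = 150, an = 1000)
  delet <- toy_variants(rep("C>T", 40), ac = 1, an = 1000)
  delet$pos <- delet$pos + 10000L
  ds <- label_pair(benign, delet, balanced = FALSE)
  expect_equal(unique(ds$weight[ds$label == 0]), 4)
  expect_equal(unique(ds$weight[ds$label == 1]), 1)
  expect_equal(sum(ds$weight[ds$label == 0]), sum(ds$weight[ds$label == 1]))
  expect_false(attr(ds, "balanced"))
})

test_that("balanced pairs fail when the deleterious pool is too small", {
  benign <- toy_variants(rep(c("A>G", "C>T"), each = 10), ac = 150,
                         an = 1000)
  delet <- toy_variants(rep("A>G", 5), ac = 1, an = 1000)
  delet$pos <- delet$pos + 10000L
  expect_error(label_pair(benign, delet, balanced = TRUE),
               "smaller than benign")
})

test_that("pair plans reproduce the combined-cohort subsample sizes", {
  counts <- data.frame(
    stratum = c("singleton", "rare", "frequent", "human_derived"),
    snvs = c(268404480, 229184030, 26255876, 14011297),
    indels = c(27934609, 30416715, 8864604, 1688847))
  plan <- pair_plan(counts, pair_config("hfs", "human_derived_plus_frequent",
                                        "singleton"))
  expect_equal(plan$snvs[plan$role == "deleterious"], 14011297 + 26255876)
  plan_hs <- pair_plan(counts, pair_config("hs", "human_derived",
                                           "singleton"))
  expect_equal(plan_hs$snvs[plan_hs$role == "deleterious"], 14011297)
  expect_equal(plan_hs$indels[plan_hs$role == "deleterious"], 1688847)
  # unbalanced plans keep the whole deleterious stratum
  plan_all <- pair_plan(counts, pair_config("hs-all", "human_derived",
                                            "singleton", balanced = FALSE))
  expect_equal(plan_all$snvs[plan_all$role == "deleterious"], 268404480)
})

test_that("stratum summaries report the frequent-stratum share", {
  toy <- data.frame(stratum = c("singleton", "frequent"),
                    snvs = c(90, 10), indels = c(0, 0))
  expect_equal(stratum_summary(toy)$frequent_share_percent, 10)
  single <- data.frame(stratum = "frequent", snvs = 5, indels = 5)
  expect_equal(stratum_summary(single)$frequent_share_percent, 100)
})
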