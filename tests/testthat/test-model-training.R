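separable_toy <- function(n = 200, seed = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, -4, 0.5), ncol = 2),
             matrix(rnorm(n, 4, 0.5), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(0, 1), each = n / 2))
}

test_that("a separable toy problem reaches perfect training AUROC", {
  toy <- separable_toy()
  trace <- train_iterative(toy$x, toy$y,
                           config = trainer_config(max_iterations = 20))
  expect_length(trace, 20L)
  s <- score(trace[[20]], toy$x)
  expect_equal(auroc(s, toy$y), 1.0)
  # objective is non-increasing across snapshots
  obj <- vapply(trace, `[[`, numeric(1), "objective")
  expect_true(all(diff(obj) <= 1e-6))
})

test_that("an all-zero feature matrix learns only the class balance", {
  x <- matrix(0, nrow = 100, ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(0, 1), c(25, 75))
  trace <- train_iterative(x, y, config = trainer_config(max_iterations = 20))
  expect_true(all(vapply(trace, function(s) all(s$coefficients == 0), TRUE)))
  expect_equal(trace[[20]]$intercept, stats::qlogis(0.75), tolerance = 1e-4)
})

test_that("degenerate labels and missing values are rejected", {
  x <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_error(train_iterative(x, rep(1, 10)), "both classes")
  x_na <- x; x_na[1, 1] <- NA
  expect_error(train_iterative(x_na, rep(c(0, 1), 5)), "missing values")
})

test_that("integer class weights equal row duplication", {
  set.seed(5)
  x <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), each = 15)
  w <- ifelse(y == 0, 3, 1)
  cfg <- trainer_config(max_iterations = 15)
  weighted <- train_iterative(x, y, weights = w, config = cfg)
  dup_idx <- c(rep(which(y == 0), each = 3), which(y == 1))
  duplicated_fit <- train_iterative(x[dup_idx, ], y[dup_idx], config = cfg)
  expect_equal(weighted[[15]]$objective, duplicated_fit[[15]]$objective,
               tolerance = 1e-8)
  expect_equal(weighted[[15]]$coefficients,
               duplicated_fit[[15]]$coefficients, tolerance = 1e-6)
})

test_that("iteration selection averages AUROC and AUPRC across sets", {
  toy <- separable_toy(n = 100)
  trace <- train_iterative(toy$x, toy$y,
                           config = trainer_config(max_iterations = 5))
  # craft validation sets aligned with the trained manifest
  vs <- list(list(features = toy$x, labels = toy$y),
             list(features = toy$x[c(1:20, 81:100), ],
                  labels = toy$y[c(1:20, 81:100)]))
  snap <- select_iteration(trace, vs)
  tbl <- attr(snap, "tuning_table")
  expect_equal(nrow(tbl), 5 * 2)
  means <- attr(snap, "mean_combined")
  expect_equal(snap$iteration, which.max(means))
  # ties resolve to the smallest iteration: scores saturate at 1 here
  expect_equal(snap$iteration, which(means == max(means))[1])
})

test_that("selection without validation sets falls back to the default", {
  toy <- separable_toy(n = 60)
  trace <- train_iterative(toy$x, toy$y,
                           config = trainer_config(max_iterations = 20,
                                                   default_iteration = 13))
  expect_warning(snap <- select_iteration(trace, list()), "default iteration")
  expect_equal(snap$iteration, 13L)
})

test_that("scoring is the inverse-logit of the linear predictor", {
  snap <- structure(list(coefficients = c(a = 0, b = 0), intercept = 0,
                         iteration = 1, objective = 0),
                    class = "model_snapshot")
  x <- matrix(rnorm(10), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(score(snap, x), rep(0.5, 5))
  snap$intercept <- 30
  expect_true(all(score(snap, x) > 0.999))
  # monotone in a positive feature's coefficient
  snap2 <- snap; snap2$intercept <- 0
  snap2$coefficients <- c(a = 1, b = 0)
  xpos <- matrix(c(2, 1, 0, 0), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  s <- score(snap2, xpos)
  expect_gt(s[1], s[2])
  # manifest mismatch names the offending columns
  xbad <- matrix(0, ncol = 2, nrow = 1, dimnames = list(NULL, c("a", "z")))
  expect_error(score(snap, xbad), "missing: \\[b\\], extra: \\[z\\]")
})

test_that("training is deterministic", {
  toy <- separable_toy(n = 100, seed = 11)
  cfg <- trainer_config(max_iterations = 8)
  t1 <- train_iterative(toy$x, toy$y, config = cfg)
  t2 <- train_iterative(toy$x, toy$y, config = cfg)
  expect_identical(t1[[8]]$coefficients, t2[[8]]$coefficients)
  expect_identical(score(t1[[8]], toy$x), score(t2[[8]], toy$x))
})

test_that("PHRED scaling anchors rank fractions to -10 log10(r/N)", {
  ref <- phred_reference(seq_len(10000) / 10000)
  # rank fraction 0.01 (the top 1 percent) maps to PHRED 20 exactly
  expect_equal(phred_scale(ref$sorted[100], ref), 20)
  expect_equal(phred_scale(ref$sorted[10000], ref), 0)
  expect_equal(phred_scale(ref$sorted[5000], ref), -10 * log10(0.5),
               tolerance = 1e-10)
  # maximum attained at the top reference score; above-range capped there
  expect_equal(phred_scale(ref$sorted[1], ref), 40)
  expect_equal(phred_scale(2, ref), 40)
  expect_equal(phred_scale(-1, ref), 0)
})

test_that("PHRED order agrees with raw-score order, ties averaged", {
  set.seed(21)
  raw <- round(runif(500), 2) # deliberate ties
  ref <- phred_reference(raw)
  ph <- phred_scale(raw, ref)
  expect_equal(order(-raw, seq_along(raw)), order(-ph, seq_along(ph)))
  # tied raw scores share one PHRED value (average rank)
  expect_equal(length(unique(ph[raw == raw[1]])), 1L)
  # spot-check the average-rank formula on a small vector
  small <- phred_reference(c(0.9, 0.5, 0.5, 0.1))
  expect_equal(phred_scale(0.5, small), -10 * log10(2.5 / 4))
})

test_that("top coefficients rank by absolute value with group sums", {
  snap <- structure(list(coefficients = c(a = 2, b = -3, c = 1),
                         intercept = 0, iteration = 1, objective = 0),
                    class = "model_snapshot")
  top2 <- top_coefficients(snap, k = 2)
  expect_equal(top2$feature, c("b", "a"))
  expect_equal(top2$coefficient, c(-3, 2))
  # k above the column count returns everything
  expect_equal(nrow(top_coefficients(snap, k = 30)), 3L)
  # all-zero coefficients fall back to deterministic manifest order
  snap0 <- snap; snap0$coefficients <- c(a = 0, b = 0, c = 0)
  expect_equal(top_coefficients(snap0, k = 2)$feature, c("a", "b"))
  # exactly k rows on a wide model, with group aggregation attached
  wide <- structure(list(coefficients = stats::setNames(rnorm(1000),
                                                        paste0("f", 1:1000)),
                         intercept = 0, iteration = 1, objective = 0),
                    class = "model_snapshot")
  t30 <- top_coefficients(wide, k = 30)
  expect_equal(nrow(t30), 30L)
  expect_s3_class(attr(t30, "group_summary"), "data.frame")
})

test_that("models round-trip through JSON with scoring intact", {
  toy <- separable_toy(n = 80)
  cfg <- trainer_config(max_iterations = 6)
  trace <- train_iterative(toy$x, toy$y, config = cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(trace[[6]], path,
              manifest = data.frame(column = c("f1", "f2"), origin = "raw",
                                    group = "other"),
              config = cfg)
  back <- read_model(path)
  expect_equal(back$snapshot$coefficients, trace[[6]]$coefficients)
  expect_equal(score(back$snapshot, toy$x), score(trace[[6]], toy$x))
  expect_equal(back$config$l2_C, 1)
})
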