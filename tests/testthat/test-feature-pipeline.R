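toy_annotations <- function() {
  keys <- data.frame(chrom = "chr1", pos = 1:4 * 10L, ref = "A", alt = "G")
  data <- data.frame(
    cons = c(1.0, NA, 3.0, 2.0),
    activity = c(0.5, 0.25, NA, 1.0),
    density = c(10, 20, 30, NA),
    vep = c("STOP_GAINED", NA, "INTRONIC", "INTRONIC"),
    stringsAsFactors = FALSE)
  schema <- data.frame(
    column = c("cons", "activity", "density", "vep"),
    kind = c("numeric", "numeric", "numeric", "categorical"),
    group = c("conservation_constraint", "epigenetic_regulatory",
              "variant_density", "other"),
    impute = c("median", "0.0", "median", "mode"))
  annotation_matrix(keys, data, schema)
}

toy_schema <- function(...) {
  am <- toy_annotations()
  feature_schema(am$schema, ...)
}

test_that("imputation fills by median, mode and literal defaults", {
  am <- toy_annotations()
  imp <- impute(am, toy_schema())
  expect_equal(imp$data$cons, c(1, 2, 3, 2))       # median of 1,3,2
  expect_equal(imp$data$activity, c(0.5, 0.25, 0, 1)) # literal 0.0
  expect_equal(imp$data$vep[2], "INTRONIC")        # mode
  expect_false(anyNA(as.matrix(imp$data)))
  # idempotence: imputing an imputed matrix changes nothing
  expect_equal(impute(imp, toy_schema())$data, imp$data)
})

test_that("imputation errors on an all-missing column without a literal", {
  keys <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "G")
  schema <- data.frame(column = "x", kind = "numeric", group = "other",
                       impute = "median")
  am <- annotation_matrix(keys, data.frame(x = c(NA_real_, NA_real_)),
                          schema)
  expect_error(impute(am, feature_schema(schema)), "all values missing")
  # with a literal default the same column imputes fine
  schema$impute <- "0.0"
  am2 <- annotation_matrix(keys, data.frame(x = c(NA_real_, NA_real_)),
                           schema)
  expect_equal(impute(am2, feature_schema(schema))$data$x, c(0, 0))
})

test_that("binarization produces per-level indicators that sum to one", {
  imp <- impute(toy_annotations(), toy_schema())
  fm <- binarize(imp, toy_schema())
  expect_true(all(c("vep=STOP_GAINED", "vep=INTRONIC") %in%
                    colnames(fm$values)))
  ind <- fm$values[, startsWith(colnames(fm$values), "vep="), drop = FALSE]
  expect_equal(unname(rowSums(ind)), rep(1, 4))
  # numeric columns pass through untouched
  expect_equal(unname(fm$values[, "cons"]), imp$data$cons)
  # indicators inherit the parent group
  expect_true(all(fm$manifest$group[fm$manifest$origin == "indicator"] ==
                    "other"))
})

test_that("unseen scoring-time levels map to zero indicators with warning", {
  imp <- impute(toy_annotations(), toy_schema())
  train <- binarize(imp, toy_schema())
  lv <- attr(train, "levels")
  score_am <- annotation_matrix(
    data.frame(chrom = "chr9", pos = 1L, ref = "A", alt = "G"),
    data.frame(cons = 1, activity = 1, density = 1, vep = "UPSTREAM"),
    toy_annotations()$schema)
  expect_warning(fm <- binarize(score_am, toy_schema(), levels = lv),
                 "unseen level")
  ind <- fm$values[, startsWith(colnames(fm$values), "vep="), drop = FALSE]
  expect_equal(sum(ind), 0)
  expect_equal(colnames(fm$values), colnames(train$values))
})

test_that("feature crosses multiply elementwise and inherit excluded tags", {
  schema <- toy_schema(crosses = list(c("cons", "activity"),
                                      c("cons", "density")),
                       exclude_groups = "variant_density")
  fm <- make_crosses(binarize(impute(toy_annotations(), schema), schema),
                     schema)
  expect_equal(unname(fm$values[, "cons x activity"]),
               fm$values[, "cons"] * fm$values[, "activity"])
  mf <- fm$manifest
  expect_equal(mf$group[mf$column == "cons x activity"],
               "conservation_constraint")
  # cross with a density member carries the excluded tag and gets dropped
  expect_equal(mf$group[mf$column == "cons x density"], "variant_density")
  dropped <- drop_groups(fm, schema)
  expect_false("cons x density" %in% colnames(dropped$values))
  expect_false("density" %in% colnames(dropped$values))
  expect_true("cons x activity" %in% colnames(dropped$values))
  # empty cross list is the identity
  plain <- binarize(impute(toy_annotations(), toy_schema()), toy_schema())
  expect_identical(make_crosses(plain, toy_schema()), plain)
  # missing cross member is a schema error
  bad <- feature_schema(toy_annotations()$schema,
                        crosses = list(c("cons", "nope")))
  expect_error(make_crosses(plain, bad), "missing from feature matrix")
})

test_that("drop_groups removes tagged columns and is idempotent", {
  schema <- toy_schema(exclude_groups = "variant_density")
  fm <- binarize(impute(toy_annotations(), schema), schema)
  d1 <- drop_groups(fm, schema)
  expect_equal(ncol(d1$values), ncol(fm$values) - 1L)
  expect_identical(drop_groups(d1, schema), d1)
  # empty exclusion set is the identity
  none <- toy_schema()
  expect_identical(drop_groups(fm, none)$values, fm$values)
})

test_that("normalization standardizes training data and freezes statistics", {
  x <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  fm <- structure(list(values = x,
                       manifest = data.frame(column = c("a", "b"),
                                             origin = "raw", group = "other",
                                             source = c("a", "b"))),
                  class = "feature_matrix")
  nz <- fit_normalizer(fm)
  expect_true(nz$constant[2])
  z <- apply_normalizer(fm, nz)
  expect_lt(abs(mean(z$values[, "a"])), 1e-8)
  # population sd convention
  expect_lt(abs(sqrt(mean(z$values[, "a"]^2)) - 1), 1e-8)
  expect_equal(unname(z$values[, "b"]), c(0, 0, 0))
  # frozen statistics: shifted scoring data keeps a nonzero mean
  fm2 <- fm; fm2$values[, "a"] <- fm$values[, "a"] + 10
  z2 <- apply_normalizer(fm2, nz)
  expect_gt(abs(mean(z2$values[, "a"])), 1)
  # column mismatch is a manifest error
  fm3 <- fm; colnames(fm3$values) <- c("a", "c")
  fm3$manifest$column <- c("a", "c")
  expect_error(apply_normalizer(fm3, nz), "manifest mismatch")
})

test_that("train and scoring featurization yield identical column layouts", {
  study <- small_study()
  ann <- simulate_annotations(study$variants, study$truth, study$params)
  schema <- feature_schema(ann$schema, exclude_groups = "variant_density")
  idx_train <- 1:5000
  idx_score <- 5001:10000
  sub <- function(idx) annotation_matrix(ann$keys[idx, ], ann$data[idx, ],
                                         ann$schema)
  train <- featurize(sub(idx_train), schema)
  scoring <- featurize(sub(idx_score), schema, state = train$state)
  expect_identical(colnames(train$features$values),
                   colnames(scoring$features$values))
  expect_identical(train$features$manifest$column,
                   scoring$features$manifest$column)
  expect_false(anyNA(scoring$features$values))
  # no variant-density column survives
  expect_false(any(train$features$manifest$group == "variant_density"))
})
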