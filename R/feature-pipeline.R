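# feature_pipeline: annotation matrix -> fully numeric, standardized
# feature matrix. Stages: impute -> binarize -> make_crosses ->
# drop_groups -> fit/apply normalizer. Every output column is traced in a
# manifest (origin: raw, indicator or cross; feature-group tag).

#' Feature schema: imputation defaults, crosses, and group exclusion
#'
#' Extends the per-column annotation schema with an ordered list of
#' feature crosses (pairs of post-binarization column names whose
#' elementwise product is appended) and a set of feature groups to
#' exclude. The cross list ships empty by default and is fully
#' user-configurable.
#'
#' @param annotations data.frame with columns `column`, `kind`, `group`
#'   and optionally `impute` (a literal default value, `"median"` or
#'   `"mode"`; defaults to `"median"` for numeric and `"mode"` for
#'   categorical columns).
#' @param crosses list of length-2 character vectors naming
#'   post-binarization columns to multiply.
#' @param exclude_groups subset of [feature_groups()] to drop (e.g.
#'   `"variant_density"`).
#' @return a list of class `feature_schema`.
#' @export
feature_schema <- function(annotations, crosses = list(),
                           exclude_groups = character()) {
  check_columns(annotations, c("column", "kind", "group"), "feature schema")
  if (!"impute" %in% names(annotations)) {
    annotations$impute <- ifelse(annotations$kind == "categorical", "mode",
                                 "median")
  }
  bad <- setdiff(exclude_groups, feature_groups())
  if (length(bad) > 0L) {
    vp_stop("exclude_groups outside the five group tags: %s",
            paste(bad, collapse = ", "))
  }
  if (!all(vapply(crosses, length, 1L) == 2L)) {
    vp_stop("each cross must name exactly two columns")
  }
  structure(list(annotations = as.data.frame(annotations), crosses = crosses,
                 exclude_groups = exclude_groups),
            class = "feature_schema")
}

schema_row <- function(schema, column) {
  i <- match(column, schema$annotations$column)
  if (is.na(i)) vp_stop("column `%s` absent from schema", column)
  schema$annotations[i, ]
}

#' Impute missing annotation values
#'
#' Fills every missing cell using the per-column imputation default:
#' a literal value, or `"median"` / `"mode"` computed on this matrix. The
#' computed fill values are recorded in the result's `fill` attribute so
#' the identical values can be reused on a scoring-time matrix.
#'
#' @param matrix an [annotation_matrix()].
#' @param schema a [feature_schema()].
#' @param fill optional named list of previously computed fill values
#'   (training-time manifest) overriding the per-column computation.
#' @return an imputed `annotation_matrix` (attribute `fill` records the
#'   values used). Imputation is idempotent.
#' @export
impute <- function(matrix, schema, fill = NULL) {
  data <- matrix$data
  used <- list()
  for (col in names(data)) {
    row <- schema_row(schema, col)
    x <- data[[col]]
    if (!anyNA(x)) {
      used[[col]] <- compute_fill(x, row, allow_empty = TRUE)
      next
    }
    value <- if (!is.null(fill) && col %in% names(fill)) fill[[col]] else
      compute_fill(x, row)
    x[is.na(x)] <- value
    data[[col]] <- x
    used[[col]] <- value
  }
  out <- annotation_matrix(matrix$keys, data, matrix$schema)
  attr(out, "fill") <- used
  out
}

compute_fill <- function(x, row, allow_empty = FALSE) {
  spec <- row$impute
  obs <- x[!is.na(x)]
  if (identical(spec, "median")) {
    if (length(obs) == 0L) {
      if (allow_empty) return(NA) # never used: nothing missing
      vp_stop("column `%s`: all values missing and no literal default",
              row$column)
    }
    stats::median(as.numeric(obs))
  } else if (identical(spec, "mode")) {
    if (length(obs) == 0L) {
      if (allow_empty) return(NA)
      vp_stop("column `%s`: all values missing and no literal default",
              row$column)
    }
    tab <- table(obs)
    names(tab)[which.max(tab)]
  } else {
    if (row$kind == "numeric") as.numeric(spec) else as.character(spec)
  }
}

new_feature_matrix <- function(values, manifest) {
  stopifnot(ncol(values) == nrow(manifest))
  colnames(values) <- manifest$column
  structure(list(values = values, manifest = manifest),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d records x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$manifest$origin)
  cat("  origins:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' One-hot encode categorical annotations
#'
#' Each categorical column with k observed levels becomes k indicator
#' columns named `column=level`; numeric columns pass through unchanged.
#' Indicators inherit the parent column's feature-group tag. Level sets
#' fixed at training time can be supplied via `levels`; scoring-time
#' values outside them map to all-zero indicators with a warning.
#'
#' @param matrix an imputed [annotation_matrix()].
#' @param schema a [feature_schema()].
#' @param levels optional named list of per-column level vectors (from a
#'   training-time run, stored in the result's `levels` attribute).
#' @return a `feature_matrix` (numeric matrix + manifest).
#' @export
binarize <- function(matrix, schema, levels = NULL) {
  data <- matrix$data
  n <- nrow(matrix$keys)
  cols <- list(); manifest <- list(); used_levels <- list()
  for (col in names(data)) {
    row <- schema_row(schema, col)
    if (row$kind == "numeric") {
      if (anyNA(data[[col]])) vp_stop("column `%s` not imputed", col)
      cols[[col]] <- as.numeric(data[[col]])
      manifest[[col]] <- data.frame(column = col, origin = "raw",
                                    group = row$group, source = col)
    } else {
      x <- as.character(data[[col]])
      if (anyNA(x)) vp_stop("column `%s` not imputed", col)
      lv <- if (!is.null(levels) && col %in% names(levels)) levels[[col]] else
        sort(unique(x))
      unseen <- setdiff(unique(x), lv)
      if (length(unseen) > 0L) {
        warning(sprintf("column `%s`: unseen level(s) %s map to all-zero indicators",
                        col, paste(unseen, collapse = ", ")), call. = FALSE)
      }
      used_levels[[col]] <- lv
      for (l in lv) {
        name <- paste0(col, "=", l)
        cols[[name]] <- as.numeric(x == l)
        manifest[[name]] <- data.frame(column = name, origin = "indicator",
                                       group = row$group, source = col)
      }
    }
  }
  values <- if (length(cols) > 0L) do.call(cbind, cols) else
    base::matrix(numeric(0), nrow = n, ncol = 0)
  out <- new_feature_matrix(values, do.call(rbind, manifest))
  attr(out, "levels") <- used_levels
  out
}

#' Append feature crosses
#'
#' For each configured pair (a, b) appends the elementwise product column
#' `a x b`. Crosses are computed before normalization so that the product
#' keeps its sign semantics. A cross inherits the group tag of its first
#' member, unless the second member carries an excluded group, which then
#' tags (and later removes) the cross.
#'
#' @param matrix a `feature_matrix`.
#' @param schema a [feature_schema()] whose `crosses` name existing
#'   post-binarization columns.
#' @return a `feature_matrix` with the cross columns appended.
#' @export
make_crosses <- function(matrix, schema) {
  if (length(schema$crosses) == 0L) return(matrix)
  values <- matrix$values
  manifest <- matrix$manifest
  for (pair in schema$crosses) {
    a <- pair[[1L]]; b <- pair[[2L]]
    miss <- setdiff(c(a, b), manifest$column)
    if (length(miss) > 0L) {
      vp_stop("cross member(s) missing from feature matrix: %s",
              paste(miss, collapse = ", "))
    }
    name <- paste(a, "x", b)
    ga <- manifest$group[match(a, manifest$column)]
    gb <- manifest$group[match(b, manifest$column)]
    grp <- if (gb %in% schema$exclude_groups) gb else
      if (ga %in% schema$exclude_groups) ga else ga
    values <- cbind(values, values[, a] * values[, b])
    manifest <- rbind(manifest,
                      data.frame(column = name, origin = "cross", group = grp,
                                 source = paste(a, b, sep = "|")))
  }
  new_feature_matrix(values, manifest)
}

#' Drop excluded feature groups
#'
#' Removes every column (raw, indicator or cross) whose manifest group tag
#' lies in `schema$exclude_groups`; the manifest is updated accordingly.
#' Idempotent.
#'
#' @param matrix a `feature_matrix`.
#' @param schema a [feature_schema()].
#' @return a `feature_matrix` without the excluded columns.
#' @export
drop_groups <- function(matrix, schema) {
  keep <- !(matrix$manifest$group %in% schema$exclude_groups)
  new_feature_matrix(matrix$values[, keep, drop = FALSE],
                     matrix$manifest[keep, , drop = FALSE])
}

#' Fit / apply a z-normalizer
#'
#' `fit_normalizer` computes per-column mean and standard deviation
#' (population convention, divide by n) on a training feature matrix;
#' columns with zero standard deviation are flagged constant.
#' `apply_normalizer` standardizes a matrix with the stored training
#' statistics — transformed training columns have mean 0 and sd 1 (within
#' 1e-8), constant columns map to all-zero, and scoring-time matrices keep
#' the training statistics frozen.
#'
#' @param matrix a `feature_matrix`.
#' @return `fit_normalizer`: an object of class `normalizer` with fields
#'   `column`, `mean`, `sd`, `constant`. `apply_normalizer`: a
#'   standardized `feature_matrix`.
#' @export
fit_normalizer <- function(matrix) {
  x <- matrix$values
  n <- nrow(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2)) # population sd
  structure(list(column = colnames(x), mean = mu, sd = sdev,
                 constant = sdev == 0),
            class = "normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer a fitted `normalizer`.
#' @export
apply_normalizer <- function(matrix, normalizer) {
  miss <- setdiff(colnames(matrix$values), normalizer$column)
  extra <- setdiff(normalizer$column, colnames(matrix$values))
  if (length(miss) > 0L || length(extra) > 0L) {
    vp_stop("manifest mismatch: %s%s",
            if (length(miss)) paste0("columns absent from normalizer: ",
                                     paste(miss, collapse = ", ")) else "",
            if (length(extra)) paste0(" columns absent from matrix: ",
                                      paste(extra, collapse = ", ")) else "")
  }
  x <- matrix$values[, normalizer$column, drop = FALSE]
  sd_safe <- ifelse(normalizer$constant, 1, normalizer$sd)
  z <- sweep(sweep(x, 2, normalizer$mean), 2, sd_safe, "/")
  z[, normalizer$constant] <- 0
  new_feature_matrix(z, matrix$manifest[
    match(normalizer$column, matrix$manifest$column), , drop = FALSE])
}

#' Full featurization pipeline
#'
#' Convenience wrapper running impute, binarize, make_crosses and
#' drop_groups, then (optionally) fitting and applying a normalizer.
#' Training-time state (imputation fills, categorical levels, normalizer)
#' is returned so disjoint scoring sets can be featurized into identically
#' named, identically ordered columns.
#'
#' @param matrix an [annotation_matrix()].
#' @param schema a [feature_schema()].
#' @param state optional state returned by a previous (training) call.
#' @param normalize fit/apply the z-normalizer (default TRUE).
#' @return list with elements `features` (a `feature_matrix`) and `state`
#'   (list of `fill`, `levels`, `normalizer`).
#' @export
featurize <- function(matrix, schema, state = NULL, normalize = TRUE) {
  imp <- impute(matrix, schema, fill = state$fill)
  fm <- binarize(imp, schema, levels = state$levels)
  lv <- attr(fm, "levels") %||% state$levels
  fm <- make_crosses(fm, schema)
  fm <- drop_groups(fm, schema)
  norm <- state$normalizer
  if (normalize) {
    if (is.null(norm)) norm <- fit_normalizer(fm)
    fm <- apply_normalizer(fm, norm)
  }
  list(features = fm,
       state = list(fill = attr(imp, "fill"), levels = lv, normalizer = norm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
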