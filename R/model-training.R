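# model_training: L2-regularized logistic regression trained as a
# sequence of per-iteration snapshots (refits from a common zero
# initialization with an increasing L-BFGS iteration cap), validation-
# based iteration selection, raw scoring, rank-based PHRED scaling, and
# coefficient reporting.
#
# Objective (minimized): sum_i w_i * [log(1 + exp(z_i)) - y_i * z_i]
#                        + ||beta||^2 / (2 * C),  z_i = x_i' beta + b
# with the intercept unpenalized. C is the inverse regularization
# strength (C = 1 by default, as in the CADD training scheme).

#' Trainer configuration
#'
#' @param l2_C inverse L2 regularization strength (default 1).
#' @param max_iterations number of optimizer-iteration snapshots (20 by
#'   default; 50 for the large combined-cohort models).
#' @param default_iteration fallback snapshot when no validation sets are
#'   supplied (default 13, the conventional pick, capped at
#'   `max_iterations`).
#' @param seed RNG seed recorded for provenance (training itself is
#'   deterministic).
#' @param class_weights optional named numeric vector `c("0" = w0, "1" =
#'   w1)` multiplied into the per-record weights.
#' @return a list of class `trainer_config`.
#' @export
trainer_config <- function(l2_C = 1, max_iterations = 20L,
                           default_iteration = min(13L, max_iterations),
                           seed = 1L, class_weights = NULL) {
  if (l2_C <= 0) vp_stop("l2_C must be > 0")
  if (default_iteration < 1L || default_iteration > max_iterations) {
    vp_stop("need 1 <= default_iteration <= max_iterations")
  }
  structure(list(l2_C = l2_C, max_iterations = as.integer(max_iterations),
                 default_iteration = as.integer(default_iteration),
                 seed = as.integer(seed), class_weights = class_weights),
            class = "trainer_config")
}

logistic_objective <- function(par, x, y, wt, inv_c) {
  beta <- par[-1L]; b <- par[1L]
  z <- drop(x %*% beta) + b
  sum(wt * (log1pexp(z) - y * z)) + sum(beta^2) * inv_c / 2
}

logistic_gradient <- function(par, x, y, wt, inv_c) {
  beta <- par[-1L]; b <- par[1L]
  z <- drop(x %*% beta) + b
  r <- wt * (stats::plogis(z) - y)
  c(sum(r), drop(crossprod(x, r)) + beta * inv_c)
}

#' Train an iterative L2-regularized logistic model
#'
#' Produces one snapshot per optimizer iteration 1..max_iterations, each
#' reflecting the parameter state after exactly that many L-BFGS
#' iterations from a common zero initialization (realized as refits with
#' an increasing iteration cap). The penalized objective is non-increasing
#' across snapshots (checked to 1e-6 per step). Training is fully
#' deterministic.
#'
#' @param features a `feature_matrix` (no missing values) or numeric
#'   matrix.
#' @param labels 0/1 vector with both classes present.
#' @param weights optional positive per-record weights.
#' @param config a [trainer_config()].
#' @return an object of class `model_trace`: list of snapshots, each with
#'   `coefficients`, `intercept`, `iteration`, `objective`; attributes
#'   `manifest` and `config`.
#' @export
train_iterative <- function(features, labels, weights = NULL,
                            config = trainer_config()) {
  x <- feature_values(features)
  manifest <- feature_manifest(features, x)
  y <- as.numeric(labels)
  if (anyNA(x)) vp_stop("feature matrix contains missing values")
  if (length(unique(y)) < 2L) {
    vp_stop("degenerate labels: both classes required for training")
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  if (!is.null(config$class_weights)) {
    weights <- weights * config$class_weights[as.character(as.integer(y))]
  }
  inv_c <- 1 / config$l2_C
  p0 <- rep(0, ncol(x) + 1L)
  snapshots <- vector("list", config$max_iterations)
  prev_obj <- Inf
  for (k in seq_len(config$max_iterations)) {
    fit <- stats::optim(p0, fn = logistic_objective, gr = logistic_gradient,
                        x = x, y = y, wt = weights, inv_c = inv_c,
                        method = "L-BFGS-B",
                        control = list(maxit = k, factr = 1e1))
    obj <- fit$value
    if (obj > prev_obj + 1e-6) {
      vp_stop("objective increased between iterations %d and %d", k - 1L, k)
    }
    prev_obj <- obj
    snapshots[[k]] <- structure(
      list(coefficients = stats::setNames(fit$par[-1L], colnames(x)),
           intercept = fit$par[1L], iteration = k, objective = obj),
      class = "model_snapshot")
  }
  structure(snapshots, class = "model_trace", manifest = manifest,
            config = config)
}

feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
}

feature_manifest <- function(features, x) {
  if (inherits(features, "feature_matrix")) features$manifest else
    data.frame(column = colnames(x) %||% paste0("f", seq_len(ncol(x))),
               origin = "raw", group = "other",
               source = colnames(x) %||% paste0("f", seq_len(ncol(x))))
}

#' @export
print.model_trace <- function(x, ...) {
  cat(sprintf("model_trace: %d snapshots, %d features\n", length(x),
              length(x[[1L]]$coefficients)))
  invisible(x)
}

#' @export
print.model_snapshot <- function(x, ...) {
  cat(sprintf("model_snapshot: iteration %d, %d coefficients, objective %.6g\n",
              x$iteration, length(x$coefficients), x$objective))
  invisible(x)
}

#' Select the best iteration on external validation sets
#'
#' For each snapshot, computes (AUROC + AUPRC) / 2 on every validation set
#' and averages unweighted across sets; returns the snapshot maximizing
#' the average (ties resolved to the smallest iteration). The full
#' per-iteration score table is attached as attribute `tuning_table`.
#' With no validation sets, falls back to the configured default
#' iteration with a warning.
#'
#' @param trace a `model_trace`.
#' @param validation_sets list of lists, each with elements `features`
#'   (matching the training manifest) and `labels` (both classes
#'   present).
#' @return the selected `model_snapshot` (attribute `tuning_table`).
#' @export
select_iteration <- function(trace, validation_sets = list()) {
  config <- attr(trace, "config")
  if (length(validation_sets) == 0L) {
    warning(sprintf("no validation sets; falling back to default iteration %d",
                    config$default_iteration), call. = FALSE)
    return(trace[[config$default_iteration]])
  }
  rows <- list()
  means <- numeric(length(trace))
  for (k in seq_along(trace)) {
    per_set <- vapply(seq_along(validation_sets), function(i) {
      vs <- validation_sets[[i]]
      s <- score(trace[[k]], vs$features)
      (auroc(s, vs$labels) + auprc(s, vs$labels)) / 2
    }, numeric(1))
    means[k] <- mean(per_set)
    rows[[k]] <- data.frame(iteration = k,
                            set = seq_along(validation_sets),
                            combined = per_set)
  }
  best <- which.max(means) # which.max returns the first (smallest) argmax
  out <- trace[[best]]
  attr(out, "tuning_table") <- do.call(rbind, rows)
  attr(out, "mean_combined") <- means
  out
}

#' Score variants with a model snapshot
#'
#' Raw score = inverse-logit of the linear predictor, interpreted as the
#' probability that a variant is deleterious. The feature columns must
#' match the snapshot's coefficient vector exactly; mismatches raise an
#' error listing the missing/extra columns.
#'
#' @param snapshot a `model_snapshot`.
#' @param features a `feature_matrix` or numeric matrix with named
#'   columns.
#' @return numeric vector of scores in \[0, 1\].
#' @export
score <- function(snapshot, features) {
  x <- feature_values(features)
  want <- names(snapshot$coefficients)
  have <- colnames(x)
  if (!identical(sort(want), sort(have))) {
    vp_stop("feature manifest mismatch; missing: [%s], extra: [%s]",
            paste(setdiff(want, have), collapse = ", "),
            paste(setdiff(have, want), collapse = ", "))
  }
  z <- drop(x[, want, drop = FALSE] %*% snapshot$coefficients) +
    snapshot$intercept
  stats::plogis(z)
}

#' PHRED reference score set
#'
#' Stores the raw scores of a reference variant set, sorted by descending
#' deleteriousness, for rank-based PHRED scaling.
#'
#' @param raw_scores numeric vector of raw model scores (length >= 1).
#' @return an object of class `phred_reference`.
#' @export
phred_reference <- function(raw_scores) {
  if (length(raw_scores) < 1L) vp_stop("reference must be non-empty")
  structure(list(sorted = sort(as.numeric(raw_scores), decreasing = TRUE),
                 n = length(raw_scores)),
            class = "phred_reference")
}

#' PHRED-scale raw scores against a reference set
#'
#' Each raw score is assigned its rank among the reference scores
#' (descending deleteriousness, ties averaged) and transformed as
#' `-10 * log10(rank / N)`. A score at rank fraction 0.01 maps to PHRED
#' 20 (the conventional "top 1 percent" anchor); the lowest rank maps to
#' 0. The transform is monotone non-increasing in rank, so raw-score
#' order is preserved.
#'
#' @param raw_scores numeric vector of raw scores to scale.
#' @param reference a [phred_reference()].
#' @return numeric vector of PHRED-scaled scores.
#' @export
phred_scale <- function(raw_scores, reference) {
  s <- reference$sorted # descending
  n <- reference$n
  # rank among reference, ties averaged: #{ref > x} + (#{ref == x} + 1) / 2
  n_gt <- n - findInterval(raw_scores, rev(s))
  n_ge <- n - findInterval(raw_scores, rev(s), left.open = TRUE)
  n_eq <- n_ge - n_gt
  # clamp into [1, n]: scores above every reference take the top rank,
  # scores below every reference take the bottom (PHRED 0)
  r <- pmin(n, pmax(1, n_gt + (n_eq + 1) / 2))
  -10 * log10(r / n)
}

#' Top model coefficients by absolute value
#'
#' Selects the k features with the highest absolute coefficient (default
#' 30), reporting signed values and feature-group tags, plus the
#' per-group sum of absolute coefficients within the selection. On
#' standardized inputs the coefficients are directly interpretable as
#' feature importance. Ties and the all-zero case resolve
#' deterministically in manifest order; `k` above the column count
#' returns all columns.
#'
#' @param snapshot a `model_snapshot`.
#' @param k number of features to report (default 30).
#' @param manifest optional manifest data.frame (columns `column`,
#'   `group`) supplying group tags; defaults to group `other`.
#' @return data.frame `feature`, `coefficient`, `abs_coefficient`,
#'   `group`, ordered by decreasing `abs_coefficient`; attribute
#'   `group_summary` holds per-group sums.
#' @export
top_coefficients <- function(snapshot, k = 30L, manifest = NULL) {
  co <- snapshot$coefficients
  if (any(!is.finite(co))) vp_stop("non-finite coefficients")
  k <- min(k, length(co))
  ord <- order(-abs(co), seq_along(co))[seq_len(k)]
  grp <- if (is.null(manifest)) rep("other", length(co)) else
    manifest$group[match(names(co), manifest$column)]
  out <- data.frame(feature = names(co)[ord], coefficient = unname(co[ord]),
                    abs_coefficient = unname(abs(co[ord])),
                    group = grp[ord], stringsAsFactors = FALSE)
  attr(out, "group_summary") <- stats::aggregate(
    abs_coefficient ~ group, data = out, FUN = sum)
  out
}

#' Serialize / restore a trained model as JSON
#'
#' The JSON document stores the selected snapshot (coefficients,
#' intercept, iteration), the feature manifest, the trainer
#' configuration, and optionally the normalizer and featurization state,
#' making scoring reproducible from the file alone.
#'
#' @param snapshot a `model_snapshot`.
#' @param path output path.
#' @param manifest feature manifest data.frame.
#' @param config a [trainer_config()].
#' @param state optional featurization state from [featurize()].
#' @return `write_model` returns `path` invisibly; `read_model` returns a
#'   list with `snapshot`, `manifest`, `config`, `state`.
#' @export
write_model <- function(snapshot, path, manifest = NULL, config = NULL,
                        state = NULL) {
  doc <- list(coefficients = as.list(snapshot$coefficients),
              intercept = snapshot$intercept,
              iteration = snapshot$iteration,
              objective = snapshot$objective,
              manifest = manifest,
              config = if (!is.null(config)) unclass(config),
              normalizer = if (!is.null(state$normalizer))
                unclass(state$normalizer),
              fill = state$fill, levels = state$levels)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  snapshot <- structure(
    list(coefficients = unlist(doc$coefficients),
         intercept = doc$intercept, iteration = doc$iteration,
         objective = doc$objective),
    class = "model_snapshot")
  norm <- if (!is.null(doc$normalizer)) {
    structure(list(column = doc$normalizer$column,
                   mean = stats::setNames(unlist(doc$normalizer$mean),
                                          doc$normalizer$column),
                   sd = stats::setNames(unlist(doc$normalizer$sd),
                                        doc$normalizer$column),
                   constant = as.logical(doc$normalizer$constant)),
              class = "normalizer")
  }
  list(snapshot = snapshot, manifest = doc$manifest, config = doc$config,
       state = list(normalizer = norm, fill = as.list(doc$fill),
                    levels = lapply(doc$levels, as.character)))
}
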