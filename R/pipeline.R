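# pipeline: orchestrate the full run matrix (fr/fs/rs and the combined-
# cohort hs/hfs identifiers, each with or without variant-density
# features) from a single configuration, with a reproducibility manifest.

# identifier -> pair recipe. Apostrophe-suffixed identifiers keep
# variant-density features; unsuffixed standing-variation pairs drop
# them. v1-6 / v1-6' contrast user-supplied human-derived and simulated
# cohorts (the germline variant simulator itself is out of scope).
pair_recipes <- function() {
  list(
    "fr"      = list(benign = "frequent", deleterious = "rare",
                     balanced = TRUE, match = TRUE, density = FALSE),
    "fr'"     = list(benign = "frequent", deleterious = "rare",
                     balanced = TRUE, match = TRUE, density = TRUE),
    "fs"      = list(benign = "frequent", deleterious = "singleton",
                     balanced = TRUE, match = TRUE, density = FALSE),
    "fs'"     = list(benign = "frequent", deleterious = "singleton",
                     balanced = TRUE, match = TRUE, density = TRUE),
    "rs"      = list(benign = "rare", deleterious = "singleton",
                     balanced = TRUE, match = TRUE, density = FALSE),
    "rs'"     = list(benign = "rare", deleterious = "singleton",
                     balanced = TRUE, match = TRUE, density = TRUE),
    "v1-6"    = list(cohorts = TRUE, balanced = TRUE, match = FALSE,
                     density = FALSE),
    "v1-6'"   = list(cohorts = TRUE, balanced = TRUE, match = FALSE,
                     density = TRUE),
    "hs"      = list(benign = "human_derived", deleterious = "singleton",
                     balanced = TRUE, match = TRUE, density = TRUE,
                     iterations = 50L),
    "hs-all"  = list(benign = "human_derived", deleterious = "singleton",
                     balanced = FALSE, match = FALSE, density = TRUE,
                     iterations = 50L),
    "hfs"     = list(benign = "human_derived_plus_frequent",
                     deleterious = "singleton", balanced = TRUE,
                     match = TRUE, density = TRUE, iterations = 50L),
    "hfs-all" = list(benign = "human_derived_plus_frequent",
                     deleterious = "singleton", balanced = FALSE,
                     match = FALSE, density = TRUE, iterations = 50L))
}

#' Run configuration for the pipeline
#'
#' @param identifiers pair identifiers from `fr, fr', fs, fs', rs, rs',
#'   v1-6, v1-6', hs, hs-all, hfs, hfs-all`. Apostrophe-suffixed
#'   identifiers keep variant-density features.
#' @param params a [simulation_params()] used when no variant table is
#'   supplied.
#' @param variants optional pre-built variant table (otherwise
#'   simulated from `params`).
#' @param human_derived optional human-derived cohort (required for
#'   hs/hfs identifiers); `simulated_cohort` is its proxy-deleterious
#'   counterpart for v1-6 identifiers.
#' @param simulated_cohort see above.
#' @param thresholds a [frequency_thresholds()].
#' @param trainer a [trainer_config()]; per-identifier iteration counts
#'   (50 for the combined-cohort models) override `max_iterations`.
#' @param seed run seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(identifiers, params = simulation_params(),
                       variants = NULL, human_derived = NULL,
                       simulated_cohort = NULL,
                       thresholds = frequency_thresholds(),
                       trainer = trainer_config(), seed = 1L) {
  if (length(identifiers) == 0L) vp_stop("identifier list is empty")
  unknown <- setdiff(identifiers, names(pair_recipes()))
  if (length(unknown) > 0L) {
    vp_stop("unknown identifier(s): %s", paste(unknown, collapse = ", "))
  }
  structure(list(identifiers = identifiers, params = params,
                 variants = variants, human_derived = human_derived,
                 simulated_cohort = simulated_cohort,
                 thresholds = thresholds, trainer = trainer,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full training/evaluation pipeline
#'
#' For each requested identifier: assembles the proxy-labeled pair,
#' featurizes it (dropping variant-density features for unsuffixed
#' identifiers), trains the iteration trace, selects the snapshot on the
#' validation set, scores and evaluates, and writes the labeled dataset
#' (TSV), model (JSON), scores (TSV) and report (JSON) into
#' `out_dir/<identifier>/`, plus a run-level `run.json` manifest with
#' seeds, thresholds, counts and the per-iteration tuning table.
#' Identical config and seed reproduce identical manifests and scores.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) named list of per-identifier results, each with
#'   `dataset`, `snapshot`, `scores`, `report`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("varprox_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(config$variants)) {
    say("simulating %d sites", config$params$n_sites)
    sim <- simulate_population_variants(config$params)
    variants <- sim$variants; truth <- sim$truth
  } else {
    variants <- config$variants; truth <- attr(config$variants, "truth")
  }
  variants <- filter_sites(variants)
  strata <- stratify_by_frequency(variants, config$thresholds)
  annotations <- simulate_annotations(variants, truth, config$params)
  akey <- variant_key(annotations$keys)

  results <- list()
  manifest <- list(seed = config$seed,
                   thresholds = unclass(config$thresholds),
                   n_sites = nrow(variants),
                   strata = lapply(strata, nrow), identifiers = list())
  for (id in config$identifiers) {
    recipe <- pair_recipes()[[id]]
    say("building pair %s", id)
    dataset <- if (isTRUE(recipe$cohorts)) {
      if (is.null(config$human_derived) || is.null(config$simulated_cohort)) {
        vp_stop("identifier %s requires human_derived and simulated_cohort inputs",
                id)
      }
      label_pair(config$human_derived, config$simulated_cohort,
                 balanced = recipe$balanced, match_spectrum = recipe$match,
                 seed = config$seed, identifier = id)
    } else {
      build_training_pair(
        strata,
        pair_config(id, recipe$benign, recipe$deleterious,
                    balanced = recipe$balanced,
                    match_spectrum = recipe$match, seed = config$seed),
        human_derived = config$human_derived,
        thresholds = config$thresholds)
    }

    schema <- feature_schema(
      annotation_schema_for(annotations),
      exclude_groups = if (recipe$density) character() else "variant_density")
    idx <- match(variant_key(dataset), akey)
    train_ann <- annotation_matrix(annotations$keys[idx, , drop = FALSE],
                                   annotations$data[idx, , drop = FALSE],
                                   annotations$schema)
    feat <- featurize(train_ann, schema)

    trainer <- config$trainer
    if (!is.null(recipe$iterations)) {
      trainer$max_iterations <- recipe$iterations
    }
    say("training %s (%d iterations)", id, trainer$max_iterations)
    trace <- train_iterative(feat$features, dataset$label,
                             weights = dataset$weight, config = trainer)

    eligible <- !(variant_key(variants) %in% variant_key(dataset))
    n_val <- min(2000L, sum(eligible & truth$deleterious == 1L),
                 sum(eligible & truth$deleterious == 0L))
    if (n_val < 50L) {
      vp_stop("identifier %s: too few sites left for validation (%d per class)",
              id, n_val)
    }
    validation <- simulate_validation_labels(variants, truth, config$params,
                                             n_per_class = n_val,
                                             exclude = dataset)
    vidx <- match(variant_key(validation), akey)
    val_ann <- annotation_matrix(annotations$keys[vidx, , drop = FALSE],
                                 annotations$data[vidx, , drop = FALSE],
                                 annotations$schema)
    val_feat <- featurize(val_ann, schema, state = feat$state)
    snapshot <- select_iteration(
      trace, list(list(features = val_feat$features,
                       labels = validation$label)))
    val_scores <- score(snapshot, val_feat$features)
    report <- list(identifier = id, iteration = snapshot$iteration,
                   auroc = auroc(val_scores, validation$label),
                   auprc = auprc(val_scores, validation$label),
                   n_train = nrow(dataset), n_validation = nrow(validation))

    id_dir <- file.path(out_dir, gsub("'", "_density", id, fixed = TRUE))
    dir.create(id_dir, showWarnings = FALSE)
    write_labeled_dataset(dataset, file.path(id_dir, "dataset.tsv"))
    write_model(snapshot, file.path(id_dir, "model.json"),
                manifest = feat$features$manifest, config = trainer,
                state = feat$state)
    utils::write.table(
      data.frame(validation[c("chrom", "pos", "ref", "alt")],
                 raw_score = val_scores),
      file.path(id_dir, "scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(report, file.path(id_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$identifiers[[id]] <- list(
      n_train = nrow(dataset), iteration = snapshot$iteration,
      auroc = report$auroc, auprc = report$auprc,
      spectrum = as.list(spectrum(dataset)[spectrum(dataset) > 0]))
    results[[id]] <- list(dataset = dataset, snapshot = snapshot,
                          scores = val_scores, report = report)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

annotation_schema_for <- function(annotations) {
  sch <- annotations$schema
  sch[c("column", "kind", "group", if ("impute" %in% names(sch)) "impute")]
}
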