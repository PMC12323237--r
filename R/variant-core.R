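# variant tables, labeled datasets, and annotation matrices: the domain
# containers that every other module consumes.
#
# A variant table is a plain data.frame with one row per (chrom, pos, ref,
# alt) allele and columns:
#   chrom  contig name, normalized to the "chr"-prefixed (UCSC) dialect
#   pos    1-based position (VCF convention, fully closed)
#   ref    reference allele string
#   alt    alternate allele string
#   ac     alternate allele count (integer >= 0, NA allowed when af given)
#   an     total allele number (integer > 0, NA allowed when af given)
#   af     alternate allele frequency in [0, 1]
#   filter filter status text (e.g. "PASS", "lowcov")
# plus optional columns `consequence` (VEP-style label) and `cohort`
# (provenance tag). MAF is never stored; use maf().

#' Construct and validate a variant table
#'
#' Validates the invariants of a variant table: positive 1-based positions,
#' `ref != alt`, `ac <= an`, and consistency of `af` with `ac/an` when both
#' are present (tolerance 1e-6). Contig names are normalized to the
#' "chr"-prefixed dialect ("MT" becomes "chrM").
#'
#' @param chrom,pos,ref,alt,ac,an,af,filter vectors of equal length (scalars
#'   are recycled); `ac`/`an` may be `NA` when `af` is supplied.
#' @param consequence optional VEP-style consequence labels.
#' @param cohort optional provenance tag (e.g. "population",
#'   "human_derived").
#' @return a `data.frame` with class `variant_table`.
#' @export
#' @examples
#' variant_table("1", 12345, "A", "G", ac = 1, an = 142312, af = 1 / 142312)
variant_table <- function(chrom, pos, ref, alt, ac = NA_integer_,
                          an = NA_integer_, af = NA_real_, filter = "PASS",
                          consequence = NULL, cohort = NULL) {
  df <- data.frame(chrom = normalize_contig(as.character(chrom)),
                   pos = as.integer(pos), ref = as.character(ref),
                   alt = as.character(alt), ac = as.integer(ac),
                   an = as.integer(an), af = as.numeric(af),
                   filter = as.character(filter),
                   stringsAsFactors = FALSE)
  if (!is.null(consequence)) df$consequence <- as.character(consequence)
  if (!is.null(cohort)) df$cohort <- as.character(cohort)
  validate_variant_table(df)
}

validate_variant_table <- function(df, line_offset = 0L,
                                   require_frequency = TRUE) {
  check_columns(df, c("chrom", "pos", "ref", "alt", "ac", "an", "af",
                      "filter"), "variant table")
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L) {
      vp_stop("invalid variant record at line %d: %s", i[1L] + line_offset,
              what)
    }
  }
  if (nrow(df) > 0L) {
    bad(is.na(df$pos) | df$pos < 1L, "pos must be >= 1")
    bad(is.na(df$ref) | is.na(df$alt) | df$ref == "" | df$alt == "" |
          df$ref == df$alt, "ref and alt must be non-empty and differ")
    bad(!is.na(df$an) & df$an <= 0L, "an must be > 0")
    bad(!is.na(df$ac) & df$ac < 0L, "ac must be >= 0")
    bad(!is.na(df$ac) & !is.na(df$an) & df$ac > df$an, "ac must be <= an")
    if (require_frequency) {
      bad(is.na(df$af) & (is.na(df$ac) | is.na(df$an)),
          "neither af nor both ac and an present")
    }
    df$af <- ifelse(is.na(df$af) & !is.na(df$ac) & !is.na(df$an),
                    df$ac / df$an, df$af)
    bad(!is.na(df$af) & (df$af < 0 | df$af > 1), "af must lie in [0, 1]")
    bad(!is.na(df$ac) & !is.na(df$an) &
          abs(df$af - df$ac / df$an) > 1e-6, "af inconsistent with ac/an")
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Normalize contig names to the "chr"-prefixed dialect
#'
#' `"1"` becomes `"chr1"`, `"MT"`/`"chrMT"` become `"chrM"`; names that
#' already carry the prefix pass through.
#'
#' @param x character vector of contig names.
#' @return character vector.
#' @export
normalize_contig <- function(x) {
  x <- as.character(x)
  x[x %in% c("MT", "M")] <- "chrM"
  pre <- !startsWith(x, "chr") & !is.na(x)
  x[pre] <- paste0("chr", x[pre])
  x[x == "chrMT"] <- "chrM"
  x
}

#' Is each record a single-nucleotide variant?
#'
#' @param records a variant table.
#' @return logical vector; `TRUE` iff `nchar(ref) == nchar(alt) == 1`.
#' @export
is_snv <- function(records) {
  nchar(records$ref) == 1L & nchar(records$alt) == 1L
}

#' Minor allele frequency
#'
#' Computed on demand as `min(af, 1 - af)`; never stored in the table.
#'
#' @param records a variant table.
#' @return numeric vector of MAF values.
#' @export
maf <- function(records) pmin(records$af, 1 - records$af)

variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

#' Read a variant table from VCF or TSV
#'
#' VCF 4.x input is parsed with \pkg{vcfR}; `AC`, `AN` and `AF` are read
#' from INFO (per-alternate comma lists honoured) and the FILTER column is
#' kept verbatim. Multi-allelic lines are decomposed into one record per
#' alternate allele, conserving the per-site total alternate allele count.
#' TSV input must carry a header with at least `chrom, pos, ref, alt` plus
#' `af` or both `ac` and `an`; `filter` defaults to "PASS".
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`; guessed from the file extension when
#'   omitted.
#' @return a `variant_table`.
#' @export
read_variant_table <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) vp_stop("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") read_variant_vcf(path) else read_variant_tsv(path)
}

read_variant_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "")
  check_columns(df, c("chrom", "pos", "ref", "alt"), "variant TSV")
  if (!"af" %in% names(df) && !all(c("ac", "an") %in% names(df))) {
    vp_stop("variant TSV must provide `af` or both `ac` and `an`")
  }
  n <- nrow(df)
  pos <- suppressWarnings(as.integer(df$pos))
  if (any(is.na(pos) & !is.na(df$pos))) {
    vp_stop("malformed coordinate at line %d",
            which(is.na(pos) & !is.na(df$pos))[1L] + 1L)
  }
  out <- data.frame(chrom = normalize_contig(df$chrom), pos = pos,
                    ref = as.character(df$ref), alt = as.character(df$alt),
                    ac = if ("ac" %in% names(df)) as.integer(df$ac) else
                      NA_integer_,
                    an = if ("an" %in% names(df)) as.integer(df$an) else
                      NA_integer_,
                    af = if ("af" %in% names(df)) as.numeric(df$af) else
                      NA_real_,
                    filter = if ("filter" %in% names(df))
                      as.character(df$filter) else "PASS",
                    stringsAsFactors = FALSE)
  for (opt in c("consequence", "cohort")) {
    if (opt %in% names(df)) out[[opt]] <- as.character(df[[opt]])
  }
  # header occupies line 1, so record i sits on file line i + 1
  validate_variant_table(out, line_offset = 1L)
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  info_list <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, n) else v
  }
  ac_s <- info_list("AC"); an_s <- info_list("AN"); af_s <- info_list("AF")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    k <- length(alts)
    split_a <- function(s) {
      if (is.na(s)) return(rep(NA_character_, k))
      parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
      if (length(parts) == k) parts else rep(parts[1L], k)
    }
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    if (is.na(pos)) vp_stop("malformed coordinate at VCF record %d", i)
    rows[[i]] <- data.frame(
      chrom = unname(normalize_contig(fix[i, "CHROM"])), pos = unname(pos),
      ref = unname(fix[i, "REF"]), alt = unname(alts),
      ac = suppressWarnings(as.integer(unname(split_a(ac_s[i])))),
      an = suppressWarnings(as.integer(rep(unname(an_s[i]), k))),
      af = suppressWarnings(as.numeric(unname(split_a(af_s[i])))),
      filter = rep(unname(fix[i, "FILTER"]), k), stringsAsFactors = FALSE,
      row.names = NULL)
  }
  validate_variant_table(do.call(rbind, rows))
}

#' Construct a labeled dataset
#'
#' A labeled dataset is a variant table plus a binary `label` column
#' (0 = proxy-benign, 1 = proxy-deleterious) and a positive `weight`
#' column. `balanced = TRUE` requires equal label-class counts.
#'
#' @param records a variant table.
#' @param labels integer/numeric vector of 0/1 labels, one per record.
#' @param weights optional positive weights (default all 1).
#' @param balanced logical flag recorded on the dataset.
#' @return a `data.frame` with class `labeled_dataset`.
#' @export
labeled_dataset <- function(records, labels, weights = NULL,
                            balanced = FALSE) {
  if (length(labels) != nrow(records)) {
    vp_stop("labels length (%d) != record count (%d)", length(labels),
            nrow(records))
  }
  if (!all(labels %in% c(0, 1))) vp_stop("labels must be 0 or 1")
  if (is.null(weights)) weights <- rep(1, nrow(records))
  if (length(weights) != nrow(records) || any(weights <= 0)) {
    vp_stop("weights must be positive, one per record")
  }
  if (balanced && sum(labels == 0) != sum(labels == 1)) {
    vp_stop("balanced dataset must have equal label-class counts (%d vs %d)",
            sum(labels == 0), sum(labels == 1))
  }
  out <- as.data.frame(records)
  out$label <- as.integer(labels)
  out$weight <- as.numeric(weights)
  attr(out, "balanced") <- balanced
  class(out) <- c("labeled_dataset", "variant_table", "data.frame")
  out
}

#' Write / read a labeled dataset as TSV
#'
#' Serialized columns are `chrom, pos, ref, alt, ac, an, af, filter, label,
#' weight` (plus `consequence`/`cohort` when present); reading reproduces
#' records, labels and weights exactly.
#'
#' @param dataset a `labeled_dataset`.
#' @param path output file path.
#' @return `write_labeled_dataset` returns `path` invisibly;
#'   `read_labeled_dataset` returns a `labeled_dataset`.
#' @export
write_labeled_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df$balanced <- attr(dataset, "balanced")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeled_dataset
#' @export
read_labeled_dataset <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  check_columns(df, c("chrom", "pos", "ref", "alt", "label", "weight"),
                "labeled dataset TSV")
  balanced <- if ("balanced" %in% names(df)) isTRUE(df$balanced[1L]) else
    FALSE
  labels <- df$label
  weights <- df$weight
  df$label <- NULL; df$weight <- NULL; df$balanced <- NULL
  labeled_dataset(validate_variant_table(df, require_frequency = FALSE),
                  labels, weights, balanced)
}

#' Construct an annotation matrix
#'
#' An annotation matrix holds per-variant annotation columns keyed by
#' (chrom, pos, ref, alt), together with a per-column schema assigning each
#' annotation a kind (`numeric` or `categorical`) and one of the five
#' feature-group tags: `conservation_constraint`, `epigenetic_regulatory`,
#' `sequence_based`, `variant_density`, `other`.
#'
#' @param keys data.frame with columns chrom, pos, ref, alt (unique rows).
#' @param data data.frame of annotation columns aligned to `keys`; missing
#'   values are `NA`, never 0.
#' @param schema data.frame with columns `column`, `kind`, `group` and
#'   optionally `impute` (literal default, `"median"` or `"mode"`).
#' @return an object of class `annotation_matrix`.
#' @export
annotation_matrix <- function(keys, data, schema) {
  check_columns(keys, c("chrom", "pos", "ref", "alt"), "annotation keys")
  check_columns(schema, c("column", "kind", "group"), "annotation schema")
  if (!"impute" %in% names(schema)) schema$impute <- "median"
  if (nrow(keys) != nrow(data)) vp_stop("keys and data row counts differ")
  k <- paste(keys$chrom, keys$pos, keys$ref, keys$alt, sep = ":")
  if (anyDuplicated(k)) {
    vp_stop("duplicate row key: %s", k[duplicated(k)][1L])
  }
  extra <- setdiff(names(data), schema$column)
  if (length(extra) > 0L) {
    vp_stop("column(s) absent from schema: %s", paste(extra, collapse = ", "))
  }
  bad_grp <- setdiff(schema$group, feature_groups())
  if (length(bad_grp) > 0L) {
    vp_stop("unknown feature group(s): %s", paste(bad_grp, collapse = ", "))
  }
  bad_kind <- setdiff(schema$kind, c("numeric", "categorical"))
  if (length(bad_kind) > 0L) {
    vp_stop("unknown annotation kind(s): %s", paste(bad_kind, collapse = ", "))
  }
  schema <- schema[match(names(data), schema$column), , drop = FALSE]
  structure(list(keys = as.data.frame(keys)[c("chrom", "pos", "ref", "alt")],
                 data = as.data.frame(data, stringsAsFactors = FALSE),
                 schema = as.data.frame(schema)),
            class = "annotation_matrix")
}

#' The five annotation feature groups
#'
#' @return character vector of valid group tags.
#' @export
feature_groups <- function() {
  c("conservation_constraint", "epigenetic_regulatory", "sequence_based",
    "variant_density", "other")
}

#' Read an annotation matrix from TSV
#'
#' Rows are keyed by (chrom, pos, ref, alt); remaining header names must
#' match the schema. Empty cells and `NA` are recorded as missing, never 0.
#'
#' @param path TSV file path with a mandatory header.
#' @param schema per-column schema data.frame (see [annotation_matrix()]).
#' @return an `annotation_matrix`.
#' @export
read_annotation_matrix <- function(path, schema) {
  if (!file.exists(path)) vp_stop("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          comment.char = "", quote = "")
  check_columns(df, c("chrom", "pos", "ref", "alt"), "annotation TSV")
  keys <- df[c("chrom", "pos", "ref", "alt")]
  data <- df[setdiff(names(df), names(keys))]
  for (col in names(data)) {
    kind <- schema$kind[match(col, schema$column)]
    if (!is.na(kind) && kind == "numeric") data[[col]] <- as.numeric(data[[col]])
    if (!is.na(kind) && kind == "categorical") {
      data[[col]] <- as.character(data[[col]])
    }
  }
  annotation_matrix(keys, data, schema)
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("annotation_matrix: %d records x %d annotations\n",
              nrow(x$keys), ncol(x$data)))
  tab <- table(x$schema$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
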