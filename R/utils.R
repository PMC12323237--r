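# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so that seeded package functions never perturb the
#' global random stream.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent error prefix; `...` passed to sprintf
vp_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# assert that a data.frame has the given columns
check_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    vp_stop("%s is missing required column(s): %s", what,
            paste(miss, collapse = ", "))
  }
  invisible(df)
}

# numerically stable log(1 + exp(z))
log1pexp <- function(z) {
  out <- numeric(length(z))
  pos <- z > 0
  out[pos] <- z[pos] + log1p(exp(-z[pos]))
  out[!pos] <- log1p(exp(z[!pos]))
  out
}
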