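#' @importFrom rlang abort warn inform %||%
#' @importFrom stats p.adjust quantile rnorm rpois rnbinom rbeta runif sd
#' @importFrom utils head
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All randomness in the package flows through this single gate.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort("`seed` must be a single integer.")
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Normalize gene symbols: trim surrounding whitespace. Matching everywhere in
# the package is case-sensitive; silent case-folding would merge distinct
# symbols.
normalize_symbols <- function(x) {
  trimws(as.character(x))
}

assert_unique_symbols <- function(x, what = "gene symbols") {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate %s are not allowed (first offenders: %s). Resolve duplicates explicitly before import.",
      what, paste(head(dup, 5), collapse = ", ")
    ))
  }
  invisible(x)
}
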