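#' Taxonomic rank ladder
#'
#' The seven-rank ladder used throughout the package, from superkingdom down
#' to species. Lowest-common-ancestor assignment, biomass aggregation and the
#' synthetic taxonomy all use this fixed ladder with no rank skipping.
#'
#' @return Character vector of the seven rank names, root first.
#' @export
tax_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
}

# Column-checked data.frame accessor used by the readers.
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
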