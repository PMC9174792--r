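#' @keywords internal
"_PACKAGE"

## NULL-coalescing helper used throughout
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' `base::round()` rounds half to even; printed stoichiometry tables follow
#' the usual laboratory convention of rounding .5 away from zero.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(-0.5)  # -1
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Internal: run `expr` under a local RNG seeded with `seed`, restoring the
## caller's random state afterwards. All stochastic entry points go through
## this so nothing in the package touches global RNG state.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

## Internal: derive a stream of child seeds from a master seed, so that
## multi-stage simulations stay reproducible while stages remain independent.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_data <- function(...) stop(..., call. = FALSE)

## Plain TSV writers/readers: every tabular artifact in the package is
## tab-separated UTF-8 with a mandatory header and no quoting surprises.
write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
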