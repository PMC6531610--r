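# Shared low-level helpers. Coordinates are 0-based half-open everywhere
# inside the package; SAM/VCF/BED writers convert on export.

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over the alphabet A, C, G, T.
#' @return The reverse complement, as an upper-case character scalar.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream alone.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_scalar_number(seed, "seed")
  withr::with_seed(as.integer(seed), code)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_probability <- function(x, name, open = FALSE) {
  check_scalar_number(x, name)
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) abort(sprintf("`%s` must be a probability, got %s.", name, x))
  invisible(x)
}

# Half-open interval intersection; returns c(start, end) or NULL.
interval_intersect <- function(a, b) {
  lo <- max(a[[1]], b[[1]])
  hi <- min(a[[2]], b[[2]])
  if (lo >= hi) NULL else c(lo, hi)
}

interval_overlaps <- function(a_start, a_end, b_start, b_end) {
  pmax(a_start, b_start) < pmin(a_end, b_end)
}

# Derive per-stage child seeds from a master seed, reproducibly and
# below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
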