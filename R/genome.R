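# Synthetic reference genomes with planted features. A `synthetic_genome`
# carries its nucleotide sequence plus ground-truth feature tables (inverted
# LCR pairs, inversion events) so downstream callers can be scored against
# truth.

new_synthetic_genome <- function(name, sequence, lcr_pairs = empty_lcr_pairs(),
                                 inversions = empty_inversions(), seed = NA_integer_) {
  structure(
    list(
      name = name,
      sequence = sequence,
      lcr_pairs = lcr_pairs,
      inversions = inversions,
      seed = seed
    ),
    class = "synthetic_genome"
  )
}

empty_lcr_pairs <- function() {
  tibble(
    copy_a_start = integer(), copy_a_end = integer(),
    copy_b_start = integer(), copy_b_end = integer(),
    orientation = character(), identity_pct = double(),
    separation_bp = integer()
  )
}

empty_inversions <- function() {
  tibble(start = integer(), end = integer(), mechanism = character())
}

#' Genome length in base pairs
#' @param genome A `synthetic_genome`.
#' @return Integer length of the sequence.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "synthetic_genome"))
  nchar(genome$sequence)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %s: %s bp, %d LCR pair(s), %d inversion(s), seed %s\n",
    x$name, format(genome_length(x), big.mark = ","),
    nrow(x$lcr_pairs), nrow(x$inversions), x$seed
  ))
  invisible(x)
}

validate_genome <- function(genome) {
  len <- genome_length(genome)
  if (len <= 0) abort("Genome sequence must be non-empty.")
  if (grepl("[^ACGT]", genome$sequence)) {
    abort("Genome sequence restricted to the alphabet A, C, G, T.")
  }
  feats <- c(
    genome$lcr_pairs$copy_a_start, genome$lcr_pairs$copy_b_end,
    genome$inversions$start, genome$inversions$end
  )
  if (length(feats) && (min(feats) < 0 || max(feats) > len)) {
    abort("Recorded feature intervals must lie within the genome.")
  }
  invisible(genome)
}

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc_fraction`, split evenly
#' between G and C (and between A and T).
#'
#' @param length_bp Genome length in base pairs (at least 1000).
#' @param gc_fraction Target GC content, strictly between 0 and 1.
#' @param seed Integer seed; the result is bit-reproducible given the seed.
#' @param name Sequence name used on FASTA/SAM export.
#' @return A `synthetic_genome` with empty feature tables.
#' @examples
#' g <- generate_genome(5000, gc_fraction = 0.4, seed = 1)
#' genome_length(g)
#' @export
generate_genome <- function(length_bp, gc_fraction = 0.5, seed, name = "chrS") {
  check_scalar_number(length_bp, "length_bp", lower = 1000)
  check_probability(gc_fraction, "gc_fraction", open = TRUE)
  check_scalar_number(seed, "seed")
  seq <- with_seed_(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    paste(sample(names(p), length_bp, replace = TRUE, prob = p), collapse = "")
  })
  new_synthetic_genome(name, seq, seed = as.integer(seed))
}

#' Plant an inverted low-copy-repeat pair
#'
#' Copies a segment of length `copy_len_bp` starting at `anchor_bp`, reverse
#' complements it, mutates `100 - identity_pct` percent of its positions
#' (substitutions only, drawn without replacement), and writes the result
#' back `separation_bp` bases downstream of the first copy. The planted pair
#' is recorded in the genome's `lcr_pairs` truth table with
#' `orientation = "inverted"`.
#'
#' @param genome A `synthetic_genome`.
#' @param copy_len_bp Length of each repeat copy.
#' @param separation_bp Gap between the end of copy A and the start of copy B.
#' @param identity_pct Target sequence identity of the two copies, in
#'   \[0, 100\]; 100 plants an exact inverted copy.
#' @param anchor_bp 0-based start of copy A.
#' @param seed Integer seed controlling which positions are mutated.
#' @return The genome with copy B overwritten and the pair recorded.
#' @export
plant_inverted_lcr <- function(genome, copy_len_bp, separation_bp, identity_pct,
                               anchor_bp, seed) {
  stopifnot(inherits(genome, "synthetic_genome"))
  check_scalar_number(copy_len_bp, "copy_len_bp", lower = 1)
  check_scalar_number(separation_bp, "separation_bp", lower = 0)
  check_scalar_number(identity_pct, "identity_pct", lower = 0, upper = 100)
  check_scalar_number(anchor_bp, "anchor_bp", lower = 0)
  len <- genome_length(genome)
  b_start <- anchor_bp + copy_len_bp + separation_bp
  b_end <- b_start + copy_len_bp
  if (b_end > len) {
    abort("Planted LCR pair exceeds the genome; shrink copy_len/separation/anchor.")
  }
  copy_a <- substr(genome$sequence, anchor_bp + 1L, anchor_bp + copy_len_bp)
  copy_b <- revcomp(copy_a)
  n_mut <- round(copy_len_bp * (100 - identity_pct) / 100)
  if (n_mut > 0) {
    copy_b <- with_seed_(seed, mutate_substitutions(copy_b, n_mut))
  }
  seq <- genome$sequence
  substr(seq, b_start + 1L, b_end) <- copy_b
  genome$sequence <- seq
  genome$lcr_pairs <- bind_rows(genome$lcr_pairs, tibble(
    copy_a_start = as.integer(anchor_bp),
    copy_a_end = as.integer(anchor_bp + copy_len_bp),
    copy_b_start = as.integer(b_start),
    copy_b_end = as.integer(b_end),
    orientation = "inverted",
    identity_pct = as.numeric(identity_pct),
    separation_bp = as.integer(separation_bp)
  ))
  validate_genome(genome)
}

# Substitute n distinct positions of `x` with a different base each.
mutate_substitutions <- function(x, n) {
  bases <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(bases), n)
  alphabet <- c("A", "C", "G", "T")
  for (p in pos) {
    bases[p] <- sample(setdiff(alphabet, bases[p]), 1L)
  }
  paste(bases, collapse = "")
}

#' Apply a paracentric inversion to a genome
#'
#' Replaces the half-open segment `[start, end)` with its reverse complement
#' (a 180-degree flip of the genomic sequence) and records the event in the
#' genome's `inversions` truth table. Applying the same inversion twice
#' restores the original sequence.
#'
#' @param genome A `synthetic_genome`.
#' @param start,end 0-based half-open inversion bounds.
#' @param mechanism Label recorded with the event: `"nahr"` when the
#'   breakpoints fall inside an inverted LCR pair, else `"arbitrary"`.
#' @return The genome with the segment flipped and the event recorded.
#' @export
apply_inversion <- function(genome, start, end, mechanism = c("arbitrary", "nahr")) {
  stopifnot(inherits(genome, "synthetic_genome"))
  mechanism <- match.arg(mechanism)
  len <- genome_length(genome)
  check_scalar_number(start, "start", lower = 0)
  check_scalar_number(end, "end", upper = len)
  if (start >= end) abort("Inversion requires start < end.")
  seg <- substr(genome$sequence, start + 1L, end)
  seq <- genome$sequence
  substr(seq, start + 1L, end) <- revcomp(seg)
  genome$sequence <- seq
  genome$inversions <- bind_rows(genome$inversions, tibble(
    start = as.integer(start), end = as.integer(end), mechanism = mechanism
  ))
  validate_genome(genome)
}
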