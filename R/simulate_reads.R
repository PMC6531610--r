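# Analytic read "alignment" simulation. Because the donor differs from the
# reference only by recorded inversion events, every read's reference-space
# position and strand can be computed exactly by coordinate reflection -- no
# aligner is involved. A donor base at position p inside an inverted segment
# [s, e) originates from reference position s + e - 1 - p on the opposite
# strand; a donor interval [a, b) inside [s, e) therefore maps to the
# reference interval [s + e - b, s + e - a) with flipped strand.

#' Paired-end library profile
#'
#' @param mean_bp Mean insert (outer fragment) size. The default mirrors a
#'   short-fragment mate-pair library with inserts of approximately 350 bp.
#' @param sd_bp Insert-size standard deviation; defaults to 10% of the mean.
#' @param read_len_bp Read length; the insert must hold two reads.
#' @param per_base_error Substitution error probability, in \[0, 0.1).
#' @return A list with class `insert_profile`.
#' @export
insert_profile <- function(mean_bp = 350, sd_bp = 35, read_len_bp = 100,
                           per_base_error = 0) {
  check_scalar_number(mean_bp, "mean_bp", lower = 1)
  check_scalar_number(sd_bp, "sd_bp", lower = 0)
  check_scalar_number(read_len_bp, "read_len_bp", lower = 1)
  check_scalar_number(per_base_error, "per_base_error", lower = 0)
  if (per_base_error >= 0.1) abort("`per_base_error` must be < 0.1.")
  if (mean_bp < 2 * read_len_bp) {
    abort("`mean_bp` must be at least twice `read_len_bp` (FR library).")
  }
  structure(
    list(mean_bp = mean_bp, sd_bp = sd_bp, read_len_bp = as.integer(read_len_bp),
         orientation = "FR", per_base_error = per_base_error),
    class = "insert_profile"
  )
}

# Map donor-space half-open intervals to reference space through the donor's
# recorded inversions (applied to the reference in order, assumed disjoint).
# Vectorized over intervals; returns ref_start, ref_end, flipped (logical),
# spanning (TRUE when the interval straddles a breakpoint; such intervals
# are returned unmapped with spanning = TRUE).
reflect_to_reference <- function(start, end, inversions) {
  ref_start <- start
  ref_end <- end
  flipped <- rep(FALSE, length(start))
  spanning <- rep(FALSE, length(start))
  if (nrow(inversions)) {
    for (i in rev(seq_len(nrow(inversions)))) {
      s <- inversions$start[[i]]
      e <- inversions$end[[i]]
      inside <- ref_start >= s & ref_end <= e
      straddle <- !inside & interval_overlaps(ref_start, ref_end, s, e)
      spanning <- spanning | straddle
      new_start <- s + e - ref_end
      new_end <- s + e - ref_start
      ref_start[inside] <- new_start[inside]
      ref_end[inside] <- new_end[inside]
      flipped <- xor(flipped, inside)
    }
  }
  tibble(ref_start = ref_start, ref_end = ref_end,
         flipped = flipped, spanning = spanning)
}

# Map one breakpoint-straddling donor read: keep the longer sub-segment that
# is wholly inside or outside an inversion, map it, and report the clipped
# length for the CIGAR.
map_clipped_read <- function(start, end, inversions) {
  cuts <- sort(unique(c(
    start, end,
    inversions$start[inversions$start > start & inversions$start < end],
    inversions$end[inversions$end > start & inversions$end < end]
  )))
  pieces <- tibble(p_start = head(cuts, -1), p_end = tail(cuts, -1))
  best <- which.max(pieces$p_end - pieces$p_start)
  m <- reflect_to_reference(pieces$p_start[best], pieces$p_end[best], inversions)
  list(
    ref_start = m$ref_start, ref_end = m$ref_end, flipped = m$flipped,
    matched = pieces$p_end[best] - pieces$p_start[best],
    clip_left = pieces$p_start[best] - start,
    clip_right = end - pieces$p_end[best]
  )
}

#' Simulate paired-end alignments of a donor genome against a reference
#'
#' Fragments are drawn uniformly from the donor with Normal(`mean_bp`,
#' `sd_bp`) insert sizes in FR orientation; each read's reference-space
#' position and strand is computed analytically by coordinate reflection
#' through the donor's recorded inversions. Reads wholly inside an inverted
#' segment are mirrored (position reflected about the inversion, strand
#' flipped); reads wholly outside are unchanged; reads overlapping a
#' breakpoint are emitted as clipped records flagged `spanning = TRUE`.
#'
#' @param reference The reference `synthetic_genome`.
#' @param donor A `synthetic_genome` derived from the reference by
#'   [apply_inversion()] (same coordinate frame and length).
#' @param coverage_x Mean sequence coverage; the pair count is
#'   `round(coverage_x * length / (2 * read_len))`.
#' @param profile An [insert_profile()].
#' @param seed Integer seed.
#' @return A tibble of aligned pairs, one row per pair, with 1-based leftmost
#'   positions `pos1 <= pos2`, strands, CIGARs, signed `template_len_bp`
#'   (positive for the leftmost mate, per SAM convention), `mapq` and a
#'   `spanning` flag.
#' @export
simulate_paired_end_alignments <- function(reference, donor, coverage_x,
                                           profile = insert_profile(), seed) {
  stopifnot(inherits(reference, "synthetic_genome"),
            inherits(donor, "synthetic_genome"),
            inherits(profile, "insert_profile"))
  if (genome_length(reference) != genome_length(donor)) {
    abort("Donor and reference must have equal length (same coordinate frame).")
  }
  check_scalar_number(coverage_x, "coverage_x", lower = 0)
  len <- genome_length(donor)
  rl <- profile$read_len_bp
  n_pairs <- round(coverage_x * len / (2 * rl))
  if (n_pairs == 0) return(empty_aligned_pairs())
  inv <- donor$inversions

  with_seed_(seed, {
    ins <- pmax(2L * rl, pmin(len, round(rnorm(n_pairs, profile$mean_bp, profile$sd_bp))))
    frag_start <- floor(runif(n_pairs, 0, len - ins + 1))
    # donor-space reads: R1 leads the fragment (+), R2 trails it (-)
    r1s <- frag_start; r1e <- frag_start + rl
    r2s <- frag_start + ins - rl; r2e <- frag_start + ins
    m1 <- reflect_to_reference(r1s, r1e, inv)
    m2 <- reflect_to_reference(r2s, r2e, inv)
    cigar_full <- paste0(rl, "M")
    out <- tibble(
      pair_id = sprintf("pair%06d", seq_len(n_pairs)),
      chrom = reference$name,
      a_start = m1$ref_start, a_end = m1$ref_end,
      a_strand = ifelse(m1$flipped, "-", "+"),
      a_cigar = cigar_full, a_span = m1$spanning,
      b_start = m2$ref_start, b_end = m2$ref_end,
      # R2 is sequenced on the fragment's reverse strand
      b_strand = ifelse(m2$flipped, "+", "-"),
      b_cigar = cigar_full, b_span = m2$spanning
    )
    # resolve breakpoint-straddling reads as clipped records
    for (side in c("a", "b")) {
      idx <- which(out[[paste0(side, "_span")]])
      for (i in idx) {
        ds <- if (side == "a") r1s[i] else r2s[i]
        de <- if (side == "a") r1e[i] else r2e[i]
        cl <- map_clipped_read(ds, de, inv)
        out[[paste0(side, "_start")]][i] <- cl$ref_start
        out[[paste0(side, "_end")]][i] <- cl$ref_end
        base_minus <- if (side == "a") cl$flipped else !cl$flipped
        out[[paste0(side, "_strand")]][i] <- if (base_minus) "-" else "+"
        # clip order follows reference orientation of the kept block
        clips <- if (out[[paste0(side, "_strand")]][i] == "+") {
          c(cl$clip_left, cl$clip_right)
        } else {
          c(cl$clip_right, cl$clip_left)
        }
        out[[paste0(side, "_cigar")]][i] <- paste0(
          if (clips[1] > 0) paste0(clips[1], "S") else "",
          cl$matched, "M",
          if (clips[2] > 0) paste0(clips[2], "S") else ""
        )
      }
    }
    # order mates so that mate 1 is leftmost in reference space
    a_first <- out$a_start <= out$b_start
    swap <- function(a, b) list(ifelse(a_first, a, b), ifelse(a_first, b, a))
    pos <- swap(out$a_start, out$b_start)
    ends <- swap(out$a_end, out$b_end)
    strands <- swap(out$a_strand, out$b_strand)
    cigars <- swap(out$a_cigar, out$b_cigar)
    tlen <- pmax(out$a_end, out$b_end) - pmin(out$a_start, out$b_start)
    tibble(
      pair_id = out$pair_id,
      chrom = out$chrom,
      pos1 = as.integer(pos[[1]] + 1L), strand1 = strands[[1]], cigar1 = cigars[[1]],
      end1 = as.integer(ends[[1]] + 1L),
      pos2 = as.integer(pos[[2]] + 1L), strand2 = strands[[2]], cigar2 = cigars[[2]],
      end2 = as.integer(ends[[2]] + 1L),
      read_len_bp = rl,
      template_len_bp = as.integer(tlen),
      mapq = 60L,
      spanning = out$a_span | out$b_span
    )
  })
}

empty_aligned_pairs <- function() {
  tibble(
    pair_id = character(), chrom = character(),
    pos1 = integer(), strand1 = character(), cigar1 = character(), end1 = integer(),
    pos2 = integer(), strand2 = character(), cigar2 = character(), end2 = integer(),
    read_len_bp = integer(), template_len_bp = integer(),
    mapq = integer(), spanning = logical()
  )
}

#' Simulate segmented long-read alignments
#'
#' Each read that spans `k` inversion breakpoints yields `k + 1` alignment
#' segments with alternating strands, their reference intervals computed by
#' the same analytic reflection used for paired ends; non-spanning reads
#' yield a single segment.
#'
#' @param reference,donor As in [simulate_paired_end_alignments()].
#' @param n_reads Number of reads (> 0).
#' @param length_law Either a single number (constant read length) or
#'   `list(meanlog =, sdlog =)` for lognormal lengths, truncated to
#'   \[200, genome length\].
#' @param seed Integer seed.
#' @return A tibble with one row per alignment segment: `read_id`,
#'   `segment` index (read order), 0-based `read_start`/`read_end` within the
#'   read, 0-based half-open `ref_start`/`ref_end`, `strand`, `read_len_bp`.
#' @export
simulate_long_read_alignments <- function(reference, donor, n_reads,
                                          length_law = list(meanlog = log(20000), sdlog = 0.5),
                                          seed) {
  stopifnot(inherits(reference, "synthetic_genome"),
            inherits(donor, "synthetic_genome"))
  if (genome_length(reference) != genome_length(donor)) {
    abort("Donor and reference must have equal length (same coordinate frame).")
  }
  if (!is.numeric(n_reads) || length(n_reads) != 1L || n_reads <= 0) {
    abort("`n_reads` must be a positive count.")
  }
  len <- genome_length(donor)
  inv <- donor$inversions
  with_seed_(seed, {
    rl <- if (is.numeric(length_law) && length(length_law) == 1L) {
      rep(as.integer(length_law), n_reads)
    } else {
      round(stats::rlnorm(n_reads, length_law$meanlog, length_law$sdlog))
    }
    rl <- pmax(200L, pmin(len, as.integer(rl)))
    start <- floor(runif(n_reads, 0, len - rl + 1))
    end <- start + rl
    purrr::map_dfr(seq_len(n_reads), function(i) {
      cuts <- sort(unique(c(
        start[i], end[i],
        inv$start[inv$start > start[i] & inv$start < end[i]],
        inv$end[inv$end > start[i] & inv$end < end[i]]
      )))
      p_start <- head(cuts, -1)
      p_end <- tail(cuts, -1)
      m <- reflect_to_reference(p_start, p_end, inv)
      tibble(
        read_id = sprintf("read%05d", i),
        segment = seq_along(p_start),
        read_start = as.integer(p_start - start[i]),
        read_end = as.integer(p_end - start[i]),
        chrom = reference$name,
        ref_start = as.integer(m$ref_start),
        ref_end = as.integer(m$ref_end),
        strand = ifelse(m$flipped, "-", "+"),
        read_len_bp = rl[i]
      )
    })
  })
}
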