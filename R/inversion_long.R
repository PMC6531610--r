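# Strand-flip inversion calling from segmented long-read alignments. A read
# crossing an inversion breakpoint aligns as consecutive segments on
# opposite strands. In reference space, each strand-flip junction localizes
# BOTH breakpoints of the inversion: the flipped segment continues from the
# image of the other breakpoint, so a (+,-) junction pairs the plus
# segment's reference end (proximal) with the minus segment's reference end
# (distal), and a (-,+) junction pairs the minus segment's reference start
# (proximal) with the plus segment's reference start (distal).

#' Detect strand-flip breakpoint candidates in one or more long reads
#'
#' Scans read-ordered segments; each adjacent pair with opposite strands and
#' a geometry consistent with a single inversion (proximal < distal; the
#' flipped segment lies between the implied breakpoints, within
#' `junction_tol_bp`) yields a (proximal, distal) candidate. Segments
#' shorter than `min_segment_bp` are ignored. Reads with three or more
#' alternating segments produce `full_span` candidates; two-segment reads
#' produce `partial` ones.
#'
#' @param segments Long-read segment tibble
#'   (see [simulate_long_read_alignments()]); may hold many reads.
#' @param min_segment_bp Minimum segment length considered (default 200).
#' @param junction_tol_bp Tolerance for segment/breakpoint consistency
#'   (default 100), absorbing clipped bases at homology boundaries.
#' @return Candidate tibble: `read_id`, `chrom`, `proximal_bp`, `distal_bp`
#'   (0-based), `pattern` (`full_span`/`partial`).
#' @export
detect_strand_flips <- function(segments, min_segment_bp = 200,
                                junction_tol_bp = 100) {
  segs <- dplyr::filter(segments, .data$ref_end - .data$ref_start >= min_segment_bp)
  if (!nrow(segs)) return(empty_flip_candidates())
  segs <- arrange(segs, .data$read_id, .data$segment)
  by_read <- split(segs, segs$read_id)
  purrr::map_dfr(by_read, function(sg) {
    if (nrow(sg) < 2L) return(empty_flip_candidates())
    n_seg <- nrow(sg)
    out <- list()
    for (i in seq_len(n_seg - 1L)) {
      a <- sg[i, ]; b <- sg[i + 1L, ]
      if (a$strand == b$strand) next
      if (a$strand == "+") {
        prox <- a$ref_end; dist <- b$ref_end
        flipped <- b
      } else {
        prox <- a$ref_start; dist <- b$ref_start
        flipped <- a
      }
      if (prox >= dist) next
      # the flipped segment must lie within the implied inverted interval
      if (flipped$ref_start < prox - junction_tol_bp ||
          flipped$ref_end > dist + junction_tol_bp) next
      out[[length(out) + 1L]] <- tibble(
        read_id = a$read_id, chrom = a$chrom,
        proximal_bp = as.numeric(prox), distal_bp = as.numeric(dist),
        pattern = if (n_seg >= 3L) "full_span" else "partial"
      )
    }
    if (length(out)) bind_rows(out) else empty_flip_candidates()
  })
}

empty_flip_candidates <- function() {
  tibble(read_id = character(), chrom = character(),
         proximal_bp = double(), distal_bp = double(), pattern = character())
}

#' Consolidate strand-flip candidates into inversion calls
#'
#' Candidates are single-linkage clustered on breakpoint proximity (both
#' junctions within `cluster_window_bp`); the consensus breakpoint is the
#' median of member junctions; reported intervals are
#' `median +/- cluster_window_bp`; support counts distinct reads and must
#' reach `min_support`.
#'
#' @param candidates Candidate tibble from [detect_strand_flips()].
#' @param min_support Minimum distinct supporting reads (default 2).
#' @param cluster_window_bp Clustering window and reported half-width
#'   (default 500).
#' @return Inversion-call tibble with `evidence = "long_read"` (same schema
#'   as [call_inversions()], plus `n_full_span`).
#' @export
consolidate_long_read_calls <- function(candidates, min_support = 2,
                                        cluster_window_bp = 500) {
  check_scalar_number(min_support, "min_support", lower = 1)
  if (!nrow(candidates)) return(empty_inversion_calls())
  cand <- arrange(candidates, .data$proximal_bp, .data$distal_bp)
  brk <- c(TRUE, diff(cand$proximal_bp) > cluster_window_bp |
             abs(diff(cand$distal_bp)) > cluster_window_bp)
  cand$cluster <- cumsum(brk)
  cand |>
    group_by(.data$cluster) |>
    summarise(
      chrom = .data$chrom[[1]],
      prox_mid = stats::median(.data$proximal_bp),
      dist_mid = stats::median(.data$distal_bp),
      support = dplyr::n_distinct(.data$read_id),
      n_full_span = dplyr::n_distinct(.data$read_id[.data$pattern == "full_span"]),
      .groups = "drop"
    ) |>
    filter(.data$support >= min_support) |>
    transmute(
      chrom = .data$chrom,
      prox_start = pmax(0, .data$prox_mid - cluster_window_bp),
      prox_end = .data$prox_mid + cluster_window_bp,
      dist_start = pmax(0, .data$dist_mid - cluster_window_bp),
      dist_end = .data$dist_mid + cluster_window_bp,
      support_pp = 0L, support_mm = 0L,
      evidence = "long_read", one_sided = FALSE,
      support = .data$support, n_full_span = .data$n_full_span
    ) |>
    arrange(.data$prox_start)
}

#' Reconcile short-read and long-read inversion calls
#'
#' Calls whose proximal AND distal intervals both intersect across
#' technologies merge into a single call with `evidence = "both"` and
#' intersected intervals; unmatched calls pass through unchanged.
#'
#' @param short_calls,long_calls Inversion-call tibbles on the same
#'   reference.
#' @return A combined inversion-call tibble.
#' @export
reconcile_evidence <- function(short_calls, long_calls) {
  if (!nrow(long_calls)) return(short_calls)
  if (!nrow(short_calls)) return(long_calls)
  merged <- list()
  used_long <- rep(FALSE, nrow(long_calls))
  used_short <- rep(FALSE, nrow(short_calls))
  for (i in seq_len(nrow(short_calls))) {
    for (j in seq_len(nrow(long_calls))) {
      if (used_long[[j]]) next
      s <- short_calls[i, ]; l <- long_calls[j, ]
      prox <- interval_intersect(c(s$prox_start, s$prox_end), c(l$prox_start, l$prox_end))
      dist <- interval_intersect(c(s$dist_start, s$dist_end), c(l$dist_start, l$dist_end))
      if (is.null(prox) || is.null(dist)) next
      used_long[[j]] <- TRUE
      used_short[[i]] <- TRUE
      merged[[length(merged) + 1L]] <- tibble(
        chrom = s$chrom,
        prox_start = prox[[1]], prox_end = prox[[2]],
        dist_start = dist[[1]], dist_end = dist[[2]],
        support_pp = s$support_pp, support_mm = s$support_mm,
        evidence = "both", one_sided = FALSE
      )
      break
    }
  }
  bind_rows(
    if (length(merged)) bind_rows(merged) else NULL,
    short_calls[!used_short, , drop = FALSE],
    long_calls[!used_long, , drop = FALSE]
  ) |>
    arrange(.data$prox_start)
}
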