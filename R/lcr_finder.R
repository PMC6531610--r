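# Inverted-repeat discovery by seeded self-alignment: shared k-mers between
# the sequence and its reverse complement identify candidate inverted pairs;
# seeds on a consistent diagonal are chained and extended ungapped with
# match +1 / mismatch -2 scoring and x-drop termination. Because the repeat
# model is substitution-only, a true inverted pair sits on one exact
# diagonal; diagonals within k of each other are merged when chaining.

# split a sequence into its overlapping k-mers (0-based start positions)
kmer_positions <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(tibble(kmer = character(), pos = integer()))
  tibble(
    kmer = substring(seq, seq_len(n), seq_len(n) + k - 1L),
    pos = seq_len(n) - 1L
  )
}

#' Find inverted repeat pairs in a sequence
#'
#' Detects pairs of highly similar segments in opposite orientation (the
#' IP-LCR configuration that predisposes a locus to NAHR-mediated
#' rearrangement) by matching k-mers between the sequence and its reverse
#' complement, chaining seeds on consistent diagonals, and extending each
#' chain ungapped with +1/-2 scoring until the running score drops `xdrop`
#' below its maximum. Hits shorter than `min_len_bp` or below
#' `min_identity_pct` are discarded; the symmetric duplicate of each hit is
#' reported once, with `interval_a` leftmost. `identity_pct` is
#' `matches / aligned_len * 100` over the ungapped alignment.
#'
#' @param sequence Character scalar (or `synthetic_genome`).
#' @param k Seed length, in \[8, 32\].
#' @param min_len_bp Minimum reported hit length (>= 100).
#' @param min_identity_pct Minimum reported identity.
#' @param xdrop Score drop that terminates extension.
#' @return A tibble of hits: 0-based half-open `a_start`/`a_end`,
#'   `b_start`/`b_end` (leftmost copy first), `identity_pct`,
#'   `aligned_len_bp`, `score`, `separation_bp`.
#' @export
find_inverted_repeats <- function(sequence, k = 12, min_len_bp = 1000,
                                  min_identity_pct = 90, xdrop = 20) {
  if (inherits(sequence, "synthetic_genome")) sequence <- sequence$sequence
  check_scalar_number(k, "k", lower = 8, upper = 32)
  check_scalar_number(min_len_bp, "min_len_bp", lower = 100)
  n <- nchar(sequence)
  if (n < min_len_bp) return(empty_repeat_hits())
  rc <- revcomp(sequence)
  fwd <- kmer_positions(sequence, k)
  rev_ <- kmer_positions(rc, k)
  hits <- dplyr::inner_join(fwd, rev_, by = "kmer", suffix = c("_f", "_r"),
                            relationship = "many-to-many")
  if (!nrow(hits)) return(empty_repeat_hits())
  # a seed: sequence[i, i+k) == rc[j, j+k), i.e. an inverted match between
  # position i and position n - j - k; matches of one repeat share d = i - j
  hits <- hits |>
    mutate(diag = .data$pos_f - .data$pos_r) |>
    arrange(.data$diag, .data$pos_f)
  # chain seeds: same diagonal bucket (tolerance k) and seed gap <= 4k
  d <- hits$diag
  p <- hits$pos_f
  # break a chain when the diagonal jumps by more than k, or when the
  # positional gap between consecutive seeds exceeds 4k
  new_chain <- c(TRUE, (diff(d) > k) | (abs(diff(p)) > 4 * k))
  chain_id <- cumsum(new_chain)
  chains <- tibble(chain = chain_id, pos_f = p, pos_r = hits$pos_r) |>
    group_by(.data$chain) |>
    summarise(
      n_seeds = n(),
      f_lo = min(.data$pos_f), f_hi = max(.data$pos_f) + k,
      r_lo = min(.data$pos_r), r_hi = max(.data$pos_r) + k,
      .groups = "drop"
    ) |>
    filter(.data$n_seeds >= 3L)
  if (!nrow(chains)) return(empty_repeat_hits())
  seq_chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  rc_chars <- strsplit(rc, "", fixed = TRUE)[[1]]
  out <- purrr::map_dfr(seq_len(nrow(chains)), function(i) {
    ch <- chains[i, ]
    ext <- xdrop_extend(seq_chars, rc_chars, ch$f_lo, ch$f_hi, ch$r_lo, ch$r_hi, xdrop)
    a_start <- ext$f_lo
    a_end <- ext$f_hi
    # rc position j corresponds to sequence position n - 1 - j, so the rc
    # block [r_lo, r_hi) is the sequence block [n - r_hi, n - r_lo)
    b_start <- n - ext$r_hi
    b_end <- n - ext$r_lo
    tibble(
      a_start = a_start, a_end = a_end, b_start = b_start, b_end = b_end,
      identity_pct = ext$identity * 100, aligned_len_bp = a_end - a_start,
      score = ext$score
    )
  }) |>
    filter(.data$aligned_len_bp >= min_len_bp,
           .data$identity_pct >= min_identity_pct)
  if (!nrow(out)) return(empty_repeat_hits())
  # orient so interval_a is leftmost, then drop symmetric duplicates and
  # self-hits (a palindromic match of a block with its own reverse image)
  swap <- out$a_start > out$b_start
  out <- out |>
    mutate(
      s1 = ifelse(swap, .data$b_start, .data$a_start),
      e1 = ifelse(swap, .data$b_end, .data$a_end),
      s2 = ifelse(swap, .data$a_start, .data$b_start),
      e2 = ifelse(swap, .data$a_end, .data$b_end)
    ) |>
    filter(.data$e1 <= .data$s2) |>
    transmute(
      a_start = as.integer(.data$s1), a_end = as.integer(.data$e1),
      b_start = as.integer(.data$s2), b_end = as.integer(.data$e2),
      identity_pct = .data$identity_pct,
      aligned_len_bp = as.integer(.data$aligned_len_bp),
      score = .data$score,
      separation_bp = as.integer(.data$s2 - .data$e1)
    ) |>
    dplyr::distinct(.data$a_start, .data$a_end, .data$b_start, .data$b_end,
                    .keep_all = TRUE) |>
    arrange(dplyr::desc(.data$score))
  # a hit and its mirror (the same pair seeded from the other copy) can
  # disagree by a few bases at the ends; keep the best-scoring of any group
  # of mutually overlapping hits
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    kept <- which(keep)
    dup <- any(
      interval_overlaps(out$a_start[kept], out$a_end[kept],
                        out$a_start[[i]], out$a_end[[i]]) &
        interval_overlaps(out$b_start[kept], out$b_end[kept],
                          out$b_start[[i]], out$b_end[[i]])
    )
    keep[[i]] <- !dup
  }
  arrange(out[keep, , drop = FALSE], .data$a_start, .data$b_start)
}

#' @importFrom dplyr transmute distinct
NULL

empty_repeat_hits <- function() {
  tibble(
    a_start = integer(), a_end = integer(), b_start = integer(),
    b_end = integer(), identity_pct = double(), aligned_len_bp = integer(),
    score = double(), separation_bp = integer()
  )
}

# Ungapped x-drop extension of the aligned block seq[f_lo, f_hi) vs
# rc[r_lo, r_hi) in both directions; returns refined bounds, score and
# identity. Match +1, mismatch -2.
xdrop_extend <- function(seq_chars, rc_chars, f_lo, f_hi, r_lo, r_hi, xdrop) {
  n_f <- length(seq_chars)
  # the chain may have slightly inconsistent spans; align on the f block and
  # re-derive the rc block from the dominant diagonal
  d <- r_lo - f_lo
  r_lo <- f_lo + d
  r_hi <- f_hi + d
  # rightward extension
  step_scores <- function(f_idx, r_idx) {
    ifelse(seq_chars[f_idx] == rc_chars[r_idx], 1, -2)
  }
  max_right <- min(n_f - f_hi, n_f - r_hi)
  if (max_right > 0) {
    sc <- cumsum(step_scores(f_hi + seq_len(max_right), r_hi + seq_len(max_right)))
    keep <- best_prefix(sc, xdrop)
    f_hi <- f_hi + keep
    r_hi <- r_hi + keep
  }
  max_left <- min(f_lo, r_lo)
  if (max_left > 0) {
    # 0-based position p lives at character index p + 1
    sc <- cumsum(step_scores(f_lo - seq_len(max_left) + 1L,
                             r_lo - seq_len(max_left) + 1L))
    keep <- best_prefix(sc, xdrop)
    f_lo <- f_lo - keep
    r_lo <- r_lo - keep
  }
  f_idx <- (f_lo + 1L):f_hi
  r_idx <- (r_lo + 1L):r_hi
  matches <- sum(seq_chars[f_idx] == rc_chars[r_idx])
  len <- f_hi - f_lo
  list(
    f_lo = f_lo, f_hi = f_hi, r_lo = r_lo, r_hi = r_hi,
    identity = matches / len,
    score = matches - 2 * (len - matches)
  )
}

# Given cumulative extension scores, return the number of steps up to the
# score maximum, stopping at the first x-drop below the running maximum.
best_prefix <- function(sc, xdrop) {
  run_max <- cummax(sc)
  stop_at <- which(run_max - sc > xdrop)
  upto <- if (length(stop_at)) stop_at[[1]] - 1L else length(sc)
  if (upto == 0L || max(sc[seq_len(upto)]) <= 0) return(0L)
  which.max(sc[seq_len(upto)])
}

#' Flag NAHR-susceptible inverted repeat pairs
#'
#' Retains hits long, similar and spaced enough to mediate non-allelic
#' homologous recombination: aligned length at least `min_len_bp`, identity
#' at least `min_identity_pct` (default 98, matching the >98% homology
#' regime of disease-associated IP-LCR pairs), and separation within
#' `[min_sep_bp, max_sep_bp]`.
#'
#' @param hits A hit tibble from [find_inverted_repeats()].
#' @param min_len_bp,min_identity_pct,min_sep_bp,max_sep_bp Thresholds.
#' @return The qualifying subset of `hits`.
#' @export
flag_nahr_susceptible <- function(hits, min_len_bp = 1000, min_identity_pct = 98,
                                  min_sep_bp = 0, max_sep_bp = Inf) {
  if (min_sep_bp > max_sep_bp) abort("`min_sep_bp` must not exceed `max_sep_bp`.")
  filter(
    hits,
    .data$aligned_len_bp >= min_len_bp,
    .data$identity_pct >= min_identity_pct,
    .data$separation_bp >= min_sep_bp,
    .data$separation_bp <= max_sep_bp
  )
}
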