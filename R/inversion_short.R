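# Discordant mate-pair inversion calling. In an FR library, an inversion
# leaves a characteristic footprint: fragments straddling the proximal
# breakpoint map with both reads on the forward strand (++ pairs, first
# mate just left of the proximal breakpoint, second mate just left of the
# distal one), while fragments straddling the distal breakpoint map as --
# pairs just right of each breakpoint. The caller models the insert-size
# distribution robustly, classifies pairs, clusters discordant pairs by
# orientation class, and pairs up ++/-- clusters into breakpoint intervals.

#' Estimate the insert-size model from properly oriented pairs
#'
#' The median and scaled MAD (1.4826 * MAD) of `|template_len_bp|` are
#' computed over FR-orientated pairs only; concordance bounds are
#' `median +/- k_spread * spread`. "Markedly different from the expected
#' insert size" is operationalized by these robust bounds.
#'
#' @param pairs Aligned-pair tibble (needs `strand1`, `strand2`,
#'   `template_len_bp`).
#' @param k_spread Bound multiplier (default 5).
#' @return A list with class `insert_size_model`: `median_bp`, `spread_bp`,
#'   `lower_bp`, `upper_bp`, `n_pairs`.
#' @export
estimate_insert_model <- function(pairs, k_spread = 5) {
  check_scalar_number(k_spread, "k_spread", lower = 0)
  fr <- dplyr::filter(pairs, .data$strand1 != .data$strand2)
  if (nrow(fr) < 100L) {
    abort("Insert-size calibration needs at least 100 FR-orientated pairs.")
  }
  tl <- abs(fr$template_len_bp)
  med <- stats::median(tl)
  spread <- stats::mad(tl)  # already scaled by 1.4826
  structure(
    list(
      median_bp = med, spread_bp = spread,
      lower_bp = max(0, med - k_spread * spread),
      upper_bp = med + k_spread * spread,
      proper_orientation = "FR", n_pairs = nrow(fr)
    ),
    class = "insert_size_model"
  )
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf(
    "<insert_size_model> median %.0f bp, spread %.1f bp, concordant range [%.0f, %.0f] (n = %d FR pairs)\n",
    x$median_bp, x$spread_bp, x$lower_bp, x$upper_bp, x$n_pairs
  ))
  invisible(x)
}

#' Classify read pairs against an insert-size model
#'
#' Orientation discordance holds iff both reads map to the same strand;
#' distance discordance iff `|template_len_bp|` falls outside the model
#' bounds. Adds a `class` column with values `concordant`,
#' `discordant_distance`, `discordant_orientation` or `discordant_both`.
#'
#' @param pairs Aligned-pair tibble.
#' @param model An `insert_size_model`.
#' @return `pairs` with the `class` column appended.
#' @export
classify_pairs <- function(pairs, model) {
  stopifnot(inherits(model, "insert_size_model"))
  ori <- pairs$strand1 == pairs$strand2
  dist <- abs(pairs$template_len_bp) < model$lower_bp |
    abs(pairs$template_len_bp) > model$upper_bp
  mutate(pairs, class = dplyr::case_when(
    ori & dist ~ "discordant_both",
    ori ~ "discordant_orientation",
    dist ~ "discordant_distance",
    TRUE ~ "concordant"
  ))
}

#' Cluster orientation-discordant pairs
#'
#' Within each same-strand orientation class (`plus_plus`, `minus_minus`),
#' pairs are single-linkage clustered on the leftmost read coordinate with
#' gap at most `max_gap_bp`. Breakpoint-spanning clipped pairs and low-mapq
#' pairs (mapq < 20, mirroring the mapping ambiguity real LCRs cause) are
#' excluded.
#'
#' @param pairs Classified pair tibble (see [classify_pairs()]).
#' @param max_gap_bp Single-linkage gap; a natural default is the insert
#'   model's `upper_bp`.
#' @return One row per cluster: `orientation_class`, `support`, first-mate
#'   and second-mate coordinate extents (1-based, from the leftmost mate
#'   = "first"), and member pair ids (list-column).
#' @export
cluster_discordant <- function(pairs, max_gap_bp) {
  check_scalar_number(max_gap_bp, "max_gap_bp", lower = 1)
  disc <- dplyr::filter(
    pairs,
    .data$class %in% c("discordant_orientation", "discordant_both"),
    !.data$spanning, .data$mapq >= 20
  )
  if (!nrow(disc)) return(empty_discordant_clusters())
  disc <- disc |>
    mutate(orientation_class = ifelse(.data$strand1 == "+", "plus_plus", "minus_minus")) |>
    arrange(.data$orientation_class, .data$pos1)
  disc |>
    group_by(.data$orientation_class) |>
    mutate(cluster = cumsum(c(TRUE, diff(.data$pos1) > max_gap_bp))) |>
    group_by(.data$orientation_class, .data$cluster) |>
    summarise(
      support = n(),
      first_start = min(.data$pos1), first_end = max(.data$end1),
      second_start = min(.data$pos2), second_end = max(.data$end2),
      members = list(.data$pair_id),
      chrom = .data$chrom[[1]],
      .groups = "drop"
    ) |>
    select(-"cluster")
}

empty_discordant_clusters <- function() {
  tibble(
    orientation_class = character(), support = integer(),
    first_start = integer(), first_end = integer(),
    second_start = integer(), second_end = integer(),
    members = list(), chrom = character()
  )
}

# breakpoint-interval proposals implied by one cluster (0-based half-open)
propose_breakpoints <- function(cl, upper_bp) {
  if (cl$orientation_class == "plus_plus") {
    # ++ pairs end just left of each breakpoint
    list(
      prox = c(cl$first_end - 1, cl$first_end - 1 + upper_bp),
      dist = c(cl$second_end - 1, cl$second_end - 1 + upper_bp)
    )
  } else {
    # -- pairs start just right of each breakpoint
    list(
      prox = c(cl$first_start - 1 - upper_bp, cl$first_start - 1),
      dist = c(cl$second_start - 1 - upper_bp, cl$second_start - 1)
    )
  }
}

#' Call inversions from discordant-pair clusters
#'
#' A `++` cluster proposes a proximal breakpoint interval starting at the
#' maximum first-mate end and a distal interval starting at the maximum
#' second-mate end (each `upper_bp` wide); a `--` cluster proposes intervals
#' ending at the minimum first-/second-mate starts. A call is emitted when a
#' `++` and a `--` cluster propose intersecting proximal AND distal
#' intervals (the intervals are intersected), or -- flagged `one_sided` --
#' when a single cluster reaches `2 * min_support` on its own. Total support
#' must reach `min_support`.
#'
#' @param clusters Cluster tibble from [cluster_discordant()].
#' @param model The `insert_size_model` (supplies `upper_bp`).
#' @param min_support Minimum total supporting pairs (default 3).
#' @return Inversion-call tibble: `chrom`, 0-based half-open
#'   `prox_start`/`prox_end`, `dist_start`/`dist_end`, `support_pp`,
#'   `support_mm`, `evidence = "short_read"`, `one_sided`.
#' @export
call_inversions <- function(clusters, model, min_support = 3) {
  stopifnot(inherits(model, "insert_size_model"))
  check_scalar_number(min_support, "min_support", lower = 1)
  if (!nrow(clusters)) return(empty_inversion_calls())
  upper <- model$upper_bp
  props <- purrr::map(seq_len(nrow(clusters)), function(i) {
    propose_breakpoints(clusters[i, ], upper)
  })
  pp_idx <- which(clusters$orientation_class == "plus_plus")
  mm_idx <- which(clusters$orientation_class == "minus_minus")
  calls <- list()
  used <- rep(FALSE, nrow(clusters))
  for (i in pp_idx) {
    for (j in mm_idx) {
      prox <- interval_intersect(props[[i]]$prox, props[[j]]$prox)
      dist <- interval_intersect(props[[i]]$dist, props[[j]]$dist)
      if (is.null(prox) || is.null(dist)) next
      support <- clusters$support[[i]] + clusters$support[[j]]
      if (support < min_support) next
      used[c(i, j)] <- TRUE
      calls[[length(calls) + 1L]] <- tibble(
        chrom = clusters$chrom[[i]],
        prox_start = floor(prox[[1]]), prox_end = ceiling(prox[[2]]),
        dist_start = floor(dist[[1]]), dist_end = ceiling(dist[[2]]),
        support_pp = clusters$support[[i]], support_mm = clusters$support[[j]],
        evidence = "short_read", one_sided = FALSE
      )
    }
  }
  # one-sided fallback: a lone, strongly supported cluster
  for (i in which(!used)) {
    if (clusters$support[[i]] < 2 * min_support) next
    pr <- props[[i]]
    calls[[length(calls) + 1L]] <- tibble(
      chrom = clusters$chrom[[i]],
      prox_start = floor(pr$prox[[1]]), prox_end = ceiling(pr$prox[[2]]),
      dist_start = floor(pr$dist[[1]]), dist_end = ceiling(pr$dist[[2]]),
      support_pp = if (clusters$orientation_class[[i]] == "plus_plus") clusters$support[[i]] else 0L,
      support_mm = if (clusters$orientation_class[[i]] == "minus_minus") clusters$support[[i]] else 0L,
      evidence = "short_read", one_sided = TRUE
    )
  }
  if (!length(calls)) return(empty_inversion_calls())
  bind_rows(calls) |>
    mutate(
      prox_start = pmax(0, .data$prox_start),
      dist_start = pmax(0, .data$dist_start)
    ) |>
    arrange(.data$prox_start)
}

empty_inversion_calls <- function() {
  tibble(
    chrom = character(), prox_start = double(), prox_end = double(),
    dist_start = double(), dist_end = double(), support_pp = integer(),
    support_mm = integer(), evidence = character(), one_sided = logical()
  )
}

#' Short-read inversion calling, end to end
#'
#' Convenience wrapper: estimate the insert model, classify pairs, cluster
#' discordant pairs (gap = model `upper_bp`), call inversions.
#'
#' @inheritParams estimate_insert_model
#' @inheritParams call_inversions
#' @return An inversion-call tibble.
#' @export
call_inversions_short <- function(pairs, k_spread = 5, min_support = 3) {
  model <- estimate_insert_model(pairs, k_spread = k_spread)
  classified <- classify_pairs(pairs, model)
  clusters <- cluster_discordant(classified, max_gap_bp = model$upper_bp)
  call_inversions(clusters, model, min_support = min_support)
}
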