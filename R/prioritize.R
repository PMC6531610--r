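# Family-based variant prioritization: the fixed filter cascade
# quality -> rarity -> zygosity -> sharing among sequenced affecteds ->
# locus restriction -> segregation with the disease haplotype -> absence
# from controls, with per-stage accounting of survivors.

#' Filter-cascade configuration
#'
#' @param sequenced_affecteds Sample ids of the sequenced affected patients
#'   (non-empty); the sharing stage requires a heterozygous carrier genotype
#'   in every one of them.
#' @param control_samples Sample ids of genotyped controls; the final stage
#'   keeps variants absent (`0/0` or `./.`) from all of them.
#' @param pedigree Pedigree tibble with disease-haplotype carrier labels,
#'   used by the segregation stage; `NULL` skips that stage.
#' @param min_quality Minimum variant QUAL (default 30).
#' @param maf_threshold Rarity threshold; a variant is rare when its MAF is
#'   strictly below this in every configured panel (novel variants, absent
#'   from a panel, count as rare). Default 0.01.
#' @param locus 0-based half-open interval restricting candidate positions,
#'   or `NULL` to skip the locus stage.
#' @param panels Panel names consulted by the rarity stage; `NULL` means
#'   every panel present on a variant.
#' @param missing_affected_fails Treat a `./.` genotype in a sequenced
#'   affected as failing the sharing stage (conservative default `TRUE`).
#' @param missing_control_compatible Treat `./.` in a control as compatible
#'   with absence (default `TRUE`).
#' @return A list with class `filter_config`.
#' @export
filter_config <- function(sequenced_affecteds, control_samples = character(),
                          pedigree = NULL, min_quality = 30,
                          maf_threshold = 0.01, locus = NULL, panels = NULL,
                          missing_affected_fails = TRUE,
                          missing_control_compatible = TRUE) {
  if (!length(sequenced_affecteds)) abort("`sequenced_affecteds` must be non-empty.")
  check_scalar_number(maf_threshold, "maf_threshold")
  if (maf_threshold <= 0 || maf_threshold > 0.5) {
    abort("`maf_threshold` must lie in (0, 0.5].")
  }
  structure(
    list(
      sequenced_affecteds = sequenced_affecteds,
      control_samples = control_samples,
      pedigree = pedigree,
      min_quality = min_quality,
      maf_threshold = maf_threshold,
      locus = locus,
      panels = panels,
      missing_affected_fails = missing_affected_fails,
      missing_control_compatible = missing_control_compatible
    ),
    class = "filter_config"
  )
}

is_carrier_gt <- function(gt) gt %in% c("0/1", "1/0", "1/1")
is_het_gt <- function(gt) gt %in% c("0/1", "1/0")
is_missing_gt <- function(gt) gt == "./."

#' Segregation of a variant with the disease haplotype
#'
#' A variant `segregates` iff every genotyped disease-haplotype carrier in
#' the pedigree carries the variant AND every genotyped non-carrier is
#' homozygous reference; any contradiction yields `violates`; fewer than two
#' informative (non-missing) genotyped pedigree samples yields
#' `uninformative`. Missing (`./.`) genotypes are uninformative for the
#' sample concerned.
#'
#' @param variant A one-row variant tibble (genotype columns named by
#'   sample) or a named character vector of genotypes.
#' @param pedigree Pedigree tibble with `sample_id` and
#'   `carries_disease_haplotype`.
#' @return One of `"segregates"`, `"violates"`, `"uninformative"`.
#' @export
check_segregation <- function(variant, pedigree) {
  if (is.data.frame(variant)) {
    stopifnot(nrow(variant) == 1L)
    gts <- vapply(intersect(pedigree$sample_id, names(variant)),
                  function(s) variant[[s]][[1]], "")
  } else {
    gts <- variant[intersect(pedigree$sample_id, names(variant))]
  }
  if (!length(gts)) return("uninformative")
  informative <- !is_missing_gt(gts)
  if (sum(informative) < 2L) return("uninformative")
  carrier <- pedigree$carries_disease_haplotype[match(names(gts), pedigree$sample_id)]
  gts <- gts[informative]
  carrier <- carrier[informative]
  ok_carriers <- all(is_carrier_gt(gts[carrier]))
  ok_noncarriers <- all(gts[!carrier] == "0/0")
  if (ok_carriers && ok_noncarriers) "segregates" else "violates"
}

#' Run the variant prioritization cascade
#'
#' Applies, in fixed order: quality (QUAL >= `min_quality`), rarity (MAF
#' strictly below `maf_threshold` in every configured panel; absent counts
#' as rare), zygosity (no sequenced affected homozygous for the alternate
#' allele, the expectation under autosomal-dominant inheritance), sharing
#' (heterozygous carrier genotype in all sequenced affecteds), locus
#' restriction, segregation with the disease haplotype (see
#' [check_segregation()]), and control absence. Survivor counts are
#' monotonically non-increasing and each stage's survivors are recorded.
#'
#' @param variants A variant tibble (see [read_variant_table()]).
#' @param config A [filter_config()].
#' @return A `filter_report`: list with `stages` (tibble `stage`, `n_in`,
#'   `n_out`), `survivors` (named list of variant-id vectors per stage) and
#'   `final_ids`.
#' @export
run_filter_cascade <- function(variants, config) {
  stopifnot(inherits(config, "filter_config"))
  known <- variant_samples(variants)
  need <- c(config$sequenced_affecteds, config$control_samples)
  if (nrow(variants) && length(setdiff(need, known))) {
    abort(sprintf("Configured sample(s) missing from genotype columns: %s",
                  paste(setdiff(need, known), collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(variants))
  stages <- list()
  survivors <- list()
  note <- function(stage, new_keep) {
    stages[[length(stages) + 1L]] <<- tibble(
      stage = stage, n_in = sum(keep), n_out = sum(new_keep)
    )
    survivors[[stage]] <<- variants$id[new_keep]
    keep <<- new_keep
  }

  gt_mat <- function(samples) {
    if (!nrow(variants)) return(matrix("", 0, length(samples)))
    do.call(cbind, lapply(samples, function(s) variants[[s]]))
  }
  aff <- gt_mat(config$sequenced_affecteds)

  note("quality", keep & !is.na(variants$qual) & variants$qual >= config$min_quality)

  rare <- vapply(seq_len(nrow(variants)), function(i) {
    pf <- variants$panel_freqs[[i]]
    if (!is.null(config$panels)) pf <- pf[intersect(names(pf), config$panels)]
    all(pf < config$maf_threshold)
  }, logical(1))
  note("rarity", keep & rare)

  no_hom <- if (nrow(variants)) !apply(aff == "1/1", 1L, any) else logical(0)
  note("zygosity", keep & no_hom)

  shared <- if (nrow(variants)) {
    apply(aff, 1L, function(g) {
      if (config$missing_affected_fails && any(is_missing_gt(g))) return(FALSE)
      g2 <- g[!is_missing_gt(g)]
      length(g2) > 0 && all(is_het_gt(g2))
    })
  } else logical(0)
  note("sharing", keep & shared)

  if (!is.null(config$locus)) {
    in_locus <- (variants$pos - 1L) >= config$locus[[1]] &
      (variants$pos - 1L) < config$locus[[2]]
    note("locus", keep & in_locus)
  }

  if (!is.null(config$pedigree)) {
    seg <- vapply(seq_len(nrow(variants)), function(i) {
      if (!keep[[i]]) return("skipped")
      check_segregation(variants[i, ], config$pedigree)
    }, "")
    note("segregation", keep & seg == "segregates")
  }

  if (length(config$control_samples)) {
    ctrl <- gt_mat(config$control_samples)
    absent_ok <- c("0/0", if (config$missing_control_compatible) "./.")
    absent <- if (nrow(variants)) apply(ctrl, 1L, function(g) all(g %in% absent_ok)) else logical(0)
    note("control_absence", keep & absent)
  }

  structure(
    list(
      stages = bind_rows(stages),
      survivors = survivors,
      final_ids = variants$id[keep]
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  cat(sprintf("final survivors: %d\n", length(x$final_ids)))
  invisible(x)
}

#' @rdname run_filter_cascade
#' @param x A `filter_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.filter_report <- function(x, ...) x$stages

#' @rdname run_filter_cascade
#' @exportS3Method generics::glance
glance.filter_report <- function(x, ...) {
  tibble(
    n_stages = nrow(x$stages),
    n_input = x$stages$n_in[[1]],
    n_final = length(x$final_ids)
  )
}
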