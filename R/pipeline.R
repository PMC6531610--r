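# End-to-end orchestration: one scenario configuration drives simulation,
# short- and long-read inversion calling, evidence reconciliation, inverted
# LCR discovery, family variant filtering and the burden association test,
# then scores each call set against the planted truth.

#' Scenario configuration for the end-to-end demo
#'
#' Defaults describe a desk-scale rendition of the discovery setting: a
#' 1.2 Mb genome carrying a pair of inverted LCRs at 98% identity, a 400 kb
#' NAHR-mediated paracentric inversion with breakpoints inside the LCR
#' copies, a 30x FR paired-end library with 350 +/- 35 bp inserts, 6x
#' long-read coverage, the three-generation dominant pedigree with the
#' 34-shared / 4-unique linked-variant structure, and the rare-variant
#' power-scenario cohort parameters (3545 bp target, 40% causal, 10%
#' protective, maximal OR 5). Per-stage seeds are derived from the master
#' seed by a fixed hash so stages are individually reproducible.
#'
#' @param genome_bp,gc_fraction Genome size and base composition.
#' @param lcr_len_bp,lcr_identity_pct LCR copy length and identity.
#' @param inversion_start,inversion_end Inversion bounds; defaults place the
#'   breakpoints inside the two LCR copies.
#' @param short_coverage_x,long_coverage_x Sequencing depths.
#' @param insert_mean_bp,insert_sd_bp,read_len_bp Paired-end library shape.
#' @param n_linked_unique,n_linked_shared,n_offlocus Family variant classes.
#' @param assoc_n_cases,assoc_n_controls,assoc_region_bp,assoc_causal_pct,assoc_protective_pct,assoc_max_or,assoc_n_perm
#'   Burden-test scenario.
#' @param seed Master seed (mandatory).
#' @return A list with class `scenario_config`.
#' @export
scenario_config <- function(genome_bp = 1.2e6, gc_fraction = 0.41,
                            lcr_len_bp = 10000, lcr_identity_pct = 98,
                            inversion_start = NULL, inversion_end = NULL,
                            short_coverage_x = 30, long_coverage_x = 6,
                            insert_mean_bp = 350, insert_sd_bp = 35,
                            read_len_bp = 100,
                            n_linked_unique = 4, n_linked_shared = 34,
                            n_offlocus = 100,
                            assoc_n_cases = 558, assoc_n_controls = 755,
                            assoc_region_bp = 3545, assoc_causal_pct = 40,
                            assoc_protective_pct = 10, assoc_max_or = 5,
                            assoc_n_perm = 2000,
                            seed) {
  check_scalar_number(seed, "seed")
  lcr_a_anchor <- round(genome_bp / 4)
  separation <- round(genome_bp / 3)
  if (is.null(inversion_start)) inversion_start <- lcr_a_anchor + round(lcr_len_bp / 2)
  if (is.null(inversion_end)) {
    inversion_end <- lcr_a_anchor + lcr_len_bp + separation + round(lcr_len_bp / 2)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "scenario_config")
}

#' Run the discovery pipeline end to end on a simulated scenario
#'
#' Simulates the genome and reads, calls inversions from both technologies,
#' reconciles the evidence, detects inverted LCR pairs and flags the
#' NAHR-susceptible configuration, runs the family filter cascade, runs the
#' burden association test, and scores every planted feature against the
#' calls. With the inversion disabled (`inversion = FALSE`) the callers run
#' on an identity donor and the variant stages still execute.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional directory; when given, reference/donor FASTA,
#'   SAM alignments, calls TSV, truth BED, variant VCF and the filter report
#'   TSV are written there.
#' @param inversion Set `FALSE` to run the inversion-free control scenario.
#' @return A list: `calls` (reconciled inversion calls), `short_calls`,
#'   `long_calls`, `lcr_hits`, `nahr_flagged`, `filter_report`, `burden`,
#'   `truth`, `truth_comparison` (per planted feature: recovered flag and
#'   breakpoint errors).
#' @export
run_end_to_end <- function(config, out_dir = NULL, inversion = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- lapply(
    setNames(nm = c("genome", "lcr", "short", "long", "family", "assoc")),
    function(s) derive_seed(config$seed, s)
  )
  reference <- generate_genome(config$genome_bp, config$gc_fraction,
                               seed = seeds$genome)
  lcr_a_anchor <- round(config$genome_bp / 4)
  separation <- round(config$genome_bp / 3)
  reference <- plant_inverted_lcr(
    reference, copy_len_bp = config$lcr_len_bp, separation_bp = separation,
    identity_pct = config$lcr_identity_pct, anchor_bp = lcr_a_anchor,
    seed = seeds$lcr
  )
  donor <- if (inversion) {
    apply_inversion(reference, config$inversion_start, config$inversion_end,
                    mechanism = "nahr")
  } else {
    reference
  }

  profile <- insert_profile(config$insert_mean_bp, config$insert_sd_bp,
                            config$read_len_bp)
  pairs <- simulate_paired_end_alignments(reference, donor,
                                          coverage_x = config$short_coverage_x,
                                          profile = profile, seed = seeds$short)
  short_calls <- call_inversions_short(pairs)

  n_long <- max(1L, round(config$long_coverage_x * config$genome_bp / 20000))
  long_segs <- simulate_long_read_alignments(reference, donor, n_reads = n_long,
                                             seed = seeds$long)
  long_calls <- consolidate_long_read_calls(detect_strand_flips(long_segs))
  calls <- reconcile_evidence(short_calls, long_calls)

  lcr_hits <- find_inverted_repeats(donor$sequence)
  nahr_flagged <- flag_nahr_susceptible(lcr_hits)

  locus <- c(config$inversion_start, config$inversion_end)
  fam <- simulate_family_variants(
    locus = locus, n_linked_unique = config$n_linked_unique,
    n_linked_shared_polymorphic = config$n_linked_shared,
    n_offlocus = config$n_offlocus, region_bp = config$genome_bp,
    chrom = reference$name, seed = seeds$family
  )
  cfg_filter <- filter_config(
    sequenced_affecteds = fam$pedigree$sample_id[fam$pedigree$sequenced],
    control_samples = fam$control_samples,
    pedigree = fam$pedigree,
    locus = locus
  )
  report <- run_filter_cascade(fam$variants, cfg_filter)

  cc <- simulate_case_control_genotypes(
    n_cases = config$assoc_n_cases, n_controls = config$assoc_n_controls,
    region_bp = config$assoc_region_bp, causal_pct = config$assoc_causal_pct,
    protective_pct = config$assoc_protective_pct, max_or = config$assoc_max_or,
    seed = seeds$assoc
  )
  burden <- permutation_burden(cc$genotypes, cc$phenotype,
                               n_perm = config$assoc_n_perm, seed = seeds$assoc)

  truth <- donor$inversions
  truth_comparison <- score_calls_against_truth(calls, truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(reference, file.path(out_dir, "reference.fasta"))
    write_fasta(donor, file.path(out_dir, "donor.fasta"))
    ref_len <- setNames(genome_length(reference), reference$name)
    write_sam_pairs(pairs, file.path(out_dir, "short_reads.sam"), ref_len)
    write_sam_long_reads(long_segs, file.path(out_dir, "long_reads.sam"), ref_len)
    readr::write_tsv(calls, file.path(out_dir, "inversion_calls.tsv"))
    readr::write_tsv(tidy(report), file.path(out_dir, "filter_report.tsv"))
    readr::write_tsv(truth_comparison, file.path(out_dir, "truth_comparison.tsv"))
    write_variant_table(fam$variants, file.path(out_dir, "family_variants.vcf"))
    truth_bed <- bind_rows(
      if (nrow(truth)) tibble(chrom = reference$name, start = truth$start,
                              end = truth$end, name = "inversion"),
      tibble(chrom = reference$name,
             start = c(reference$lcr_pairs$copy_a_start, reference$lcr_pairs$copy_b_start),
             end = c(reference$lcr_pairs$copy_a_end, reference$lcr_pairs$copy_b_end),
             name = rep(c("lcrA", "lcrB"), each = nrow(reference$lcr_pairs)))
    )
    write_bed(truth_bed, file.path(out_dir, "truth.bed"))
  }

  list(
    calls = calls, short_calls = short_calls, long_calls = long_calls,
    lcr_hits = lcr_hits, nahr_flagged = nahr_flagged,
    filter_report = report, burden = burden,
    truth = truth, truth_comparison = truth_comparison,
    reference = reference, donor = donor
  )
}

#' Score inversion calls against planted truth
#'
#' For each planted inversion, reports whether any call's proximal and
#' distal intervals contain the true breakpoints, and the distance from the
#' true breakpoints to the nearest interval midpoints.
#'
#' @param calls Inversion-call tibble.
#' @param truth Inversion truth tibble (`start`, `end`).
#' @return A tibble: one row per planted inversion with `recovered`,
#'   `evidence`, `prox_error_bp`, `dist_error_bp`.
#' @export
score_calls_against_truth <- function(calls, truth) {
  if (!nrow(truth)) {
    return(tibble(start = integer(), end = integer(), recovered = logical(),
                  evidence = character(), prox_error_bp = double(),
                  dist_error_bp = double()))
  }
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    s <- truth$start[[i]]; e <- truth$end[[i]]
    hit <- calls[calls$prox_start <= s & s <= calls$prox_end &
                   calls$dist_start <= e & e <= calls$dist_end, , drop = FALSE]
    if (nrow(hit)) {
      hit <- hit[1, ]
      tibble(
        start = s, end = e, recovered = TRUE, evidence = hit$evidence,
        prox_error_bp = abs((hit$prox_start + hit$prox_end) / 2 - s),
        dist_error_bp = abs((hit$dist_start + hit$dist_end) / 2 - e)
      )
    } else {
      tibble(start = s, end = e, recovered = FALSE, evidence = NA_character_,
             prox_error_bp = NA_real_, dist_error_bp = NA_real_)
    }
  })
}
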