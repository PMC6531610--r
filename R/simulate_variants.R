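# Family and cohort genotype simulation. The default pedigree mirrors the
# shape of a three-generation autosomal-dominant dementia family with four
# sequenced affected members in three generation-III sibships; variants
# either ride the disease haplotype (family-unique or shared rare
# polymorphisms) or segregate independently of affection (off-locus), with
# Mendelian transmission throughout.

#' Default three-generation autosomal-dominant pedigree
#'
#' Fifteen samples over three generations: an affected founder transmits the
#' disease haplotype to three affected generation-II children, whose
#' sibships contain four affected haplotype carriers in generation III that
#' are marked `sequenced` (the whole-genome-sequenced patients). All members
#' are genotyped for segregation analysis.
#'
#' @return A pedigree tibble: `sample_id`, `father`, `mother` (NA for
#'   founders and married-ins), `generation`, `affection`
#'   (`affected`/`unaffected`), `carries_disease_haplotype`, `sequenced`,
#'   `aao_years`, `aai_years`.
#' @export
default_pedigree <- function() {
  tibble::tribble(
    ~sample_id, ~father, ~mother, ~generation, ~affection, ~carries_disease_haplotype, ~sequenced,
    "I-1",   NA,     NA,     1L, "affected",   TRUE,  FALSE,
    "I-2",   NA,     NA,     1L, "unaffected", FALSE, FALSE,
    "II-1",  "I-1",  "I-2",  2L, "affected",   TRUE,  FALSE,
    "II-2",  NA,     NA,     2L, "unaffected", FALSE, FALSE,
    "II-3",  "I-1",  "I-2",  2L, "affected",   TRUE,  FALSE,
    "II-4",  NA,     NA,     2L, "unaffected", FALSE, FALSE,
    "II-5",  "I-1",  "I-2",  2L, "affected",   TRUE,  FALSE,
    "II-6",  NA,     NA,     2L, "unaffected", FALSE, FALSE,
    "III-1", "II-1", "II-2", 3L, "affected",   TRUE,  TRUE,
    "III-2", "II-1", "II-2", 3L, "unaffected", FALSE, FALSE,
    "III-3", "II-3", "II-4", 3L, "affected",   TRUE,  TRUE,
    "III-4", "II-3", "II-4", 3L, "unaffected", FALSE, FALSE,
    "III-5", "II-5", "II-6", 3L, "affected",   TRUE,  TRUE,
    "III-6", "II-5", "II-6", 3L, "affected",   TRUE,  TRUE,
    "III-7", "II-5", "II-6", 3L, "unaffected", FALSE, FALSE
  ) |>
    mutate(
      aao_years = ifelse(.data$affection == "affected", 67, NA_real_),
      aai_years = ifelse(.data$affection == "affected", 70, 72)
    )
}

validate_pedigree <- function(pedigree) {
  if (!nrow(pedigree)) abort("Pedigree must not be empty.")
  req <- c("sample_id", "father", "mother", "affection", "carries_disease_haplotype")
  missing <- setdiff(req, names(pedigree))
  if (length(missing)) {
    abort(paste("Pedigree lacks columns:", paste(missing, collapse = ", ")))
  }
  # a child carries the disease haplotype only if a parent in the pedigree does
  for (i in seq_len(nrow(pedigree))) {
    p <- pedigree[i, ]
    if (is.na(p$father) && is.na(p$mother)) next
    parents <- pedigree[pedigree$sample_id %in% c(p$father, p$mother), ]
    if (p$carries_disease_haplotype && nrow(parents) == 2L &&
        !any(parents$carries_disease_haplotype)) {
      abort(sprintf("Sample %s carries the disease haplotype but neither parent does.",
                    p$sample_id))
    }
  }
  invisible(pedigree)
}

# Mendelian gene dropping of a biallelic variant with founder allele
# frequency q; returns alt-allele dosage named by sample, in pedigree order
# (parents must precede children, as in default_pedigree()).
gene_drop <- function(pedigree, q) {
  alleles <- list()
  for (i in seq_len(nrow(pedigree))) {
    p <- pedigree[i, ]
    if (is.na(p$father) || !p$father %in% pedigree$sample_id) {
      alleles[[p$sample_id]] <- rbinom(2L, 1L, q)
    } else {
      alleles[[p$sample_id]] <- c(
        sample(alleles[[p$father]], 1L),
        sample(alleles[[p$mother]], 1L)
      )
    }
  }
  vapply(alleles, sum, integer(1))
}

dosage_to_gt <- function(d) c("0/0", "0/1", "1/1")[d + 1L]

random_alleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

#' Simulate a multi-sample family variant table with ground truth
#'
#' Emits a minimal-VCF-compatible variant tibble over the pedigree members
#' plus `n_controls` unrelated control samples, in three ground-truth
#' classes: `linked_unique` variants ride the disease haplotype and are
#' absent from every panel and every control; `linked_shared` variants ride
#' the haplotype but are rare polymorphisms (panel MAF < 1%, and at least
#' one control carrier is guaranteed so the control-absence filter stage is
#' exact by construction); `offlocus` variants are placed outside the locus
#' and transmitted through the pedigree by Mendelian gene dropping,
#' independently of affection. The default class sizes (4 unique, 34 shared)
#' mirror the 38 co-segregating / 4 family-unique structure of the study
#' family.
#'
#' @param pedigree A pedigree tibble (see [default_pedigree()]).
#' @param locus Numeric length-2: 0-based half-open linked-locus bounds.
#' @param n_linked_unique,n_linked_shared_polymorphic,n_offlocus Class sizes.
#' @param n_controls Number of unrelated genotyped control samples.
#' @param region_bp Total coordinate span in which variants are placed
#'   (off-locus variants fall outside `locus` but inside `[0, region_bp)`).
#' @param chrom Chromosome label.
#' @param panels Panel names for the `panel_freqs` entries.
#' @param seed Integer seed.
#' @return A list: `variants` (variant tibble as in [read_variant_table()]),
#'   `truth` (tibble `id`, `class`), `pedigree`, `control_samples`.
#' @export
simulate_family_variants <- function(pedigree = default_pedigree(),
                                     locus = c(3e5, 7e5),
                                     n_linked_unique = 4,
                                     n_linked_shared_polymorphic = 34,
                                     n_offlocus = 100,
                                     n_controls = 40,
                                     region_bp = 1e6,
                                     chrom = "chrS",
                                     panels = c("1kg", "inhouse"),
                                     seed = 1) {
  validate_pedigree(pedigree)
  stopifnot(n_linked_unique >= 0, n_linked_shared_polymorphic >= 0, n_offlocus >= 0)
  if (!any(pedigree$carries_disease_haplotype & is.na(pedigree$father))) {
    abort("Pedigree needs at least one founder carrying the disease haplotype.")
  }
  samples <- pedigree$sample_id
  controls <- sprintf("CTRL%02d", seq_len(n_controls))
  carriers <- pedigree$carries_disease_haplotype

  with_seed_(seed, {
    n_total <- n_linked_unique + n_linked_shared_polymorphic + n_offlocus
    cls <- rep(c("linked_unique", "linked_shared", "offlocus"),
               c(n_linked_unique, n_linked_shared_polymorphic, n_offlocus))
    pos <- integer(n_total)
    in_locus <- cls != "offlocus"
    pos[in_locus] <- sample(seq(locus[[1]] + 1, locus[[2]]), sum(in_locus))
    off_space <- setdiff(seq_len(region_bp), seq(locus[[1]] + 1, locus[[2]]))
    pos[!in_locus] <- sample(off_space, sum(!in_locus))
    al <- random_alleles(n_total)

    gt <- matrix("0/0", nrow = n_total, ncol = length(samples) + n_controls,
                 dimnames = list(NULL, c(samples, controls)))
    pf <- vector("list", n_total)
    qual <- stats::runif(n_total, 50, 99)
    for (v in seq_len(n_total)) {
      if (cls[[v]] == "offlocus") {
        q <- 10^stats::runif(1, -3, -0.3)
        gt[v, samples] <- dosage_to_gt(pmin(2L, gene_drop(pedigree, q)))
        gt[v, controls] <- dosage_to_gt(rbinom(n_controls, 2L, q))
        pf[[v]] <- setNames(rep(min(q, 1 - q), length(panels)), panels)
        qual[[v]] <- stats::runif(1, 20, 99)
      } else {
        gt[v, samples] <- ifelse(carriers, "0/1", "0/0")
        if (cls[[v]] == "linked_unique") {
          pf[[v]] <- setNames(rep(0, length(panels)), panels)
        } else {
          maf <- stats::runif(1, 5e-4, 9e-3)
          pf[[v]] <- setNames(rep(maf, length(panels)), panels)
          ctrl_car <- rbinom(n_controls, 1L, 2 * maf)
          if (!any(ctrl_car)) ctrl_car[sample.int(n_controls, 1L)] <- 1L
          gt[v, controls] <- dosage_to_gt(ctrl_car)
        }
      }
    }
    variants <- tibble(
      chrom = chrom, pos = as.integer(pos),
      id = sprintf("var%04d", seq_len(n_total)),
      ref = al$ref, alt = al$alt,
      qual = round(qual, 1), filter = "PASS",
      panel_freqs = pf, annotation = NA_character_
    )
    for (s in colnames(gt)) variants[[s]] <- gt[, s]
    ord <- order(variants$pos)
    list(
      variants = variants[ord, , drop = FALSE],
      truth = tibble(id = variants$id, class = cls)[ord, , drop = FALSE],
      pedigree = pedigree,
      control_samples = controls
    )
  })
}

#' Simulate rare-variant case/control genotypes under a logistic model
#'
#' Places rare variants (MAF < 1%) in a region; `causal_pct` of them
#' increase disease odds and `protective_pct` decrease it, each with
#' per-variant log-odds-ratio proportional to `|log10 MAF|` and scaled so
#' the rarest effect variant attains `max_or`; the rest are neutral.
#' Phenotypes are drawn from the induced logistic model and individuals are
#' sampled retrospectively until the requested case and control counts are
#' reached. The defaults reproduce a rare-variant power-analysis scenario
#' (3545 bp target, 40% causal, 10% protective, maximal odds ratio 5).
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param region_bp Target region length (default 3545).
#' @param causal_pct,protective_pct Percentages of variants with risk /
#'   protective effects; their sum must not exceed 100.
#' @param max_or Odds ratio attained by the rarest effect variant (> 1).
#' @param n_variants Number of rare variants; defaults to one per 100 bp.
#' @param maf_range MAF sampling range (log-uniform), upper bound below 1%.
#' @param prevalence Baseline disease prevalence of the logistic model.
#' @param seed Integer seed.
#' @return A list: `genotypes` (cases then controls; samples x variants
#'   dosage matrix), `phenotype` (1 = case), `variants` tibble
#'   (`id`, `pos`, `maf`, `effect`, `beta`).
#' @export
simulate_case_control_genotypes <- function(n_cases, n_controls,
                                            region_bp = 3545,
                                            causal_pct = 40,
                                            protective_pct = 10,
                                            max_or = 5,
                                            n_variants = NULL,
                                            maf_range = c(1e-4, 0.0099),
                                            prevalence = 0.1,
                                            seed = 1) {
  check_scalar_number(causal_pct, "causal_pct", lower = 0, upper = 100)
  check_scalar_number(protective_pct, "protective_pct", lower = 0, upper = 100)
  if (causal_pct + protective_pct > 100) {
    abort("`causal_pct` + `protective_pct` must not exceed 100.")
  }
  if (max_or <= 1) abort("`max_or` must exceed 1.")
  if (is.null(n_variants)) n_variants <- max(3L, round(region_bp / 100))

  with_seed_(seed, {
    m <- n_variants
    maf <- 10^stats::runif(m, log10(maf_range[[1]]), log10(maf_range[[2]]))
    pos <- sort(sample.int(region_bp, m))
    n_causal <- round(causal_pct / 100 * m)
    n_prot <- round(protective_pct / 100 * m)
    effect <- rep("neutral", m)
    idx <- sample.int(m, n_causal + n_prot)
    effect[idx[seq_len(n_causal)]] <- "causal"
    if (n_prot > 0) effect[idx[n_causal + seq_len(n_prot)]] <- "protective"
    beta <- rep(0, m)
    eff <- effect != "neutral"
    if (any(eff)) {
      scale <- log(max_or) / max(abs(log10(maf[eff])))
      beta[eff] <- scale * abs(log10(maf[eff])) *
        ifelse(effect[eff] == "causal", 1, -1)
    }
    b0 <- stats::qlogis(prevalence)

    need_case <- n_cases; need_ctrl <- n_controls
    case_rows <- list(); ctrl_rows <- list()
    batch <- max(1000L, min(200000L, ceiling((n_cases / prevalence) / 4)))
    while (need_case > 0 || need_ctrl > 0) {
      g <- matrix(rbinom(batch * m, 2L, rep(maf, each = batch)), nrow = batch)
      p <- stats::plogis(b0 + as.vector(g %*% beta))
      y <- rbinom(batch, 1L, p)
      if (need_case > 0) {
        take <- which(y == 1L)[seq_len(min(need_case, sum(y == 1L)))]
        if (length(take)) {
          case_rows[[length(case_rows) + 1L]] <- g[take, , drop = FALSE]
          need_case <- need_case - length(take)
        }
      }
      if (need_ctrl > 0) {
        take <- which(y == 0L)[seq_len(min(need_ctrl, sum(y == 0L)))]
        if (length(take)) {
          ctrl_rows[[length(ctrl_rows) + 1L]] <- g[take, , drop = FALSE]
          need_ctrl <- need_ctrl - length(take)
        }
      }
    }
    genotypes <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
    rownames(genotypes) <- c(sprintf("case%05d", seq_len(n_cases)),
                             sprintf("ctrl%05d", seq_len(n_controls)))
    colnames(genotypes) <- sprintf("v%03d", seq_len(m))
    list(
      genotypes = genotypes,
      phenotype = rep(c(1L, 0L), c(n_cases, n_controls)),
      variants = tibble(
        id = colnames(genotypes), pos = pos, maf = maf,
        effect = effect, beta = beta
      )
    )
  })
}
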