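# Association and cohort statistics: allelic Fisher exact test with sample
# odds ratio and Woolf confidence interval, a permutation omnibus
# rare-variant burden test over the kernel/burden mixing grid, exact
# Mann-Whitney U, Pearson chi-square for familial load, HGVS protein
# consequence classification, and multi-reference-gene geometric-mean
# expression normalization.

#' Classify a protein-level variant annotation
#'
#' Parses HGVS-like protein tokens. Nonsense (`p.Q230*`) and frameshift
#' (`p.E79Gfs*9`) notations are premature-termination-codon (`PTC`)
#' variants; single-residue substitutions with different residues are
#' `missense` (identical residues `synonymous`); in-frame duplications or
#' deletions (`p.G61_G62dup`) are `inframe_indel`; anything unparseable is
#' `other` with a warning.
#'
#' @param hgvs_protein Character vector of tokens beginning `p.`.
#' @return Character vector over
#'   `{PTC, missense, inframe_indel, synonymous, other}`.
#' @export
classify_consequence <- function(hgvs_protein) {
  vapply(hgvs_protein, function(tok) {
    if (is.na(tok) || !startsWith(tok, "p.")) {
      warn(sprintf("Unparseable protein annotation: %s", tok))
      return("other")
    }
    body <- sub("^p\\.", "", tok)
    if (grepl("^[A-Z][a-z]{0,2}\\d+[A-Z][a-z]{0,2}fs\\*?\\d*$", body)) return("PTC")
    if (grepl("^[A-Z][a-z]{0,2}\\d+(\\*|Ter)$", body)) return("PTC")
    if (grepl("^[A-Z]\\d+_[A-Z]\\d+(dup|del|ins[A-Z]*)$", body) ||
        grepl("^[A-Z]\\d+(dup|del)$", body)) {
      return("inframe_indel")
    }
    m <- regmatches(body, regexec("^([A-Z])(\\d+)([A-Z])$", body))[[1]]
    if (length(m) == 4L) {
      return(if (m[[2]] == m[[4]]) "synonymous" else "missense")
    }
    if (grepl("=$", body)) return("synonymous")
    warn(sprintf("Unparseable protein annotation: %s", tok))
    "other"
  }, "", USE.NAMES = FALSE)
}

#' Allelic Fisher exact test with odds ratio and Woolf interval
#'
#' Builds the 2x2 allele-count table (alt/ref alleles in cases vs controls).
#' The two-sided p-value sums hypergeometric probabilities of all tables,
#' with the observed margins, whose probability does not exceed the observed
#' table's (probability-mass method). The odds ratio is the sample
#' cross-product ratio with the Haldane-Anscombe +0.5 correction applied to
#' every cell when any cell is zero; the 95% CI is the Woolf log-OR interval
#' `exp(log OR +/- 1.96 * SE)` on the (possibly corrected) table.
#'
#' @param case_alt,case_total_alleles Alt-allele count and total allele
#'   count (2n for a diploid cohort) in cases.
#' @param control_alt,control_total_alleles Same for controls.
#' @return A list with class `contingency_result`: `table`, `odds_ratio`,
#'   `ci95`, `p_two_sided`.
#' @export
fisher_allelic <- function(case_alt, case_total_alleles,
                           control_alt, control_total_alleles) {
  counts <- c(case_alt, case_total_alleles, control_alt, control_total_alleles)
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (case_alt > case_total_alleles || control_alt > control_total_alleles) {
    abort("Alt-allele counts cannot exceed total allele counts.")
  }
  a <- case_alt; b <- case_total_alleles - case_alt
  c_ <- control_alt; d <- control_total_alleles - control_alt
  m <- a + c_             # total alt alleles
  n <- b + d              # total ref alleles
  k <- a + b              # case alleles
  # two-sided p: mass method over the hypergeometric family with the
  # observed margins
  x_all <- max(0, k - n):min(k, m)
  probs <- dhyper(x_all, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  structure(
    list(
      table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                     dimnames = list(c("case", "control"), c("alt", "ref"))),
      odds_ratio = or, ci95 = ci, p_two_sided = p
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> OR = %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
              x$odds_ratio, x$ci95[[1]], x$ci95[[2]], x$p_two_sided))
  invisible(x)
}

#' @rdname fisher_allelic
#' @param x A `contingency_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.contingency_result <- function(x, ...) {
  tibble(
    estimate = x$odds_ratio, conf.low = x$ci95[[1]], conf.high = x$ci95[[2]],
    p.value = x$p_two_sided
  )
}

#' Permutation omnibus rare-variant burden test
#'
#' For each mixing weight `rho` in `{0, 0.25, 0.5, 0.75, 1}` the statistic
#' `Q_rho = (1 - rho) * sum_j (w_j s_j)^2 + rho * (sum_j w_j s_j)^2`
#' combines the variance-component (kernel, `rho = 0`) and burden
#' (`rho = 1`) scores, where `s_j = sum_i G_ij (y_i - mean(y))` and
#' `w_j = dbeta(MAF_j, 1, 25)`. Each `Q_rho` is standardized by its
#' phenotype-permutation moments; the omnibus statistic is the maximum over
#' the grid, and its p-value is `(1 + #{permuted >= observed}) /
#' (n_perm + 1)` under phenotype-label permutation. This is the permutation
#' analogue of the optimal kernel/burden association test, exact by
#' construction rather than via small-sample moment adjustment.
#'
#' @param genotypes Samples x variants dosage matrix of rare variants.
#' @param phenotype 0/1 vector (constant phenotype is an error).
#' @param n_perm Number of permutations (>= 1000).
#' @param weights Per-variant weights, or `NULL` for Beta(1, 25) weights on
#'   the sample MAF.
#' @param rho_grid Mixing grid.
#' @param seed Integer seed for the permutations.
#' @return A list with class `burden_result`: `statistic` (standardized
#'   omnibus maximum), `p_value`, `rho_best`, `n_perm`.
#' @export
permutation_burden <- function(genotypes, phenotype, n_perm = 2000,
                               weights = NULL,
                               rho_grid = c(0, 0.25, 0.5, 0.75, 1),
                               seed = 1) {
  genotypes <- as.matrix(genotypes)
  if (length(unique(phenotype)) < 2L) {
    abort("Phenotype must not be constant.")
  }
  if (n_perm < 1000) abort("`n_perm` must be at least 1000.")
  n <- nrow(genotypes)
  stopifnot(length(phenotype) == n)
  if (is.null(weights)) {
    maf <- colMeans(genotypes) / 2
    maf <- pmin(pmax(maf, 1e-6), 0.5)
    weights <- stats::dbeta(maf, 1, 25)
  }
  gw <- sweep(genotypes, 2L, weights, `*`)
  with_seed_(seed, {
    yc <- phenotype - mean(phenotype)
    perms <- replicate(n_perm, sample(yc))
    s_obs <- crossprod(gw, yc)                  # m x 1
    s_perm <- crossprod(gw, perms)              # m x n_perm
    q_for <- function(s) {
      skat <- colSums(s^2)
      burden <- colSums(s)^2
      vapply(rho_grid, function(r) (1 - r) * skat + r * burden,
             numeric(ncol(s)))
    }
    q_perm <- q_for(s_perm)                     # n_perm x n_rho
    q_obs <- q_for(matrix(s_obs, ncol = 1))     # 1 x n_rho
    mu <- colMeans(q_perm)
    sg <- apply(q_perm, 2L, stats::sd)
    sg[sg == 0] <- 1
    z_perm <- sweep(sweep(q_perm, 2L, mu), 2L, sg, `/`)
    z_obs <- (q_obs - mu) / sg
    t_perm <- apply(z_perm, 1L, max)
    t_obs <- max(z_obs)
    p <- (1 + sum(t_perm >= t_obs)) / (n_perm + 1)
    structure(
      list(
        statistic = t_obs,
        p_value = p,
        rho_best = rho_grid[[which.max(z_obs)]],
        n_perm = n_perm,
        n_variants = ncol(genotypes),
        n_samples = n
      ),
      class = "burden_result"
    )
  })
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(
    "<burden_result> omnibus statistic %.3f (rho = %.2f), p = %.4g (%d permutations, %d variants, %d samples)\n",
    x$statistic, x$rho_best, x$p_value, x$n_perm, x$n_variants, x$n_samples
  ))
  invisible(x)
}

#' @rdname permutation_burden
#' @param x A `burden_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.burden_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, rho = x$rho_best)
}

#' @rdname permutation_burden
#' @exportS3Method generics::glance
glance.burden_result <- function(x, ...) {
  tibble(n_perm = x$n_perm, n_variants = x$n_variants, n_samples = x$n_samples)
}

#' Exact two-sided Mann-Whitney U test
#'
#' When `min(n, m) <= 10` and enumeration is feasible, the two-sided p-value
#' is computed by full enumeration of all `choose(n + m, n)` group
#' labelings (ties handled exactly by the enumeration); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. `U` is reported for `group_a`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list: `U`, `p_two_sided`, `method`.
#' @export
mann_whitney_exact <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) abort("Both groups must be non-empty.")
  n <- length(group_a); m <- length(group_b)
  pooled <- c(group_a, group_b)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  if (min(n, m) <= 10 && choose(n + m, n) <= 2e5) {
    combos <- utils::combn(n + m, n)
    u_all <- colSums(matrix(ranks[combos], nrow = n)) - n * (n + 1) / 2
    # two-sided: deviation from the null mean at least as large as observed
    dev <- abs(u_all - n * m / 2)
    p <- mean(dev >= abs(u_obs - n * m / 2) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n * m / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1))
    sigma <- sqrt(n * m / 12 * ((n + m + 1) - tie_term))
    z <- (abs(u_obs - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(-max(0, z)))
    method <- "normal approximation"
  }
  list(U = u_obs, p_two_sided = p, method = method)
}

#' Pearson chi-square test on an RxC count table
#'
#' No continuity correction; `df = (R - 1)(C - 1)`. A zero expected count is
#' an error (use [fisher_allelic()] for sparse 2x2 allele tables).
#'
#' @param table Matrix of non-negative counts.
#' @return A list: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) abort("Counts must be non-negative.")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    abort("Zero expected count; use a Fisher exact test instead.")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    expected = res$expected
  )
}

#' Geometric-mean reference-gene expression normalization
#'
#' Divides each sample's target-gene expression by the geometric mean of
#' that sample's reference-gene values (multi-reference-gene normalization
#' as used for qRT-PCR), leaving values scale-invariant per sample.
#'
#' @param expression A samples x genes data frame or tibble of positive
#'   expression values, with a `sample` id column allowed.
#' @param reference_genes Column names of the reference genes; all must be
#'   present with positive values.
#' @return The tibble with target-gene columns normalized and reference
#'   columns dropped; a `norm_factor` column records each sample's
#'   geometric mean.
#' @export
geometric_normalize <- function(expression, reference_genes) {
  expression <- as_tibble(expression)
  missing <- setdiff(reference_genes, names(expression))
  if (length(missing)) {
    abort(paste("Reference gene(s) absent:", paste(missing, collapse = ", ")))
  }
  ref <- as.matrix(expression[, reference_genes])
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    abort("Reference-gene values must all be positive.")
  }
  gm <- exp(rowMeans(log(ref)))
  targets <- setdiff(names(expression)[vapply(expression, is.numeric, logical(1))],
                     reference_genes)
  out <- expression
  for (g in targets) out[[g]] <- out[[g]] / gm
  out <- out[, setdiff(names(out), reference_genes)]
  out$norm_factor <- gm
  out
}
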