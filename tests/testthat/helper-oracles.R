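# Independent oracles and small fixture builders used across the suite.

# Reflection oracle: maps a donor base position p through an inversion
# [s, e) by direct arithmetic (scalar, no package code).
oracle_reflect_pos <- function(p, s, e) {
  if (p >= s && p < e) s + e - 1 - p else p
}

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins, computing each table's probability from products of choose().
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  x_all <- max(0, k - n):min(k, m)
  tab_prob <- function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }
  probs <- vapply(x_all, tab_prob, numeric(1))
  p_obs <- tab_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force two-sided Mann-Whitney p: enumerate all group-A index sets and
# compute U by direct pairwise comparison of the raw values (ties count 1/2).
oracle_mw_p <- function(a_vals, b_vals) {
  pooled <- c(a_vals, b_vals)
  n <- length(a_vals); m <- length(b_vals)
  u_of <- function(idx) {
    av <- pooled[idx]; bv <- pooled[-idx]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2L, u_of)
  mean(abs(u_all - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-9)
}

# Simulated inversion scenario shared by caller tests.
make_inversion_scenario <- function(genome_bp = 2e5, inv_start = 6e4,
                                    inv_end = 1.4e5, coverage = 30,
                                    seed = 1, with_inversion = TRUE) {
  ref <- generate_genome(genome_bp, 0.45, seed = seed)
  don <- if (with_inversion) apply_inversion(ref, inv_start, inv_end) else ref
  pairs <- simulate_paired_end_alignments(ref, don, coverage,
                                          insert_profile(), seed = seed + 1L)
  list(ref = ref, don = don, pairs = pairs)
}

# Default family scenario plus matching filter configuration.
family_scenario <- function(seed = 4) {
  fam <- simulate_family_variants(seed = seed)
  cfg <- filter_config(
    sequenced_affecteds = fam$pedigree$sample_id[fam$pedigree$sequenced],
    control_samples = fam$control_samples,
    pedigree = fam$pedigree,
    locus = c(3e5, 7e5)
  )
  list(fam = fam, cfg = cfg)
}

hamming_identity_pct <- function(x, y) {
  xb <- strsplit(x, "")[[1]]; yb <- strsplit(y, "")[[1]]
  100 * mean(xb == yb)
}
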