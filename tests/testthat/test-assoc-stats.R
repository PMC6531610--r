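test_that("every published protein annotation classifies without 'other'", {
  classes <- classify_consequence(dpp6_patient_variants()$protein)
  expect_false(any(classes == "other"))
  expect_identical(sum(classes == "PTC"), 2L)
  expect_identical(classify_consequence("p.Q230*"), "PTC")
  expect_identical(classify_consequence("p.E79Gfs*9"), "PTC")
  expect_identical(classify_consequence("p.G61_G62dup"), "inframe_indel")
  expect_identical(classify_consequence("p.A20T"), "missense")
  expect_identical(classify_consequence("p.A20A"), "synonymous")
  expect_warning(res <- classify_consequence("g.12345A>T"), "Unparseable")
  expect_identical(res, "other")
})

test_that("a symmetric allele table gives OR 1 and p 1", {
  res <- fisher_allelic(5, 200, 5, 200)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_two_sided, 1)
  expect_true(res$ci95[[1]] <= 1 && 1 <= res$ci95[[2]])
})

test_that("fisher p equals exhaustive hypergeometric enumeration", {
  cases <- list(c(3, 8, 1, 8), c(0, 100, 5, 100), c(7, 20, 2, 30),
                c(10, 12, 1, 14), c(2, 40, 2, 40))
  for (cc in cases) {
    res <- fisher_allelic(cc[1], cc[2], cc[3], cc[4])
    oracle <- oracle_fisher_p(cc[1], cc[2] - cc[1], cc[3], cc[4] - cc[3])
    expect_equal(res$p_two_sided, oracle, tolerance = 1e-12)
  }
  # zero cell: finite OR through the Haldane-Anscombe correction
  z <- fisher_allelic(0, 100, 5, 100)
  expect_true(is.finite(z$odds_ratio) && z$odds_ratio > 0)
  # cross-check p against stats::fisher.test on a handful of tables
  for (cc in cases) {
    ft <- stats::fisher.test(matrix(c(cc[1], cc[2] - cc[1],
                                      cc[3], cc[4] - cc[3]), 2, byrow = TRUE))
    expect_equal(fisher_allelic(cc[1], cc[2], cc[3], cc[4])$p_two_sided,
                 ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_allelic(-1, 10, 1, 10), "non-negative")
  expect_error(fisher_allelic(11, 10, 1, 10), "exceed")
})

test_that("exact Mann-Whitney matches full labeling enumeration", {
  res <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_sided, 1 / 3, tolerance = 1e-12)

  expect_equal(mann_whitney_exact(c(3, 1, 2), c(1, 2, 3))$p_two_sided, 1)

  withr::local_seed(5)
  for (rep in 1:5) {
    a <- round(rnorm(6, 10, 3), 1)
    b <- round(rnorm(6, 11, 3), 1)
    res <- mann_whitney_exact(a, b)
    expect_equal(res$p_two_sided, oracle_mw_p(a, b), tolerance = 1e-12)
    # label symmetry: U maps to n*m - U with identical p
    swapped <- mann_whitney_exact(b, a)
    expect_equal(swapped$U, 36 - res$U)
    expect_equal(swapped$p_two_sided, res$p_two_sided, tolerance = 1e-12)
    # agreement with the reference implementation in the tie-free case
    if (!any(duplicated(c(a, b)))) {
      wt <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(res$p_two_sided, wt$p.value, tolerance = 1e-9)
      expect_equal(res$U, unname(wt$statistic))
    }
  }
  expect_error(mann_whitney_exact(numeric(), 1:3), "non-empty")
})

test_that("large-sample Mann-Whitney falls back to the corrected normal approximation", {
  withr::local_seed(9)
  a <- rnorm(40); b <- rnorm(40, 0.5)
  res <- mann_whitney_exact(a, b)
  expect_identical(res$method, "normal approximation")
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$p_two_sided, wt$p.value, tolerance = 1e-6)
})

test_that("chi-square test follows the Pearson formula", {
  hom <- chi_square_test(matrix(10, 2, 2))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p_value, 1)
  res <- chi_square_test(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_identical(unname(res$df), 1L)
  expect_identical(chi_square_test(matrix(c(5, 6, 7, 8, 9, 10), 2))$df, 2L)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "Fisher")
})

test_that("geometric normalization is exact on closed-form cases and scale-invariant", {
  expr <- tibble::tibble(sample = c("s1", "s2"), target = c(8, 8),
                         ref1 = c(2, 4), ref2 = c(32, 4))
  out <- geometric_normalize(expr, c("ref1", "ref2"))
  expect_equal(out$target, c(1, 2))
  expect_equal(out$norm_factor, c(8, 4))

  scaled <- dplyr::mutate(expr, dplyr::across(c(target, ref1, ref2), ~ .x * 10))
  out10 <- geometric_normalize(scaled, c("ref1", "ref2"))
  expect_equal(out10$target, out$target)

  expect_error(geometric_normalize(expr, c("ref1", "nope")), "absent")
  expect_error(geometric_normalize(dplyr::mutate(expr, ref1 = -1), c("ref1", "ref2")),
               "positive")
})

test_that("the permutation burden test is significant under the cohort power scenario", {
  cc <- simulate_case_control_genotypes(558, 755, seed = 3)
  expect_identical(dim(cc$genotypes), c(558L + 755L, 35L))
  expect_true(all(cc$variants$maf < 0.01))
  expect_identical(sum(cc$variants$effect == "causal"), 14L)
  expect_identical(sum(cc$variants$effect == "protective"), 4L)
  # the rarest effect variant attains the maximal odds ratio
  eff <- cc$variants[cc$variants$effect != "neutral", ]
  expect_equal(max(exp(abs(eff$beta))), 5, tolerance = 1e-9)
  bt <- permutation_burden(cc$genotypes, cc$phenotype, n_perm = 1000, seed = 4)
  expect_lt(bt$p_value, 0.05)
  expect_error(permutation_burden(cc$genotypes, rep(1, nrow(cc$genotypes)),
                                  n_perm = 1000), "constant")
})

test_that("a single-variant burden test agrees with the allelic exact test", {
  cc <- simulate_case_control_genotypes(300, 300, n_variants = 1,
                                        causal_pct = 100, protective_pct = 0,
                                        max_or = 4, maf_range = c(0.008, 0.0099),
                                        seed = 6)
  g <- cc$genotypes[, 1]; y <- cc$phenotype
  bt <- permutation_burden(cc$genotypes, cc$phenotype, n_perm = 4000, seed = 7)
  fis <- fisher_allelic(sum(g[y == 1]), 2 * sum(y == 1),
                        sum(g[y == 0]), 2 * sum(y == 0))
  expect_lt(abs(bt$p_value - fis$p_two_sided), 0.05)
})

test_that("null burden p-values are approximately uniform", {
  withr::local_seed(77)
  pvals <- replicate(120, {
    g <- matrix(rbinom(200 * 8, 2, 0.02), nrow = 200)
    y <- rep(c(1L, 0L), each = 100)
    permutation_burden(g, y, n_perm = 1000, seed = sample.int(1e6, 1))$p_value
  })
  # super-uniformity up to Monte-Carlo error
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.001)
  expect_lt(abs(mean(pvals <= 0.2) - 0.2), 0.12)
})
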