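test_that("insert model uses robust statistics over FR pairs only", {
  base <- tibble::tibble(
    pair_id = sprintf("p%d", 1:200), chrom = "chrS",
    pos1 = 1:200, strand1 = "+", cigar1 = "100M", end1 = 101:300,
    pos2 = 401:600, strand2 = "-", cigar2 = "100M", end2 = 501:700,
    read_len_bp = 100L, template_len_bp = 350L, mapq = 60L, spanning = FALSE
  )
  m <- estimate_insert_model(base)
  expect_equal(m$median_bp, 350)
  expect_equal(m$spread_bp, 0)
  expect_equal(c(m$lower_bp, m$upper_bp), c(350, 350))

  # ++ pairs are excluded from calibration
  shifted <- dplyr::mutate(base, strand2 = "+", template_len_bp = 5000L)
  both <- dplyr::bind_rows(base, shifted)
  expect_equal(estimate_insert_model(both)$median_bp, 350)

  expect_error(estimate_insert_model(base[1:50, ]), "100 FR")

  withr::local_seed(1)
  big <- dplyr::mutate(
    dplyr::slice_sample(base, n = 1e5, replace = TRUE),
    template_len_bp = as.integer(round(rnorm(1e5, 350, 35)))
  )
  mb <- estimate_insert_model(big)
  expect_gte(mb$median_bp, 348); expect_lte(mb$median_bp, 352)
  expect_gte(mb$spread_bp, 33); expect_lte(mb$spread_bp, 37)
})

test_that("pair classification separates orientation and distance discordance", {
  model <- structure(list(median_bp = 350, spread_bp = 30, lower_bp = 200,
                          upper_bp = 500, proper_orientation = "FR", n_pairs = 100),
                     class = "insert_size_model")
  pairs <- tibble::tibble(
    pair_id = c("a", "b", "c", "d"), chrom = "chrS",
    pos1 = 1L, strand1 = c("+", "+", "+", "-"), cigar1 = "100M", end1 = 101L,
    pos2 = 301L, strand2 = c("-", "+", "-", "-"), cigar2 = "100M", end2 = 401L,
    read_len_bp = 100L, template_len_bp = c(350L, 350L, 5000L, 5000L),
    mapq = 60L, spanning = FALSE
  )
  cls <- classify_pairs(pairs, model)$class
  expect_identical(cls, c("concordant", "discordant_orientation",
                          "discordant_distance", "discordant_both"))
})

test_that("discordant clustering groups by orientation class and gap", {
  mk <- function(pos, strand, n) tibble::tibble(
    pair_id = sprintf("%s%d_%d", strand, pos, seq_len(n)), chrom = "chrS",
    pos1 = as.integer(pos + seq_len(n) * 50), strand1 = strand, cigar1 = "100M",
    end1 = as.integer(pos + seq_len(n) * 50 + 100),
    pos2 = as.integer(pos + 5000 + seq_len(n) * 50), strand2 = strand,
    cigar2 = "100M", end2 = as.integer(pos + 5100 + seq_len(n) * 50),
    read_len_bp = 100L, template_len_bp = 5000L, mapq = 60L, spanning = FALSE,
    class = "discordant_both"
  )
  cl <- cluster_discordant(dplyr::bind_rows(mk(1000, "+", 5)), max_gap_bp = 500)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$support, 5L)

  two <- dplyr::bind_rows(mk(1000, "+", 5), mk(11000, "+", 4))
  cl2 <- cluster_discordant(two, max_gap_bp = 500)
  expect_identical(nrow(cl2), 2L)

  none <- dplyr::mutate(mk(1000, "+", 5), class = "concordant")
  expect_identical(nrow(cluster_discordant(none, max_gap_bp = 500)), 0L)
})

test_that("a simulated inversion is called with breakpoints inside the intervals", {
  s <- 3e5; e <- 7e5
  sc <- make_inversion_scenario(genome_bp = 1e6, inv_start = s, inv_end = e,
                                coverage = 30, seed = 80)
  calls <- call_inversions_short(sc$pairs)
  expect_identical(nrow(calls), 1L)
  expect_true(calls$prox_start <= s && s <= calls$prox_end)
  expect_true(calls$dist_start <= e && e <= calls$dist_end)
  model <- estimate_insert_model(sc$pairs)
  expect_lte(calls$prox_end - calls$prox_start, model$upper_bp + 100)
  expect_lte(calls$dist_end - calls$dist_start, model$upper_bp + 100)
  expect_identical(calls$evidence, "short_read")
  expect_false(calls$one_sided)
})

test_that("raising min_support never increases the number of calls", {
  sc <- make_inversion_scenario(genome_bp = 3e5, inv_start = 1e5, inv_end = 2e5,
                                coverage = 8, seed = 81)
  n_calls <- vapply(c(1, 3, 10, 50, 1000), function(ms) {
    nrow(call_inversions_short(sc$pairs, min_support = ms))
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("weakly supported single-orientation clusters are not called", {
  cl <- tibble::tibble(
    orientation_class = "plus_plus", support = 2L,
    first_start = 1000L, first_end = 1100L,
    second_start = 9000L, second_end = 9100L,
    members = list(c("a", "b")), chrom = "chrS"
  )
  model <- structure(list(median_bp = 350, spread_bp = 30, lower_bp = 200,
                          upper_bp = 500, proper_orientation = "FR", n_pairs = 100),
                     class = "insert_size_model")
  expect_identical(nrow(call_inversions(cl, model, min_support = 3)), 0L)
  # but a lone strong cluster yields a flagged one-sided call
  strong <- dplyr::mutate(cl, support = 10L, members = list(sprintf("m%d", 1:10)))
  one <- call_inversions(strong, model, min_support = 3)
  expect_identical(nrow(one), 1L)
  expect_true(one$one_sided)
})

test_that("inversion-free simulations produce zero calls", {
  for (seed in c(90, 91, 92, 93, 94)) {
    sc <- make_inversion_scenario(genome_bp = 2e5, coverage = 30, seed = seed,
                                  with_inversion = FALSE)
    expect_identical(nrow(call_inversions_short(sc$pairs)), 0L)
  }
})
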