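test_that("identity-donor pairs are FR with inserts centred on the profile mean", {
  sc <- make_inversion_scenario(genome_bp = 1e5, coverage = 20, seed = 31,
                                with_inversion = FALSE)
  pairs <- sc$pairs
  expect_true(all(pairs$strand1 != pairs$strand2))
  expect_false(any(pairs$spanning))
  tl <- abs(pairs$template_len_bp)
  n <- length(tl)
  expect_lt(abs(median(tl) - 350), 3 * 35 / sqrt(n) * sqrt(pi / 2) + 1)
  expect_gt(sd(tl), 25); expect_lt(sd(tl), 45)
})

test_that("pair count follows the coverage expectation", {
  ref <- generate_genome(1e6, 0.5, seed = 40)
  pairs <- simulate_paired_end_alignments(ref, ref, 30, insert_profile(), seed = 41)
  expect_lt(abs(nrow(pairs) - 150000) / 150000, 0.05)
})

test_that("reads inside an inversion are mirrored per the reflection oracle", {
  s <- 6e4; e <- 1.4e5
  sc <- make_inversion_scenario(genome_bp = 2e5, inv_start = s, inv_end = e,
                                coverage = 10, seed = 32)
  pairs <- sc$pairs
  # fragments straddling the proximal breakpoint: both reads on + strand
  pp <- dplyr::filter(pairs, strand1 == "+", strand2 == "+", !spanning)
  expect_gt(nrow(pp), 0)
  expect_true(all(pp$end1 - 1 <= s))
  expect_true(all(pp$end2 - 1 <= e & pp$pos2 - 1 >= s))
  mm <- dplyr::filter(pairs, strand1 == "-", strand2 == "-", !spanning)
  expect_gt(nrow(mm), 0)
  expect_true(all(mm$pos1 - 1 >= s))
  expect_true(all(mm$pos2 - 1 >= e))

  # hand-placed fragment straddling the proximal breakpoint, checked against
  # the scalar reflection oracle: read2 occupies donor [s+10, s+110)
  rl <- 100
  r2_ref_start <- oracle_reflect_pos(s + 110 - 1, s, e)  # leftmost ref base
  expect_identical(r2_ref_start, s + e - (s + 110))
  # reflection is an involution
  p <- 123456
  expect_identical(oracle_reflect_pos(oracle_reflect_pos(p, s, e), s, e), p)
})

test_that("breakpoint-spanning reads are emitted clipped and flagged", {
  sc <- make_inversion_scenario(genome_bp = 1.5e5, inv_start = 5e4,
                                inv_end = 1e5, coverage = 15, seed = 33)
  sp <- dplyr::filter(sc$pairs, spanning)
  expect_gt(nrow(sp), 0)
  expect_true(any(grepl("S", c(sp$cigar1, sp$cigar2))))
  # clipped records still place their matched block within the genome
  expect_true(all(sp$pos1 >= 1 & sp$end2 - 1 <= genome_length(sc$ref)))
})

test_that("long reads split into alternating-strand segments at breakpoints", {
  ref <- generate_genome(1e5, 0.5, seed = 50)
  don <- apply_inversion(ref, 3e4, 7e4)

  # no inversion: single + segment per read
  flat <- simulate_long_read_alignments(ref, ref, 40, length_law = 5000, seed = 51)
  expect_true(all(table(flat$read_id) == 1))
  expect_true(all(flat$strand == "+"))

  segs <- simulate_long_read_alignments(ref, don, 60, length_law = 20000, seed = 52)
  by_read <- split(segs, segs$read_id)
  for (sg in by_read) {
    sg <- sg[order(sg$segment), ]
    if (nrow(sg) > 1) {
      expect_true(all(sg$strand[-1] != sg$strand[-nrow(sg)]))
    }
    # read-coordinate intervals tile the read without overlap
    expect_true(all(sg$read_start[-1] == sg$read_end[-nrow(sg)]))
    # minus segments sit inside the inverted interval
    expect_true(all(sg$ref_start[sg$strand == "-"] >= 3e4))
    expect_true(all(sg$ref_end[sg$strand == "-"] <= 7e4))
  }

  # a read entirely inside the inverted segment: one minus-strand segment
  don_small <- apply_inversion(ref, 1e4, 9e4)
  inner <- simulate_long_read_alignments(ref, don_small, 200, length_law = 2000, seed = 53)
  one_seg <- dplyr::filter(
    dplyr::add_count(inner, read_id), n == 1,
    ref_start >= 1e4, ref_end <= 9e4
  )
  expect_gt(nrow(one_seg), 0)
  expect_true(all(one_seg$strand == "-"))
})

test_that("simulators are bit-reproducible given a seed", {
  ref <- generate_genome(5e4, 0.5, seed = 60)
  don <- apply_inversion(ref, 2e4, 3e4)
  p1 <- simulate_paired_end_alignments(ref, don, 5, insert_profile(), seed = 61)
  p2 <- simulate_paired_end_alignments(ref, don, 5, insert_profile(), seed = 61)
  expect_identical(p1, p2)
  l1 <- simulate_long_read_alignments(ref, don, 20, seed = 62)
  l2 <- simulate_long_read_alignments(ref, don, 20, seed = 62)
  expect_identical(l1, l2)
  expect_error(
    simulate_paired_end_alignments(ref, generate_genome(6e4, 0.5, seed = 1), 5,
                                   insert_profile(), seed = 2),
    "equal length"
  )
})
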