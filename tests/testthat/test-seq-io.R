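test_that("FASTA writer/reader round-trips, normalizes case, rejects bad input", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(chrA = "ACGTACGTAC", chrB = strrep("TTGGCCA", 30))
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)

  writeLines(c(">x", "acgTn"), path)
  expect_identical(unname(read_fasta(path)), "ACGTN")

  writeLines(character(), path)
  expect_length(read_fasta(path), 0)

  writeLines(c(">x", "ACGT", ">x", "GGCC"), path)
  expect_error(read_fasta(path), "Duplicate")

  writeLines(c(">x", "AC!T"), path)
  expect_error(read_fasta(path), "IUPAC")
})

test_that("SAM pair writer/reader round-trips with the TLEN sign convention", {
  sc <- make_inversion_scenario(genome_bp = 5e4, inv_start = 2e4, inv_end = 3e4,
                                coverage = 4, seed = 70)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam_pairs(sc$pairs, path, setNames(genome_length(sc$ref), sc$ref$name))

  lines <- readLines(path)
  expect_true(any(startsWith(lines, "@SQ")))
  body <- lines[!startsWith(lines, "@")]
  tlen <- as.integer(vapply(strsplit(body, "\t"), `[[`, "", 9L))
  pos <- as.integer(vapply(strsplit(body, "\t"), `[[`, "", 4L))
  # positive TLEN on the leftmost mate of each pair
  pair_pos <- matrix(pos, ncol = 2, byrow = TRUE)
  pair_tlen <- matrix(tlen, ncol = 2, byrow = TRUE)
  left_is_first <- pair_pos[, 1] <= pair_pos[, 2]
  expect_true(all(ifelse(left_is_first, pair_tlen[, 1], pair_tlen[, 2]) >= 0))

  back <- read_sam_pairs(path)
  ord <- function(x) as.data.frame(x[order(x$pair_id), ])
  expect_equal(ord(back), ord(sc$pairs), ignore_attr = TRUE)
})

test_that("unmated SAM reads are excluded with a warning; malformed FLAG errors", {
  sc <- make_inversion_scenario(genome_bp = 5e4, coverage = 2, seed = 71,
                                with_inversion = FALSE)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam_pairs(sc$pairs, path, setNames(genome_length(sc$ref), sc$ref$name))
  lines <- readLines(path)
  writeLines(head(lines, -1), path)  # drop one mate
  expect_warning(back <- read_sam_pairs(path), "unmated")
  expect_identical(nrow(back), nrow(sc$pairs) - 1L)

  bad <- lines
  bad[[3]] <- sub("^(\\S+)\t\\d+", "\\1\tXX", bad[[3]])
  writeLines(bad, path)
  expect_error(read_sam_pairs(path), "FLAG")

  writeLines(lines[!startsWith(lines, "@")], path)
  expect_error(read_sam_pairs(path), "@SQ")
})

test_that("long-read SAM round-trips the segment structure via SA records", {
  ref <- generate_genome(8e4, 0.5, seed = 72)
  don <- apply_inversion(ref, 3e4, 5e4)
  segs <- simulate_long_read_alignments(ref, don, 25, length_law = 15000, seed = 73)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam_long_reads(segs, path, setNames(genome_length(ref), ref$name))
  back <- read_sam_long_reads(path)
  ord <- function(x) as.data.frame(dplyr::arrange(x, read_id, segment))
  expect_equal(ord(back)[names(ord(segs))], ord(segs), ignore_attr = TRUE)
})

test_that("variant table round-trips genotypes, panel MAFs and missingness", {
  fam <- simulate_family_variants(n_linked_unique = 2,
                                  n_linked_shared_polymorphic = 3,
                                  n_offlocus = 5, n_controls = 4, seed = 74)
  v <- fam$variants
  v[["III-1"]][[1]] <- "./."
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(v, path)
  back <- read_variant_table(path)
  expect_identical(back$pos, v$pos)
  expect_identical(back[["III-1"]], v[["III-1"]])
  expect_identical(back[["CTRL01"]], v[["CTRL01"]])
  expect_equal(back$panel_freqs, v$panel_freqs, tolerance = 1e-9)
  expect_identical(back$qual, v$qual)

  # INFO AF key parsing
  lines <- readLines(path)
  i <- which(!startsWith(lines, "#"))[1]
  expect_match(lines[[i]], "AF_1KG=")

  # column-count mismatch is a parse error
  writeLines(c(lines[1:2], sub("\t[^\t]*$", "", lines[[i]])), path)
  expect_error(read_variant_table(path), "column count")
})

test_that("BED writer sorts and validates intervals", {
  path <- withr::local_tempfile(fileext = ".bed")
  iv <- tibble::tibble(chrom = "chrS", start = c(500L, 0L), end = c(900L, 100L),
                       name = c("lcrB", "lcrA"))
  write_bed(iv, path)
  out <- readLines(path)
  expect_identical(out, c("chrS\t0\t100\tlcrA", "chrS\t500\t900\tlcrB"))
  expect_error(write_bed(dplyr::mutate(iv, end = start), path), "end > start")
  expect_error(write_bed(dplyr::mutate(iv, start = -1L), path), ">= 0")
})
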