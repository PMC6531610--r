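# Readers and writers for the formats the pipeline touches: FASTA (via
# Biostrings), a minimal SAM text dialect (11 mandatory columns, M/S CIGARs,
# SA tag for split long reads), a minimal tab-separated VCF (single ALT per
# row, GT-only FORMAT, per-panel allele frequencies as AF_<PANEL> INFO keys)
# and BED3+name. Readers reject malformed records rather than coercing;
# writer/reader compositions are identities on valid data.

FIXED_VARIANT_COLS <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter",
                        "panel_freqs", "annotation", "truth_class")

#' Read / write FASTA
#'
#' Sequences are uppercased on read; duplicate record names and non-IUPAC
#' characters are errors. An empty file yields an empty mapping.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector, one element per record,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) return(setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) abort("Duplicate FASTA record names.")
  if (any(grepl("[^ACGTURYSWKMBDHVN-]", seqs))) {
    abort("Non-IUPAC characters in FASTA sequence.")
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences (or a `synthetic_genome`).
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "synthetic_genome")) {
    seqs <- setNames(seqs$sequence, seqs$name)
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

cigar_ref_span <- function(cigar) {
  purrr::map_int(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    lens <- as.integer(regmatches(cg, gregexpr("\\d+", cg))[[1]])
    kinds <- regmatches(cg, gregexpr("[MS]", cg))[[1]]
    if (length(lens) != length(kinds)) abort(sprintf("Malformed CIGAR: %s", cg))
    sum(lens[kinds == "M"])
  })
}

#' Write aligned pairs as minimal SAM
#'
#' Two records per pair (FLAG bits 0x1/0x40/0x80 for pairing, 0x10/0x20 for
#' strands); TLEN is positive on the leftmost mate. Breakpoint-spanning
#' pairs carry the optional tag `ZS:i:1`.
#'
#' @param pairs A tibble as produced by [simulate_paired_end_alignments()].
#' @param path Output path.
#' @param ref_lengths Named integer vector of reference sequence lengths for
#'   the `@SQ` header lines.
#' @export
write_sam_pairs <- function(pairs, path, ref_lengths) {
  stopifnot(is.numeric(ref_lengths), !is.null(names(ref_lengths)))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)))
  flag1 <- 1L + 64L + ifelse(pairs$strand1 == "-", 16L, 0L) +
    ifelse(pairs$strand2 == "-", 32L, 0L)
  flag2 <- 1L + 128L + ifelse(pairs$strand2 == "-", 16L, 0L) +
    ifelse(pairs$strand1 == "-", 32L, 0L)
  tag <- ifelse(pairs$spanning, "\tZS:i:1", "")
  rec1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*%s",
                  pairs$pair_id, flag1, pairs$chrom, pairs$pos1, pairs$mapq,
                  pairs$cigar1, pairs$pos2, pairs$template_len_bp, tag)
  rec2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*%s",
                  pairs$pair_id, flag2, pairs$chrom, pairs$pos2, pairs$mapq,
                  pairs$cigar2, pairs$pos1, -pairs$template_len_bp, tag)
  writeLines(c(hdr, as.vector(rbind(rec1, rec2))), path)
  invisible(path)
}

#' Read aligned pairs from minimal SAM
#'
#' Pairs are reconstructed by QNAME mate-joining. Unmated reads are excluded
#' with a warning; a malformed FLAG is a parse error; a missing `@SQ` header
#' is an error.
#'
#' @param path SAM file path.
#' @return A tibble of aligned pairs (see [simulate_paired_end_alignments()]).
#' @export
read_sam_pairs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  if (!any(startsWith(hdr, "@SQ"))) abort("SAM header lacks @SQ lines.")
  body <- lines[!startsWith(lines, "@")]
  if (!length(body)) return(empty_aligned_pairs())
  f <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(f)
  if (any(ncols < 11L)) abort("SAM record with fewer than 11 mandatory columns.")
  flag <- suppressWarnings(as.integer(vapply(f, `[[`, "", 2L)))
  if (anyNA(flag)) abort("Malformed FLAG field in SAM record.")
  rec <- tibble(
    qname = vapply(f, `[[`, "", 1L),
    flag = flag,
    chrom = vapply(f, `[[`, "", 3L),
    pos = as.integer(vapply(f, `[[`, "", 4L)),
    mapq = as.integer(vapply(f, `[[`, "", 5L)),
    cigar = vapply(f, `[[`, "", 6L),
    tlen = as.integer(vapply(f, `[[`, "", 9L)),
    spanning = vapply(f, function(x) any(grepl("^ZS:i:1$", x[-(1:11)])), logical(1)),
    first = bitwAnd(flag, 64L) > 0L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  )
  counts <- table(rec$qname)
  unmated <- names(counts)[counts != 2L]
  if (length(unmated)) {
    warn(sprintf("Excluding %d unmated read name(s): %s",
                 length(unmated), paste(head(unmated, 5), collapse = ", ")))
    rec <- rec[!rec$qname %in% unmated, , drop = FALSE]
  }
  if (!nrow(rec)) return(empty_aligned_pairs())
  r1 <- rec[rec$first, , drop = FALSE]
  r2 <- rec[!rec$first, , drop = FALSE]
  r2 <- r2[match(r1$qname, r2$qname), , drop = FALSE]
  span1 <- cigar_ref_span(r1$cigar)
  span2 <- cigar_ref_span(r2$cigar)
  read_len <- purrr::map_int(r1$cigar, function(cg) {
    sum(as.integer(regmatches(cg, gregexpr("\\d+", cg))[[1]]))
  })
  tibble(
    pair_id = r1$qname,
    chrom = r1$chrom,
    pos1 = r1$pos, strand1 = r1$strand, cigar1 = r1$cigar,
    end1 = r1$pos + span1,
    pos2 = r2$pos, strand2 = r2$strand, cigar2 = r2$cigar,
    end2 = r2$pos + span2,
    read_len_bp = read_len,
    template_len_bp = abs(r1$tlen),
    mapq = pmin(r1$mapq, r2$mapq),
    spanning = r1$spanning | r2$spanning
  )
}

#' Write / read segmented long-read alignments as minimal SAM
#'
#' The first segment of each read is the primary record; further segments are
#' supplementary records (FLAG 0x800) and all records carry an `SA:Z:` tag
#' listing every segment as `rname,pos,strand,cigar,mapq,0;`.
#'
#' @param segments A tibble as produced by [simulate_long_read_alignments()].
#' @param path Output path.
#' @param ref_lengths Named integer vector for the `@SQ` header.
#' @export
write_sam_long_reads <- function(segments, path, ref_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)))
  by_read <- split(segments, segments$read_id)
  recs <- purrr::map(by_read, function(sg) {
    sg <- sg[order(sg$segment), , drop = FALSE]
    mlen <- sg$read_end - sg$read_start
    lead <- sg$read_start
    trail <- sg$read_len_bp - sg$read_end
    cigar <- ifelse(
      sg$strand == "+",
      paste0(ifelse(lead > 0, paste0(lead, "S"), ""), mlen, "M",
             ifelse(trail > 0, paste0(trail, "S"), "")),
      paste0(ifelse(trail > 0, paste0(trail, "S"), ""), mlen, "M",
             ifelse(lead > 0, paste0(lead, "S"), ""))
    )
    sa <- paste0(sg$chrom, ",", sg$ref_start + 1L, ",", sg$strand, ",",
                 cigar, ",60,0;", collapse = "")
    flag <- ifelse(sg$strand == "-", 16L, 0L) +
      c(0L, rep(2048L, nrow(sg) - 1L))
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tSA:Z:%s",
            sg$read_id, flag, sg$chrom, sg$ref_start + 1L, cigar, sa)
  })
  writeLines(c(hdr, unlist(recs, use.names = FALSE)), path)
  invisible(path)
}

#' @rdname write_sam_long_reads
#' @return `read_sam_long_reads()`: a segment tibble with read-coordinate and
#'   reference-coordinate intervals per segment.
#' @export
read_sam_long_reads <- function(path) {
  lines <- readLines(path)
  if (!any(startsWith(lines, "@SQ"))) abort("SAM header lacks @SQ lines.")
  body <- lines[!startsWith(lines, "@")]
  f <- strsplit(body, "\t", fixed = TRUE)
  purrr::map_dfr(f, function(x) {
    flag <- suppressWarnings(as.integer(x[[2]]))
    if (is.na(flag)) abort("Malformed FLAG field in SAM record.")
    cg <- x[[6]]
    lens <- as.integer(regmatches(cg, gregexpr("\\d+", cg))[[1]])
    kinds <- regmatches(cg, gregexpr("[MS]", cg))[[1]]
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    mlen <- sum(lens[kinds == "M"])
    lead <- if (kinds[1] == "S") lens[1] else 0L
    trail <- if (kinds[length(kinds)] == "S") lens[length(lens)] else 0L
    if (strand == "-") { tmp <- lead; lead <- trail; trail <- tmp }
    tibble(
      read_id = x[[1]],
      read_start = lead,
      read_end = lead + mlen,
      chrom = x[[3]],
      ref_start = as.integer(x[[4]]) - 1L,
      ref_end = as.integer(x[[4]]) - 1L + mlen,
      strand = strand,
      read_len_bp = sum(lens)
    )
  }) |>
    arrange(.data$read_id, .data$read_start) |>
    group_by(.data$read_id) |>
    mutate(segment = row_number()) |>
    ungroup() |>
    select("read_id", "segment", "read_start", "read_end", "chrom",
           "ref_start", "ref_end", "strand", "read_len_bp")
}

variant_samples <- function(variants) {
  setdiff(names(variants), FIXED_VARIANT_COLS)
}

#' Write / read a multi-sample variant table (minimal VCF)
#'
#' One ALT per row; FORMAT is `GT` only; per-panel minor allele frequencies
#' travel as `AF_<PANEL>=<maf>` INFO keys and surface as the `panel_freqs`
#' list-column; a free-text `ANN=` INFO key carries the `annotation` column.
#' Genotype columns (one per sample) hold `0/0`, `0/1`, `1/1` or `./.`;
#' missing genotypes are preserved and never counted as carriers downstream.
#'
#' @param variants Variant tibble: columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, `qual`, `filter`, `panel_freqs` (list of named numerics),
#'   optional `annotation`, then one genotype column per sample.
#' @param path File path.
#' @export
write_variant_table <- function(variants, path) {
  samples <- variant_samples(variants)
  info <- purrr::map_chr(seq_len(nrow(variants)), function(i) {
    pf <- variants$panel_freqs[[i]]
    parts <- character()
    if (length(pf)) {
      parts <- sprintf("AF_%s=%s", toupper(names(pf)),
                       formatC(unname(pf), format = "g", digits = 10))
    }
    if (!is.null(variants$annotation) && !is.na(variants$annotation[[i]]) &&
        nzchar(variants$annotation[[i]])) {
      parts <- c(parts, paste0("ANN=", variants$annotation[[i]]))
    }
    if (length(parts)) paste(parts, collapse = ";") else "."
  })
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt <- do.call(cbind, lapply(samples, function(s) variants[[s]]))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[[i]], variants$pos[[i]], variants$id[[i]],
            variants$ref[[i]], variants$alt[[i]],
            ifelse(is.na(variants$qual[[i]]), ".", variants$qual[[i]]),
            variants$filter[[i]], info[[i]], "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- lines[startsWith(lines, "#CHROM")]
  if (length(header) != 1L) abort("Variant table lacks a #CHROM header line.")
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(empty_variant_table(samples))
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != length(cols))) {
    abort("Variant record column count does not match the sample header.")
  }
  gts <- c("0/0", "0/1", "1/0", "1/1", "./.")
  info <- vapply(f, `[[`, "", 8L)
  pf <- purrr::map(info, function(s) {
    if (s == ".") return(setNames(numeric(), character()))
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    kv <- kv[vapply(kv, function(x) startsWith(x[[1]], "AF_"), logical(1))]
    setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
             tolower(sub("^AF_", "", vapply(kv, `[[`, "", 1L))))
  })
  ann <- vapply(info, function(s) {
    m <- regmatches(s, regexpr("(?<=ANN=)[^;]+", s, perl = TRUE))
    if (length(m)) m else NA_character_
  }, character(1), USE.NAMES = FALSE)
  out <- tibble(
    chrom = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 2L)),
    id = vapply(f, `[[`, "", 3L),
    ref = vapply(f, `[[`, "", 4L),
    alt = vapply(f, `[[`, "", 5L),
    qual = suppressWarnings(as.numeric(vapply(f, `[[`, "", 6L))),
    filter = vapply(f, `[[`, "", 7L),
    panel_freqs = pf,
    annotation = ann
  )
  for (j in seq_along(samples)) {
    g <- vapply(f, `[[`, "", 9L + j)
    if (!all(g %in% gts)) abort("Unparseable genotype field; expected GT-only FORMAT.")
    out[[samples[[j]]]] <- g
  }
  ok_ref <- grepl("^[ACGT]+$", out$ref)
  ok_alt <- grepl("^[ACGT]+$", out$alt) | grepl("^<[A-Z0-9_:]+>$", out$alt)
  if (any(!ok_ref | !ok_alt)) abort("REF/ALT alleles must be A/C/G/T or symbolic.")
  out
}

empty_variant_table <- function(samples = character()) {
  out <- tibble(
    chrom = character(), pos = integer(), id = character(), ref = character(),
    alt = character(), qual = double(), filter = character(),
    panel_freqs = list(), annotation = character()
  )
  for (s in samples) out[[s]] <- character()
  out
}

#' Write BED3+name intervals
#'
#' Intervals are 0-based half-open and written sorted by chromosome and
#' start. `end <= start` or negative coordinates are validation errors.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`, `name`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(intervals)))
  if (nrow(intervals)) {
    if (any(intervals$start < 0)) abort("BED start coordinates must be >= 0.")
    if (any(intervals$end <= intervals$start)) abort("BED requires end > start.")
  }
  out <- arrange(intervals, .data$chrom, .data$start, .data$end)
  readr::write_tsv(out[, c("chrom", "start", "end", "name")], path,
                   col_names = FALSE)
  invisible(path)
}
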