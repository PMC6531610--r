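# Published reference values for the DPP6 locus analyses, entered as code so
# downstream computations (inversion span, consequence tallies, cohort
# Fisher tests) run from first inputs.

#' Long-read inversion breakpoints at the DPP6 locus (hg19)
#'
#' The strand-flip long-read caller localized the paracentric 7q36 inversion
#' at chr7:149,704,610-153,786,893 (hg19). Returned 1-based, as printed.
#'
#' @return A one-row tibble: `chrom`, `proximal_bp`, `distal_bp`.
#' @export
dpp6_inversion_breakpoints <- function() {
  tibble(chrom = "chr7", proximal_bp = 149704610, distal_bp = 153786893)
}

#' Inversion span in megabases
#'
#' Subtracts the proximal from the distal breakpoint coordinate and rounds
#' to the nearest megabase.
#'
#' @param breakpoints A tibble as returned by
#'   [dpp6_inversion_breakpoints()].
#' @return Span in Mb, rounded to the nearest integer.
#' @examples
#' inversion_span_mb(dpp6_inversion_breakpoints())
#' @export
inversion_span_mb <- function(breakpoints = dpp6_inversion_breakpoints()) {
  round((breakpoints$distal_bp - breakpoints$proximal_bp) / 1e6)
}

#' Rare DPP6 variants found only in patients (cohort resequencing)
#'
#' Per-carrier rows of the rare (MAF <= 1%) protein-changing DPP6 variants
#' identified exclusively in the dementia patient cohorts, with clinical
#' diagnosis and HGVS coding/protein annotations.
#'
#' @return A tibble: `patient`, `diagnosis`, `cdna`, `protein`.
#' @export
dpp6_patient_variants <- function() {
  tibble::tribble(
    ~patient,  ~diagnosis, ~cdna,              ~protein,
    "DR1149",  "FTD",      "c.14C>A",          "p.A5D",
    "DR1143",  "AD",       "c.58G>A",          "p.A20T",
    "DR1143",  "AD",       "c.109G>A",         "p.G37S",
    "DR1350",  "FTD-PPA",  "c.109G>A",         "p.G37S",
    "DR40",    "FTD",      "c.140G>T",         "p.R47L",
    "DR623",   "FTD",      "c.140G>T",         "p.R47L",
    "DR1144",  "AD",       "c.160C>G",         "p.R54G",
    "DR807",   "FTD",      "c.160C>G",         "p.R54G",
    "DR1351",  "AD",       "c.160C>G",         "p.R54G",
    "DR1352",  "AD",       "c.160C>G",         "p.R54G",
    "DR1147",  "FTD",      "c.182_187dup",     "p.G61_G62dup",
    "DR1145",  "FTD-ALS",  "c.235_236dupG",    "p.E79Gfs*9",
    "DR1153",  "FTD",      "c.331G>A",         "p.V111I",
    "DR1151",  "FTD",      "c.383A>G",         "p.K128R",
    "DR1198",  "FTD",      "c.622G>C",         "p.E208Q",
    "DR1150",  "PPA",      "c.685C>A",         "p.P229T",
    "DR1154",  "FTD",      "c.688C>T",         "p.Q230*",
    "DR1155",  "AD",       "c.821G>A",         "p.R274H",
    "DR1156",  "AD",       "c.965G>A",         "p.R322H",
    "DR1289",  "AD",       "c.1070A>G",        "p.H357R",
    "DR414",   "PPA",      "c.1526C>G",        "p.P509R",
    "DR1152",  "FTD-ALS",  "c.1705G>A",        "p.D569N",
    "DR1353",  "FTD",      "c.1711A>C",        "p.K571Q",
    "DR1354",  "AD",       "c.1711A>C",        "p.K571Q",
    "DR114",   "FTD",      "c.1964C>T",        "p.A655V"
  )
}

#' Cohort sizes of the DPP6 resequencing study
#'
#' @return A named list: `n_ad` (558), `n_ftd` (614), `n_controls` (755).
#' @export
dpp6_cohort_sizes <- function() {
  list(n_ad = 558L, n_ftd = 614L, n_controls = 755L)
}
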