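---
title: "Methods: inversion discovery and rare-variant prioritization with invscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inversion discovery and rare-variant prioritization with invscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invscout)
```

## The problem

A megabase-scale paracentric inversion is invisible to single-nucleotide
variant calling: it changes no base, only the orientation of a segment.
What it does change is the geometry of sequencing evidence. invscout
implements the three complementary lines of evidence used to discover and
characterize such an inversion at a disease locus, together with the
family-based variant prioritization and cohort statistics that surround
that discovery:

1. **Discordant mate pairs** (short reads): in an FR ("innie") paired-end
   library, fragments straddling the proximal breakpoint map with both
   reads on the forward strand, fragments straddling the distal breakpoint
   with both reads on the reverse strand.
2. **Strand-flip split alignments** (long reads): a read crossing a
   breakpoint aligns as consecutive segments on opposite strands.
3. **Inverted low-copy repeats** (IP-LCRs): two highly similar inverted
   sequence copies flanking the inversion identify the NAHR substrate that
   makes the locus unstable.

Because the cohort data behind the original discovery are not public, every
method here is validated on synthetic data whose generator is itself
first-class, tested code with recorded ground truth.

## The synthetic-data model

`generate_genome()` draws i.i.d. bases at a configurable GC fraction
(default 0.41, a typical mammalian value). `plant_inverted_lcr()` copies a
segment, reverse-complements it, and applies substitutions at exactly
`100 - identity_pct` percent of positions; `apply_inversion()` replaces a
half-open segment with its reverse complement. All coordinates are 0-based
half-open internally and 1-based on SAM/VCF export.

Read "alignment" is analytic: since the donor differs from the reference
only by recorded inversions, a donor interval inside an inverted segment
$[s, e)$ maps to the reference interval by reflection,
$[a, b) \mapsto [s + e - b, s + e - a)$, with flipped strand. No aligner
runs, so simulated positions are exact and recovery tests measure the
callers, not an aligner. Consequences of this choice:

* Sequencing errors are substitutions only and do not perturb mapped
  positions; there are no indels, chimeras or mapping ambiguity. Passing
  recovery tests therefore demonstrate the correctness of the calling
  logic under the library geometry, not robustness to alignment noise.
* Reads overlapping a breakpoint are emitted as clipped records carrying a
  `spanning` flag rather than dropped. The short-read caller ignores them
  (real pipelines cannot place them confidently); the long-read caller
  consumes the full segment structure.

The paired-end library defaults to 350 bp inserts, matching the fragment
size the discovery library was selected to, with standard deviation 35 bp.
The real library's spread is not reported anywhere we could find; 10% of
the mean is typical of size-selected short-fragment libraries and is the
package's own choice. Long reads default to lognormal lengths with median
20 kb (meanlog `log(20000)`, sdlog 0.5), a realistic nanopore
size-selected profile.

The pedigree template (`default_pedigree()`) mirrors the discovery
family's shape: three generations, autosomal-dominant transmission, four
sequenced affected carriers in three generation-III sibships, all 15
members genotyped. `simulate_family_variants()` plants three variant
classes with recorded truth: family-unique variants on the disease
haplotype (panel MAF 0, no control carriers), shared rare polymorphisms on
the haplotype (panel MAF drawn below 1%; at least one carrier among the
simulated controls is *guaranteed*, not merely likely, so the final
control-genotyping filter stage has an exact expected count), and
off-locus variants transmitted by Mendelian gene dropping independently of
affection. The default class sizes, 34 shared + 4 unique = 38
co-segregating variants, reproduce the structure of the discovery
family's filter cascade.

`simulate_case_control_genotypes()` reproduces a rare-variant
power-analysis scenario: a 3545 bp target with one rare variant per 100 bp
(MAF log-uniform on [1e-4, 0.0099]), 40% causal and 10% protective
variants, per-variant log-odds-ratio proportional to $|\log_{10}
\text{MAF}|$ and scaled so the rarest effect variant attains the maximal
odds ratio 5, baseline prevalence 0.1, and retrospective sampling from the
induced logistic model. The $|\log_{10}\text{MAF}|$ convention follows
standard kernel-association power frameworks; the source analysis named
the framework's parameters but not the per-variant scaling, so the scaling
is declared here as a design decision.

## Short-read calling

`estimate_insert_model()` operationalizes "markedly different from the
expected insert size" as median ± 5 × (1.4826 × MAD) over FR pairs only —
robust to the discordant tail and configurable via `k_spread`. Calibration
refuses to run on fewer than 100 FR pairs.

`cluster_discordant()` single-linkage clusters same-strand ("++" and
"--") pairs on the leftmost read coordinate with gap ≤ the model's upper
bound, excluding spanning-flagged and low-mapq (< 20) pairs, the latter
mirroring the ambiguity real LCRs cause. `call_inversions()` converts
cluster geometry into breakpoint intervals: a ++ cluster's first mates end
just left of the proximal breakpoint and its second mates just left of the
distal one, so it proposes intervals `[max mate end, + upper_bp]`; a --
cluster proposes `[min mate start − upper_bp, min mate start]`. A call
requires intersecting proximal AND distal proposals from both orientation
classes (intervals intersected, support summed), with a flagged
`one_sided` fallback when a lone cluster reaches twice the support
threshold — whether the original tool required both classes is not
documented, so the fallback is this package's addition and is labelled in
the output. `min_support` defaults to 3, balancing 6-30x scenarios.

## Long-read calling

A key geometric fact drives `detect_strand_flips()`: in reference space,
*every* strand-flip junction localizes both breakpoints. A read entering
the inverted segment continues from the segment's far end in reference
coordinates, so a (+,−) junction pairs the plus segment's reference end
(proximal breakpoint) with the minus segment's reference end (distal), and
a (−,+) junction pairs the two segment starts. Two-segment "partial"
reads — the only kind available when reads are much shorter than the
inversion, as at 6x coverage over a 400 kb event — therefore still propose
a full (proximal, distal) candidate; reads with three alternating segments
are labelled `full_span`. Segments under 200 bp are ignored and a 100 bp
junction tolerance absorbs clipped bases at homology boundaries.
`consolidate_long_read_calls()` clusters candidates within 500 bp, takes
median consensus breakpoints, and counts distinct supporting reads
(unweighted; the original caller's internal mapping-quality weighting is
not described) with a default threshold of 2. `reconcile_evidence()`
merges short- and long-read calls whose proximal and distal intervals both
intersect into `evidence = "both"`.

## Inverted-repeat discovery

`find_inverted_repeats()` matches k-mers (default k = 12) between the
sequence and its reverse complement, chains seeds on consistent diagonals
(tolerance k; at least 3 seeds per chain), and extends each chain ungapped
with +1/−2 scoring under x-drop 20, keeping the maximum-scoring prefix
only when it improves the score. Ungapped extension is sufficient because
the LCR model is substitution-only; it is also what keeps megabase
self-comparison tractable on a desk. Mirror-image duplicate hits (the same
pair seeded from the other copy) are collapsed, keeping the best score.
`flag_nahr_susceptible()` applies the stricter thresholds under which
inverted repeats are regarded as NAHR substrates — identity ≥ 98%, the
homology regime reported for the disease locus — on top of the finder's
permissive defaults (min_len 1000, min_identity 90).

## The filter cascade

`run_filter_cascade()` fixes the stage order: quality → rarity → zygosity
→ sharing → locus → segregation → control absence. Decisions recorded as
design choices:

* Rarity is a strict `MAF < 0.01` in **every** configured panel (the
  methods wording of the source analysis uses "< 1%"; its table legend
  says "≤ 1%" — the methods wording wins, and the threshold is
  configurable). A variant absent from a panel counts as rare (novel).
* "Good quality" is operationalized as `QUAL >= 30`; the original
  pipeline's internal criteria for its variant caller are not published,
  so this is an explicit stand-in.
* A missing (`./.`) genotype in a sequenced affected fails the sharing
  stage (conservative), while a missing control genotype is compatible
  with absence; both behaviours are configurable.

`check_segregation()` requires every genotyped haplotype carrier to carry
the variant and every genotyped non-carrier to be homozygous reference,
with fewer than two informative genotypes yielding `uninformative`.

## Statistics

* `fisher_allelic()` — two-sided p by the probability-mass method
  (summing hypergeometric masses ≤ the observed table's); odds ratio is
  the **sample** cross-product ratio with the Haldane–Anscombe +0.5
  correction when any cell is zero, and the CI is the Woolf log-OR
  interval. The source analysis does not state its CI method or whether
  its OR is conditional-MLE; the sample-OR + Woolf choice is declared
  here and cross-checked against `fisher.test()`'s p-value (identical
  method) in the tests.
* `permutation_burden()` — the omnibus kernel/burden statistic
  $\max_\rho \tilde Q_\rho$, $Q_\rho = (1-\rho)\sum_j (w_j s_j)^2 +
  \rho(\sum_j w_j s_j)^2$ over $\rho \in \{0, .25, .5, .75, 1\}$ with
  Beta(1, 25) MAF weights, standardized by permutation moments, with
  phenotype-permutation p-values. Permutation replaces the analytic
  small-sample adjustment of the optimal kernel test: exact by
  construction at desk-scale cost, at the price of Monte-Carlo error
  (resolution 1/(n_perm + 1)).
* `mann_whitney_exact()` — full enumeration of all $\binom{n+m}{n}$
  labelings when $\min(n,m) \le 10$ (ties handled exactly by the
  enumeration), otherwise normal approximation with tie and continuity
  corrections.
* `chi_square_test()` — Pearson, no continuity correction, erroring on a
  zero expected count with advice to use the exact test.
* `classify_consequence()` — HGVS protein grammar: nonsense and
  frameshift → PTC; single-residue substitution → missense/synonymous;
  in-frame dup/del/ins → inframe_indel; unparseable → other + warning.
* `geometric_normalize()` — per-sample division by the geometric mean of
  the reference genes (multi-reference-gene qRT-PCR normalization).

## Problem sizes and what the tests show

The validation suite runs, per replicate, a 1.2 Mb genome with a 400 kb
inversion — the low end of a deliberate 10-fold scale-down of the 4 Mb
event, preserving the geometry (breakpoints far apart relative to both
insert size and read length) while keeping 20-replicate sweeps fast. At
30x short-read coverage, true breakpoints fall inside the reported
intervals in ≥ 95% of seeds and inversion-free replicates produce zero
calls; at 6x long-read coverage (the discovery depth) the consolidated
call contains the truth in ≥ 80% of seeds. LCR recovery uses 5 kb copies
at 98% identity, where the identity estimate lands within ±0.5 points and
endpoints within one seed length. The burden test's type-I error is
calibrated over 1000 null replicates of 400 samples × 8 rare variants at
2000 permutations each. These numbers are all recomputed — not asserted
from memory — by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`.

What passing does *not* show: robustness to alignment artifacts, indels,
multi-mapping inside the LCRs, population structure in the cohorts, or
recombination within the pedigree locus (explicit non-goals of the
generator).

## Worked example

```{r demo, eval = FALSE}
cfg <- scenario_config(seed = 5, genome_bp = 4e5, lcr_len_bp = 5000,
                       assoc_n_cases = 150, assoc_n_controls = 150,
                       assoc_n_perm = 1000)
res <- run_end_to_end(cfg)
dplyr::filter(res$calls, evidence == "both")
res$filter_report
generics::tidy(res$burden)
```

The demo recovers the planted inversion with both technologies merged into
a single `evidence = "both"` call, ends the filter cascade at the four
planted family-unique variants, and rejects the null for the planted
case/control scenario. The same pipeline with `inversion = FALSE` yields
zero calls while the variant stages still run.

## Known limitations

* One chromosome per genome; no translocations, duplications or deletions.
* The short-read caller does not genotype the inversion or assemble
  breakpoints; intervals are bounded by the insert-size upper bound.
* The burden test offers no covariate adjustment or kinship correction.
* Exact inversion spans flanked by near-identical LCRs are localized only
  to within the homology block in real data; the simulator's exact
  positions make the callers look sharper than alignment noise would
  allow.
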