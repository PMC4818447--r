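---
title: "Mapping a recessive defect: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive defect: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recessmap)
```

# The model

recessmap targets one specific and common situation in livestock
genetics: a rare, fully penetrant autosomal recessive defect descending
from a single founder.  Under that model,

- every affected animal is homozygous identical-by-descent for the
  founder's chromosome segment around the causal mutation (affected ⇔
  homozygous, exactly, before genotyping noise);
- unaffected animals carry zero or one copy of the founder haplotype;
  population-scale ascertainment makes homozygous unaffected animals
  effectively absent at the frequencies involved (~0.4 % haplotype
  frequency);
- the causal variant is private to the breed: it must not segregate in
  other populations.

Each pipeline stage is the statistical image of one of these
assumptions, and the package's simulator generates cohorts in which the
assumptions hold by construction, with configurable noise.

# Stage models and tunable parameters

## Array QC (`apply_qc`)

Thresholds (all strict, i.e. a marker *at* the boundary fails): MAF
> 0.005, exact HWE P > 1e-4, per-marker and per-individual call rate
> 0.95.  Individuals are filtered first, then marker statistics are
recomputed.  The HWE statistic is the exact conditional test on
heterozygote counts; by default **affected animals are excluded from the
HWE computation** (`hwe_include_affected = FALSE`): a case series
enriched for one homozygous genotype violates HWE at the mapped locus by
design, and including it would preferentially remove exactly the
informative markers.  Whether the original analyses included cases in
their HWE filter is generally unstated; the choice is exposed.

## Haplotype scan (`scan_genome`)

Window size 25 markers, step 2, haplotype frequency filter 0.5 %
(haplotypes at or below it are untested but still counted in
frequencies), α = 0.05.  Haplotype identity is the exact allele string —
no clustering of near-identical haplotypes, since no clustering rule is
standard.  The Bonferroni divisor is the total number of *tested
haplotypes summed over windows*, the construction that reproduces the
published threshold arithmetic (0.05 / 787,232 ≈ 6.35e-8).  The test is
the two-sided Fisher exact test on haplotype-copy counts, computed with
log-factorial arithmetic; the two-sidedness convention (sum of tables
with point probability ≤ observed) matches `stats::fisher.test`, and for
the extreme tables this application produces, one- and two-sided P
coincide (the opposite tail contributes no table with probability below
the observed one) — so the unstated sidedness choice of any particular
study is numerically irrelevant here.  Individuals with unknown
phenotype enter frequency estimation but not the 2×2 tables.  Haplotype
copies with a missing allele inside a window are dropped from that
window's tabulation (the pipeline consumes phased input; imputation is
deliberately out of scope).

## Autozygosity (`detect_roh`, `shared_case_segment`)

ROH detection is genotype-based (AA/BB vs AB), since autozygosity
mapping on array data is a statement about genotypes, not phase.
Defaults `min_markers = 20`, `max_het = 1`, `max_missing = 2`: no
standard exists, so these were chosen once such that a ~1.8-Mb
autozygous segment is recovered at the simulated ~50-kb marker density,
and all three are CLI-exposed.  Reported runs are *maximal* (extending
either end violates a constraint).  With `max_het > 0`, two maximal runs
can legitimately share flanking markers, so "non-overlapping" is not
enforced — this is exactly the output of the exhaustive
all-subintervals oracle the implementation is tested against.  Segment
bounds are the first/last marker positions (no midpoint extension).
The shared segment is the interval intersection of the per-case ROH
unions; an empty intersection is a reported outcome, not an error.

## Recessive filtering (`recessive_compatibility_filter`)

A variant passes iff every case is hom-alt, every obligate carrier het,
every control hom-ref.  Missing genotypes in decisive samples fail the
variant in the default strict mode; a lenient mode (ignore missing) is
flag-selectable because published filter descriptions rarely state their
missing-data handling.  Multi-allelic records are decomposed upstream;
indels are left-aligned and parsimony-trimmed before comparison, so
3'-anchored descriptions of a homopolymer deletion normalize to the same
record.  Panel exclusion removes any candidate whose alternate allele is
observed in any panel genotype; candidates absent from panel data are
retained but labelled "untested".  Deep-intronic survivors are
deprioritized at `splice_distance_max = 4000` bp — a named constant, on
the reasoning that an intronic variant several kb from the nearest
splice site has no plausible molecular mechanism relative to a coding
frameshift competitor.

## Consequence engine

Variants are applied to the spliced CDS and translated with the
standard genetic code to the first stop.  HGVS frameshift naming counts
the termination codon with the first changed residue as 1
(`p.Glu1430LysfsTer66` ⇒ stop codon at overall residue
1430 + 66 − 1 = 1495, mutant length 1494, i.e. 745 of 2239 residues
lost).  Note that a stop "at position 1496" is inconsistent with both
fsTer66 and a 745-residue truncation under this convention; the
HGVS-consistent arithmetic is used throughout and the record exposes
`stop_residue` explicitly, so the off-by-one ambiguity of prose
descriptions never enters the computation.  A mutant protein that is a
clean prefix of the wild type is named as simple nonsense
(`p.Thr4Ter`), a distinct branch from frameshift naming.  Translation
running off the transcript end is flagged `runoff` with truncation
statistics undefined.  In-silico RT-PCR is exact-match only — no
mismatch tolerance or thermodynamics — which suffices for validating
primer logic on known transcripts; all (forward, reverse) site pairs
are enumerated.

## Population statistics

LD r² is computed from phased haplotype copies
(r² = D²/(p_A q_A p_B q_B)); genotype-based composite-LD estimation is
deliberately not offered, because it would add an estimator whose
correspondence to any published r² cannot be verified.  Monomorphic loci
give NA (flagged), never 0.  Haplotype frequencies are reported at full
precision; rounding is a display concern (81/20908 = 0.387 %, which some
reports truncate to 0.38 %).  `expected_homozygous_births(q, N) = q²N`
is the random-mating Hardy–Weinberg expectation.

# The synthetic world

`simulation_config()` states the emulated cohort once:

- 27 affected paternal half-sib analogues, all homozygous for a planted
  founder haplotype spanning 14.88–16.73 Mb of chromosome "3" with the
  causal 1-bp deletion at 15,079,217;
- 2,000 controls (the real cohort's 10,454 scaled down for runtime — a
  scale, not a structure change) carrying the haplotype at 0.4 %
  frequency, never homozygous;
- 5 chromosomes × 400 markers at ~50 kb spacing (≈ 50k-array density
  over a reduced genome), background MAF uniform in [0.05, 0.5], markers
  independent: the planted haplotype supplies the only long-range LD.
  This is sufficient to exercise window scanning and ROH detection, and
  is *not* a model of real LD decay — marker geometry is a stand-in,
  never a calibration target;
- genotyping error 0.001 per call (symmetric single-allele flip) and
  missingness 0.005 per call, typical array rates, injected only after
  the truth phase is recorded;
- a sequence cohort of 1 case + 1 obligate carrier + 288 controls and a
  1005-animal multi-breed panel; 9 compatible decoy variants of which
  8/9 segregate in the panel — so the default world reproduces the
  canonical narrowing 10 compatible → 2 after panel exclusion → 1 after
  deep-intronic triage; plus 40 ordinary polymorphisms that fail the
  compatibility conditions.

What a green test establishes: that the inference chain recovers a
planted truth under the stated noise in a world whose LD structure is
trivial outside the founder segment.  What it does not establish:
robustness to real LD, imputation error, relatedness-induced inflation
(no kinship correction is applied, matching the mapped design where
extreme relatedness among cases is expected), or structural-variant
breakpoint uncertainty.

The engineered gene fixture is constructed, not asserted: a 31-exon,
2239-codon CDS in which codon 1429 is a CCC homopolymer, codon 1430 GAA
(Glu), and the downstream codons are designed so the −1 frame is
stop-free for exactly 65 shifted codons with a stop as the 66th; the
intron after the deletion exon begins GTG·TAA so that, with the deletion
applied, retention terminates translation at residue 1492; primers
placed in the flanking exons give a 348-bp spliced product.  Every one
of these properties is verified in tests by splicing and translating
the actual sequence, including a reverse-complement mirror of the whole
locus (minus-strand round trip).  One published number is intentionally
not matched: the retained-intron RT-PCR product is 1487 bp here (348 −
1-bp deletion + 1140-bp intron) where the original gel/sequence estimate
was 1488 bp — the 1-bp difference is the deletion itself, which the gel
cannot resolve.

# Numerical choices

- Fisher exact and HWE tests accumulate in log space; ties at the
  observed probability are included with a 1 + 1e-7 relative tolerance
  (the same convention as `stats::fisher.test`), and `log10p` stays
  finite far below double underflow.
- Scan ranking uses `log10p`; ties break by (chromosome, window start).
- Degenerate tables (any zero margin) return P = 1; an all-missing
  marker has call rate 0 and undefined MAF/HWE and fails QC with the
  call-rate reason.
- Window haplotypes are encoded as 25-bit integer keys (exact in
  doubles); allele strings are materialized lazily for tested
  haplotypes only.
- The pipeline config file is JSON (schema-checked, unknown keys are
  errors) rather than an INI dialect: the stage configs nest naturally
  and jsonlite is already a dependency.

# Limitations

Beagle-style phasing/imputation, read alignment, variant calling, SV
discovery and full consequence ontologies are out of scope by design:
the pipeline consumes phased haplotypes and called genotypes.  The
simulator does not model pedigree-realistic LD, sequencing reads or
imputation error.  Real-data coordinates that depend on a specific
genotype archive (post-QC SNP counts, regional variant counts,
population frequency trajectories) are not reproduction targets.
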