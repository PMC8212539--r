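---
title: "Detecting off-target and de novo mutations in cloned, gene-edited animals"
author: "clonemut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting off-target and de novo mutations in cloned, gene-edited animals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemut)
```

## The problem and the study design

CRISPR-Cas9 editing of livestock raises the question of whether the
nuclease induces mutations away from its intended target. The difficulty is
that cells accumulate spontaneous de novo mutations anyway, so any claim
about off-target mutagenesis must separate editing-induced changes from the
background of culture- and development-acquired variation.

A clone-based design makes this separation tractable. All samples descend
from one parental fibroblast line; an edited cell clone is isolated from
transfected cells, and cloned animals are produced by somatic cell nuclear
transfer from both the edited clone and the unedited parental line. Because
every genome is a clonal copy of the same founder, any variant present in
one sample but explicitly absent in the others is a candidate de novo
event, and its sharing pattern across the lineage dates it:

* **post-transfection** -- heterozygous in the edited cell line *and* in
  both animals cloned from it, absent everywhere else: the mutation existed
  in the transfected cell before the clonal bottleneck, alongside any true
  off-target event;
* **culture expansion** -- heterozygous and unique to a single cloned
  animal (it arose in that animal's donor cell during culture), or mosaic
  in the edited cell line;
* **calf development** -- mosaic (allele dosage well below 0.5) in a single
  cloned animal: it arose after that animal's first embryonic cell
  division, so only a fraction of its cells carry it.

`clonemut` implements this analysis as a reusable pipeline: reading
multi-sample variant calls, the staged presence/absence filter cascade, the
allele-dosage classification, guide-homology off-target scanning, mutation
spectra, and the group statistics, plus a fully truth-labelled simulator so
every stage can be tested without access to the original sequencing data.

## Genotype encoding and the filter cascade

Genotypes are dummy coded per alternate allele: 0 = no coverage, 1 =
homozygous reference, 2 = heterozygous, 3 = homozygous alternate.
Multi-allelic records are split into one row per alternate allele (the
cascade and the dosage test are per-allele decisions), with allele depths
subset accordingly. Phase is ignored.

The cascade applies, in order: removal of sites monomorphic across all
samples (no inter-sample information), removal of sites with no coverage in
the parental line (no baseline to call a variant de novo against), removal
of variants segregating in a large unrelated population (matched exactly on
chromosome, position, reference and alternate allele), presence/absence
selection for the branch in question, and a site-level mapping-quality
filter. Three conventions matter and are deliberately fail-closed:

* "absent" always means an explicit homozygous-reference call, never a
  missing genotype;
* missing MQ fails the MQ filter; the filter is `MQ >= 60` by default with
  a strict-equality mode (`filter_mapq(strict_equal = TRUE)`), since RMS
  mapping quality below 60 indicates non-unique alignment in common
  aligners while values above it are legitimate;
* ambiguous bases never satisfy a pattern position in the guide scanner.

The original analysis included a manual read-level review step. Manual
review is not reproducible, so `annotate_candidates()` replaces it with
automated proxy flags -- proximity to a candidate indel (< 10 bp), a
homopolymer run of at least 6 bp within 10 bp of the site, coincidence with
a call discarded in another sample. Flags annotate rather than remove;
`strict = TRUE` in `run_pipeline()` excludes flagged sites from the
"likely" counts, emulating the effect of review.

## The allele-dosage test

At a truly heterozygous site the alternate read count is Binomial(n, 0.5).
`binomial_lower_p(x, n)` computes the exact lower tail by term-by-term
log-space summation of the probability mass function (accurate for depths
of at least 10,000, and within 1e-12 relative of the reference
distribution function for n up to 200 -- this is asserted against
independent oracles in the test suite). A heterozygous call whose lower-tail
p-value falls below the Bonferroni-corrected level is labelled **mosaic**;
otherwise it is a genuine heterozygous variant. At 60x depth a 10:50
alt:ref site gives p = 8.1e-8, far below 0.05/457, and is classified
mosaic:

```{r}
classify_dosage(10, 50, 2L, test_config(m = 457))
```

The test is one-sided (lower tail) because mosaicism specifically means
dosage *below* 0.5; a two-sided option (`test_config(two_sided = TRUE)`)
exists for the "statistically equivalent to 0.5" phrasing used when
filtering off-target candidates. Homozygous-alternate calls are checked for
consistency with dosage 1 under a per-read error rate (default 0.01):
too many reference reads labels the call `inconsistent` rather than
silently passing it.

**Bonferroni family size.** `run_pipeline()` sets m to the number of
dosage tests performed in the branch, following the family-wise logic of
the original filter (457 tests in the off-target branch there). The
standalone default in `test_config()` is m = 1: a single site examined in
isolation is one test. This distinction has real consequences: at depth
50--60x and dosages uniform in (0.1, 0.35), the one-sided exact test at the
nominal 0.05 level detects about 95% of mosaics, whereas a family-wise
threshold of 0.05/500 detects only about 60% -- dosages near 0.35 are simply
not separable from 0.5 at 55x under a 1e-4 threshold. Both numbers follow
from the binomial power function; the package exposes m so the caller
chooses the error-control regime, and the simulator's recovery tests
measure classification accuracy in the standalone regime.

## Group statistics

Pairwise comparisons of per-animal mutation counts use a pooled
two-proportion z-test with continuity correction
(`two_proportion_test()`), with the number of filtered variants entering
the classification (31,190 in the published study) as the common
denominator. With the published per-calf counts this choice reproduces all
twenty printed pairwise p-values to two significant figures, which is how
the denominator convention was validated (the test suite cross-checks the
implementation against `prop.test`, which implements the equivalent
Yates-corrected chi-square).

Spectrum comparisons use an exact conditional test on the 2 x k table of
one substitution class versus the rest across k groups
(`fisher_exact_2xk()`): full enumeration of all tables with the observed
margins, summing multivariate hypergeometric probabilities of tables no
more probable than the observed one. Ties are included at relative
tolerance 1e-12 -- tables whose probability equals the observed table's up
to floating-point noise count as "as extreme", which matches the
convention of the classical two-sided Fisher test. Per-class p-values are
reported raw by default (mirroring how such scans are usually reported); a
`p.adjust` method can be requested.

## Guide-homology scanning

`scan_genome()` scans every position of both strands for matches to the
20-nt protospacer within a mismatch budget (default 5), gated by an
adjacent IUPAC PAM pattern (default NGG) as a hard constraint -- PAM bases
are never counted as mismatches, and bulges are not modelled. Mismatch
positions are numbered from the PAM-distal end, where mismatches are most
tolerated by the nuclease. Ambiguous genome bases count as mismatches in
the protospacer window and fail every PAM position; this fail-closed choice
can shift site counts slightly relative to tools that skip ambiguous
stretches, and is therefore stated here rather than buried. Candidate
mutations are matched to predicted sites within a +/- 50 bp window
(`match_candidates()`, distance zero inside the protospacer+PAM span), and
`flank_homology()` exhaustively aligns the protospacer across the +/- 75 bp
flank of any candidate to find the best PAM-adjacent and best
unconstrained alignments, with deterministic tie-breaking (smaller
coordinate, then + strand).

Correctness of the scanner is defined solely by equivalence with a naive
character-by-character oracle, asserted over seeded random genomes and over
simulator-planted degenerate sites; matching is exact string comparison
after `Biostrings` narrows the candidate positions.

## The simulator and what passing tests mean

`simulate_reference()` plants the on-target protospacer+PAM exactly once
in a random genome, plus any requested degenerate copies at specified
mismatch counts on random strands. `simulate_study()` then builds the
seven-sample call set along the clonal lineage. Defaults are the study
conditions, not tuning knobs:

| parameter | default | basis |
|---|---|---|
| `mu_per_doubling`, `mu_sd` | 3.5, 0.5 | reported accumulation rate per population doubling in cultured cells |
| `doublings_pre_split`, `doublings_post_split` | 20, 20 | the ~20 doublings needed to expand a single doublet to confluency |
| `mean_depth` | 50 | the ~50x mean mapped depth of the study |
| `mosaic_dosage_range` | (0.1, 0.35) | the dosage band in which mosaics are both plausible and detectable |
| `calf_mosaic_mean` | 10 | order of the per-animal mosaic counts observed |
| `error_rate` | 0.005 | typical short-read per-base error after filtering |

Stable germline variants are shared by all samples (and are therefore
monomorphic in the dummy coding); a configurable fraction is
population-shared and lands in the blacklist. Unstable background sites
model caller noise in repetitive regions: blacklisted ones keep MQ 60, the
rest get low MQ, so the population and MQ filters each have planted work to
do. Depths are Poisson (optionally negative-binomial) around `mean_depth`,
alternate counts Binomial at the true dosage with per-read miscalls, and
genotype codes come from a maximum-likelihood call over the three genotype
hypotheses -- so, as with a real caller, low-dosage mosaics are sometimes
genotyped homozygous reference and drop out before the dosage test ever
sees them. `error_rate = 0` instead selects an idealised noise-free mode
(deterministic depth and counts, truth-derived codes); this is the regime
in which the cascade provably recovers the planted non-germline set
exactly, and the tests assert exactly that. Mosaic dosages are drawn
uniformly over `mosaic_dosage_range` because only the classification rule,
not the dosage distribution, is constrained by the source analysis.

The simulator also emits read-level co-observation tables for each planted
mosaic: reads split evenly between parental haplotypes, with the mosaic
allele riding on one of them, mixed with a 1% random-assignment error.
`three_haplotype_support()` calls a candidate supported when exactly three
of the four (candidate allele x linked-site allele) combinations exceed a
noise floor (default 2% of reads, minimum 10 reads for decidability);
all four combinations present implies an artifact or two independent
events. The original analysis performed this check manually and reports
confirmed fractions without stating a threshold, so these two thresholds
are this package's own documented choices and no attempt is made to match
those fractions.

What the simulator does *not* emulate is worth stating: alignment artifacts
with positionally correlated errors, indel realignment ambiguity,
GC-dependent coverage, structural variation, and linked selection during
culture. Passing recovery tests therefore demonstrates the correctness of
the filtering and classification logic under the stated statistical model,
not robustness of variant calling on real reads -- upstream calling is out
of scope by design.

## Numerical and problem-size choices

Tolerances: binomial tail oracle agreement at 1e-12 relative (n <= 200);
Fisher enumeration tie tolerance 1e-12 relative; z-test agreement with the
Yates-corrected chi-square at 1e-9. Degenerate inputs have defined
behaviour rather than errors where a value is meaningful: pooled
proportions of 0 or 1 give p = 1 with a degenerate flag, zero margins give
p = 1, zero-depth dosage calls are `inconsistent` with a warning, and an
empty variant table flows through the whole pipeline producing zero counts.

The test suite and the acceptance script run simulations at genome sizes
of 10--100 kb with 2--3 contigs, 20 scanner-oracle genomes, 500 dosage
instances and 200 spectra replicates. These sizes were chosen so the full
statistical behaviour (recovery, power, oracle equivalence) is exercised
with comfortable margins while a complete run stays in the tens of
seconds; all counts scale linearly if larger studies are simulated.

## Known limitations

* The pipeline consumes VCFs; it does not realign reads or re-genotype,
  so its verdicts inherit upstream caller behaviour.
* The off-target scanner does not model DNA/RNA bulges or activity scores;
  it is a pure sequence-similarity search.
* Stage attribution follows the lineage rules literally; sites with
  conflicting evidence (for example heterozygous in the edited line but
  mosaic in an animal) are left unassigned with a warning rather than
  resolved by a heuristic.
* The three-haplotype check consumes co-observation counts; building those
  counts from a BAM is left to a thin adapter outside the package core, so
  the core stays testable from the simulator alone.
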