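---
title: "Methods: multiplexed CRISPR-Cas9 screen design and analysis with multiguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed CRISPR-Cas9 screen design and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiguide)
```

## Overview

`multiguide` implements the computational side of a multiplexed
CRISPR-Cas9 knockout workflow in zebrafish: several guide RNAs are
co-injected with Cas9 mRNA into one-cell embryos, founders are raised
and genotyped by Sanger sequencing, and homozygous mutants are screened
with a fast behavioral readout (the acoustic C-start startle response)
followed by hair-cell staining. The package covers five computational
stages:

1. **Guide selection** — scanning exon sequence for protospacers.
2. **Template assembly** — building each guide's T7 transcription
   template and decomposing it into six synthesisable oligos whose
   sticky ends force a unique ligation order.
3. **Indel calling** — classifying Sanger-resolved mutant alleles.
4. **Cohort summary** — founder-screen efficiency and mutation-spectrum
   statistics.
5. **Phenotype statistics** — latency-gated C-start response rates,
   group comparisons, and intensity/count summaries, with matched
   synthetic-data generators.

## Guide selection

A candidate target is a 23-nt window whose sequence starts `GG` and ends
`NGG`. The two constraints serve different masters: the `NGG` suffix is
the Cas9 protospacer-adjacent motif (PAM), required for cleavage, while
the `GG` prefix is required by the T7 polymerase for efficient
transcription initiation, because the spacer is transcribed directly
from the template with no extra 5' bases. `findTargets()` scans every
window on the forward strand and, by default, the reverse complement.
Windows containing `N` are skipped: the PAM rule is undefined on an
ambiguous base, and a guide containing `N` cannot be synthesised.
Coordinates are 0-based half-open on the forward strand; minus-strand
hits report their sequence in target-strand orientation. Overlapping
and nested hits are all reported — deduplication is a presentation
concern, and no exclusion rule is part of the selection criterion.

`rankTargets()` orders candidates by absolute distance between the hit
start and the coding-sequence start. Indels near the N-terminus of the
coding sequence are most likely to produce early premature stop codons,
the intended loss-of-function outcome. Ties break `+` strand first,
then lower coordinate — an arbitrary but documented and stable rule.
`maskVariants()` removes candidates overlapping user-supplied variant
positions (known SNPs can abolish guide binding); it takes a plain
position list rather than a VCF to keep the dependency surface small.

## Template assembly

`buildTemplate()` concatenates three blocks:

| block | length | content |
|---|---|---|
| T7 promoter | 21 nt | `AATTTAATACGACTCACTATA` |
| spacer region | 23 nt (or 20) | the target; PAM kept by default |
| scaffold | 81 nt | constant single-guide scaffold |

for a 125-nt template (122 without the PAM). Keeping the PAM inside the
transcribed spacer is unusual for sgRNA design, but it is what the
published template pattern specifies, so `includePAM = TRUE` is the
default and the conventional PAM-free variant is an explicit option.
The ~120-bp figure sometimes quoted for such templates is the rounded
value; the exact length from the pattern is 125 nt.

`splitTemplate()` decomposes the template into three double-stranded
fragments built from six oligos (38–46 nt), joined at two sticky
junctions. The solver enumerates top- and bottom-strand cut positions
subject to:

* all six oligo lengths within 38–46 nt — short enough that chemical
  synthesis errors stay rare, long enough for stable annealing;
* every target-dependent base inside fragment 1. Note the truly
  variable region is template positions 23–41: the spacer's leading
  `GG` and the PAM's trailing `GG` are fixed by the selection rule, so
  junction 1 may legally sit inside the PAM's constant `GG`. This is
  what makes a new guide cost only two fresh oligos — fragments 2 and 3
  are byte-identical across guides;
* blunt, non-ligating outer ends;
* admissible junction overhangs: the two overhangs must be distinct,
  non-self-complementary (a palindromic overhang can dimerise and
  circularise), and not reverse complements of each other (which would
  enable wrong-order joins). These are the minimal conditions that make
  the ligation order unique and suppress circular products.

Among admissible splits the solver picks the one with the most balanced
oligo lengths, with ties resolved by scan order — fully deterministic,
no seed. The default overhang is 4 nt (the standard length for ordered
ligation; the original protocol does not print its overhangs, so the
constraint set above is derived from the stated design goals).
Overhangs of 3 and 5 nt are supported; note that a 5-nt overhang is
infeasible on the 125-nt PAM-keeping template because fragment-1 oligos
would have to exceed 46 nt, and the solver reports this rather than
bending a constraint. Melting-temperature optimisation and secondary
structure are out of scope.

`simulateLigation()` is the verifier implied by the design claims: it
exhaustively joins fragments (each usable once per product, both
orientations) wherever sticky ends are complementary with matching
protrusion sides, blunt ends never ligate, and it reports all maximal
linear products plus every possible circular closure. For a valid
design it must return exactly one product: the full-length linear
template. The reported sequence of a linear product is the
lexicographically larger of the two strands, so the output is
independent of fragment input order (a double-stranded molecule has no
intrinsic "top" strand).

```{r assembly}
tpl <- buildTemplate("GGTGTAGATTCGGGGAGAGGAGG", gene = "tmem183a")
os <- splitTemplate(tpl)
oligos(os)[, c("name", "length", "fragment", "variable_per_target")]
simulateLigation(os)[, c("topology", "n_fragments", "length")]
```

## Indel calling

`callEvent()` compares one Sanger-resolved allele to wild type and
extracts **one edit region per allele**: the longest common prefix and
suffix are trimmed, remaining wild-type bases are the deletion
component and remaining allele bases the insertion component. This is
exactly the convention of founder-screen tables — a deletion is written
`-8`, a combined event `+2 (-5, +7)` (net first, components
parenthesised only when both are present) — and the event is placed
directly after the longest common prefix, which is where published
alignments place it. Classification is a pure function
(`classifyNet()`): *complex* iff both components are present,
*frameshift* iff the net change is not a multiple of 3. Equal-length
alleles are block substitutions at the sequence level; they are
reported position-wise in a side channel with class `none`, because
indel screens record only length-changing events.

A global affine-gap aligner (`alignAllele()`; match +1, mismatch −2,
gap open −5, extension −1, via `Biostrings::pairwiseAlignment()`) is
provided for inspecting alignments, and its scores are verified against
an independent dynamic-programming oracle in the test suite. The event
caller deliberately does not use alignment gap placement: under any
affine scoring with these magnitudes, a deletion-plus-insertion region
scores worse than the mismatch-heavy alignment of the same pair, so
gap-run extraction would demote published complex alleles (e.g.
`+2 (-5, +7)`) to short insertions plus scattered substitutions.
Prefix/suffix trimming reproduces the published annotation for every
printed allele and recovers all planted events in the round-trip tests.

The single-edit-region model matches the data-generating process (one
repair event at one cut site, resolved from one Sanger trace). Its
known limitation: an allele carrying several widely separated edits is
summarised as one spanning event; net length change remains exact, but
component bookkeeping merges. Mosaic founder trace deconvolution is out
of scope — input is one resolved allele per fish and gene.

```{r indel}
ev <- callEvent("GGATGTCCCTTGAGAACGGGAGGGTGTCGCTG",
                "GGATGTCCCTTGAGAAGGAGGGTGGGTGTCGCTG", gene = "gabbr1a")
ev
```

## Cohort summary

`summarizeCohort()` turns a fish-by-gene matrix of event labels into
the screening statistics. Two denominators are deliberately
distinguished, because mixing them is a common source of irreproducible
percentages:

* the **event**-class distribution (deletion/insertion/complex shares)
  counts every called cell — the same allele found in two fish counts
  twice;
* the **type**-level frameshift fraction counts each distinct
  (gene, label) pair once.

Both are labelled explicitly in the output. On the bundled six-founder
example these denominators are 10 events and 8 types, giving the
60/30/10 class split and the 87.5% frameshift fraction. Per-gene
efficiencies are reported at 2 decimals; the mean is additionally
reported integer-rounded, the precision at which such screens are
usually quoted.

## Phenotype statistics

`scoreTrials()` applies the response definition: a trial is a response
iff a latency was recorded and is at or below the cutoff (default
25 ms, inclusive — "within 25 ms" includes the boundary; 0 ms is a
legal latency, which is why "no response" is encoded as an empty field,
never 0). The per-fish rate is responses over trials delivered, and the
group rate is the unweighted mean of per-fish rates: the fish is the
independent unit. `compareGroups()` compares per-fish rates with
Welch's t-test by default — the safer choice when group variances may
differ and the behaviour of the original point-and-click analysis is
unknown — with Student's t and a label-permutation test (two-sided,
+1-smoothed) as alternatives, and `comparePooledTrials()` as a
pooled-trial chi-square sensitivity check. Degenerate zero-variance
comparisons return p = 1 at equal means.

`relativeIntensity()` reports mutant staining as percent of the control
mean (scale-free) and `countSummary()` reports group means of integer
counts at 2 decimals, each with a Welch test on raw values.

## Synthetic-data generators

Every stochastic generator takes an explicit seed, uses it locally, and
restores the caller's RNG state; identical seeds give identical
fixtures.

* `synthExon()` plants `GG…N18…NGG` motifs at known positions and
  strands and, in collision-free mode, resamples until a scan finds
  nothing else, so the planted coordinates are complete ground truth.
* `synthAlleles()` plants one deletion-plus-insertion edit inside the
  target window, emulating repair at a cut site, and returns the
  ground-truth event constructed directly from the edit (never via the
  caller). Inserted bases are resampled so the first/last inserted base
  differs from the first/last deleted base: without that, the planted
  event is genuinely ambiguous at the sequence level and no caller
  could recover it. Recovery tests compare net change, class, label and
  frameshift, not coordinates — indel position within a repeat run is
  not identifiable from sequence alone.
* `simulateCstartTrials()` draws independent Bernoulli trials per fish
  at the group rate; 48 fish by 10 trials per arm are the default study
  conditions used in the tests, and the wild-type, mutant-line and
  null-comparison rates (0.6854, 0.4354, equal-rate controls) are the
  published screen's operating points. Responding trials get latencies
  uniform on 8–22 ms, well inside the gate; that distribution carries
  no scientific claim beyond "typical short-latency startle". An
  optional Beta-distributed per-fish rate (off by default) documents
  the exchangeability assumption the t-test makes: real fish are
  heterogeneous, and the homogeneous default is the idealised case.
* `simulateIntensity()` and `simulateCounts()` draw Gaussian
  intensities (control mean 100, SD 10 — a 10% coefficient of
  variation, typical of averaged fluorescence readouts) and rounded
  zero-truncated Gaussian counts (SD 2 count units around means of
  7–10). The published figures do not state the error model behind
  their error bars, so these SDs are plausibility choices fixed once;
  the recovery tests and acceptance script measure how well the
  pipeline re-estimates the generating parameters (ratio 64.66%,
  means 10.4 and 7.34) under them.

What passing these tests shows — and does not show. The generators
emulate idealised versions of the real data: planted motifs in random
background (not real exon composition), single clean edits (no mosaic
mixtures or trace noise), independent Bernoulli responses (no
habituation across the 10 pulses, no session effects), Gaussian
intensities (no segmentation artefacts). Green tests demonstrate that
the algorithms are correct on data matching their stated assumptions
and that the statistical procedures have the advertised operating
characteristics (power ≈ 100% at the published effect size; type-I
error within [0.03, 0.07] at α = 0.05); they do not certify performance
on raw traces or videos, which the package does not ingest.

## Numerical and design choices

* Problem sizes in the routine test run: 500 allele round-trips, 30
  scanner-oracle sequences, 50 reassembly targets, 12 ligation-oracle
  systems, 200 power replicates, 1000 null replicates, 100 recovery
  seeds each for intensity and counts — sizes chosen so the whole suite
  completes in under a minute on one core while keeping Monte-Carlo
  error far from every decision threshold.
* Acceptance thresholds for stochastic properties are set analytically
  before measurement: e.g. the count-recovery band (both means within
  ±0.8) has per-seed success ≈ 0.96 under the generator, so the test
  requires ≥ 0.90 of 100 seeds, > 3 binomial SDs below the mean.
* Under pure Bernoulli sampling at the published conditions the SE of a
  group mean rate is ≈ 2.1 points, so single-seed rate recovery is only
  checked loosely; the sharp test is that the average over 200 seeds
  lands within 1 point of the generating rate.
* All percentages are rounded only at the reporting edge (2 decimals,
  plus integer for the quoted mean efficiency); internal arithmetic is
  unrounded.
* `parseLabel()` validates component/net consistency, so a cohort table
  with a typo (e.g. `+2 (-2, +5)`) fails loudly at construction.

## Limitations

* No on-/off-target activity scoring and no genome-wide off-target
  search; these belong to dedicated external tools.
* No chromatogram (.ab1) parsing or mosaic trace deconvolution; inputs
  are resolved allele sequences.
* No FASTQ/SAM/VCF ingestion; variant masking takes a position list.
* The ligation model is combinatorial (complementarity only): no
  thermodynamics, no partial-mismatch annealing, blunt ligation
  disabled by design.
* C-start kinematics (video analysis) and image quantification are
  upstream of the package; it consumes their tabular outputs.
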