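---
title: "Termination-window analysis: model, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Termination-window analysis: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termwindow)
```

## The problem

In *S. cerevisiae*, Pol II terminates transcription by two routes: the
poly(A)-site (PAS)/cleavage route of mRNA 3' ends, and the NNS/NRD route
(Nrd1–Nab3–Sen1) that terminates short noncoding units — snoRNA, CUTs,
SUTs, XUTs — and attenuates a set of protein-coding (NAPC) genes near their
5' ends. NRD terminators combine a proximal Nrd1-binding site (NBS) with
more efficient distal elements; because release requires termination
factors to catch the elongating polymerase, slow transcription widens the
"termination window" while fast transcription (e.g. growth at 37 °C)
pushes termination downstream. Termination mutants leave Pol II reading
through these terminators, and the defect is visible in coverage tracks as
elevated signal downstream of the terminator relative to wild type.

`termwindow` packages the genomic side of such a study: readthrough
classification, cohort metagenes and heat maps, factor peak-shift
statistics, set/proportion statistics, amplicon quantification — plus a
mechanistic simulator that generates all inputs with planted ground truth,
so that every analysis stage has a recoverable answer.

## The occupancy model

A transcription unit is modelled as a 1-nt lattice from its TSS through a
downstream flank (default 1000 nt). A polymerase initiates at the TSS at
rate `init_rate` and, at each position `x`, terminates with per-nt hazard
`h(x)`. The expected occupancy density is

```
density(x) = init_rate * S(x) * dwell(x),     S(x) = prod_{i<x} (1 - h(i))
```

`S(x)` is the survival function of the hazard process; `dwell(x)` is the
local residence time, `1/speed` scaled by a pause multiplier where
pausing applies. Both terms matter: termination removes polymerases
(density decays past hazard elements), pausing concentrates them (density
piles up where dwell is long) — together they reproduce the two
qualitatively different mutant phenotypes, plain readthrough
(*nrd1*-like) versus readthrough with downstream pile-up (*sen1*-like).

Hazard elements, with offsets relative to a class-specific terminator
anchor (snoRNA mature 3' end; a point ~350 nt before the annotated end of
CUT/SUT/XUT units; ~150 nt past the TSS of NAPC genes):

| element  | window (nt)    | per-nt hazard | cumulative hazard |
|----------|----------------|---------------|-------------------|
| proximal NBS | [-20, +40) | 0.008         | ~0.48             |
| distal       | [+150, +350) | 0.006       | ~1.20             |
| PAS (optional) | [+430, +460) | 0.03      | ~0.91             |

The proximal window is placed so the NBS center sits at +10, matching the
observed Nrd1 recruitment maximum between −20 and +40 around snoRNA mature
3' ends; the distal window carries most of the terminator strength,
consistent with distal NRD elements being the more efficient terminators.
With these defaults, wild-type survival past the full terminator zone is
`exp(-2.6) ≈ 0.08`: ~92 % of polymerases terminate within the window.

**Temperature.** Hazards are specified per unit time at the base speed and
converted to per-nt hazards via the speed: at 37 °C the speed is multiplied
by `temp37_speed_mult` (default 1.5, a moderate rate increase for elevated
temperature) and per-nt hazards become `1 - (1 - h)^(1/1.5)`. Faster
polymerase sees less exposure per nt, so `S(x)` decays more slowly and the
position where survival crosses 0.5 moves strictly downstream — the 37 °C
termination shift falls out of the model rather than being painted on.

**Pausing.** The pause zone ([+60, +460) from the anchor by default)
multiplies dwell only, not hazard. A physically stricter model would also
scale hazard exposure with dwell; we keep the two axes orthogonal so that
genotype tables can state "terminator weakened" and "polymerase pauses"
independently — the phenotypes of interest are combinations of exactly
these two dials.

## Genotypes and planted truth

A genotype is a row of multipliers: proximal hazard, distal hazard, PAS
hazard, pause dwell, Ser2-P amplitude. The shipped table
(`default_genotypes()`) encodes the qualitative phenotypes of the classic
alleles: CID-compromised *pcf11* alleles lose most distal NNS-terminator
activity and Ser2-P; the cleavage-defective allele (*pcf11-2*) loses PAS
activity only; *sen1-1* combines a terminator defect with strong (5×)
downstream pausing; *nrd1-102*/*nab3-11* weaken the proximal element. The
numbers are stated once as the simulator's world — they are not fitted to
any dataset, and tests recover *planted* truth, never published values.

Not every unit responds to a mutant: per class, exactly
`round(defect_prob * n)` units are planted responsive (defaults 0.75 /
0.65 / 0.70 / 0.70 / 0.73 for snoRNA / CUT / SUT / XUT / NAPC, chosen in
the realistic range for NNS-dependent classes). Only responsive units have
the genotype multipliers applied. A unit is *planted defective* for a
genotype when its modified terminator-zone cumulative hazard falls below
`defect_fraction` (default 0.5) of the wild-type value; the flag, the
modified cumulative hazards and the closed-form expected readthrough
(survival past the distal window) are emitted as the truth table.

One deliberate edge: a responsive unit carrying *only* the proximal
element under a genotype with proximal multiplier 0.5 sits exactly at the
0.5 cumulative-hazard boundary (convexity of `-log(1-h)` tips the flag to
"defective" by a float-level margin) while its physical readthrough change
is ~1.2× and not meaningfully detectable. We left this case in the stated
world rather than nudging parameters around it; it is rare (units lacking
both distal element and PAS) and absent from the acceptance cohorts, which
plant distal elements on every unit.

**Noise.** Tracks are per-base Poisson counts around
`depth * density + background` (depth 30, background 0.2 counts/nt by
default — a uniformly covered toy genome with plateau coverage ~30× and a
low nonspecific floor). Poisson is the minimal count-noise model with
variance tied to the mean; it deliberately omits overdispersion,
mappability structure, fragment-length smearing and input biases of real
ChIP-seq. Factor tracks are Gaussian recruitment kernels — Nrd1 centered
on the NBS (σ 60 nt), Pcf11 140 nt downstream of it (σ 80 nt) — and the
CTD-mark tracks modulate the Pol II profile (Ser5-P decays from the TSS
with τ = 500 nt; Ser2-P rises with τ = 800 nt and is scaled by the
genotype's Ser2-P multiplier). A green recovery test therefore
establishes that the pipeline inverts *this* generative model at realistic
signal-to-noise — not that it is robust to every artefact of real data.

## The readthrough index

For a mutant-vs-WT contrast the per-unit index is

```
RI = (D_mut / R_mut) / (D_wt / R_wt)
```

with `D` the mean 220-nt-smoothed signal in the class's downstream window
and `R` in its reference window (unit 5' end to the anchor). Windows
(relative to the anchor): snoRNA [+150, +650); CUT/SUT/XUT and NAPC
[+100, +600), NAPC clipped to the gene end. These sit past the distal
terminator and the Pcf11 recruitment maximum, so wild-type signal there is
mostly terminated. The inner ratios cancel expression differences between
strains; denominators are floored at a pseudocount (10⁻⁶ of the track
mean). RI is invariant under common track scaling and equivariant under
scaling of the mutant downstream signal.

A unit is called defective when `RI >= 1.5` *and* the absolute increase
`D_mut - D_wt` reaches twice the background estimate. The threshold is a
design choice: 1.5 asks for a 50 % relative gain in terminated-region
signal, large against Poisson noise at plateau coverage but permissive
enough to catch partially penetrant defects; the absolute guard stops
large ratios of near-zero signals. A unit-level Poisson rate-ratio test
would be a stricter alternative; thresholding keeps the call criterion
transparent and monotone in RI, and the threshold is exposed.

**Low-signal filter.** Genome-wide cohorts contain units too weakly
transcribed to classify; these are flagged and excluded from every
denominator. Two modes: an absolute floor on the wild-type reference mean,
or a cohort-relative floor at the 0.25 quantile (the default, mimicking
the practice of discarding the weakest quarter of a real cohort, where
expression spans orders of magnitude). For simulated cohorts the quantile
default is the wrong tool — initiation rates are drawn from [0.5, 1.5], so
no unit is genuinely dark and a quantile floor would discard good units
arbitrarily; recovery tests therefore pass an absolute floor (0.5, a
quarter of the weakest expected reference mean). Both the floor used and
the flagged counts are recorded in the outputs.

## Metagenes, heat maps, peaks

Anchored matrices are extracted strand-aware (5'→3' in transcript
orientation, position 0 = the anchor base; bases beyond chromosome ends
masked; a bin is valid only if all its bases are). Rows are normalized to
their unmasked mean by default so high-occupancy units do not dominate the
cohort average — raw mode is retained, and the flag travels with the
matrix since cohort profiles differ visibly between the two conventions.
Profiles are column means over unmasked cells smoothed with a 220-nt
centered moving average; the window truncates (shrink-to-fit) at the
edges, keeping every position defined rather than NaN-padding; all-masked
columns stay as gaps and are never interpolated.

Heat-map matrices sort rows by unit length (ascending) and export, per
row, the bin holding the unit's 5' end, so plots can draw the 5'-end
marker; both orderings are data, not baked into a figure.

Per-unit peak positions are the argmax of the smoothed anchored signal in
a search window (defaults [−200, +400] for anchor-proximal factors,
[0, +600] for downstream factors), ties breaking toward the most 5'
position (a plateau is reported where it starts). Peak positions are
invariant under positive scaling and constant offsets. The shift test is
a paired sign-flip permutation test on per-unit differences `B − A`,
one-sided in the 3' direction: the field reports positional P-values
without naming a test, and the sign-flip null (no consistent 3' shift
within units) is the weakest assumption that respects the pairing. All
`2^n` assignments are enumerated exactly for n ≤ 20; Monte-Carlo sampling
with `p = (1 + #{perm ≥ obs})/(n_perm + 1)` otherwise, so p is never 0 and
never anti-conservative by construction.

## Set and proportion statistics

Overlap of two unit-id sets in a universe (all units surviving the
low-signal filter) is tested with the exact hypergeometric distribution,
both one-sided tails reported; a label-permutation mode exists for
stratified designs. Matching is by unit id, not by coordinate
intersection — the cohorts share one annotation, so identity is
well-defined; coordinate-level overlap is a different (out-of-scope)
question. Proportion contrasts (e.g. CID-dependent fraction vs
cleavage-dependent fraction) use Fisher's exact test, two-sided by summing
all margin-fixed tables no more probable than the observed one; odds
ratios get the Haldane 0.5 correction only when a cell is zero. Pathway
assignment crosses the defect flags of a CID-mutant and a cleavage-mutant
contrast into four categories (CID-only, cleavage-only, both, neither),
reporting all four so either reading of "defective in either mutant" is
derivable. The pipeline applies one Benjamini–Hochberg pass over the
p-value battery it emits, flagged as such.

## Amplicon quantification

Fold enrichment is the mean signal of a query amplicon over a
nontranscribed background amplicon. Replicates are aggregated
ratio-then-average — each replicate's enrichment is computed against its
own background, then averaged — because the mean of per-replicate ratios
equals the ratio of means only when backgrounds are identical; the sample
SD (n−1) is reported, with SD 0 and a flag at n = 1, and replicates are
treated as exchangeable. Phospho-CTD signals are normalized per amplicon
to total Pol II, with uncertainty propagated in quadrature; DIP
(RNA:DNA-hybrid) tracks go through the identical arithmetic. Time-course
ratios between two amplicons follow the last transcribing wave after a
promoter shutoff.

## Numerical and engineering choices

* Coordinates are 0-based half-open everywhere internally (bedGraph/BED
  native; GFF3 converted on read); "downstream" always means 3' in
  transcript orientation.
* The moving average is computed from a cumulative sum (absolute error
  ~1e-12 on 10⁴-length arrays against the brute-force loop, tested at
  1e-9).
* bedGraph output is run-length encoded with 17 significant digits, so
  write-then-read is the identity on value arrays; zeros are implicit.
* All randomness flows from explicit integer seeds: annotation from
  `config$seed`, each simulated track from a seed derived from
  `config$seed` and the sample's index (so a track's content does not
  depend on which other samples are requested), Monte-Carlo tests from
  their `seed` arguments. Pipeline runs are byte-identical under a fixed
  seed, and every run writes its config hash into the manifest.
* Degenerate inputs fail loudly and early: empty cohorts, missing anchors
  (named units), unknown genotypes/factors (with the supported list),
  conflicting bedGraph overlaps, windows outside chromosomes, chromosomes
  too short to place the requested units (named class).

## Known limitations

* The simulator's Poisson/Gaussian-kernel world omits overdispersion,
  crosslinking and mappability biases, replicate batch effects, and any
  sequence content; it validates the analysis logic, not robustness to
  real-data artefacts.
* Per-unit defect calls are threshold-based, not inferential; no per-unit
  p-value is attached (the optional rate-ratio route is deliberately out
  of the default path).
* The depth-normalization question for cross-sample comparison is handled
  only through the ratio-of-ratios index and per-track scaling; no
  spike-in or quantile normalization is provided.
* bigWig input is a thin optional wrapper around `rtracklayer`; bedGraph
  is the contract format.
* Reproducing published genome-wide percentages from deposited data is
  possible in principle (point the readers at real tracks and an NUT
  annotation) but untested and outside the acceptance surface.
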