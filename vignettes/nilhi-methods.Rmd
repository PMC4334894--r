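---
title: "Methods: introgression-based hybrid-incompatibility mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression-based hybrid-incompatibility mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nilhi)
```

## The problem and the design

`nilhi` implements the analysis pipeline behind introgression-based mapping
of hybrid-incompatibility (HI) loci between a donor and a recipient
nematode species (the motivating pair is *C. briggsae* donor into
*C. nigoni* recipient). A dominant GFP marker integrated in the donor
genome is pushed into the recipient background by serial backcrossing with
selection on GFP. After enough generations the line is a near-isogenic line
(NIL): recipient genome everywhere except one donor segment carrying the
marker. The segment's boundaries are mapped two ways (donor-specific PCR
markers; read-depth enrichment), its HI consequences are scored from
progeny counts (embryonic lethality, larval arrest, brood size, sex ratio,
male sterility/inviability), and overlapping segments with discordant
phenotypes are contrasted to localize the responsible loci.

Everything user-facing takes and returns tibbles, so stages compose with
the pipe; `run_pipeline()` strings them together.

## Coordinates and interval algebra

All intervals are 0-based, half-open, in base pairs. Megabase values with
two decimals (rounded half-up) appear only at the reporting layer; the
algebra itself is integer-valued, which keeps consolidation and coverage
percentages free of float drift. Abutting intervals merge: under the
half-open convention `end == start` adjacency is unambiguous. The default
coordinate system is the six cb4 chromosome sizes carried by
`cb4_chromosomes()`. Consolidation (`consolidate_intervals()`) delegates to
interval-tree reduction and is validated in the test suite against a
per-base union count on toy chromosomes.

## Marker-based boundary calling

PCR with donor-specific primer pairs gives a `+`/`-`/`NA` call per marker
per strain. The boundary rule: the *inner* interval spans the outermost
consensus `+` markers; the *outer* interval (the reported size estimate)
extends to the midpoint of the nearest consensus `-` marker on each side,
or to the chromosome end when the `+` run reaches the terminal marker.
Marker position is the amplicon midpoint — the natural point estimate given
a primer-pair span; the choice of midpoint versus amplicon edges is
configurable in how panels are constructed but midpoint is the default and
the one used throughout.

Isolated contradictions are treated as candidate assembly errors: a
maximal run of contradicting calls of length at most `exception_max_run`
(default 1), flanked on both sides by at least `min_consensus` (default 2,
relaxed to 1 where the flank touches the panel edge) consistent calls, is
flagged and excluded from boundary computation. This formalizes calling
boundaries by the consensus of multiple primers: a single primer that
contradicts two concordant neighbours on each side is more plausibly
mis-placed in the assembly than a double recombinant. A consequence worth
knowing: an introgression covering a *single* marker is indistinguishable
from an assembly error and is deliberately consumed by the rule, so
fixtures and real panels should put at least two markers inside any segment
of interest. `NA` calls are transparent — skipped for run construction and
never flagged. Two or more adjacent contradictions exceed the exception run
length and are instead reported as a second segment with a warning.

Zygosity is never inferred from PCR (donor-specific primers amplify in
heterozygotes and homozygotes alike); it is an annotation from crossing
records.

## Coverage-based boundary calling

For NGS validation, depth in fixed windows (default 10 kb) is normalized to
depth per gigabase sequenced, and donor-derived segments show strong
enrichment when the introgression strain's reads are mapped against the
donor assembly. The rule is five-fold enrichment over "flanking" depth.
Because the source analysis does not define "flanking", the default
baseline is the chromosome-wide median excluding candidate windows,
re-estimated once — robust and parameter-free; a local-flank variant
(median of 20 windows each side of a candidate run) is available via
`coverage_call_config(baseline = "local_flank")`.

With multiplicative lognormal noise at realistic sigma (0.2), roughly a
third of genuinely enriched windows fall below `fold` times baseline, so a
hard per-window threshold fragments calls. The caller therefore uses
seed-and-extend hysteresis: runs containing at least `min_windows` windows
at or above `fold` x baseline seed a call, and seeds are extended through
contiguous windows above the geometric midpoint `sqrt(fold)` x baseline —
the depth at which a window is closer (in log space) to the enriched level
than to baseline. Under the simulator's noise model a baseline window
exceeds that midpoint with probability about 3e-5, which is what gives the
plus/minus one window boundary accuracy verified in the tests. Calls are
invariant to rescaling all depths by a constant. Multi-segment output is
first-class: a secondary enriched region is a biological observation, not
an error. A baseline of exactly zero with positive windows is floored at a
configurable epsilon with a warning.

## The XX/XO Mendelian engine

Single locus, two alleles (`G` = marker/introgression, `+` = wild). Females
are XX, males XO; males produce X-bearing and nullo-X gametes at exactly
1/2, so for X-linked loci the father's nullo gamete determines maleness,
while autosomal loci segregate independently of an (adjustable) conceived
sex ratio of 1/2. Probabilities are integer weights over a common
denominator, so every expectation the analysis relies on is an exact
rational — 3/4 GFP overall and among males for the autosomal
heterozygote-by-heterozygote cross, 1/2 GFP males for the X-linked cross,
1/3 GFP among survivors when GFP hemizygous males are inviable, 1/4
inviable under fully penetrant recessive lethality, 1/8 joint
(homozygous, male) mass at conception, and (1/3)^2 = 1/9 for a
double-homozygote plate in the homozygosing step. Per-class survival in
{0, 1} preserves exactness; fractional survival degrades gracefully to
floating point. The engine is single-locus by design: the study's
inferences are all single-marker, and multi-locus epistasis is out of
scope. A note on the 12.5% male-sterility chance: it is the joint
probability of (homozygous and male) over all progeny, i.e. 25% of males;
`expected_fraction()` exposes both the joint and the conditional reading.

Segregation distortion (size-dependent X versus nullo-X sperm success) is
deliberately *not* in the analytic engine; it exists only as the
`male_x_transmission` perturbation of the progeny simulator, because the
analytic expectations are the null hypotheses the tests are built on.

## Phenotype statistics and HI classification

Rates follow the field's definitions: embryonic lethality = unhatched /
eggs laid; larval arrest = (L1 - adults) / L1; fertility = 72-hour brood
size. Replicate-level rates feed a one-way ANOVA over all groups with
Tukey's HSD as the post-hoc test against the control strain; segregation
and sex-ratio tests are Pearson chi-squared on pooled counts against the
engine-derived expectation, without continuity correction (the multi-class
expected-ratio setting makes Yates inappropriate; counts, not percentages,
are the observations — the only statistically defensible reading).
Zero-variance groups take an exact-equality fast path (equal means p = 1,
differing means p = 0). No multiple-testing correction is applied across
lines beyond Tukey within the ANOVA, matching the original design; this is
recorded in the output rather than silently changed.

Categorical calls: male sterility = no progeny from the male-direction
test cross while the reciprocal is productive; male inviability (X-linked)
= zero GFP males despite GFP females; homozygous inviability = five failed
homozygosing attempts (`homozygosing_threshold`). A heterozygous line is
called *dominant* for a lethality phenotype when its rate exceeds control
plus the 25% expected from fully penetrant recessive homozygote death
(strict inequality); the same formula is mirrored for larval arrest for
consistency. Significance tiers default to 0.05 and 0.01.

## Locus refinement by interval contrast

Severity is ordered male_inviable > male_sterile > male_fertile and
homozygous_inviable > homozygous_viable. For an overlapping pair where `a`
is strictly more severe, `a \ b` must contain a locus required for the
capability `b` retains (e.g. inviable vs sterile localizes a male-viability
locus; the printed worked example yields the 490-kb interval at
14.62–15.11 Mb). Concordant overlapping candidates of the same class are
intersected (tightest support); discordant contrasts are reported, never
silently resolved. The per-class locus count is lower-bounded by greedy
interval scheduling (maximum set of mutually disjoint candidates), which
is exact for the bound. Nested same-phenotype pairs where the inner member
is *more* severe by more than a margin (default 20 percentage points,
motivated by the observed 4.9% vs 51.1% GFP-male contrast) implicate a
suppressor in the superset-minus-subset region.

## The synthetic-data generator

The generator produces every input the pipeline consumes, under the
statistical structure the analysis assumes:

* **Backcross simulator** — one meiosis of the donor-carrying chromosome
  per generation; crossover count Poisson on the genetic map (no
  interference), positions uniform in genetic distance; the GFP-carrying
  recombinant is kept, mirroring single-worm selection. The default map is
  50 cM per chromosome, uniform in bp — a *Caenorhabditis*-like assumption,
  since the true donor/recipient map is unknown; recombination suppression
  is modelled as local rate-multiplier intervals rather than a fitted map.
  The retained segment's per-side genetic length after *t* generations has
  mean (1 - e^(-tL))/t (L = map distance to the chromosome end), and the
  simulator is validated against this closed form at t = 7, 10, 15 over
  5,000 replicates.
* **Progeny counts** — multinomial draws from the engine's exact
  pre-selection distribution, per-class viability applied at the embryonic
  or larval stage, then baseline embryonic lethality and larval arrest.
  Baselines default to 14.1% larval arrest (the recipient inbred strain's
  published rate) and 10% embryonic lethality — the latter is not printed
  anywhere for the recipient strain, so a realistic inbred-line value was
  fixed once; brood sizes are Poisson with mean 150.
* **Genotype matrices** — truth by amplicon midpoint, optional per-call
  flips, and assembly-error corruption that inverts a named marker's truth
  (its amplicon really maps elsewhere).
* **Coverage tracks** — lognormal multiplicative noise, times `fold`
  inside the planted segment.

All generators are deterministic under a fixed seed. What passing tests on
these data do *not* show: the generator has no linkage between marker loci,
no GC or mappability structure in coverage, no inbreeding-depression
genetics beyond the baseline rates, and a uniform genetic map — so
recovery rates here bound what is attainable under the model's
assumptions, not under every property of real data.

## Problem sizes and numerical choices

The validation suite uses the study's scale where it matters: crosses of
about 200 progeny with 5 replicates and 10 brood replicates per line, 2,000
simulated lines for null calibration of the statistical flags (false-positive
rate 0.05 with a tolerance of 0.02), at least 100 truth-positive lines for
planted-effect recovery (target at least 95%), 1,000 random marker fixtures
for the boundary-caller round trip, and 100 seeded tracks for the coverage
caller. Ties and degenerate inputs: zero-egg or zero-L1 replicates are
excluded with a warning; an all-negative strain is an explicit "no
introgression detected" error; identical intervals contrast to an empty
candidate with a warning; a whole-chromosome coverage plant has no flanking
contrast and is correctly uncallable.

## Known limitations

Single-locus genetics only; no alignment (the coverage module consumes
window depths, not reads); no liftover between assembly versions; no
fine-mapping below marker resolution and no gene models. The landscape
reproduction asserts only cells whose printed inputs are self-consistent —
two published rows carry visible rounding drift from unrounded originals
and are recomputed but not asserted against.
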