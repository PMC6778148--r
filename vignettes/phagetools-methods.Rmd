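---
title: "phagetools: models, parameters and numerical choices"
author: "phagetools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagetools: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetools)
```

phagetools covers the computational arc of a monobody phage-display
campaign: designing an NNK loop-diversified library on a 10FN3 scaffold,
triaging and clustering the Sanger-sequenced output of selection rounds,
quantifying panning and ELISA screens, fitting the binding models used to
characterize purified clones, and mapping binding epitopes from NMR
chemical-shift perturbations. This vignette records the models, the
defaults and why they hold, the numerical decisions, and what the
synthetic fixtures can and cannot demonstrate.

## Library combinatorics

An NNK codon (N = A/C/G/T, K = G/T) expands to 32 codons covering all 20
amino acids with a single stop, the amber TAG. `aaDistribution()`
translates the expansion with the standard genetic code (NCBI table 1);
the initiator special-casing of translation is disabled, since library
codons are internal. Amber is counted as a stop by default: the clone
filter downstream treats in-loop stops as invalid, so design math should
agree with it. Suppressor-strain arithmetic (TAG read as Gln in supE
hosts) is available behind `suppressAmber = TRUE` but changes no default.

Diversity counts are exact integers. The default design — 5–9 NNK codons
in the BC loop, 7–13 in the FG loop — encodes
$\sum_{l=5}^{9} 32^l \times \sum_{m=7}^{13} 32^m \approx 1.4\times10^{33}$
DNA variants, far beyond the 2^53 integer range of doubles, so the
package carries these counts in a small exact base-1e7 digit-vector
arithmetic and reports the decimal string with log10 alongside. At the
protein level each NNK position contributes 21 distinct symbols, or 20
with `stopFree = TRUE`.

`stopFreeFraction()` averages $(1 - p_{stop})^{L}$ over the loop-length
combinations with equal weights, because the mutagenic oligos are pooled
equimolar; independence across loops lets the combination average
factorize into per-loop means.

Two routes exist for turning "96 sequenced colonies" into a library-size
statement and the package deliberately ships both without asserting
either as canonical: the transformant count (an experimental number,
passed through untouched), and `collisionDiversityBound()`, a
birthday-model lower confidence bound — the smallest diversity $D$ at
which the observed number of pairwise sequence collisions (or fewer) has
probability at least $1-\text{confidence}$ under uniform sampling. With
zero collisions the exact product $\prod_{i<n}(1-i/D)$ is solved for $D$;
with collisions a Poisson model over the $\binom{n}{2}$ pairs is used.
Ninety-six collision-free colonies certify only about 1.5 thousand
distinct clones at 95% confidence, which is why the bound is a
sanity floor, not an estimate.

## The synthetic cassette

No deposited cassette sequence exists for this scaffold family, so the
package constructs one in code (`fn3Scaffold()`), clearly labelled
synthetic: the wild-type 10FN3 protein (1FNA numbering, 94 residues)
reverse-translated with common E. coli codons, 5'-flanked by
HindIII/BamHI and 3'-flanked by NotI/KpnI recognition sites, with the BC
variable stretch at codons 25–29 and FG at 75–81. Codon positions at the
user interface are 1-based wild-type numbering (matching how loop
positions are quoted in the field); internal string indices are 0-based
half-open. The 18-nt spans flanking each variable stretch serve as
orientation/frame anchors and are verified unique at construction.

## Clone triage

`orientAndFrame()` searches both strands for the four loop-flank anchors
with at most `maxAnchorMismatch = 2` substitutions (Sanger phagemid reads
are long and low-error; two mismatches in 18 nt already tolerates a ~10%
error rate locally). Ties break deterministically: fewest mismatches,
then leftmost hit, then forward strand. Because loop-length variation
shifts positions by whole codons, a single anchor fixes the reading frame
for the entire read (positions shift by multiples of 3). When no anchor
survives, a six-frame translation is globally aligned against the
scaffold protein and the best frame is accepted above 50% identity;
below that the read is an "unalignable read" and never enters any
downstream denominator.

`validateClone()` then runs every check — required restriction sites,
loop extraction, in-loop stop codons, ambiguous bases — and accumulates
all failures rather than stopping at the first, so a QC table shows the
full pathology of each read. Decisions worth recording:

* Restriction-site checks are exact matches on the oriented read: a
  mutated site is genuinely non-functional for cloning, so mismatch
  tolerance would defeat the check's purpose.
* "Variable region" means the loops by default; whole-ORF stop screening
  is available behind `wholeOrf = TRUE`. The loop-only reading matches
  the filter's purpose (a stop in a fixed region is a sequencing artifact
  more often than a real clone defect, and such clones fail other checks
  anyway).
* Reads with N inside a loop are invalid ("ambiguous base in variable
  region"): the loop peptide's identity is undefined.
* Base qualities, when present, are carried but unused: triage operates
  on base-called sequence.

## Alignment and clustering

`nwAlign()` is a from-scratch Needleman–Wunsch global aligner with linear
gap penalty and deterministic traceback (diagonal, then up, then left on
ties). Defaults are match +1 / mismatch −1 / gap −2: loop peptides are
short and compositionally unusual, so transparent identity scoring is
preferred over a substitution matrix tuned for globular homologs;
BLOSUM62 is selectable. Fraction identity (matches / alignment length)
feeds the similarity graph.

`similarityMatrix()` compares concatenated BC+FG loop peptides by default
— the diversified positions carry all the signal, and the shared scaffold
would otherwise compress all pairwise identities toward 1. Edges below
`edgeThreshold = 0.5` are dropped: half-identity across two unrelated
random NNK loops is already far above chance, so the threshold separates
family resemblance from noise without being tuned to any dataset.

`mcl()` re-implements Markov clustering: add self-loops (weight 1),
column-normalize, then alternate expansion (matrix power 2) and inflation
(entrywise power 2 with renormalization), pruning entries below 1e-5,
until the largest entry change falls below 1e-8 or 100 iterations.
These are the canonical MCL settings. Clusters are read off attractor
rows; overlapping attractor systems are merged so the output is a true
partition, and nodes unclaimed by any attractor (a numerical corner case)
join the cluster holding most of their column mass. Non-convergence
returns the current partition with a flag rather than failing. Consensus
sequences are built per cluster by aligning members to the medoid (the
member with the highest mean identity; label order breaks ties) and
taking the most frequent residue per medoid column, ties alphabetical — a
deliberate lightweight substitute for progressive MSA, which is out of
scope.

## Selection analytics

Titers follow the standard constants: OD268 of 1.0 equals 5e12 phage/mL,
and colony counts scale by dilution over plated volume; a dilution series
is combined as total colonies over total effective volume, the Poisson
maximum-likelihood estimate. The enrichment ratio is target eluate over
control eluate; a zero control gives an `Inf` sentinel flagged
"unbounded" rather than an error. Two stringency schedules are shipped as
presets (100/50/25 nM and 100/20/4 nM) because both appear in print for
the same campaign; neither is hard-coded as truth.

Phage-ELISA analysis subtracts each target's blank-well mean (clipping
negatives to zero — a well cannot bind less than nothing), calls a clone
a binder of its primary target above 3 blank standard deviations (a
conventional detection threshold; no quantitative cut-off is published
for this assay), and reports specificity as primary signal over the
strongest off-target signal, with an infinity sentinel when all
off-targets sit at blank level.

## Binding models

All fits share one engine policy: trust-region Levenberg–Marquardt
(`minpack.lm`) over log-scaled positive parameters, restarted from a
deterministic set of initial points log-spaced around method-of-moments
guesses, keeping the best final residual. Every fit is therefore
reproducible bit-for-bit from the same data.

**Single-cycle kinetics.** The 1:1 Langmuir model in closed form:
association $R(t) = R_{eq} + (R_0 - R_{eq})e^{-(k_{on}C + k_{off})t}$
with $R_{eq} = k_{on} C R_{max}/(k_{on}C + k_{off})$, dissociation
$R(t) = R_0 e^{-k_{off}t}$, chained continuously across the five
ascending injections (120 s contact, 70 s dissociation, 600 s final).
The bulk refractive-index term is fixed at 0 and mass transport is
ignored (transfer constant effectively infinite); the two-compartment
transport model is out of scope. `KD` is stored as exactly
`koff / kon`, an identity the class validity enforces. Sensorgrams
whose residuals show strong systematic sign structure (Wald–Wolfowitz
runs test z < −4 with RMS residual above 0.5% of Rmax) are flagged
biphasic — such data are not 1:1 and the fitted numbers should not be
quoted; the thresholds are deliberately conservative so noiseless
perfect fits are never flagged.

**Steady state.** $R_{eq}(C) = R_{max}C/(K_D + C)$ by least squares from
three quantile-spaced KD starts; all-equal responses are rejected as
degenerate.

**ITC.** One set of N identical sites. After injection $i$ (cumulative
volume $d_i$, cell volume $V_0$), totals follow the midpoint
displaced-volume bookkeeping
$M_t = M_0\,\frac{1-d_i/2V_0}{1+d_i/2V_0}$,
$X_t = X_{syr}\,\frac{d_i/V_0}{1+d_i/2V_0}$; the bound complex comes from
the quadratic mass balance (evaluated in the cancellation-free form
$2ab/(s+\sqrt{s^2-4ab})$), the cumulative heat is $Q_i = V_0 \Delta H
[MX]_i$, and the measured heat is $\Delta Q_i = Q_i - Q_{i-1} +
\frac{v_i}{V_0}\frac{Q_i+Q_{i-1}}{2}$. The first (0.5 µL) pre-injection
participates in the volume bookkeeping but its heat is excluded from
fits, as is standard. Fits run on heats normalized per mole of injectant;
the Wiseman c-value $N M_t / K_D$ outside [0.1, 1e4] produces a warning
(the isotherm no longer constrains KD) but not a failure.

**Fluorescence polarization.** The direct titration uses the exact
two-component (depletion-corrected) bound fraction
$F_B = \frac{(K_D + L_t + R_t) - \sqrt{(K_D+L_t+R_t)^2 - 4L_tR_t}}{2L_t}$
— computed in the stable quadratic form — mapped linearly between the
free and bound polarization plateaus. Competition uses the exact ternary
equilibrium: the mass balance in free receptor is a cubic, solved by the
trigonometric closed form and then polished with two Newton steps, which
holds the solution at machine precision across extreme
concentration/affinity ratios (the bare closed form loses digits when the
competitor term dominates). The published formulas being cited rather
than reprinted in the source literature, these standard exact forms are
the faithful reading. A curve flat within 2% of its signal scale is
reported as "KI lower bound only".

**Competitive pull-down.** Band densitometry is normalized to the
zero-competitor lane (100%) — when proteolyzed competitor is present this
normalization choice is a known confound, and normalizing to the
no-competitor lane is the least-assuming option — then fitted as a
four-parameter logistic in log competitor whose midpoint is tied to the
inhibition constant by Cheng–Prusoff,
$IC_{50} = K_I(1 + [tracer]/K_{D,tracer})$, with tracer concentration and
tracer KD supplied as fixed constants.

**Effective concentration.** For two binding modules tethered into one
fusion, $C_{eff} = K_{D,A} K_{D,B} / K_{D,fusion}$. Module affinities in
the 0.1–1 µM range with sub-nanomolar fusion affinities put $C_{eff}$ in
the tens of millimolar — the avidity regime the fusion strategy exploits.

## Chemical-shift perturbation mapping

The combined amide perturbation is
$\Delta\delta(N,H) = \sqrt{0.14\,\Delta\delta_{15N}^2 +
\Delta\delta_{1HN}^2}$ with the 0.14 weight outside the square, exactly
as the formula is usually printed; the common alternative
$(0.14\,\Delta\delta_{15N})^2$ sits behind `weightInsideSquare = TRUE`
and changes no default. Classification uses 0.3 ppm (strong) and
0.15 ppm (moderate) thresholds, applied globally to every dataset rather
than per panel. Exchange broadening beyond detection in the bound state
classifies a residue as `broadened` regardless of any measurable shift —
broadening is itself evidence of contact — and residues missing or
ambiguous in either state are `no-data`; the five classes are exhaustive
and mutually exclusive. Shift tables are plain CSV; NMR-STAR parsing is
deliberately out of scope.

## Synthetic fixtures: what they emulate and what they do not

`genLibraryReads()` emulates a 96-colony Sanger run: clone families with
stop-free NNK loops at the designed length ranges, ~50% reverse-strand
reads, per-base substitution errors (default 0.2%, Sanger-like), optional
5' truncations, and invalid clones planted at stated rates (in-loop amber
stops, destroyed NotI sites). Families are sampled uniformly with every
planted family guaranteed at least one read — the generator defines the
planted structure, so all of it is present by construction. It does not
model chromatogram traces, quality-score profiles, chimeric reads, or the
strongly non-uniform clone abundances a real selection produces; passing
tests therefore demonstrate correctness of the triage/clustering logic,
not robustness to every real-world pathology.

`genTitrations()` generates one dataset per assay class from planted
parameters with additive Gaussian noise (counting data use Poisson noise
in `genDilutionSeries()`, matching the physical measurement classes), on
the standard instrument geometries: five twofold-ascending single-cycle
injections; 0.5 µL + 29 × 1 µL into a 200 µL cell; 50 nM tracer;
duplicate pull-down lanes. `genShiftTables()` plants a contiguous epitope
patch and a broadened subset. Each generator uses one local seeded RNG
and restores the caller's RNG state, so identical (seed, parameters) give
byte-identical output and no hidden global state exists.

## Numerical choices and degenerate inputs

* Quadratic roots are always taken in the form without subtractive
  cancellation; the competition cubic is Newton-polished.
* Root-finding on concentrations runs in log space (linear-space
  bisection tolerances are meaningless across six decades).
* MCL convergence: max entry change < 1e-8, 100 iterations, prune 1e-5.
* All fits: log-scaled parameters, deterministic multi-starts, best
  residual wins; failures from every start raise a diagnostic error.
* Degenerate inputs have defined behaviour: zero control titer is an
  unbounded-enrichment sentinel; all-equal steady-state responses are a
  fit error; flat competition curves are a lower-bound-only result; a
  clone failing orientation is recorded, not dropped silently.

## Problem sizes

The test suite runs entirely on generated data: 96-read/11-family
pipelines for end-to-end checks, 12-node planted-partition graphs
(20 seeds) for the MCL-versus-components property, exhaustive alignment
oracles on all length-≤3 pairs over a three-letter alphabet plus sampled
pairs to length 6, 12-point kinetic parameter grids for round-trip
recovery, and 25-draw parameter sweeps for the equilibrium oracles. These
sizes were chosen to exercise every code path at full fidelity while
keeping the whole suite in the minutes range on a single core.

## Known limitations

* The scaffold cassette is a synthetic stand-in; real campaigns should
  load their own `ScaffoldTemplate` (JSON) with their cassette and
  anchors.
* Indel sequencing errors inside anchors defeat the k-mer search and fall
  through to the (slower, coarser) six-frame fallback.
* MCL granularity depends on inflation; the default 2.0 is canonical but
  no value is universally right for all similarity structures.
* The SPR model is strictly 1:1 and kinetics-limited; heterogeneous or
  transport-limited data are flagged at best, never modelled.
* ITC fitting assumes baseline-corrected, integrated injection heats;
  peak integration from raw power traces is out of scope.
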