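---
title: "Methods: bias-aware essentiality calling from transposon insertion data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias-aware essentiality calling from transposon insertion data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical model, the
choices made where the design was genuinely open, and the limits of what
its tests demonstrate.

## The data and its filters

The input is a table of mapped transposon–genome junctions with per-sample
read counts. Mariner-family transposons insert into the TA dinucleotide of
the duplex, so a junction reported at the A position is collapsed onto the
same site as one reported at the T (site identity is the plus-strand
position of the T). Records are kept when they map uniquely, accumulate at
least 8 reads across samples, and coincide with a TA site; the discard
report tallies each reason, assessed in the order non-unique, low-count,
non-TA. Non-TA records are required to match exactly — the data gives no
basis for a tolerance window, and a window would silently reassign true
near-TA artifacts. Samples are combined by union: a site is *inserted* if
any retained record from any sample maps to it, because the question the
caller asks is viability of the insertion mutant, not its abundance.

Coordinates are 0-based and half-open throughout; a TA site belongs to a
gene iff its T position lies in `[start, end)`. Sites covered by two
overlapping genes are excluded from all gene statistics (an insertion
there is uninformative about either gene). Within each gene the *core*
excludes the terminal 2% of the gene length at the 3' end — insertions
there frequently leave enough of the protein intact — while the 5' end is
not trimmed.

## Insertion-event estimation

Because independent colonies can carry the exact same insertion, unique
inserted sites undercount insertion events. With `m` colonies over `n`
sites, per-site event counts are approximately Poisson(`m/n`), so the
expected unique-site count is `n(1 − e^{−m/n})`; inverting gives
`m = −n·ln(1 − u/n)`. This zero-truncation correction is applied globally,
per sliding window for the location fit, and per motif class — the same
estimator at every level, which keeps the three bias summaries mutually
consistent. A saturated stratum (`u = n`) has no finite estimate; it is
capped at `u = n − ½` with a warning.

## Location bias

Insertion frequency is tallied in 20,000-nt windows stepped by 2,000 nt
(full-width windows only; a trailing partial window would have a different
variance) and fitted by ordinary least squares as
`f(x) = a·x² + b·|x| + c` with `x` the signed distance from the
chromosome midpoint in megabases. This coordinate convention puts the
replication origin at the extremes and is the only one under which the
quadratic-plus-absolute-value shape reproduces the observed symmetric
origin-versus-midpoint excess of roughly 25% for coefficients near
`(0.0032, 0.0081, 0.1615)`. Consecutive windows share 90% of their sites,
so the naive OLS standard errors are inflated by `sqrt(window/step)`.
Evaluated anywhere, `f` is clamped at zero. Location *weights* are
`f(x)` normalized by its mean over all TA sites, so the average weight is
exactly 1 and the weight only redistributes, never rescales, the event
total.

## Motif bias and the independence test

The flanking context is the 6-mer centred on the TA. The duplex presents
each context and its reverse complement identically, so contexts are
canonicalized to the lexicographically smaller of the pair: 136 classes,
16 of them palindromic. Class probabilities are estimated only on genes
that contain no fewer insertions than expected under the genome-wide mean
(binomial lower tail > 0.1), so that essential-gene depletion does not
masquerade as motif avoidance. The prescreen is applied once, not
iterated: a second pass would re-select genes using probabilities
estimated on the first selection and can ratchet the estimate upward;
the single pass is conservative and reproducible.

The independence question — do the four flanking positions contribute
multiplicatively? — is answered by weighted least squares of the class
rates against a product model, weights inversely proportional to the
per-class binomial variance (classes with zero insertions get a
rule-of-three variance so their weight stays finite). Because canonical
classes merge the two strand orientations, an unconstrained four-position
model is not strand-consistent; the contributions are therefore
parameterized strand-symmetrically — an outer-position factor and an
inner-position factor, with the 3' factors the complement-indexed 5'
factors — giving 7 free parameters (two factor vectors normalized to mean
1, plus one scale). Inside the optimizer the factor vectors are
gauge-fixed to geometric mean 1, which removes the flat scale directions
that otherwise let a quasi-Newton step drift to overflow. The minimized
weighted sum of squares is the chi-square statistic with
`classes − 7` degrees of freedom.

## Per-gene probability and calls

Each non-excluded site's rate is `λᵢ ∝ motif rate × location weight`,
scaled so `Σλᵢ` equals the estimated event total, and
`pᵢ = 1 − e^{−λᵢ}`. The inserted-site count of a gene's core is
Poisson-binomial; its PMF is built by iterative convolution of
`(1 − pᵢ + pᵢx)`, which is exact (no normal or Poisson approximation) and
reduces to the binomial when all `pᵢ` are equal. The observed count
`t_obs` counts unique inserted sites, not reads — the generating function
models site occupancy, and read depth carries fitness information, not
viability information.

The essential-call cutoff is calibrated, not fixed: for a candidate
cutoff `c`, each gene's probability of being falsely called under the
nonessential model is the largest attainable cumulative probability below
`c`; the calibrated cutoff is the largest `c` whose summed marginals stay
at or below the target expected false-positive count (one by default).
The sum is a monotone step function of `c`, and the cutoff is found by
bisection to 1e-12 with the step function evaluated exactly, so the
procedure is deterministic. Calls use strict inequality (`p < c`); ties
are not called. The naive `1/n_genes` threshold is reported alongside for
reference, but calibration always uses the summed-marginals procedure.
Genes whose strongest attainable evidence `P(X = 0)` is not below the
cutoff can never be called essential and are marked accordingly; genes
with zero core sites are always `unknown`.

Nonessential calls mirror the procedure on the upper tail under an
essential-gene model whose site probabilities are scaled by
`ρ = Σt_obs / ΣE` over the essential calls. The nonessential calibration
sums marginals over *all* genes: the essential-call set is itself
uncertain, and restricting the sum would make the two cutoffs depend on
each other's output order. Genes crossing both cutoffs are reported as
conflicts rather than silently resolved — a conflict is biologically
informative (e.g. a gene with an essential domain and a dispensable,
highly inserted region).

## Monte Carlo validation

Null libraries are simulated at the site level — independent Bernoulli
draws at the fitted `pᵢ` — which matches colony-level multinomial
placement at the occupancy level and is far cheaper; the colony-level
sampler lives in the synthetic module for end-to-end tests. The NDE
histogram uses 61 equal bins on `[−6, 6]` with overflow bins at both ends
(the binning is this package's choice); bins are fixed across replicates
so per-bin means and standard deviations (`n − 1` denominator) are
well-defined, and one master seed spawns per-replicate seeds.

## Operon polar effects

A transcriptionally terminated transposon silences everything downstream
in the operon, so an essential call is retained only when the gene is
operon-terminal or its immediately downstream neighbor is called
nonessential. A downstream neighbor with an `unknown` call does not
rescue the gene: the polar explanation cannot be excluded, and flagging
is the conservative side. Nonessential calls are never flagged — polar
effects can only fake essentiality.

## The FBA comparator

The metabolic module solves `max v_biomass` under `S v = 0` and flux
bounds, with medium uptake limits applied to each exchange reaction's
uptake direction (inferred from its stoichiometry; bound values are taken
verbatim from the medium table, units being the user's responsibility).
Gene deletions shut off reactions whose GPR boolean evaluates false and
are called essential below 1% of wild-type growth, with the
zero-growth (< 1e-6) call reported alongside. Blocked reactions are found
by maximizing and minimizing each flux. Constraint relaxations add an
export reaction per metabolite (`free_endpoints`) or make all reactions
reversible with symmetric bounds (`no_thermo`); the two compose
order-independently. Confusion-table percentages are rounded half away
from zero to integers, matching how such tables are conventionally
printed. The linear programs are solved by a built-in two-phase dense
simplex with Bland's anti-cycling rule — deterministic and exact at the
scale of validation models — cross-checked in the test suite against
hand-solved optima and a ridge-regularized quadratic-programming oracle.

## The synthetic generator

The generator emulates the features of a real mariner library that the
caller relies on: a circular chromosome with tunable TA density (i.i.d.
nucleotides with `P(T) = P(A) = sqrt(density)`); non-overlapping genes
grouped into operons; colonies placed multinomially over TA sites with
rates proportional to a planted motif spectrum times the location
polynomial; essential-gene cores at a residual rate `ρ_true` with the
3'-terminal 2% at full rate; log-normal per-colony read counts split
across four samples; and non-TA mapping artifacts layered on top so they
form the stated fraction of unique records. Default scale follows the
study conditions: 5 Mb, ~4,200 genes, TA density 0.032 (~160,000 sites, a
typical gamma-proteobacterial density), 40,000 colonies, 10× motif
spread, `(a, b, c) = (0.0032, 0.0081, 0.1615)`. The read-count
distribution is a modeling choice (log-normal, meanlog `log 120`,
sdlog 1); only the ≥8-read filter interacts with it.

What the generator does *not* emulate: sequencing error and mapping
ambiguity structure, fitness-dependent clone abundance (slow growers
escaping detection), operonic co-regulation, GC-skew-correlated motif
composition, and real gene-length/TA-density correlations. Passing
recovery tests on synthetic data therefore demonstrates the estimator's
correctness under its own assumptions, not robustness to everything real
libraries do.

## Identifiability and calibration limits

Two structural points matter when reading recovery results.

*Scale of the location polynomial.* The generator (and the biology) uses
`f` only as a relative weight — the colony count sets the absolute event
scale — so `(a, b, c)` is identified only up to one overall factor.
Recovery is assessed after normalizing the fitted curve to the planted
mean rate over TA sites; the same applies to the motif spectrum.

*Power at one expected false positive.* With `n` genes, the calibrated
cutoff sits near `1/n`. A gene with `s` core sites and *zero* insertions
has evidence `P(X = 0) ≈ (1 − p̄)^s`; at the default study scale
(~40,000 colonies over ~160,000 sites, mean site probability ≈ 0.19)
this beats the cutoff only for `s` of roughly 32 and above. Essential
genes with fewer TA sites are structurally uncallable at this coverage
regardless of implementation, and residual insertions push the threshold
higher still — which is why a large fraction of genes is reported
`unknown`, and why sensitivity quoted for "genes with ≥ 20 TA sites"
cannot approach unity at this depth. The package's tests verify the two
halves separately: the false-positive calibration holds at the stated
scale, and sensitivity rises above 95% when the simulated library is a
few-fold deeper.

*Estimating ρ.* The residual-rate estimate is taken over called essential
genes only, which selects for genes with the fewest insertions and biases
it downward at limited power; conversely, at very deep coverage the
ratio-of-occupancies estimator sits above the planted rate scaling
because occupancy saturates nonlinearly. The estimate is reported as
what it is — the observed/expected insertion ratio in the called set.

## Problem sizes used by the test suite

Module tests run on genomes of 0.1–1 Mb with a few hundred genes; the
calibration-soundness check uses 200 simulated null libraries over an
840-gene genome; the end-to-end recovery check and the acceptance script
use the full study scale (5 Mb, 4,200 genes, 40,000 colonies). These
sizes were chosen as the smallest at which each property is
distinguishable from noise.
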