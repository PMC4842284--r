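---
title: "Non-targeted mass-isotopolome analysis with midas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-targeted mass-isotopolome analysis with midas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midas)
```

## The model behind the methods

A mass isotopomer distribution (MID) is the vector of relative abundances
$M_0 \dots M_n$ of a mass-spectrometric fragment's isotopologues. When cells
are fed an isotopic tracer and labeling has reached steady state, the MID of
a metabolite pool is determined by the *ratios* of the fluxes feeding it:
absolute fluxes, pool sizes and kinetics drop out. Two consequences drive
everything in this package:

1. **A change in an MID between conditions implies a flux change** somewhere
   upstream of that pool. The converse does not hold — fluxes can change
   without moving an MID — so the variation analysis here is a detector with
   one-sided guarantees.
2. **The MID of a molecule made of independently labeled moieties is the
   convolution (Cauchy product) of the moiety MIDs.** This underlies the
   natural-abundance envelope, the correction of measured patterns, and the
   deconvolution of a moiety MID from a parent/sub-fragment pair.

All stages consume a `labeling_dataset`: a long table of per-fragment MIDs
keyed by condition, tracer, replicate and compound. Compound identity across
conditions is carried by `compound_id` in the input; matching spectra across
samples is the job of the upstream peak-detection software that produced the
table, not of this package. Stages that need one MID per
(condition, tracer, compound, fragment) use the arithmetic mean of the
replicate MIDs, renormalized — replicate scatter is measurement noise, and
the downstream formulas are defined on one MID per condition.

## Quality control

`qc_thresholds()` encodes the acceptance rules, with these defaults:

| parameter | default | meaning |
|---|---|---|
| `min_r2` | 0.98 | minimal MID-determination quality R² (strict `>`) |
| `max_abs_sum` | 1.05 | maximal $\sum_i |M_i|$, catches correction artifacts |
| `m0_lower`, `m0_upper` | 0.45, 1.0 | open interval for $M_0$ |
| `min_enrichment` | 0.05 | minimal labeled fraction $1 - M_0$ (inclusive `>=`) |
| `trailing_noise` | 0.01 | trailing abundances below this are removed |
| `min_passing_fragments` | 2 | fragments that must pass in ≥ 1 condition |

Two details are deliberate. First, $\sum_i |M_i|$ is evaluated on the MID
*as read*, before any clamping of small negatives: the criterion exists to
flag over-corrected patterns, and clamping first would hide exactly what it
looks for. Second, after trailing-noise removal the vector is renormalized
to unit sum, because the Canberra and variation formulas downstream assume
probability vectors. The upper M₀ bound stays strict: M₀ = 1 cannot co-occur
with enrichment ≥ 0.05 anyway, so the boundary case is moot.

A compound passes as a whole if at least `min_passing_fragments` of its
fragments pass in at least one (condition, tracer) slice; it is then kept in
*all* slices where it occurs, so cross-condition comparisons are not biased
toward conditions with strong labeling. Exclusion-list matching is exact on
`compound_id` and case-insensitive substring on the name, because
contaminant (siloxane) naming varies between spectral libraries.

## Variation analysis

For each isotopomer index $j$, across the $n$ per-condition MIDs,

$$\sigma_j = \sqrt{\tfrac{1}{n} \sum_{i=1}^{n} (\bar p_j - p_{j,i})^2},
\qquad \text{score} = \max_j \sigma_j .$$

This is the *population* standard deviation over conditions ($1/n$, not
$1/(n-1)$): the conditions are the whole universe being compared, not a
sample from one. Whether the spread should be taken over conditions or over
all replicate wells is genuinely open; this package averages replicates per
condition first (one $p_{j,i}$ per condition), which matches the formula's
indexing, and the replicate-level alternative can be had by passing each
replicate as its own condition label.

Vectors of unequal length are zero-padded to the common maximum after
trailing-noise stripping — a missing heavy isotopomer is an observed ≈ 0
abundance, not missing data. The fragment compared is the **heaviest
fragment observed (with qualifying R²) in every condition where the compound
is enriched**: heavier fragments retain more of the carbon backbone and
therefore more flux information. Compounds enriched in fewer than
`min_conditions` (default 3) conditions are skipped, as are unlabeled
compounds, defined by the same enrichment criterion as QC
($1 - M_0 <$ `min_enrichment`). When several derivatization variants of the
same *named* metabolite qualify, only the highest-scoring one is reported;
unidentified compounds are never merged, since equal retention indices are
not evidence of identity.

## MID alignment and similarity

Loss or gain of a labeled moiety shifts an MID along the mass axis. To keep
such pathway neighbors close, vectors are globally aligned
(Needleman–Wunsch) before the distance is computed, minimizing
$\sum |a_i - b_j|$ over matched positions plus a penalty of 0.4 per gap. The
distance is then the Canberra sum over aligned positions, with gaps valued
0 and the $0/0$ term defined as 0, normalized by the *input* dimensions:

$$d^{\mathrm{norm}}_{A,B} = \frac{1}{\dim A + \dim B}
\sum_i \frac{|A_i - B_i|}{|A_i| + |B_i|} \in [0, 1].$$

Under this convention a pure index shift has distance exactly 0 — the
behavior the alignment exists to produce. One numerical subtlety: minimal
alignment *cost* does not determine the alignment uniquely (pure shifts tie
with anti-shifts at the top DP cell), and a fixed traceback preference
yields 0 for one shift direction but not its mirror, breaking symmetry. The
aligner therefore optimizes lexicographically — cost first, then the
gap-as-zero Canberra sum along the path — with a fixed move preference
(match, then gap in the first vector, then the second) as the final
tie-break. This keeps the minimal-cost contract, is deterministic and
symmetric, and makes shifts score 0 in both directions. The alternative
convention that *drops* gap terms from the Canberra sum is available
(`gap_terms = "drop"`).

Distances are computed within one condition and one tracer only (MIDs under
different tracers live on different label sources and are not comparable);
per-compound the heaviest fragment with R² > 0.95 is used. The network
cutoff has **no default**: it is an empirical, dataset-dependent choice, so
the CLI requires `--cutoff` or `--top-edges`. Per-condition networks are
overlaid; an edge records every condition supporting it, and
multi-condition edges are the ones most likely to be biologically real.

## Moiety deconvolution

If fragments at m/z $p$ and $s$ of one compound differ by a moiety, then
$\mathrm{MID}_p = \mathrm{MID}_s \otimes \mathrm{MID}_{\text{moiety}}$. In
matrix form the known vector populates a banded design matrix $C$ (column
$k$ = known vector shifted by $k$) and the moiety MID solves
$C x = \text{parent}$ — for a 7-long parent and 5-long sub-fragment, a 7×3
system. The solver minimizes $\sum_i w_i (obs_i - (Cx)_i)^2$ subject to
$x \ge 0$ via Lawson–Hanson nonnegative least squares; the contract is the
minimizer, not any particular algorithm. Default weights are
$1/\max(obs_i, \varepsilon)$ with $\varepsilon = 10^{-3}\max(obs)$ —
variance proportional to intensity, the standard assumption for spectral
counts — and are overridable because the weighting scheme is an assumption,
not a measurement.

When raw spectral intensities are available for both fragments the system
is populated with them (the known column is the sub-fragment's intensities
normalized to unit sum) and the solved moiety pattern is corrected for
natural isotope abundance *afterwards*, using the moiety's elemental
formula. When only corrected MIDs are available they are used directly and
no further correction is applied. The solution is invariant under uniform
rescaling of the observations, and standard errors come from the
unconstrained normal equations on the active coefficient set.

## Natural isotope abundance

The envelope of a formula is the convolution of per-atom isotope
distributions; the default table covers ¹³C (0.0107), ²H (0.000115), ¹⁵N
(0.00364), ¹⁷O/¹⁸O (0.00038/0.00205), ²⁹Si/³⁰Si (0.04685/0.03092) and
sulfur — silicon matters because every TMS group adds one Si and three C to
the fragment. Correction solves the banded system $C x = \text{measured}$
whose columns are the envelope of the *non-tracer* atoms (the fragment
formula minus the tracer-capable backbone positions) shifted by the label
count; the solve is NNLS rather than triangular back-substitution because
measured patterns carry noise that back-substitution amplifies into
alternating negatives. Condition numbers above $10^8$ trigger a warning.
Fragments without a formula are passed through unchanged on the assumption
that the upstream software already corrected them — formula knowledge is
optional in non-targeted mode. Which correction algorithm the upstream tool
applies internally is not specified anywhere; what this package guarantees
is the round trip: correcting a forward-convolved pattern recovers the true
MID to $10^{-6}$.

## The simulator: the stated world

`simulate_labeling()` propagates *positional* isotopomer distributions
(vectors over the $2^n$ labelings of a compound's tracer-element backbone,
$n \le 12$, i.e. ≤ 4096 states — exact at desk scale) through an atom-mapped
reaction network to a fixed point, starting from the unlabeled state.
Mixing nodes take flux-fraction-weighted mixtures of producing reactions;
condensations form outer products of substrate distributions; cleavages
marginalize. Cycles are allowed and converge geometrically whenever every
cycle is diluted by an external inflow. For acyclic networks the fixed
point is reached in at most longest-path many sweeps.

Assumptions and deliberate simplifications:

- **Condensation independence.** Substrate labelings are treated as
  independent, which is exact for distinct pools at steady state but
  ignores correlations when both substrates descend from a shared pool.
  The packaged example network exhibits this (acetyl and oxaloacetate both
  descend from pyruvate), which is precisely why citrate's simulated MID
  equals the convolution of its moieties — a feature for testing the
  deconvolution, a caveat for quantitative realism.
- **Noise model.** Gaussian noise (default sd 0.01, a typical GC-MS MID
  reproducibility) is added on the abundance scale, clamped at 0 and
  renormalized — matching how mean ± SD is reported for replicate wells —
  rather than a Dirichlet resampling.
- **Simulated metadata.** Fragment m/z labels are synthetic
  (100 + 10 × atom count, sub-fragments 15 lower), and R² values are drawn
  uniformly from [0.985, 0.9995] under noise (0.9999 noiseless): high
  enough to pass default QC, variable enough to exercise R²-dependent
  code paths. Both are stated-world choices, not measurements.

The packaged `example_model()` is a toy glycolysis/TCA network: glucose
cleaved into two pyruvate halves, a PDH-like node mixing pyruvate-derived
acetyl units with an unlabeled acetyl pool (`pdh_fraction`), pyruvate
carboxylation and exchange feeding oxaloacetate, citrate as the
acetyl×oxaloacetate condensation, and a glutamate/2-oxoglutarate exchange
cycle providing a glutamine entry. Sweeping `pdh_fraction` across
conditions makes the acetyl pool's M₂ abundance the most variable signal in
the dataset — the qualitative pattern a two-tracer labeling study detects —
and the tests assert exactly that, in kind rather than in number.

The parallel-pathway fixture used for network recovery gives both sources
partial positional purity (80% and 45%) so that *every* isotopomer is
solidly populated. This is a realism constraint, not a convenience: the
Canberra ratio $|a-b|/(a+b)$ on a structurally zero isotopomer evaluates
two noise draws and is distributed near 1, so pathways whose intermediate
isotopomers are exact zeros are dominated by noise terms — real tracer
incorporation is never all-or-nothing, and the fixture should not be either.
Within-pathway steps dilute by 5% each with an unlabeled exchange pool.

## Numerical conventions

- MIDs are validated to sum to 1 within $10^{-6}$; entries as low as −0.02
  are tolerated as correction artifacts and clamped on normalization;
  anything lower is an error.
- Serialized floats carry 6 significant digits; round-trip tests compare at
  $10^{-6}$.
- All-zero abundance vectors, empty atom subsets, unknown elements, missing
  columns, duplicate measurement keys and non-bijective atom maps raise
  named errors; an unknown tracer label only warns.
- Condition labels keep first-encounter order unless supplied explicitly,
  so outputs are deterministic.

## What a green test establishes — and what it does not

The test suite proves internal consistency against independent oracles:
exhaustive alignment enumeration, closed-form binomial envelopes, direct
evaluation of the variation formula, forward-convolution round trips, and
simulator ground truth. It does **not** establish agreement with any
particular instrument pipeline: upstream peak picking, spectral
deconvolution and library matching are out of scope, the upstream
correction algorithm is unspecified (only the round-trip property is
checkable), and the simulator's independence and noise assumptions are
idealizations. Quantities that depend on real chromatography — retention
indices, fragment formulas, contaminant inventories — enter only as inputs.

## Limitations

- No statistical testing of MID differences (no p-values) and no absolute
  flux estimation; the variation score ranks, it does not test.
- Distances are meaningful within one tracer only; networks from different
  tracers are overlaid, never pooled.
- Deconvolution requires the user to name the parent/sub-fragment pair;
  discovering which fragments differ by a moiety is out of scope.
- No correction for tracer impurity and no isotope fine structure; the
  correction operates at nominal mass.
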