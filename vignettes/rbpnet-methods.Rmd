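---
title: "Methods: RNA-aware RBP interactome analysis with rbpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA-aware RBP interactome analysis with rbpnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpnet)
```

# The experiment and its model

rbpnet analyzes an RNase-coupled IP-MS screen of RNA-binding protein
(RBP) baits. Each bait is immunopurified in triplicate with and without
RNase treatment; whether an interactor survives RNA digestion classifies
the interaction's RNA dependency. Samples are multiplexed in TMT11 mixes
with a fixed channel layout: one pooled spike-in reference (channel 126),
three RNase-treated IPs, three untreated IPs, and two IgG controls per
condition. Replicates of one bait are rotated across mixes so that no
mix carries two replicates of the same bait — this matters for the
normalization below, because an interactor enriched in many channels of
one mix would otherwise partially cancel itself during within-mix batch
correction.

The orthogonal arm is SEC-MS: whole lysate fractionated by size, each
fraction measured by MS, so members of a stable complex co-elute around
the fraction implied by the complex's apparent mass.

# Normalization chain

The chain is fixed in order and each stage records itself, so re-applying
a stage is an error rather than a silent double transformation:

1. **MS1 apportioning** (per mix): a protein's channel values become its
   Top3-MS1 quantity distributed proportionally to the reporter
   intensities, so reporter ratios are kept but the per-mix scale is
   MS1-derived. The per-protein channel sum then equals the Top3 quantity
   (tolerance 1e-9); all-zero reporter rows become missing rather than
   dividing by zero. The exact arithmetic of MS1-level correction is not
   standardized; proportional apportioning is this package's choice.
2. **ppm + log2**: each sample column is rescaled to sum 1e6 over its
   observed proteins, then log2(x + 1). Missing stays missing.
3. **Batch correction** (per mix): each non-spike sample minus the
   protein-wise mean of the *other* non-spike samples of its mix; the
   spike-in minus the mean of the entire rest of the mix (it pools both
   conditions). Missing values are excluded from means.
4. **z-scoring** (per sample, across proteins): sample standard deviation
   (n − 1); constant columns become zeros and are flagged.

z-scoring is per sample, not per protein: the 1.645 enrichment threshold
is meaningful only within a sample's distribution ("top 5% of measured
proteins"). No missing-value imputation is performed anywhere; missing
observations are simply absent from means, medians and rank-sum tests.

# Interactor calling and RNA-dependency classes

A bait × condition IP set passes quality control when the bait itself has
z > 1.645 in at least 2 replicates and no replicate is "too sparse"
(fewer quantified proteins than 50% of its mix median — the sparsity
fraction is configurable because no canonical value exists). Failed IP
sets are not discarded: their channels join the IgG controls of the same
condition as the background pool, which both enlarges the null sample and
keeps the failed material from contaminating calls.

A prey passes for a bait and condition when all three hold:

* enriched (z > 1.645, strict, because the rule is written as an
  exceedance) in ≥ 2 of 3 replicates;
* log2 ratio of median IP signal over median background > 1 (strict);
* one-sided rank-sum p < α, prey greater.

The rank-sum p is computed exactly by enumerating rank subsets (using
midranks, so ties — common after pseudocounting — are handled) whenever
`choose(n, n1)` ≤ 5·10^4; beyond that, the normal approximation with
continuity correction via `stats::wilcox.test`. All-tied degenerate input
returns p = 1. α defaults to 0.05 with 0.01 available as a per-bait
override for high-signal baits; no automatic switching rule is applied
because none is well defined.

Classification is then a function of the condition pattern: both
conditions → **direct**; only without RNase → **RNA-mediated**; only with
RNase → **RNA-shielded**; bait QC-failed in exactly one condition → all
its preys **undetermined**; failed in both → the bait is dropped. The
classes are exclusive by construction.

# SEC co-elution calling

This module is deliberately a compact co-elution caller restricted to a
candidate pair list, not a reimplementation of a full complex-centric
framework: the analysis goal is orthogonal support for candidate pairs
(the IP network plus a reference complex catalogue), with error control
against decoys.

Replicates are averaged cellwise with missing values removed from the
mean. Peaks are local maxima of a 3-fraction moving average above a noise
floor `max(min_intensity, 2 × median)`, with maxima closer than 3
fractions merged (higher peak kept). A pair shares a peak when apexes are
within 2 fractions; its score is the Pearson correlation over a
±5-fraction window centred on the mean apex (requiring ≥ 3 mutually
observed fractions). Δ = 2, window ±5 and smoothing 3 are defaults chosen
at the scale of ~1.5-fraction-wide elution peaks; all are configurable.

Decoy pairs are drawn uniformly from co-measured proteins outside the
candidate set and scored identically; a pair without a shared peak ranks
below every real score. Empirical p = (1 + #{decoy ≥ score}) /
(1 + n_decoys) is never zero; q-values are Benjamini–Hochberg, and calls
require q < 0.1 *and* a shared peak. Because unrelated proteins of
similar monomer mass genuinely co-elute, the decoy distribution carries a
high-score tail and the caller is intentionally conservative about
candidate pairs whose co-elution is explainable by mass coincidence.

# Network assembly and stoichiometry

Edges are unordered pairs; per-bait directed provenance is kept in a
`source_baits` record. When two baits report the same pair with different
classes, the pair-level type follows the precedence direct > mediated >
shielded > undetermined and the conflict is flagged rather than hidden —
direct evidence is the strongest claim, and no published convention
exists for this case. Merging with SEC is a plain set union with
dual-support flags, so |merged| = |IP| + |SEC| − |overlap| holds exactly.

Stoichiometries deliberately bypass the normalization chain: raw
intensities + 1, log2, replicates averaged (mean of logs; the alternative
log-of-means differs negligibly at these CVs and the choice is recorded
here), then prey minus bait — once within the bait's IP channels, once in
the total proteome. Ratios near 0 indicate 1:1 complex membership;
connector proteins are expected substoichiometric.

# Bridge scores

For baits s ∈ S1, t ∈ S2 of two life-cycle steps, σ_{s,t} counts
shortest s–t paths (BFS layered counting) and σ_{s,t|v} those with v as
an *interior* node — v ∈ {s, t} never counts for itself, matching
standard betweenness. The pairwise score is Σ σ_{s,t|v}/σ_{s,t} divided
by N, the number of (s, t) pairs; unreachable pairs contribute 0 but stay
in N (the normalizer is "the total number of pairs"; an
exclude-unreachable option exists), and degenerate s = t pairs are
excluded. The all-steps score divides the grand sum by N′ = Σ pairs; the
balanced variant rescales each step pair by a = 1000/#pairs and divides
by N″ = 1000 × #step-pairs. The 1000s cancel algebraically, so the
balanced score equals the unweighted mean of the pairwise scores — the
package computes it literally with the 1000 factors and the tests assert
the identity to 1e-12, plus exact agreement with a brute-force
depth-first path-enumeration oracle on hundreds of random ≤ 12-node
graphs. Baits without a step label stay in the graph but outside the
step sets; multi-step baits would use their primary assignment.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every recovery claim is made.

* **Design**: 12 baits (8 life-cycle steps; one negative-control bait
  with a private 5-member complex disconnected from the rest; one bait
  planted to fail QC in the RNase-plus condition), 300 preys, ~30 true
  interactors per life-cycle bait, type proportions direct 0.20 /
  mediated 0.26 / shielded 0.47 / undetermined 0.07 (the undetermined
  fraction routes to the failing bait, mirroring the operational
  definition of the class as a bait property).
* **Intensities**: protein baselines log2 ~ N(20, 1.5) (between-protein
  spread of ~4 orders of magnitude); channel noise sd 0.3 log2 units, a
  typical reporter-level CV for TMT quantification; planted log2
  enrichment 3.0 for true interactors and bait self-enrichment; the
  spike-in is the linear mean of the mix's other channels times noise, so
  with zero noise it equals that mean exactly. Dropout is
  missing-not-at-random: raw values below 2^15.5 (≈ 3 log2 sd below the
  baseline mean, ~0.5% of values) are deleted, exercising the missing
  -value paths without starving the caller.
* **The planted bridge** is one prey wired to one bait of every step
  with its enrichment reduced by 1 log2 unit: multi-step connectors bind
  their many partners substoichiometrically, which is exactly the
  phenomenon the stoichiometry analysis should reveal, while remaining
  detectable by the HCIP caller.
* **SEC**: fractions 10–66 (57 fractions), log-linear mass calibration
  from ~5 MDa to ~10 kDa, Gaussian peaks of width 1.5 fractions.
  Complexes are a bait plus 2–4 of its direct or RNA-mediated preys
  (SEC runs without RNase, so RNA-scaffolded complexes are intact);
  members put 70% of their signal under the shared complex apex and the
  rest under their monomer apex. Replicate noise is multiplicative,
  sd 0.3 log2.
* **Binding sites**: 500 windows of 100 bp on a synthetic chromosome;
  each protein includes each window with probability 0.10; for every true
  edge the partner inherits the other's occupancy per window with
  probability rho(type) — 0.60 undetermined, 0.55 direct, 0.35 shielded,
  0.25 mediated, reproducing the observed ordering in which direct and
  undetermined interactors share the most RNA targets. With rho = 0 the
  expected Jaccard reduces to the independent baseline p/(2 − p).

What the generator does **not** emulate: peptide/spectrum-level effects,
isotopic impurity, retention-time structure, cross-mix batch effects
beyond what the within-mix correction removes, correlated contaminant
background, or RNase-concentration dose effects. Passing recovery tests
therefore demonstrates the pipeline's logic and statistics, not
robustness to every artifact of real instruments.

# Resampling test

F_exp is the fraction of network pairs present in a reference list. The
null preserves per-bait degrees: for each bait, its prey count is redrawn
uniformly without replacement from the universe (independently across
baits, so a protein may serve several baits), pooled, and F_i computed
identically; the all-pairs mode draws |edges| uniform pairs instead. The
one-sided p uses the add-one estimator (1 + #{F_i ≥ F_exp})/(1 + n), so
p is never 0 and is valid (super-uniform) under the null — a property the
acceptance suite checks by drawing the "observed" network from the null
itself and testing the p-distribution against uniformity. n defaults to
1000, with larger values available; the validity tests run at n = 200 to
keep the suite fast.

# Problem sizes and determinism

Every generator and resampling routine is a pure function of its seed;
the pipeline runs each stage from the previous stage's output and two
runs with the same seed are byte-identical. The shipped analyses use the
default conditions above (312 proteins, ~340 true edges, 12 TMT mixes,
57 fractions × 3 replicates); the oracle comparisons use 200 random
graphs of ≤ 12 nodes, 100 simulated networks for bridge ranking, and 200
replicates × 200 resamples for p-value validity — sizes chosen so the
full suite completes in a few minutes on one core while keeping
Monte-Carlo error well inside the asserted margins.

# Known limitations

* The co-elution caller scores pairs only; it does not deconvolve
  higher-order complexes or estimate complex masses.
* Conflicting RNA-dependency classes between baits are resolved by a
  fixed precedence and flagged; with deeper bait coverage a
  probabilistic reconciliation would be preferable.
* The exact-enumeration rank-sum bound (5·10^4 subsets) keeps p-values
  exact for the 3-vs-24 comparisons the design produces; larger designs
  silently move to the tie-corrected normal approximation.
* Binding-site sharing is generated by a copy mechanism along edges; for
  proteins in many edges the realized pairwise overlap depends weakly on
  edge processing order.
* Reproducing the published network counts end to end requires the
  deposited per-bait supplementary tables, which cannot ship with the
  package; the corresponding acceptance test documents this dependency
  and runs whenever the tables are placed under
  `tests/testthat/deposited/`.
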