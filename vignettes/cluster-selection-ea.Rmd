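---
title: "Dynamic cluster selection for molecular evolutionary algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic cluster selection for molecular evolutionary algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterEA)
```

## The problem

Global-minimum searches over molecular potential-energy surfaces face a
classic exploration/exploitation dilemma. A cut-and-splice evolutionary
algorithm (EA) exploits: it recombines the fittest members of a population
and tends to converge on whichever basin its parents already occupy.
Clustering the starting population by structural similarity and running the
EA within clusters restores exploration — but then some clusters are far
more productive than others, and allocating equal effort to all of them
wastes evaluations. `clusterEA` treats the clusters as arms of a
multi-armed bandit: a lightweight reinforcement-learning agent decides,
selection by selection, which cluster's sub-population the EA works on
next. The reference system throughout is the quinoline-like composition
C9H7N (17 atoms).

The pipeline has three stages, each usable on its own:

1. **Fingerprint and cluster** a structure library
   (`distance_matrix()`, `cluster_complete_linkage()`,
   `merge_small_clusters()`).
2. **Tune the agent's four learning parameters** against a cheap Gaussian
   surrogate of per-cluster EA output (`run_trial()`, `grid_search()`).
3. **Run the clustered EA** with the tuned parameters
   (`clustered_ea()`), or the unclustered baseline (`unclustered_ea()`).

## Structure fingerprints and distances

For an element pair (A, B), every A–B distance $R_{ij}$ contributes a
Gaussian of width $\delta$ centred at $R_{ij}$ with weight
$V_{uc} / (4\pi R_{ij}^2 N_A N_B \Delta)$; contributions are integrated
over histogram bins of width $\Delta$ on $[0, R_{max})$ and the baseline 1
is subtracted, so an empty bin tends to $-1$. Defaults: $\delta = 0.2$ Å,
$\Delta = 0.5$ Å, $R_{max} = 8$ Å. Hydrogen is excluded as structurally
redundant for organic frameworks; the default pair set is C–C and C–N,
configurable for other chemistries. Two structures are compared per pair
with the bounded cosine distance $d = (1 - \cos\theta)/2$ and the pair
distances combine as $\sqrt{d_{CC}^2 + d_{CN}^2}$.

Two numerical choices deserve comment.

* **Gaussian tails are truncated at $\pm 4\delta$**: a pair farther than
  $R_{max} + 4\delta$ is skipped entirely. The neglected tail mass is
  below $10^{-4}$ of a peak, and truncation makes the cost per structure
  deterministic.
* **The scaling volume matters.** $V_{uc}$ multiplies only the peaks, not
  the subtracted baseline, so it controls the signal-to-baseline ratio of
  the cosine distance. With $V_{uc} = 1$ Å$^3$ a 17-atom molecule's peaks
  are $O(10^{-3})$ against a baseline of $-1$ and *all* pairwise cosine
  distances collapse to $O(10^{-6})$, far below any useful clustering
  threshold. The default is therefore $V_{uc} = R_{max}^3 = 512$ Å$^3$ —
  the bounding volume of the cutoff region — which makes typical peak
  weights order one and places inter-structure distances on the $10^{-2}$
  scale that the default clustering threshold (0.026) and lookalike
  threshold (0.005) presume. Both $V_{uc}$ and the thresholds are
  configurable; only their combination is meaningful.

## Clustering

Complete-linkage agglomeration merges the pair of clusters with the
smallest maximum inter-point distance until that distance exceeds the
threshold, so every cluster's diameter is bounded by the threshold. The
default threshold 0.026 was tuned for a quinoline-like reference library;
it does not transfer automatically. The synthetic libraries produced by
this package's builder are more geometrically diverse than a curated
reference set, so the examples and tests choose the threshold from the
observed distance distribution (for instance the 30th percentile of the
pairwise distances), which reliably yields several clusters of comparable
size. Clusters smaller than `min_size` (default 20) are pooled into one
"misfit" cluster that participates in the EA like any other — whether such
a pool should be eligible for selection is a judgement call; here it is,
since its members are by construction the structures nothing else
represents.

## The selection agent

Each cluster starts at weight 100 and is selected with probability
proportional to its weight. After each batch of simulated or real EA runs,
four rules fire per result, always comparing against the best energies
recorded at the start of the batch (this makes the update
order-independent within a batch):

| rule | condition | effect |
|------|-----------|--------|
| 1 | run minimum beats the overall best *and* is the batch minimum | `+A` |
| 2 | run minimum beats the cluster's own best | `+B` |
| 3 | rule 2 did not fire | `-C` |
| 4 | always | `-(selections/total) * D` |

Weights are clamped at a floor of 1 — a positive floor implements the
"no negative probabilities" cutoff *and* guarantees every cluster retains
a nonzero selection probability, so no arm is permanently starved. Rules 1
and 2 stack; with the tuned `B = 3` the stacking is nearly inconsequential.
Rule 1 requires both a new overall record and being the batch minimum: the
weaker reading (batch minimum alone) rewards some cluster every single
batch and turns A into a pure lock-in force, which experimentation showed
degrades rather than improves tuned behaviour. Rule 4's ratio uses the
cluster's share of *all* selections so far, so an overselected cluster is
penalised harder than an underselected one at equal D.

## The Gaussian surrogate and parameter tuning

Tuning A–D by running real EAs is prohibitively expensive, so each
cluster's 50-iteration EA run minimum is modelled as one draw from a
Gaussian fitted to repeated runs (the packaged nine-cluster reference
models, `cluster_models_fixture()`, have means from −558.11 to −555.47 eV
and SDs from 1.76 to 3.13 eV). A surrogate trial draws batches of 5 runs
(250 iterations per batch), updates the agent between batches, and stops
at the first draw below a success threshold `e_min`, for at most 20
batches = 5000 iterations. A parameter combination's score is the area
under the cumulative success curve of 100 such trials, on a 0–5000 scale
where 5000 means every trial succeeded immediately. Success on draw *j* of
batch *b* is credited at iteration $(b-1) \times 250 + 50j$ — the end of
the run in which it occurred, since the surrogate cannot localise success
within a run.

**Choice of `e_min`.** The threshold must sit deep enough that no
combination saturates the curve within 5000 iterations, or every policy
looks alike. For the packaged models, −560 eV gives per-draw success
probabilities of 0.03–0.15 and near-universal success within two or three
batches; the default is therefore −563.0 eV, where per-draw probabilities
span 1×10⁻³–6×10⁻³, a typical combination succeeds in roughly half its
trials, and areas land in the 1000–1400 band. Absolute areas remain a
function of `e_min`; only orderings between combinations are comparable
across settings.

**What the surrogate can and cannot show.** With the packaged models the
per-cluster success probabilities at any deep threshold are driven by the
*tails* (largest SDs), while the agent's rewards are driven by low run
minima (best means) — two different orderings over clusters whose
disagreement caps how much any A–D combination can gain; measured on this
implementation the spread across the whole parameter box is a few percent
of area. When one cluster is clearly superior in both senses (a
heterogeneous model set with one mean several SDs below the rest), the
expected structure emerges robustly: high-A/balanced-D combinations
dominate, the all-zero combination is mid-pack, and exploration-heavy
low-A/high-D combinations trail. The test suite demonstrates both
regimes. Grid searches use one reproducible RNG substream per combination
derived from the master seed, so serial and parallel runs agree exactly.

## The evolutionary algorithm

Selection follows fitness times uniqueness. Fitness is the half-tanh form
$F = \tfrac12 \left(1 - \tanh(2\rho - 1)\right)$ with
$\rho = (E - E_{lo}) / (E_{hi} - E_{lo})$ over the population's energy
range (a degenerate population gets $F = 0.5$ throughout); uniqueness is
$U = (1+n)^{-1/2} (1+m)^{-1/2}$ where $n$ counts pairings and $m$
structural lookalikes turned away at the population door. Cut-and-splice
centres both parents, cuts with a random plane through the common
centroid, and repairs stoichiometry by dropping surplus atoms farthest
from the plane and refilling deficits with unused parent atoms; children
violating the 70%-of-covalent-radius-sum separation rule are rejected and
the plane redrawn. Offspring are quenched (at most 100 steepest-descent
steps or to a maximum force of 0.05 eV/Å) and replace the weakest member
only if strictly better.

Between cluster selections the next 20-member parent population is curated
under an energy threshold ΔE to suppress energy-duplicate parents:
method 1 keeps only molecules with no pool neighbour within ±ΔE; methods
2/3 scan upward in energy keeping each molecule that clears the last kept
energy by more than ΔE, method 2 pooling the previous run's offspring with
the previous parents and method 3 pooling everything the cluster has ever
produced. When fewer than 20 molecules survive (method 3 early on, or
large ΔE) the population is padded with the lowest-energy excluded
candidates rather than shrunk. Method 1 scans the full pool, including
molecules already excluded — the literal reading of its rule.

The toy calculator is a pairwise Morse potential (per-element well depths,
equilibrium at the covalent-radius sum, stiffness 1.7 Å⁻¹) with an
analytic gradient: deterministic, permutation- and rigid-motion-invariant,
and cheap enough for thousands of quenches per minute. It is a genuine
(if crude) energy model with a real global-optimisation landscape, not a
chemistry engine; any calculator implementing the
`energy_calculator()` contract — `evaluate()` plus a never-uphill
`relax()` — can replace it.

## The synthetic structure builder

`build_structure()` emulates an atom-by-atom growth process: atoms are
drawn in random order from the stoichiometry, attached to a random open
site of a placed atom at the sum of the two covalent radii, with sp/sp²/sp³
hybridization geometries (180°/120°/109.47°, randomly oriented) defining
each atom's sites and hydrogen terminal. Any pair closer than 70% of the
covalent-radius sum restarts the build. This generates diverse, chemically
plausible *input libraries* — trees of correctly bonded atoms — but it does
not enforce valence satisfaction, rings, or conjugation, so builder
libraries are more heterogeneous than a curated molecular dataset. Tests
passing on builder libraries therefore exercise the machinery under
realistic diversity, but say nothing about quantum-chemical accuracy or
about reproducing any particular molecule's energetics.

## Desk-scale study conditions

The packaged experiments run on one CPU in minutes, with sizes chosen once:

* surrogate grid checks: stride 20 over the integer box
  [0,80)×[0,40)×[0,20)×[0,90) (the half-open reading reproduces the
  published combination count 80×40×20×90 = 5,760,000), 30 trials per
  combination;
* end-to-end comparison: C5H4N, 60-structure libraries, minimum cluster
  size 8, 20 cluster selections × 10 iterations against a random-search
  baseline given the identical iteration budget (one builder structure,
  quenched, per iteration), 50 seeds in the test suite and 20 in the
  acceptance script;
* quenches capped at 30 steps in the small-molecule runs.

## Known limitations

* The fingerprint is strictly two-body; enantiomers and some distinct
  bonding topologies with similar radial statistics are indistinguishable.
* The printed nine-cluster Gaussian models are too homogeneous for cluster
  selection to change surrogate success by more than a few percent at any
  threshold (see above); the large printed spreads across millions of
  grid combinations are consistent with selection noise at 100 trials per
  combination.
* The builder and toy potential support method development and testing,
  not chemical prediction; coupling to a tight-binding or DFT calculator
  is the intended production path via the calculator contract.
* Unclustered populations grow without bound (one structure per
  iteration); memory is linear in the iteration budget.
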