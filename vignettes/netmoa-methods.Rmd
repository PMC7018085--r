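---
title: "Modelling drug mechanism-of-action ensembles with netmoa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug mechanism-of-action ensembles with netmoa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmoa)
```

## The modelling problem

A drug perturbs a handful of target proteins, yet its clinical effect —
wanted or unwanted — emerges from signal spreading through the whole
protein-interaction network. For complex diseases there is no single
mechanism of action (MoA): different patients can realise different
molecular routes from the same drug to the same phenotype. **netmoa**
models this explicitly. It samples an *ensemble* of candidate MoAs over a
directed signed protein network, each MoA being one self-consistent
assignment of signal values to every protein that (approximately)
satisfies a set of known active/inactive outcomes. Reading each MoA as a
"prototype patient" — a hypothetical individual whose cells all follow
that one mechanism — the ensemble becomes an in-silico cohort that can be
stratified, compared geometrically, and mined for biomarkers that separate
responder subtypes. The motivating application is the heart-failure drug
combination sacubitril/valsartan (a neprilysin + angiotensin-receptor
inhibitor) and its hypothesised link to macular degeneration; the package
ships the published 30-protein biomarker table from that analysis as a
reference dataset (`reference_biomarkers()`).

## The propagation model

The network is a set of proteins joined by directed edges, each edge
carrying a fixed biological sign $s_l \in \{+1,-1\}$ (activation or
inhibition) and a tunable weight $\omega_l$. The drug stimulus clamps its
target proteins at $\pm 1$. Every other protein $i$ responds to the sum of
its incoming signals through a hyperbolic tangent:

$$x_i = \tanh\Big(\sum_{l:\,j \to i} \omega_l\, x_j\Big),$$

so all signals live in $[-1, 1]$ and saturate smoothly. This is a
perceptron-like transfer function, but a protein network is cyclic, so the
system is solved as a damped synchronous fixed-point iteration

$$x \leftarrow (1-d)\,\tanh(Wx) + d\,x,$$

with damping $d = 0.5$, convergence tolerance $10^{-6}$ on the largest
per-node change, and a 200-sweep cap (`propagation_params()`). On an
acyclic graph this reduces to ordinary layered feed-forward evaluation.
Signals start at 0 and stimulus nodes never move, so proteins unreachable
from the stimulus stay exactly at 0 ("neutral") — a convention, not an
approximation. The damping factor trades convergence speed against
oscillation on negative cycles; $d = 0.5$ converges on every network we
generate while halving the residual per sweep near the fixed point.

### Restrictions and accuracy

Training data are *restrictions*: proteins required to end active ($+1$)
or inactive ($-1$). A restriction is satisfied when the propagated signal
has the required sign **and** magnitude at least `min_magnitude = 0.05`;
anything closer to zero counts as neutral. The floor is a numerical
honesty device — without it, a signal of $10^{-9}$ of the right sign would
count as "active". Model *accuracy* is the satisfied fraction.

### Weight fitting by simulated annealing

Weights are confined by default to the half-interval matching the curated
edge sign ($[0,1]$ for activation, $[-1,0]$ for inhibition); a `free_sign`
switch lifts this, since curated signs are not beyond doubt. One fit
(`anneal_weights()`) is a Metropolis search: perturb one uniformly chosen
edge weight by a Gaussian step (sd `move_scale = 0.25`, clipped to the
allowed interval), re-propagate, and accept by the Metropolis rule at the
current temperature. The objective is the satisfied-restriction count plus
a continuous tie-break (the mean restriction-aligned signal, scaled below
one restriction unit) so the search is not blind on accuracy plateaus. The
schedule is geometric: initial temperature 1 (in restriction units),
cooling factor 0.9, 100 steps per temperature, 60 temperatures. The search
propagates warm-started at a coarser tolerance ($100\times$ the final
one); the returned solution is always re-propagated cold at full
tolerance, so reported signals are exact fixed points of the reported
weights. A run that satisfies every restriction stops early.

None of these schedule constants are claimed optimal; they are the
package's defaults, chosen so that one fit on the default 300-node
synthetic instance takes well under a second while recovering planted
solutions reliably (20/20 seeds reach the 80% accuracy bar in the test
suite). All are exposed in `anneal_schedule()`.

### Ensembles and selection

`netmoa()` runs `n_runs` independent fits (seeds `base_seed + 0, 1, ...`,
embarrassingly parallel by construction) and keeps the `K = 200` most
accurate that clear `min_accuracy = 0.8` — the published selection rule
(200 MoAs, at least 80% of restrictions). Ties in accuracy resolve by seed
so selection is total and order-independent.

## Stratification by TSignal

The response intensity of a MoA for a phenotype is the state-weighted mean
signal over that phenotype's effector proteins,

$$P = \frac{1}{|E|} \sum_{e \in E} \text{state}_e \cdot x_e \in [-1, 1].$$

$P = +1$ means the phenotype is fully induced, $P = -1$ fully reverted.
The published definition ("average signal arriving at the effectors")
leaves open whether signals are state-weighted; we use the signed
projection because a single formula then reproduces both published
quartile readings — strongest *reverters* of an indication and strongest
*inducers* of an adverse event — via one role-dependent orientation
(intensity $=-P$ for indications, $+P$ for adverse events). The choice is
recorded in the stratification output. `stratify_ensemble()` ranks the
ensemble by intensity and labels the top and bottom $\lfloor K/4 \rfloor$
MoAs ("Low"/"High" disease for an indication, "High"/"Low" adverse event),
keeping the middle half as "Mid" so intersections stay well-defined.

## Comparing MoA groups

Each MoA is a point in $\mathbb{R}^{|\text{proteins}|}$ (all network
proteins, not only effectors — the full mechanism is the object of
interest; a `proteins=` argument restricts the view). Group geometry uses:

- **Modified Hausdorff distance** (`mhd()`): the Dubuisson–Jain
  max-of-mean-nearest-neighbour set distance. Of their candidate set
  distances we use the variant they recommend. It is symmetric and
  non-negative but deliberately *not* a metric (no triangle inequality),
  and none of our tests assume one.
- **Dispersion** (`dispersion()`): mean Euclidean distance to the group
  centroid.
- **UPGMA dendrogram** (`group_dendrogram()`): average-linkage
  agglomeration of the group-level distance matrix, with a lexicographic
  tie-break on group names so the tree is bit-reproducible; emitted as
  merge table plus Newick text rather than a plot object.
- **Classical MDS** (`mds_embed()`): Torgerson scaling via
  `stats::cmdscale`, with axes ordered by eigenvalue and each axis's sign
  fixed (first nonzero loading positive), because classical MDS is
  otherwise defined only up to reflection. When points are intrinsically
  2-D the embedding reproduces the distance matrix exactly; the test suite
  asserts this.

## Biomarker extraction

Given two MoA groups, `best_classifiers()` scores every protein by how
well a single-threshold rule on its signal separates the groups, using
leave-one-out accuracy: for each held-out MoA, the threshold (midpoints of
the remaining sorted unique values, plus sentinels) and orientation are
refitted on the rest, then the held-out MoA is classified. The published
"data-science strategy" behind best-classifier proteins is not public;
an optimal-threshold stump with LOO validation is the simplest faithful
reading of "proteins (or pairs of proteins) with the highest
classification accuracy", and pairwise axis-aligned two-threshold
conjunctions are available behind `include_pairs` (quadratic cost, off by
default). Two conventions matter:

- a protein whose pooled values are constant is uninformative and scores
  0.5;
- a LOO accuracy *below* chance is reported as 0.5 rather than mirrored.
  Orientation search already happens inside each fold; mirroring the final
  LOO estimate would award identical distributions a spurious 1.0
  (deterministic LOO on duplicated data misclassifies every fold — a
  known LOO pathology), while clamping keeps accuracies in $[0.5, 1]$ and
  identical distributions at chance.

The top 200 candidates then pass to `differential_test()` /
`differential_filter()`: a two-sided Mann–Whitney U test per protein
(exact when both groups have $\le 8$ tie-free values, normal approximation
with tie correction otherwise), Benjamini–Hochberg adjustment (the
published table says only "adjusted"; BH is the default of a
`{none, BH, bonferroni}` enum), and the two published keep-rules: adjusted
$p < 0.01$ — the stricter adjusted-value reading of the published
"p-value < 0.01" — and strictly opposite-signed group means (a zero mean
fails). Survivors partition into group-A-active and group-A-inactive;
`biomarker_report()` orders them by signal strength
$|\bar{x}_A \cdot \bar{x}_B|$ and annotates best-classifier membership.
The published table's own strength column is *not* the product of its
printed means and its formula is not public, so `reference_biomarkers()`
carries it verbatim as `strength_printed` and the package never recomputes
it.

`overrepresentation()` is a generic one-sided Fisher over-representation
utility on user-supplied GMT gene sets (log10 odds with Haldane correction
on zero cells); it does not attempt to reproduce any specific enrichment
service's permutation machinery.

## Proximity cross-check

`propagate_seeds()` is a random-walk-with-restart scorer on the
unweighted, undirected network skeleton (restart probability 0.15,
dangling mass recycled to the restart distribution, scores summing to 1).
It is a generic stand-in for service-based guilt-by-association scorers,
and its outputs are labelled as such — it does not replicate any
particular web service. `top_fraction()` takes the top 2% by default (the
published cut), rescuing seeds that fall below the cut, and
`overlap_report()` counts biomarkers in the union of top sets with a
hypergeometric enrichment p-value.

## The synthetic-data generator

Real inputs to such a study — the curated human protein network, the
proprietary effector catalogue, expression-derived node states — are not
redistributable. `generate_network()` and `plant_instance()` exist so
every downstream stage is testable with known ground truth:

- topology: undirected preferential attachment (`igraph::sample_pa`,
  attachment 2), random edge orientation, inhibitory sign with probability
  0.3 — scale-free-ish and sparse like curated signalling networks;
- scale: 300 proteins by default, two stimulus targets both clamped at
  $-1$ (mirroring a dual-inhibitor drug), 15 + 15 effectors, 15 extra
  restrictions. Large enough for quartile statistics over a 200-MoA
  ensemble, small enough that a full 250-run analysis takes about a
  minute on one CPU — these are the problem sizes used by the acceptance
  script and test suite;
- ground truth: true weights are drawn in the sign-respecting intervals,
  true signals propagated from them, and effectors drawn only among
  reachable nodes whose true signal clears a 0.05 magnitude floor, so
  planted states are never numerical noise. Indication effectors carry the
  *opposed* (disease) state — the planted mechanism reverts them, as a
  working treatment should — while adverse-event effectors carry the
  induced state. Restrictions hold the response states, so with zero
  restriction noise the planted weights satisfy all of them exactly, and
  `restriction_noise` flips each extra restriction to emulate noisy
  expression-derived labels.

What the generator does **not** emulate: tissue-specific wiring, the
hundreds of phenotype definitions of a real effector catalogue, realistic
expression noise structure, or phenotype pairs with partially independent
molecular bases. The last point matters when interpreting synthetic runs:
both planted phenotypes are read off the same optimized signal field, so
indication response and adverse-event induction are strongly coupled
across the ensemble — intersection groups can be lopsided, and with only
$\sim$12 MoAs a side the intersection contrast often yields few or no
differential biomarkers after BH at $\alpha = 0.01$, whereas the full
quartile contrasts (50 vs 50) are well powered. Passing tests on planted
instances therefore demonstrate correctness of the machinery, not
biological realism of any particular count.

## Degenerate inputs and numerical conventions

- Duplicate edges, self-loops, contradictory states, out-of-range weights
  and malformed sign tokens are rejected with named errors, never
  repaired.
- Ensemble selection errors when no run clears `min_accuracy` (advising
  schedule changes) and, unless `allow_fewer`, when fewer than `K` do.
- Tied intensities at a quartile boundary fill groups in seed order and
  warn.
- `mhd`/`mds_embed` refuse dimension mismatches; `mds_embed` errors when
  the requested dimension exceeds the positive spectrum, listing it.
- All stochastic stages are pure functions of their seed: the C++
  annealing core uses its own mt19937-derived uniform/Gaussian draws
  (the standard library distributions are implementation-defined), and R
  generators save and restore the caller's RNG state.

## Known limitations

Signals are qualitative ($[-1,1]$ saturation, no dosage or expression
quantities). The annealing schedule is a default, not a tuned optimum, and
accuracy on hard (noisy or contradictory) restriction sets depends on it.
LOO stump accuracy on groups this small has high variance, which is why
the multiple-testing step is applied to the Mann–Whitney p-values rather
than classifier accuracies. The proximity scorer is one member of a family
of propagation scorers and results should not be read as replicating any
specific external service. And the in-silico cohort metaphor is exactly
that: labels like "Low-disease MoA" describe model strata, not clinical
claims about real patients.
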