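---
title: "Mining descriptive structure-odor rules: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining descriptive structure-odor rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorminer)
```

## The model

`odorminer` treats structure–odor analysis as supervised descriptive rule
discovery. The data are a set $M$ of odorant molecules, each molecule $m$
described by numeric physicochemical descriptors $f_i(m)$ and annotated with
a set of olfactory qualities $\mathrm{class}(m)$. A *description* is a
conjunction of closed intervals $D = \langle [x_1,y_1], \dots \rangle$ over
a subset of descriptors; its *coverage* is
$\{ m \in M : x_i \le f_i(m) \le y_i \ \forall i \}$. A *structure–odor
rule* $D \to Q$ pairs a description with a target quality set $Q$; a covered
molecule is a positive when it carries **every** quality of $Q$, i.e.
$Q \subseteq \mathrm{class}(m)$ — a molecule with additional qualities still
counts, which is the only reading consistent with multi-label data (almost
every molecule carries labels beyond $Q$).

Rule quality combines precision $P$ (fraction of the coverage that is
positive) and recall $R$ (fraction of all positives covered) through a
support-adaptive F-measure:

$$F_\beta = \frac{(1+\beta)\,P\,R}{\beta P + R}, \qquad
\beta(x) = \left(\tfrac12\bigl(1 + \tanh\tfrac{x - x_\beta}{\ell_\beta}\bigr)\right)^2,$$

with $x$ the support of $Q$. At $\beta = 0$ the measure reduces to $P$, at
$\beta = 1$ to the harmonic mean F1, and as $\beta \to \infty$ to $R$, so
rare qualities are judged almost purely on precision while frequent ones
must also be recalled broadly. Note the $(1+\beta)$ numerator: this is a
weighted harmonic family in which $\beta$ itself (not $\beta^2$ as in the
classical Fβ) interpolates, and the squared sigmoid keeps
$\beta(x_\beta) = 1/4$ at the centre. Both choices are implemented exactly
as stated; the `beta_direction` switch provides the mirrored (decreasing)
sigmoid for sensitivity analyses.

### Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_supp` | 5 (sweep 5/10/20/30) | molecules | minimum coverage of an emitted rule |
| `max_supp` | 700 | molecules | maximum coverage of an emitted rule |
| `max_qual` | 1 | qualities | size cap of the target set $Q$ |
| `max_properties` | 8 | descriptors | size cap of the description |
| `beam_width` | 30 | candidates | beam kept per search level |
| `max_output` | 100 | rules | rules returned per target |
| `x_beta` | 110 | molecules | sigmoid centre of $\beta(x)$ |
| `l_beta` | 20 | molecules | sigmoid width of $\beta(x)$ |
| `grid` | `"observed"` | — | refinement grid (or integer $k$ for quantiles) |

These defaults mirror the reference study's settings so a bare run
reproduces its operating point; `x_beta = 110` places the precision/recall
crossover above the median quality support, and `l_beta = 20` makes the
transition span roughly 40–80 molecules.

## The search

The beam starts from the unrestricted description and repeatedly applies
*minimal refinements*: shrink one bound of one descriptor to the next grid
value inside the current coverage (introducing a condition on a fresh
descriptor counts toward `max_properties`). Candidates below `min_supp` are
pruned, candidates are de-duplicated by coverage set (scores depend only on
coverage), and the `beam_width` best by $F_\beta$ survive to the next level.
All distinct candidates ever seen feed the result pool; the `max_output`
best that also satisfy `max_supp` are returned. Ties are broken
deterministically: larger support, then fewer conditions, then
lexicographically on the conditions. The search uses no randomness, and
because scoring and de-duplication work on coverage sets (molecule ids, not
row indices) the output is invariant to input row order.

Two design points deserve justification:

- **Termination.** The natural greedy stop — halt when no refinement
  improves the best $F_\beta$ — strands the search: removing a covered
  positive always lowers both precision and recall, so the first level at
  which every extreme molecule is a positive is a local optimum (the "hull
  of the positives"), even when a far better box lies a few worsening steps
  deeper past a handful of stray positives. The default therefore runs the
  beam until the (finite, de-duplicated) refinement lattice is exhausted,
  which on enumerable instances makes a wide beam provably equivalent to
  exhaustive search; `terminate = "plateau"` retains the greedy variant.
- **Refinement grid.** On the observed-value grid every refinement removes
  at least one molecule, which is exact but means $O(n)$ levels on large
  datasets. The quantile grid (`grid = k`) coarsens the candidate bounds to
  $k$ per descriptor, trading boundary resolution (about half a quantile
  spacing per side) for an order-of-magnitude shorter search; it is the
  recommended setting for datasets of hundreds of molecules or more.
- **`max_supp` on output only.** Broad intermediate descriptions are needed
  to reach specific boxes, so the coverage ceiling applies to emitted
  rules, not beam members.

## Selection, significance, validation

Per quality, candidate rules from each `min_supp` run are ranked by
precision and the nested prefixes of size 1..12 are evaluated as
*combinations* — disjunctions whose coverage is the union of member
coverages, the only reading under which adding rules raises recall. The
combination minimizing the Euclidean distance of its
$(\mathrm{error}, \mathrm{recall})$ point from the ideal $(0, 1)$ (error
$= 1 - P$) is selected; ties are all retained, candidates from different
`min_supp` runs are not mixed inside one combination, and an exhaustive
subset search (`strategy = "exhaustive"`, pools $\le 15$) serves as the
oracle for the prefix heuristic. Outcomes are classified into four groups by
the conventions error $< 0.5$ (groups 1–2) and recall $\ge 0.5$ (groups
1, 3), and into distance quartiles at linearly interpolated 25/50/75
percentiles (a molecule-ranking convention the source material leaves
unstated; fixed here for reproducibility).

Significance of a selected ruleset covering $X$ molecules is assessed
against chance: 100,000 resamples of $X$ molecules drawn uniformly **with
replacement**, each scored with the same measure used in mining, and a
two-sided 99% percentile interval; the ruleset is significant when its
observed F exceeds the upper bound (one-sided). Because draws are with
replacement, per-resample precision counts duplicate draws while recall
counts distinct molecules (capped at 1); the duplicate-counting variant is
available as `recall_mode = "multiset"`. Two consequences are worth knowing:
the distinct-ID convention shifts the null F slightly below an
equivalently-sized set's F, making the test mildly anticonservative (the
measured null flag rate is near 1% rather than the continuous-nominal
0.5%), and no multiple-testing correction is applied across qualities —
deliberately, to match the procedure being reproduced.

External validation applies a quality's selected combination to an
independently rated odorant panel: molecules in the union coverage are
Rule(1), the rest Rule(0) (missing descriptor values force Rule(0), never an
error), and ratings are compared by classical one-way ANOVA with
$\eta^2 = SS_{between}/SS_{total}$, skipping qualities with fewer than five
Rule(1) molecules. Ratings are analysed untransformed; cross-vocabulary
quality matching is an explicit user-supplied alias table, never automatic.

## The synthetic generator

`synthetic_spec()` emulates the statistical structure the miner assumes,
not real chemistry: i.i.d. uniform or normal descriptors (no inter-descriptor
correlation), planted axis-aligned boxes that assign their label with
probability `p_inside` inside and `p_outside` outside, and background
qualities with a geometric support profile rescaled to the target mean
labels per molecule (defaults: 1689 molecules, 82 descriptors, 74
qualities, supports spanning roughly 2–570, mean 2.88 labels/molecule,
every molecule guaranteed at least one label). Planted boxes live in the
miner's own hypothesis class, so recovery benchmarks test parameter
recovery under label noise, not model misspecification; passing them says
nothing about descriptor collinearity, heavy-tailed descriptors or
annotation biases of real atlases.

## Numerical choices and problem sizes

- Zero denominators in $P$, $R$, F1, $F_\beta$ yield 0 with a flag; mining
  never raises on degenerate counts.
- $\beta(x)$ saturates to exactly 1 in double precision around
  $x \approx x_\beta + 19\,\ell_\beta$; monotonicity is strict before that.
- Interval bounds are closed on both ends; a missing value on a restricted
  descriptor excludes the molecule from coverage (conservative).
- Correlation pruning keeps the earlier column in file order; variance
  retained is the summed raw per-column variance ratio (a stand-in
  definition, `standardize = TRUE` available).
- Selection ties use a $10^{-12}$ distance tolerance.
- Test and benchmark sizes were chosen to exercise each property at
  desk scale: exhaustive-search equivalence on instances of up to 8
  molecules and 3 descriptors (where full enumeration is the oracle);
  planted-box recovery at 500 molecules, 5 descriptors, `p_inside` 0.9 /
  `p_outside` 0.02 over 20 seeds with a 32-quantile grid; bootstrap null
  calibration at 1689 molecules with 1,000 shuffled-label qualities and
  10,000 resamples (the acceptance script runs a 300 x 2,000 version).

## Known limitations

The beam is a heuristic: outside enumerable instances optimality is not
guaranteed, only never-exceeding the exhaustive optimum. The quantile grid
bounds box edges to grid resolution. The bootstrap test inherits the
selection optimism of mined rules (it compares against random coverages,
not against rulesets mined on shuffled labels), so its significance verdict
is a necessary, not sufficient, indication of structure. The generator's
independence assumptions make recovery benchmarks optimistic relative to
strongly collinear real descriptor sets.
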