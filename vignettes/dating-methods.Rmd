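---
title: "Penalized-likelihood dating with fossil calibrations: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized-likelihood dating with fossil calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pldater)
```

## The problem

Given a rooted phylogram — a fixed topology whose branch lengths are
expected substitutions per site, estimated from a molecular alignment — we
want a chronogram: the same topology with node ages in millions of years
(My), tips at the present. Branch lengths confound rate and time
(`length = rate x duration`), so absolute ages require two extra
ingredients: an assumption restraining how rates vary across the tree, and
fossil calibrations that pin some node ages inside hard intervals.
`pldater` implements the penalized-likelihood (PL) approach for this,
together with the machinery around it: calibration-bound generation from a
fossil table, cross-validated selection of the smoothing parameter
(including a subsampled scheme for very large trees), bootstrap node-age
confidence intervals, taxonomy-based constraint trees for the upstream tree
search, and a quality-control cascade for database-mined barcode sequences.

## The model

Let `x_k = round(length_k * n_sites)` be the substitution count on edge
`k`, where `n_sites` is the alignment length. The model treats
`x_k ~ Poisson(r_k * t_k * n_sites)` with `r_k` the edge's rate
(substitutions/site/My) and `t_k` its duration (My). The fitted objective
is

```
-sum_k log Poisson(x_k; r_k t_k n_sites)
  + lambda * [ sum_{k non-root} (r_k - r_parent(k))^2 + Var(root-child rates) ]
```

minimised jointly over all node ages and edge rates, subject to
`age(parent) >= age(child)`, tips at age zero, and every calibrated node
inside its hard `[min, max]` window. The penalty expresses rate
autocorrelation: adjacent edges should have similar rates, and the
smoothing parameter `lambda` (dimensionless) sets how strongly. As
`lambda -> infinity` the fit approaches a single-rate molecular clock; as
`lambda -> 0` rates are free and the likelihood saturates (`mu_k = x_k`),
in which limit the ages are determined only by the constraint set and the
penalty's preference among rate surfaces. Factorial terms of the Poisson
log-probability are retained, so the reported objective is a true negative
log-likelihood plus penalty.

Zero-length edges get `x_k = 0` and contribute only their expected count
`r_k t_k n_sites` to the objective; durations are floored at `1e-9` My
inside the optimiser so logarithms stay finite.

### Optimisation

Ages are parametrised per internal node as a height fraction in `[0, 1]`
between that node's feasible envelope: the lower end is the largest
minimum bound among its descendants, the upper end the smaller of its own
maximum bound and its parent's current age. Every parameter vector
therefore maps to a feasible chronogram by construction — no penalty terms
or repair steps are needed for the hard constraints. Rates are optimised
in log space. Gradients are analytic (the envelope transform is
differentiated by a backward sweep), and L-BFGS-B does the local search
from five starts by default: a projection of the phylogram's own node
depths onto the feasible envelope with per-edge rate estimates, a flat
mid-envelope start with a global rate, and seeded jitters of the
projection. Convergence tolerances default to `factr = 1e4`
(objective-scaled) and up to 500 iterations; validation experiments that
need tight optima raise `maxit` and tighten `factr`, at costs noted below.
A calibration window with `min == max` pins a node exactly (its envelope
collapses), which is also how the clock likelihood-ratio test fixes the
root age at 1 to remove the unidentifiable overall scale.

Two facts about this objective are worth stating plainly, because they
drive several design choices below. First, absolute scale is only
identified by the calibration windows: rescaling all ages by `c` and rates
by `1/c` leaves the likelihood unchanged and scales the penalty by
`1/c^2`, so the fit tends to drift toward the oldest ages the windows
allow, and within a window interior the objective can be nearly flat.
Second, the numerical weight of the penalty depends on the square of the
rate scale: at realistic plastid rates (~2e-3 substitutions/site/My) a
given `lambda` is roughly a million times weaker than at rates of order 1.
Meaningful smoothing values are therefore data-scale dependent, which is
why the cross-validation grid is a tunable input rather than a constant of
the method.

## Calibrations

The fossil table (packaged at
`system.file("extdata", "fossil_calibrations.tsv", package = "pldater")`,
55 fossil rows) supplies minimum ages; every fossil is treated as a hard
minimum, and the hard maximum is generated from the minimum. Two bound
schemes are implemented:

* **empirical** (default): `max = min + w`, with `w` resolved from the
  table as the modal rounded `max - min` difference, 16.82 My. The
  table's maxima print at most four significant figures, so rows with
  three-digit ages show the same constant rounded to one decimal (16.8);
  the modal value reproduces every printed maximum at its printed
  precision.
* **analytic**: `max = min + exp(log_mean + z(level) * log_sd)` — the
  upper quantile of a log-normal offset at the fossil age. With mean 1,
  sd 1 and level 0.95 this adds about 14.08 My, which does not equal the
  table's constant; both schemes are exposed and the discrepancy is left
  visible rather than reconciled.

Crown calibrations attach to the most recent common ancestor of the
clade's tips; stem calibrations to that node's parent. Non-monophyletic
tip sets still resolve to their MRCA, with a warning. The root window
defaults to 180–220 My, a conventional hard bracket for the angiosperm
crown age. `emit_dating_config()` writes the constraint system in the
treePL configuration dialect, deterministically ordered, with a JSON
mirror.

## Smoothing selection by cross-validation

`cv_score()` implements terminal-pruning cross-validation: drop a tip,
refit at the candidate `lambda`, and predict the dropped terminal's
substitution count as (rate of the merged sibling edge) x (age of the
attachment point) x `n_sites`, the attachment age interpolated along the
merged edge in proportion to the original branch lengths. Prediction error
is chi-square by default (`(obs - exp)^2 / exp`; plain squared error is a
switch). Terminals whose parent is the root, or whose pruning leaves a
calibration without its clade, are skipped and logged.

Each grid value is scored from the same deterministic cold starts. An
earlier design warm-started each `lambda` from the previous one's
solution; that is faster but subtly wrong here, because at numerically
weak penalties the optimiser simply inherits the previous solution and the
comparison between grid values degenerates.

`subsampled_cv()` is the scheme for trees too large to cross-validate
directly: many replicates are drawn by randomly keeping a fraction of the
tips (default 10%), each replicate runs the grid cross-validation, and the
selected smoothing value is the one chosen by the highest proportion of
replicates (ties break toward the smaller value, i.e. less smoothing).
Subsampling can invert the nesting of calibrated clades — after pruning,
one clade's MRCA may slide below another's while keeping an older minimum
— so calibrations that make a replicate's bound system infeasible are
dropped for that replicate, mirroring the rule that only surviving clades
constrain.

The default grid is the geometric sequence from 10 down to 1e-4 with ratio
0.9 (110 values). For the synthetic validation experiments in this
package, the tests use a grid shifted upward (e.g. 1e6 down to 10, eight
values): at plastid-scale rates the penalty is numerically invisible
anywhere inside 1e-4..10, and a grid that cannot change the fit cannot be
selected over.

## The clock test

`clock_test()` is a chi-square likelihood-ratio test: the free model fits
one Poisson mean per edge (closed form, `mu_k = x_k`); the clock model
fits a single shared rate with ultrametric ages, root age fixed at 1
because only rate x time products are identifiable without calibrations.
The degrees of freedom are `#edges - #internal nodes`: the clock model's
identifiable parameter count is the number of internal nodes (ages times
rate, less one for the arbitrary scale). On a rooted binary tree with `n`
tips this is `n - 1`. Simulation under the null (strict clock, Poisson
counts) puts the empirical size at the nominal 5% level within Monte-Carlo
error, which would not hold for the naive count that ignores the scale
non-identifiability.

## Bootstrap confidence intervals

`make_bootstrap_phylograms()` redraws each edge's substitution count as
`Poisson(length * n_sites)` on the fixed topology — a site-resampling
surrogate that preserves the contract of dating every replicate on the one fixed
ML topology. `date_replicates()` dates each replicate
under the same calibrations and smoothing, warm-starting from the
full-data fit; `summarize_node_ages()` collects per-node age samples keyed
by bipartition (so newick rotations are harmless) and reports equal-tailed
empirical intervals using type-7 (linear) quantile interpolation, stated
here for bit-reproducibility. Bootstrap samples are frequentist, so
equal-tailed quantiles are the default; a highest-density option exists
for comparison with TreeAnnotator-style summaries. Annotated output is
NEXUS with `[&age_95_CI={lower,upper}]` comments plus a per-node TSV.

Two caveats follow from the model section. At nodes where a hard bound is
active, every replicate tends to sit on the same boundary and the interval
collapses to zero width — a real artifact of hard-bound PL dating, not a
summariser bug. And branch-length resampling cannot see the absolute-scale
flatness inside windows, so the intervals quantify substitution-sampling
noise conditional on the calibration scheme, not total dating uncertainty.

## The synthetic-data generators

`simulate_chronogram()` runs a constant-rate birth-death process
conditioned on the number of extant tips by simple sampling: forward
simulation stops the first time the extant count reaches `n_tips`, the
standing tree is observed at a uniform point of the exponential overshoot
before the next event (so the youngest divergence has a positive age),
extinct lineages are pruned, and fully extinct runs are retried.
`simulate_rates()` lays geometric Brownian motion over the tree: each edge
multiplies its parent's rate by `exp(N(-sd^2/2, sd))`, the drift keeping
expected rates constant along paths — the autocorrelation structure the PL
penalty smooths toward. `chronogram_to_phylogram()` forms
`rate x duration` lengths, optionally Poisson-noised at a stated alignment
length; `sample_calibrations()` draws true-age-consistent min/max windows
of constant width (redrawing minima whose window would miss the truth);
and taxonomy/marker-record generators produce family-structured coding
sequences for the QC chain.

Defaults are chosen to emulate a plastid-barcode supermatrix study: birth
0.05/lineage/My and no extinction (root ages near 100 My for 100 tips),
root rate 0.002 substitutions/site/My, log-sd 0.2 per edge, 4,968
alignment columns. What the generators deliberately do **not** emulate:
alignment error, rate variation among sites, GTR-level sequence evolution,
topology error (the bootstrap surrogate keeps the topology fixed), or the
database-mining process itself. Tests passing on these data therefore
validate the estimation machinery, not robustness to misalignment or
topological uncertainty.

## Quality control for mined sequences

The QC chain is an offline, auditable re-implementation of a
GenBank-mining filter cascade; every record receives exactly one verdict
and every dropped record names its rule. In order: dual-checklist name
validation (a name must be valid in both lists — conjunction), a
similarity screen (k-mer-seeded local alignment against a user-supplied
reference panel; kept only if the best significant hit is in the record's
own family-level group; defaults E-value 5e-4, word size 8, 250 candidate
hits), an ambiguity filter (drop above 1% non-ACGT symbols by default), a
reading-frame screen on coding spans (frame given for rbcL, longest-ORF
scan for matK inside trnK; drop on broken codon structure, internal stops,
or translated identity below 0.7 to a same-family reference), and
conflicting-duplicate handling (same name, sequences beyond 5% p-distance
on the aligned overlap: the species is removed; consistent duplicates
collapse to the best accession — fewest ambiguities, then longest, then
highest mean similarity to the species' other accessions, ties broken by
accession string). The similarity screen's E-value uses fixed
Karlin-Altschul-style constants as a surrogate for a service-side BLAST
statistic; the decision rule, not the service, is what is preserved.
Thresholds without a published value (ambiguity fraction, duplicate
divergence, translated-identity floor) are configurable and logged.

## Validation experiments and their problem sizes

The test suite ties every stage to an independent oracle or known truth.
The sizes below are the package's choices for a single-CPU run of the
whole suite in well under half an hour:

* the penalized objective against a naive brute-force implementation on
  200 random 6-tip instances (agreement to 1e-8);
* exact age recovery with every node pinned `min = max`, and sub-0.5%
  recovery on noiseless clock data with the root age known (40 tips,
  1e5 sites; nodes younger than 1 My are excluded from the per-node
  relative check because a single rounded substitution count exceeds
  0.5% of their age);
* the clock limit: rates' coefficient of variation below 1e-3 at
  `lambda = 1e6` on data whose rate scale makes that value deeply
  clock-forcing (20 tips, rate 1, 300 sites);
* clock-test size on 500 strict-clock simulations (8 tips, 5,000 sites)
  and power at log-sd 0.5;
* age recovery on 50 heterogeneous-rate simulations (100 tips, log-sd
  0.2, 4,968 sites, a root window plus 10 random windows of width
  16.82 My): median **relative RMSE** below 10%, where relative RMSE is
  the root-mean-square error of internal node ages divided by the true
  root age. Tree-height normalisation is used deliberately: per-node
  relative errors are unbounded at near-present nodes (a 0.1 My node
  carries about two expected substitutions), and no estimator can bound
  them — an independent PL implementation (`ape::chronos`) run on the
  same data shows substantially larger normalised errors than this
  package's fits;
* subsampled cross-validation on a 200-tip strict-clock tree (20
  replicates keeping 10%, an 8-value grid): the modal smoothing value
  must land in the top two grid values;
* interval quantiles against a brute-force type-7 oracle (the planted
  sample 1..100 yields [3.475, 97.525] at 95%), and interval coverage on
  30 simulated datasets (70 tips, 60 replicates, strict clock,
  `lambda = 1e7`, root age pinned at truth): true ages inside the 95%
  interval for at least 80% of nodes on average. The root is pinned in
  this experiment because, as discussed above, branch-length resampling
  carries no information about the absolute scale inside a hard window;
  with a windowed root the point estimate parks on a boundary and
  coverage measures the window placement, not the summariser;
* QC chain conservation and idempotence, with a planted cross-order
  mislabel that must fall to the similarity screen.

## Known limitations

The optimiser is local: multi-start with informed projections has been
reliable on the tested scales, but very flat penalty regimes (tiny
`lambda` at small rate scales) leave ages underdetermined by construction,
and different starts can then return different, equally-scoring
chronograms. Hard bounds make boundary solutions common; interpret
zero-width bootstrap intervals at calibrated nodes as "constraint active",
not "age known exactly". The Poisson branch-count model ignores among-site
rate variation and alignment uncertainty, inheriting the standard PL
assumptions. The subsampled cross-validation inherits the variance of
random pruning; its output is a mode over replicates and should always be read together
with its proportion — on large heterogeneous datasets winning proportions
near 10–15% are typical: the mode is clear but not dominant.
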