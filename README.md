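# pldater

Penalized-likelihood divergence-time estimation with hard fossil
calibrations, for R.

## What problem this solves, and for whom

Molecular phylogenies come with branch lengths in expected substitutions
per site; comparative biologists, community ecologists and biogeographers
need branch lengths in time. Because a branch length is the product
`rate x duration`, converting a phylogram into a chronogram requires an
assumption about how substitution rates vary across the tree plus fossil
calibrations that bound some node ages. For very large trees (tens of
thousands of tips, e.g. megaphylogenies mined from sequence databases),
penalized likelihood with hard minimum/maximum age constraints is the
standard workhorse. `pldater` implements that method and the full pipeline
around it, in pure R, with every stage testable offline against synthetic
data of known truth.

## The core model

Per-edge substitution counts `x_k = round(length_k * n_sites)` are modelled
as `Poisson(r_k * t_k * n_sites)`, with `r_k` the edge rate
(substitutions/site/My) and `t_k` the edge duration (My). Node ages and
rates jointly minimise

    -log L(ages, rates) + lambda * Phi(rates)

where `Phi` is the rate-autocorrelation roughness penalty (squared
parent–child rate differences plus the variance of the root's child-edge
rates) and `lambda` is the smoothing parameter: large `lambda` forces a
molecular clock, small `lambda` lets rates roam. Hard constraints —
`age(parent) >= age(child)`, tips at zero, calibrated nodes inside
`[min, max]` windows, a root window — are enforced by construction through
a feasible-envelope parametrisation, and gradients are analytic.

Around the core: fossil-table handling with maximum ages regenerated from
fossil minima (`min + 16.82` My, the constant interval of the packaged
55-row calibration table); smoothing selection by terminal-pruning
cross-validation, including a subsampled-replicate scheme for trees too
large to cross-validate directly; a chi-square likelihood-ratio clock
test; bootstrap pseudo-replicate dating with per-node 95% confidence
intervals (TreeAnnotator-style annotated NEXUS output); an order-backbone
constraint-tree builder (families as polytomies, genera unconstrained);
and an auditable quality-control cascade for database-mined barcode
sequences (similarity screen, best-accession choice, ambiguity filter,
frame-shift screen, conflicting-duplicate removal, dual-checklist name
validation).

## A worked example

Simulate a 50-tip truth set (birth–death chronogram, autocorrelated
log-normal rates, Poisson substitution noise at 4,968 sites), date it back
under a root window plus seven sampled fossil-style windows, and summarise
bootstrap intervals:

```r
library(pldater)

cfg   <- sim_config(n_tips = 50, rate_log_sd = 0.2, seed = 42)
truth <- simulate_truth(cfg, k_calibrations = 8)
max(truth$ages)                             # true root age: 67.98 My

ri   <- which(truth$calibrations$clade_label == "root")
root <- root_constraint(truth$calibrations$min_age[ri],
                        truth$calibrations$max_age[ri])
cals <- truth$calibrations[-ri, ]

problem <- pl_problem(truth$phylogram, cals, root, lambda = 1e5)
fit     <- date_tree(problem, seed = 1)
fit
#> PL fit: root age 65.65 My, rate range [0.000812, 0.00477] subst/site/My,
#>   penalized -lnL = 295.3877 (lambda = 1e+05)

age_recovery_error(fit, truth$chronogram)   # 0.0178

reps  <- make_bootstrap_phylograms(truth$phylogram, 30, seed = 2)
dated <- date_replicates(reps, problem, fit)
summarize_node_ages(dated, fit$chronogram)
#> Annotated chronogram: 49 internal nodes, 95% quantile intervals
#>   root age 65.65 My, interval [64.61, 67.52]

clock_test(truth$phylogram, seed = 1)
#> Molecular clock LRT: chi-square = 2108.891, df = 49, p = 0
```

Reading the numbers: the fitted root age (65.65 My) sits inside its hard
window and within 3.5% of the simulated truth; the recovery error (RMSE of
all internal node ages over the true root age) is 1.8%; the bootstrap
interval reflects substitution-sampling noise around the point estimate;
and the clock test decisively rejects rate constancy for these
heterogeneous-rate data, which is exactly why a smoothed, calibrated
dating step is needed.

The fossil calibration table ships with the package:

```r
tab <- read_calibration_table(system.file("extdata",
        "fossil_calibrations.tsv", package = "pldater"))
nrow(tab)                    # 55 fossil calibration rows
resolve_interval_width(tab)  # 16.82 My constant max - min interval
compute_max_age(37.8)        # 54.62
```

`run_pipeline()` (and the thin wrapper in `inst/scripts/run_pipeline.R`)
chains simulation, calibration emission, optional cross-validated
smoothing selection, dating, bootstrap dating and interval annotation into
one seeded, manifest-writing run.

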