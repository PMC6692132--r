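# mutfit

Tools for estimating the fitness effects of single-nucleotide mutations in
a bacterial gene from head-to-head competition assays, and for the
downstream questions those estimates raise: do synonymous and
nonsynonymous mutations have different distributions of fitness effects
(DFE)? What is the shape of the beneficial tail? Do codon usage, position,
or transcript abundance explain the fitness variation? Do the fitter
mutations recur across a phylogeny of related strains?

The package is aimed at experimental-evolution and molecular-evolution
researchers working with site-directed mutant libraries and competition
fitness data.

## What it computes

**Relative fitness.** Per replicate, `w = (f_final / f_initial)^(1/d)`
where `f` is the mutant:reference colony-count ratio and `d` the number of
population doublings; plates with fewer than 30 colonies of either strain
are excluded, replicates are averaged per mutation with a standard error,
and a marked-reference control is estimated by the same code path
(`estimate_fitness()`, `marker_control()`).

**DFE comparison.** Selection coefficients `s = w - 1` per mutation class;
two-sample Kolmogorov-Smirnov `D` with a permutation-resampled p-value
(pooled label shuffle, add-one convention, `B = 10,000` by default)
(`build_dfe()`, `ks_compare()`).

**Beneficial tail.** Beneficial mutations (`w > 1`) are shifted to the
smallest observed `s` and the exceedances fitted by the Generalised Pareto
Distribution, `f(x) = (1/tau) (1 + kappa x / tau)^(-1/kappa - 1)`; a
likelihood-ratio test against the exponential (`kappa = 0`), with a
parametric-bootstrap null, classifies the tail into the Weibull
(`kappa < 0`, bounded: a local fitness optimum), Gumbel or Frechet domain
(`beneficial_tail()`, `fit_gpd()`, `gpd_tail_test()`).

**Codon covariates.** Mutation classification under the bacterial genetic
code, delta-CAI and delta-tAI for each substitution, distance from the
start codon, 42-nt mRNA windows for external folding tools, and a
translational-ramp test (`classify_mutation()`, `delta_metrics()`,
`ramp_test()`).

**Permutation regressions.** OLS with reduced-model
permutation-of-residuals p-values for all covariate and
expression-fitness regressions; plate-reader reporter series reduced to
relative expression values (`permlm()`, `process_expression()`,
`expression_fitness_regression()`).

**Phylogenetic presence.** Fitch parsimony over an ensemble of randomly
resolved polytomies, per-site independent-origin counts, and a binomial
model of presence on `log w` (`site_summary()`, `presence_model()`).

**Synthetic data.** A generator (`sim_config()`, `write_simulated_data()`)
producing every input file with the statistical structure the analysis
assumes -- a GPD beneficial tail planted in the true DFE, binomial
plate sampling, a linear expression-fitness link, and tip-state patterns
whose presence probability rises with fitness -- so the entire pipeline is
testable end to end without external data.

## Worked example

```r
library(mutfit)

cfg <- sim_config(seed = 7)                  # study-design defaults
dir <- file.path(tempdir(), "demo")
sim <- write_simulated_data(cfg, dir)

ft <- estimate_fitness(read.csv(file.path(dir, "competitions.csv")))
ft <- merge(as.data.frame(ft), sim$mutations[, c("mutation_id", "class")],
            by = "mutation_id")

dfe <- build_dfe(ft)                          # nonsense merged into nonsyn
ks_compare(dfe$synonymous$s, dfe$nonsynonymous$s, B = 10000, seed = 7)
#> Two-sample K-S test (permutation null, B = 10000)
#>   n = 39 vs 71;  D = 0.2120;  p = 0.1703

pooled <- ft[ft$class != "nonsense", ]
tl <- beneficial_tail(data.frame(w = pooled$w_mean))
#> threshold shifted to smallest beneficial s = 0.0001353419; minimal
#> observation dropped from likelihood
gpd_tail_test(tl$x, n_null_sims = 2000, seed = 7)
#> Beneficial-tail characterisation (GPD vs exponential)
#>   exponential: tau = 0.044617  (logLik 122.360)
#>   free GPD:    tau = 0.0648, kappa = -0.4546  (logLik 127.083)
#>   LR = 9.4473, bootstrap p = 0.008996 (2000 null sims), chisq p = 0.002115
#>   domain call: Weibull
```

Read: the synonymous and nonsynonymous DFEs are not distinguishable at
this sample size (`D = 0.21`, permutation `p = 0.17`); the pooled
beneficial tail rejects the exponential (`p = 0.009`) with a negative
shape estimate, i.e. a bounded, Weibull-domain tail -- the generator
planted `kappa = -0.35`, and at ~50 tail observations the estimate
scatters around it (here `-0.45`).

The same analysis runs as one call from a config:

```r
run_pipeline(list(seed = 7, outdir = "run", simulate = TRUE))
```

which writes `fitness.csv`, `dfe_report.json`, `covariates.csv`,
`regressions.json`, `phylo_presence.csv`, `presence_model.json`, a
`manifest.json` with seeds and input hashes, and an aggregated
`report.json`. Reruns with the same config are bit-identical.

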