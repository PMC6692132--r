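---
title: "Methods: fitness effects of point mutations, from colony counts to the beneficial tail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitness effects of point mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mutfit` implements a complete analysis chain for single-nucleotide mutants
of a bacterial gene assayed by head-to-head competition: estimating
relative fitness from colony counts, building and comparing distributions
of fitness effects (DFE) for synonymous and nonsynonymous mutations,
characterising the beneficial tail with extreme-value theory, regressing
fitness on codon-level and expression covariates with permutation
inference, and asking whether fitter mutations recur across a phylogeny of
related strains. A synthetic-data generator reproduces the statistical
structure of every input, so the full chain is testable without any
external data. This vignette records the models, the tunable parameters,
the numerical choices, and what the simulations do and do not demonstrate.

## Relative fitness from competition counts

Each mutant is competed 1:1 against a neutrally marked reference strain in
glucose-limited medium; initial and final aliquots are plated and colonies
of each strain counted. Per replicate,

$$ w = \left( \frac{f_{\mathrm{final}}}{f_{\mathrm{initial}}} \right)^{1/d}, $$

where $f$ is the mutant:reference count ratio and $d$ the number of
population doublings over the competition (about 6.7 or 13.2 depending on
the dilution regime; both are available as named presets, and `doublings`
is a per-replicate input column because the underlying dilution factors
are an experimental choice, not something the package can infer).
Replicates are technical; per mutation we report the arithmetic mean, the
standard error `sd/sqrt(n)`, and the replicate count, warning below four
replicates. Plates with fewer than 30 colonies of either strain, or any
zero count, are excluded with a logged reason; a mutation whose replicates
are all excluded is flagged as missing rather than dropped silently.

Two properties pin the estimator down and are enforced by tests: swapping
the mutant and reference labels maps $w \mapsto 1/w$ exactly, and
noiseless counts generated from any $(w^*, d)$ invert back to $w^*$ at
machine precision.

The marked reference's own cost is estimated by the identical code path
from marker-vs-wild-type control competitions. No marker correction is
applied by default -- the reported control fitness is close enough to
neutral that correcting is a judgment call -- but an opt-in flag divides
every mutant $w$ by the control mean.

## DFE comparison and the beneficial tail

Fitness values become selection coefficients $s = w - 1$. The synonymous
and nonsynonymous DFEs are compared with the two-sample
Kolmogorov-Smirnov statistic $D$; because the samples are small and tied
values occur, the null distribution is built by resampling rather than
the asymptotic formula. Our default is the exchangeability construction:
pool both samples, reshuffle the class labels $B = 10{,}000$ times, and
report $p = (1 + \#\{D^* \ge D\})/(B+1)$. The add-one convention keeps
$p$ off zero; a resample-with-replacement variant is behind a flag since
"bootstrapping the K-S statistic" admits both readings. Nonsense
mutations are merged into the nonsynonymous sample for this full-DFE
comparison (their strongly deleterious effects are exactly what
distinguishes the distributions) and always excluded from tail and
covariate analyses, where a prematurely truncated protein is
uninformative; a flag controls the merge.

The beneficial tail is the set of mutations with mean $w > 1$ -- a
deliberate plain-threshold rule with no significance filter, matching how
the pooled beneficial sample size is counted in this assay design. The
threshold is then shifted to the smallest observed beneficial $s$, and
exceedances $x = s - \min(s)$ are fitted by the Generalised Pareto
Distribution

$$ f(x) = \frac{1}{\tau}\left(1 + \frac{\kappa x}{\tau}\right)^{-1/\kappa - 1}, $$

in the sign convention where $\kappa < 0$ is the Weibull domain (bounded
tail, a local fitness optimum at $x = -\tau/\kappa$), $\kappa = 0$ the
Gumbel/exponential boundary and $\kappa > 0$ the heavy-tailed Frechet
domain. The minimal observation sits exactly at the shifted threshold and
carries no likelihood information, so it is dropped by default; the drop
is logged and can be disabled, since either convention is defensible.

The exponential null ($\kappa = 0$) has the closed-form MLE
$\hat\tau = \bar x$. The free model is maximised by a multi-start search:
a coarse grid over $(\log\tau, \kappa)$ restricted to the feasible region
$\{\tau > 0,\ 1 + \kappa x_i/\tau > 0\}$, with the best starts refined by
Nelder-Mead at `reltol = 1e-12`. The likelihood ratio
$\mathrm{LR} = 2(\ell_{\mathrm{free}} - \ell_{\mathrm{exp}})$ is clamped
at zero (values below $-10^{-6}$ raise a warning as optimiser failure);
its null distribution is nonstandard here because $\kappa = 0$ is not an
interior point, so the p-value comes from a parametric bootstrap --
simulate same-size samples from the fitted exponential, refit both
models, count $\mathrm{LR}^* \ge \mathrm{LR}$ with the add-one convention
-- with the asymptotic $\chi^2_1$ p-value reported only for reference.
Null refits that fail to converge are excluded and counted in the result.
The extreme-value domain is called from the sign of $\hat\kappa$, with
$|\hat\kappa| < 0.01$ flagged as indistinguishable from the Gumbel
boundary.

Tests anchor this machinery to independent ground truth: the closed-form
exponential MLE; the uniform distribution as GPD$(\tau, -1)$; a 100x100
feasible-grid likelihood oracle that the fitted optimum must dominate;
the support bound $\max x \le -\hat\tau/\hat\kappa$ for negative shapes;
parameter recovery at $n = 10{,}000$ across all three domains; and
type-I-error calibration of the bootstrap LRT at the study's tail size.

## Codon covariates

Mutation classification translates reference and mutant codons under the
bacterial genetic code (translation table 11; ATG/GTG/TTG accepted as
starts), with an exhaustive enumeration oracle covering every
codon-substitution pair. CAI follows the Sharp-Li definition: codon
counts pooled over a user-supplied reference gene set (typically
ribosomal proteins; the reference is a data input, not code), zero counts
smoothed to 0.5 so no weight is zero, weights normalised to the maximum
within each synonymous family, and the gene value the geometric mean over
codons excluding stops and the single-codon families ATG and TGG. tAI
weights each codon by the penalty-weighted gene-copy total of its
decoding tRNAs under the standard wobble rules (G34:U at 0.41, I:C at
0.28, I:A at 0.9999, U34:G at 0.68; Watson-Crick at 0); codons with no
decoding tRNA receive the geometric mean of the nonzero weights.
Species-specific re-optimisation of the wobble penalties is out of scope
and a documented limitation, as is any special handling of bacterial
AUA/lysidine decoding.

Per-mutation covariates are the mutant-minus-reference change in
gene-level CAI and tAI, the codon index, and the nucleotide distance from
the start codon ($p - 1$). mRNA folding energies are consumed as an input
column from an external folding tool; the package only extracts the
42-nt windows. For even widths the window is
$[p - 21,\ p + 20]$, placing the mutated base immediately right of
centre -- the centring convention for an even width is genuinely open,
and this choice is recorded here and asserted by tests. Windows running
past the available sequence (CDS plus optional flanks) are truncated and
flagged.

The translational-ramp question -- are early codons enriched for rare
codons? -- is answered two ways, because the published phrasing does not
fix the test: a linear trend of per-codon weight on codon index along the
whole gene, and a first-50-codons-versus-remainder contrast. Both use the
permutation engine below.

## Permutation inference for regressions

All covariate and expression regressions are ordinary least squares with
permutation-of-residuals p-values. Among the residual-permutation
variants we use the reduced-model (Freedman-Lane-style) scheme: for each
tested term, fit the model without it, permute those residuals, add them
back to the reduced fit, refit the full model, and compare the term's
partial F statistic to the observed one, add-one convention, default
$B = 10{,}000$. Raw response permutation is available behind a flag. The
partial F is invariant to affine rescaling of response and predictors, so
p-values are too; degenerate inputs are handled explicitly (a constant
response gives $F = 0$, $p = 1$; an exactly collinear design is an
error). The implementation is vectorised -- all permuted responses are
projected through precomputed QR factorisations at once -- so large $B$
is cheap. Tests verify the exact-fit and null edges, affine invariance,
agreement with the classical F-test under Gaussian errors, and nominal
type-I error.

Plate-reader reporter data are reduced to one relative expression value
per strain before regression: subtract the background strain's
fluorescence at every time point, locate the time of maximum net signal
(over the whole series -- the published "about 7 h" is descriptive, not a
fixed evaluation time), divide by blank-corrected optical density at that
time, and normalise to the wild type. Records with non-positive
blank-corrected OD at the chosen time are rejected with a reason. Group
comparisons of expression use the pooled-variance two-tailed t-test, with
the zero-variance edge cases documented rather than left to error.

## Phylogenetic presence

The phylogeny arrives as a rooted Newick tree, polytomies allowed; branch
lengths are ignored because the analysis is parsimony-based. Each
polytomy is resolved by sequential random pairing of its children, and
the whole analysis is repeated over an ensemble of 100 random resolutions
(seed-reproducible). Per site, a two-pass Fitch reconstruction gives the
minimum number of state changes; a single most-parsimonious
reconstruction is then fixed by unit-cost dynamic programming and
transitions are counted per branch, with ties between placing a change
early or late broken root-wards ("acctran", default) or tip-wards
("deltran") -- totals are identical either way and always equal the Fitch
score, which tests verify against brute-force enumeration over all
internal labelings and against an independent parsimony implementation.

Presence of a mutation "accounting for relatedness" has no published
formula, so two indicators are emitted: raw tip occurrence, and the
default rule requiring both occurrence and a mean inferred origin count
of at least one across the ensemble, so that a mutation carried by a
single clade is not counted as recurring. The presence-fitness model is
a binomial GLM of presence on $\log w$ (the "logarithmic relationship";
a linear-in-$w$ variant is behind a flag since the published transform is
not stated), reported with both the likelihood-ratio p-value and a
label-permutation p-value. Complete separation is detected and flagged
rather than silently returned.

## The synthetic-data generator

The generator exists to give every pipeline stage an input with the
statistical structure the analysis assumes, under the study's design:
39 synonymous, 65 nonsynonymous and 6 nonsense mutations at default; a
true DFE in which a beneficial draw (probability 55/104 among
non-nonsense mutations) has $s \sim \mathrm{GPD}(\tau = 0.05,
\kappa = -0.35)$ exactly, and non-beneficial draws come from a
half-Gaussian near-neutral component (sd 0.01) or a truncated-Gaussian
deleterious component (mean $-0.1$, sd 0.05, mixed 50:50), both confined
to $(-1, 0]$ so the DFE mode sits at neutrality; nonsense mutations from
the deleterious component shifted by $-0.6$. The non-beneficial families
are a modelling choice -- the published DFE shape is qualitative away
from the tail, and any family with a mode near zero serves the tests.
The tail scale $\tau = 0.05$ is likewise a choice (the study prints the
tail shape but not its scale).

Competitions are simulated as binomial plate samples: five replicates of
a 1:1 starting mixture, expected final mutant frequency
$f_0 w^d / (f_0 w^d + 1 - f_0)$ after $d = 6.7$ doublings, 200 colonies
per initial plate. The final plating depth adapts to the outcome: the
plate total is scaled so the rarer strain is still expected at about 100
colonies, emulating the experimenter's choice of plating dilution --
without this, a strongly deleterious mutant could never pass the
30-colony inclusion rule that the real assay applied while still
reporting nonsense fitness values. Colony counts are binomial with the
plate total fixed, so counts conserve the total on every plate; a
noiseless mode returns expected counts for exact-inversion tests. The
per-plate colony total is a config knob, not a claim about the study,
which does not report plating depths.

Expression is linear in true fitness with Gaussian noise for a 27-strong
synonymous subset; the defaults (slope 10, intercept $-9$, noise sd 0.27)
put the wild type at relative expression 1 and give the regression an
adjusted $R^2$ in the high-0.6s at the study's sample size, matching the
strength of the published relationship. Tip states are generated at the
pattern level -- present on at least one tip with probability
$\mathrm{logit}^{-1}(-1 + 8 \log w)$, carriers then scattered over a
small random tip set -- because the downstream analysis consumes only
binary states; no sequence evolution is simulated. The tree is a random
77-tip rooted tree with 20% of internal edges collapsed into polytomies.

Determinism is strict: one master seed, per-stage substreams derived from
it, and byte-identical output files for identical configurations, which
the tests check by hashing.

What passing on synthetic data shows -- and does not. The generator
matches the analysis assumptions by construction: linear
expression-fitness link, logistic presence model, binomial plate noise,
exchangeable replicates. Recovery of planted parameters therefore
demonstrates correctness of the estimators, not robustness to the ways
real data violate these assumptions (batch effects across competition
blocks, non-binomial overdispersion of colony counts, phylogenetic
non-independence beyond what the origin-count rule captures, reporter
saturation in expression assays).

## Pipeline, problem sizes, and reproducibility

`run_pipeline()` drives simulate, fitness, dfe, covariates, regressions
and phylo from one R-list/YAML/JSON config, validates that every enabled
stage's inputs resolve before anything runs, writes per-stage tables plus
a `manifest.json` (package version, seeds, config echo, input hashes) and
a `report.json`, and aborts naming the failing stage while keeping
earlier outputs. Reruns under a fixed config are bit-identical. The
orchestrator is exposed as an R function with a file-based config rather
than a shell executable: the package's users work in R, and a script
wrapper would add surface without capability.

Default inference sizes follow the analysis standards above
($B = 10{,}000$ permutations, 100 tree resolutions, 30-colony filter,
42-nt windows). The test suite and the acceptance script scale the
simulation-heavy checks to sizes chosen for tight Monte-Carlo error at
reasonable cost: GPD recovery at $n = 10{,}000$ per shape; LRT size
estimated from 500 outer replicates with 99-simulation inner bootstraps
(which make the nominal 0.05 attainable exactly); K-S calibration from
2000 replicates at $B = 199$ (binomial SE about 0.005 against a $\pm$0.02
acceptance band); 1000 random parsimony instances of up to 8 tips against
exhaustive enumeration; and one full pipeline run at the study-design
defaults.

## Known limitations

- tAI wobble penalties are the standard published constants; no
  species-specific optimisation, no lysidine/AUA special case.
- CAI is a gene-level metric; single-codon changes move it only by
  $(w_{\mathrm{new}}/w_{\mathrm{old}})^{1/L}$, so covariate regressions
  on $\Delta$CAI have intrinsically small dynamic range.
- mRNA folding energies and promoter-strength scores are inputs from
  external tools; the package neither predicts structures nor scans
  motifs.
- The generator's polytomy count is approximate when collapsed edges are
  adjacent (merges compound); only the zero-polytomy case is exact.
- Parsimony assumes unordered binary states and ignores branch lengths;
  ancestral-state frequencies are reported per original internal node by
  clade matching across resolutions and are undefined for nodes created
  by resolution.
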