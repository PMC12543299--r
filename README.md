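# mlggm — multilevel Bayesian graphical models for nested time series

Functional-connectivity studies record a multivariate time series per
participant and usually want conclusions at the *group* level. The two
common shortcuts — estimating each participant's network separately and
then eyeballing commonalities, or aggregating the raw data into one
"average participant" — both discard a level of the data. Aggregation in
particular hides individual differences and can reverse effect
directions (Simpson's paradox). `mlggm` instead fits both levels
jointly:

```
p(G, S_1, ..., S_N | data)  ∝  ∏_n p(data_n | S_n) p(S_n | G) · p(G)
```

* **Individual level** — each participant's network `S_n = (Ω_n, γ_n)`
  is a Gaussian graphical model: time points are `N(0, Ω_n⁻¹)`, a zero
  off-diagonal in the precision matrix `Ω_n` means conditional
  independence, and a spike-and-slab prior with binary indicators `γ_n`
  decides which of the `E = P(P−1)/2` edges are present.
* **Group level** — the edge indicators of all participants follow a
  Curie-Weiss model
  `p(γ | μ, σ) ∝ exp{ Σ_e γ_e μ_e + (σ/E) (Σ_e γ_e)² }`,
  with per-edge main effects `μ` and a single average interaction
  `σ ≥ 0` capturing how strongly edges travel together.

Given the group state, participants are conditionally independent, so a
Gibbs sampler alternates per-participant spike-and-slab sweeps (Rcpp)
with a Metropolis-within-Gibbs update of `(μ, σ)`. The package also
ships the two baselines (individual-only and aggregated analysis), an
exact simulator for the full generative process (Curie-Weiss graphs →
G-Wishart precision matrices → Gaussian series), and the evaluation
statistics used to compare them: ROC/AUC edge recovery, inclusion Bayes
factors `BF_e = posterior odds / prior odds`, group-to-individual
prediction with 95% bands, per-edge heterogeneity variance, and
split-R̂ convergence diagnostics.

## Worked example

Simulate a small cohort from the model, fit it, and ask which edges the
group-level network supports:

```r
library(mlggm)

cfg   <- simulation_config(P = 10, N = 12, T = 200, rho = 100, seed = 7)
truth <- simulate_study(cfg)
data_list <- lapply(truth$timeseries, prepare_data)

fit <- fit_multilevel(data_list,
                      fit_config(iterations = 300, burnin = 100,
                                 chains = 2, seed = 7))
fit
#> ml_fit (multilevel): 12 participants, 10 nodes, 2 chain(s) x 300 sweeps (burnin 100)
#>   max split-Rhat (Curie-Weiss parameters): 1.553

individual_edge_auc(fit, truth)   # 0.991
group_edge_auc(fit, truth)        # 1

bf  <- inclusion_bf(fit$group_probs)
tab <- data.frame(edge_id = 1:45, incl_prob = round(fit$group_probs, 3),
                  bf = signif(bf, 3), category = bf_category(bf))
head(tab[order(-tab$incl_prob), ], 5)
#>    edge_id incl_prob    bf category
#> 23      23     0.983 57.40  include
#> 36      36     0.981 51.40  include
#> 29      29     0.912 10.40  include
#> 1        1     0.897  8.72  include
#> 8        8     0.896  8.62  include
```

All five top-scored edges are true group edges. The AUCs say the
multilevel fit recovers essentially every individual edge
(pooled AUC 0.991) and ranks every true group edge above every absent
one (group AUC 1). `incl_prob` is the model-implied marginal probability
that an edge belongs to the group network, averaged over the posterior;
`bf` is the inclusion Bayes factor against the even prior odds, with
`include`/`exclude`/`insufficient` at the conventional 3 and 1/3
cutoffs. The elevated split-R̂ on some Curie-Weiss main effects is
typical of such a short chain at strong cohesion (saturated edges have
plateau likelihoods); edge summaries are stable long before those
plateaus mix, and longer runs at identified configurations pass the
R̂ < 1.05 criterion (see the convergence test in the suite).

A shell interface covering `simulate`, `fit`, `evaluate`,
`predict-individuals`, and `recovery-experiment` is installed at
`system.file("scripts", "mlggm", package = "mlggm")`; every run writes
its resolved configuration, seed, acceptance rates, and R̂ summary next
to its outputs, and reruns with identical flags are byte-identical.

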