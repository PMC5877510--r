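# nanoscreen

Comparative hazard screening of engineered nanomaterials (TiO2-, Ag-,
ZnO-class nanoparticles) by two quantitative frameworks, for
nanotoxicology and regulatory risk-assessment work:

* a **weight-of-evidence (WoE) / multi-criteria engine** that scores
  individual lines of evidence (LOEs) and aggregates them into a
  hazard score, with Monte Carlo uncertainty and rank-stability
  analysis, and
* a **discrete Bayesian-network engine** with exact inference by
  variable elimination, expectation-maximization (EM) learning from
  incomplete categorical records, entropy-based value-of-information
  analysis, normalized hazard scoring, and out-of-sample
  cross-validation,

plus a synthetic line-of-evidence generator with a known ground-truth
network, so the full two-framework comparison runs end to end with no
external data.

## The models

**WoE.** For LOE *j* of a material, a physico-chemical index
S<sub>j</sub><sup>p.chem</sup> ∈ [0,100] (mean of per-criterion state
scores) and a toxicity index
S<sub>j</sub><sup>tox</sup> = Σ<sub>i</sub> C<sub>i</sub><sup>tox</sup> D<sub>i,j</sub>
(class scores against the study's class-likelihood assignment) are
aggregated as

S<sub>j</sub> = w<sub>p.chem</sub> S<sub>j</sub><sup>p.chem</sup> + w<sub>tox</sub> S<sub>j</sub><sup>tox</sup>,  w<sub>p.chem</sub> < w<sub>tox</sub>,

weighted by normalized study-quality weights
w'<sub>j</sub> = W<sub>j</sub> / Σ W<sub>j</sub>, and summed into the
hazard score **V = Σ<sub>j</sub> S<sub>j</sub> w'<sub>j</sub>** used
for relative ranking. Monte Carlo scenarios redraw any subset of
{S<sup>p.chem</sup>, S<sup>tox</sup>, W} uniformly per LOE and report
the distribution of V′ and of the ranking order, including the average
absolute deviation mean(|V′ − V|).

**BN.** A directed acyclic network over categorical nodes
(physico-chemical descriptors, study descriptors, hazard) with one CPT
per node. Inference is exact; CPTs are learned by EM from records with
missing values; input nodes are ranked by entropy reduction
H(hazard|e) − Σ<sub>x</sub> P(x|e) H(hazard|e,x); and a hazard
posterior is collapsed to a normalized score with the uniform scale
(0, 1/3, 2/3, 1) over (None, Low, Medium, High).

## Worked example

```r
library(nanoscreen)

tab <- tio2_fixture()                  # bundled 22-LOE nano-TiO2 table
fit <- fit_aggregation_weights(tab)    # recover the unprinted weights
fit
#> Aggregation weights: w_pchem = 0.3000, w_tox = 0.7000 (max |residual| = 0.0043)

hazard_score(tab, weights = fit)
#> WoE hazard score for TiO2: V = 44.23 over 22 LOE (w_pchem = 0.30, w_tox = 0.70)

run_scenario(tab, scenario_spec(vary_weights = TRUE, seed = 42), weights = fit)
#> MC scenario [weights] for TiO2: V = 44.23; mean V' = 42.68 (sd 2.17), avg |V'-V| = 2.15 over 10000 iterations
```

The recovered weights say toxicity evidence carries 70% of each LOE's
aggregated index; V = 44.23 is TiO2's hazard score on the 0–100 scale
(printed two-decimal columns accumulate to within 0.01 of the published
44.24); and under weight-only uncertainty the score distribution
re-centres at the unweighted mean of the per-LOE indices (42.7) with a
2.2-point spread — the ranking signal survives weight uncertainty.

On the network side:

```r
net  <- synthetic_ground_truth()
post <- infer_posterior(net, list(nanoparticle = "NM_C"), "nm_hazard")
normalized_hazard_score(post)   # utility-weighted posterior, in [0, 1]
```

The complete analysis — WoE ranking, Monte Carlo uncertainty,
synthetic-database generation, EM learning with cross-validation
against the enumerated Bayes-optimal ceiling, and the two-framework
comparison — is laid out as numbered drivers under `analysis/`
(`01_woe_hazard_ranking.R` … `05_compare.R`), each writing its tables
under `results/`.

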