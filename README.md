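# tricotkit

Tools for **tricot** trials — *triadic comparisons of technology options* —
the citizen-science format for decentralized on-farm testing. Each
participant receives a blind package of three options (e.g. crop varieties)
labelled only A, B and C, grows them under their own conditions, and reports
which performed **best** and which **worst** for each trait. Many such small,
simple tasks aggregate into a statistically rigorous trial that covers far
more environments than a research station could.

`tricotkit` implements the computational core of that methodology for trial
designers and analysts:

- **Design**: incomplete block designs with blocks of three distinct
  options, approximately **A-optimal** (minimizing the Kirchhoff index
  `Kf = t · Σᵢ 1/μᵢ` of the option-concurrence graph, the sum of pairwise
  effective resistances — lower means comparisons are better connected and
  more robust to lost plots), **sequentially balanced** (any run of
  consecutive package numbers is near-uniformly replicated, so consecutive
  packages can be handed out per village, day or stratum) and
  **position-balanced** (each option appears about equally often as A, B
  and C).
- **Rankings**: best/worst reports become strict or partial rankings over
  option names; partial reports (only best, or only worst) are kept, not
  dropped.
- **Model**: the **Plackett–Luce model** assigns each option a worth
  `w_i > 0`; a ranking is built by successive choices with probabilities
  proportional to worths, and `w_i/(w_i + w_j)` is the probability that `i`
  outperforms `j` head to head. Fitting is by Hunter's monotone MM
  iteration, with optional pseudo-comparison regularization against a ghost
  item so estimates stay finite under attrition.
- **Heterogeneity**: **Plackett–Luce trees** recursively split the rankings
  on covariates (agro-climatic indices, management, household traits) via
  likelihood-ratio tests, and **forward selection** ranks covariates by
  cross-validated held-out log-likelihood.
- **Covariates**: growing degree days, maximum dry spell and heat days from
  user-supplied daily weather, windowed by planting date.
- **Reports**: a markdown overview for the trial manager plus one
  personalized result sheet per participant, revealing their three options
  and how their ranking compares with the trial-wide result.

## Worked example

```r
library(tricotkit)

# a design for 20 farmers testing 10 varieties
d <- generate_design(design_spec(10, 20, seed = 42))
validate_design(d)
#> tricot design diagnostics
#>   replication: 6-6
#>   max position deviation: 0
#>   max prefix imbalance:   2
#>   Kirchhoff index: 6.833333
#>   connected: TRUE; no within-block repeats: TRUE
```

Every variety is grown by exactly 6 farmers, occupies each position A/B/C
exactly twice, and any prefix of consecutive packages is replicated to
within 2 — you can hand packages 1–10 to one village and 11–20 to another.

```r
# a synthetic trial whose two environments have opposite preferences
syn <- synthesize_trial(5, 120, covariate_effect = 1, seed = 7)
rs  <- build_ranking_set(syn$responses, syn$project$design, "overall")
fit_plackett_luce(rs)
#> Plackett-Luce fit: 5 options, 120 rankings, loglik -214.589
#>     option log_worth
#>  option_04    0.1253
#>  option_03   -0.0005
#>  option_01   -0.0047
#>  option_05   -0.0549
#>  option_02   -0.0654

fit_pl_tree(rs, syn$covariates, min_node_size = 25L)
#> Plackett-Luce tree: 120 rankings, 2 leaves
#> environment in { env2 }  (LR = 10.85, p = 0.0283)
#>   * leaf: n = 60, top option = option_01
#>   * leaf: n = 60, top option = option_04
```

The pooled fit is nearly flat — the two environments cancel each other out —
but the tree recovers the interaction: preferences reverse between
environments, exactly how genotype-by-environment signal shows up in tricot
data. `generate_report()` then renders the overview and the per-participant
sheets.

A command-line umbrella covers the same pipeline:

```sh
Rscript -e 'tricotkit::tricot_cli()' design --options 10 --packages 20 --seed 42 --out design.csv
Rscript -e 'tricotkit::tricot_cli()' fit --design design.csv --observations obs.csv --out fit.json
```

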