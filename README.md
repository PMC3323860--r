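# mimofilter

Causal feature selection for classification problems with several binary
outcomes — e.g. prognostic gene signatures where survival, tumor size and
histological grade are all recorded for the same patients.

Conventional filter rankings score each feature by its univariate
association with the outcome, so the top of the list fills up with
*downstream effects* of the disease process rather than its causes.
`mimofilter` implements a forward-selection filter whose score adds a
causal term built from three-way interaction information across all
recorded outcomes:

- relevance: I(x_k; y_1) = -(1/2) log(1 - rho^2), the Gaussian-approximation
  mutual information of feature and primary target (point-biserial rho for
  the binary class);
- structural score of a feature pair: C(x_i, x_k) = -(1/m) * sum_j
  I(x_i; x_k; y_j), where I(x_i; x_k; y_j) = I(x_i; x_k) - I(x_i; x_k | y_j)
  is negative for joint causes of a collider (the "explaining-away"
  signature replicated across outcomes) and positive for effects;
- forward rule, step d+1: select argmax_k I(x_k; y_1) + (lambda/d) *
  sum_{i in S} C(x_i, x_k). With lambda = 0 this is exactly the plain MI
  ranking; lambda > 0 promotes features that look like joint causes of all
  the targets.

The package also ships:

- a linear-Gaussian causal-network simulator (40-node benchmark DAG with
  indirect/direct causes, a latent disease node, three median-binarized
  targets, effects and irrelevant nodes) plus cause-prioritization metrics;
- a Gaussian naive Bayes harness with AUC / 1-RMSE / SAR / F criteria and
  exact McNemar + Wilcoxon comparisons with Holm correction;
- meta-analytic multi-study protocols (holdout and leave-one-dataset-out)
  that pool correlations across cohorts with the Fisher z transform, and a
  5-year survival binarization helper;
- TSV/CSV readers, a JSON network/manifest format, and a thin CLI
  (`inst/cli/mimo.R`) with `simulate`, `rank`, `eval-synthetic` and
  `protocol` subcommands.

## Worked example

Simulate one benchmark dataset and rank its 36 observed features at
lambda = 2:

```r
library(mimofilter)

net <- default_network(seed = 2, sigma = 0.1)
d   <- simulate_network(net, n_samples = 100, seed = 102)
causal_forward_rank(d$features, d$targets, lambda = 2, v = 10)
#> MIMO causal ranking: lambda = 2, 10 of 36 features, 3 targets (primary y1)
#> # A tibble: 10 × 5
#>     step feature relevance causal_term  score
#>    <int> <chr>       <dbl>       <dbl>  <dbl>
#>  1     1 x16      0.501        0       0.501
#>  2     2 x4       0.000532     0.0961  0.0966
#>  3     3 x2       0.143        0.251   0.393
#>  4     4 x1       0.299        0.00694 0.306
#>  5     5 x5       0.0215       0.201   0.223
#>  6     6 x6       0.211        0.0772  0.288
#>  7     7 x8       0.289       -0.0379  0.251
#>  8     8 x19      0.498       -0.334   0.164
#>  9     9 x23      0.495       -0.411   0.0834
#> 10    10 x3       0.0333       0.00289 0.0361
```

Step 1 is pure relevance and picks an effect (`x16`), but from step 2 the
causal term takes over: the direct causes `x4`, `x5`, `x6`, `x8` and all
three indirect causes (`x1`–`x3`) enter the top 10 — `x4` with almost no
relevance (0.0005 nats) purely on causal evidence — while further effects
(`x19`, `x23`) are pushed down by their negative causal terms. The ground
truth is in `d$truth`.

Aggregated over 50 fresh networks at noise sd 0.1 (`eval_synthetic`):

```r
eval_synthetic(trials = 50, sigmas = 0.1, lambdas = c(0, 1, 2), seed = 1)
#>   sigma lambda mean_rank rank_ci top5_rate top5_ci n_trials
#> 1   0.1      0      21.7   0.366     0.000  0.0000       50
#> 2   0.1      1      20.3   0.626     0.052  0.0206       50
#> 3   0.1      2      14.3   1.313     0.132  0.0416       50
```

At lambda = 0 the five direct causes sit at an average rank of ~22 of 36
and *never* reach the top 5; at lambda = 2 their mean rank drops to ~14
and they hold 13% of the top-5 slots. `autoplot()` draws the curves;
`tidy()`/`glance()` give tibble views of every result object.

Multi-study validation, given a named list of studies (each `features` +
`targets`, aligned by feature identifier):

```r
hp <- holdout_protocol(studies, v = c(20, 50), lambdas = c(0, 1, 2),
                       reps = 100, seed = 7)
glance(hp)      # mean AUC / 1-RMSE / SAR / F per (v, lambda)
hp$win_loss     # datasets where lambda > 0 significantly beats lambda = 0
```

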