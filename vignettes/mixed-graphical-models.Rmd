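---
title: "Mixed graphical models from random-forest stability selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed graphical models from random-forest stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grafonet)
```

## The model

Multi-omics cohort data mix variable types: continuous molecular markers
(methylation, expression, glycan and metabolite levels, DXA body
composition) alongside binary and categorical clinical phenotypes. A
*mixed graphical model* (MGM) is an undirected network over such variables
in which an edge between $x$ and $y$ means that $x$ and $y$ are dependent
*conditionally on all other modeled variables*. Compared to a correlation
network, the conditioning removes edges that are explained by mediation
through a third variable, leaving the undirected skeleton of the direct
associations.

Estimating conditional dependence across mixed types is done here with
random forests. For each variable $i$ a forest predicts it from all
remaining variables (regression for continuous targets, classification
otherwise), and predictor importances within the target's row are converted
to ranks $1, \dots, p-1$. Every unordered pair $\{i, j\}$ thus receives two
directional ranks — $j$ as predictor of $i$ and $i$ as predictor of $j$ —
and is scored by the *worse* (maximum) of the two. The best-scoring $q$
pairs become the edges of one candidate graph. Ranks rather than raw
importances make the score comparable across regression and classification
targets, whose importance scales differ; this is also why ranks are
computed within each target row rather than globally.

A single forest fit overselects, so edge selection is wrapped in
*complementary pairs stability selection* (CPSS): the samples are split
$B$ times into random halves and their complements, the ranking is repeated
on each of the $2B$ half-samples, and the final model keeps only edges whose
selection frequency across the $2B$ candidate graphs is strictly greater
than a threshold $\tau$. With $\tau = 0.8$ and the default $q$, the
expected number of falsely selected edges is bounded near
$q^2 / ((2\tau - 1)P)$, with $P = \binom{p}{2}$ candidate pairs, which the
default $q = \lceil \sqrt{\alpha (2\tau - 1) P} \rceil$ keeps around
$\alpha = 0.05$ — and the empirical family-wise error rate under a global
null sits far below that bound (the test suite measures it directly).

Forest importances are non-linear partial effects and carry no sign, so
edge signs are estimated afterwards for display: each variable is regressed
on all others (linear or logistic), and an edge is labelled `+`/`-` when
the two partner coefficients agree in sign, `ambiguous` otherwise.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `B` | 100 | complementary half-sample pairs; `2B` candidate graphs |
| `q` | automatic | edges kept per candidate graph. The automatic rule targets null error control; for *recovery* studies on data with known or expected structure, set `q` near the expected edge count — a `q` far below the true number of edges caps recall by construction. |
| `tau` | 0.8 | selection-frequency threshold, strict `>` ("more than 80%") |
| `rf_trees` | 500 | trees per forest; ranking stabilizes quickly, and reduced-scale studies in the tests use 40–100 |
| `rf_importance` | permutation | permutation importance is less biased across mixed predictor types than impurity |
| `sample_max_missing`, `variable_max_missing` | 0.2 | strict "more than 20%" missingness exclusion, samples first, then variables |
| Blom offset | 3/8 | inverse-normal rank offset, `qnorm((r - 3/8)/(n + 1/4))` |

Three further conventions are worth stating. Ties in a target row's
importances (including the degenerate all-`NA` row of a half-sample whose
classification target is constant) share their *worst* rank, which keeps
the score column-order invariant. Pairs with equal worse-rank are ordered
by the sum of their directional ranks, then lexicographically — fully
deterministic. Every forest is seeded from a hash of
`(seed, subsample index, target name)`, so the inferred edge set is
invariant to row and column permutations of the input table.

## Family structure

Twin cohorts violate sample independence. Following the design this
package implements, a categorical *family* indicator (layer `meta`) is
added to the data before inference so that every forest can absorb
family-shared variation; the family node and its incident edges are then
removed from the returned network. Sign regressions exclude the meta
variable, since a several-hundred-level factor would make the designs
singular.

## Preprocessing choices

The original analysis imputed with multiple imputation by chained
equations; this package substitutes deterministic single-shot imputation
(median/mode, or k-NN on commonly observed cells). The inference layer is
rank- and forest-based and insensitive to imputation refinement, and a
deterministic imputer keeps the whole pipeline reproducible bit-for-bit.
This is a deliberate deviation, not an equivalence claim. Whether the 20%
missingness rule and the 80% frequency rule are strict is not fixed by
their usual phrasing; both are implemented strictly ("more than") and
exposed as arguments. The 100% endpoint of the robustness cutoff sweep
uses `>=`, otherwise that network would be empty by construction.

## Topology layer

Degree, local clustering (0 for degree < 2), and betweenness are computed
per node; betweenness is normalized by $(n-1)(n-2)/2$ *within the node's
connected component* — the only normalization under which percentage
values for nodes of a component are meaningful — with multiple shortest
paths counted fractionally. The small-world index follows Humphries &
Gurney: $S = (C/C_{rand}) / (L/L_{rand})$ against analytic Erdős–Rényi
expectations $C_{rand} = \bar k / n$, $L_{rand} = \ln n / \ln \bar k$ by
default (deterministic; a Monte-Carlo mode over sampled $G(n, M)$ graphs
exists for validation). The mediation fraction of a node divides its
unnormalized betweenness by the count of *all* connected pairs, adjacent
pairs included (their one-edge geodesic simply has no interior vertex); a
flag restricts the denominator to non-adjacent pairs.

Module detection maximizes Newman–Girvan modularity. `exact` is a
branch-and-bound over sequential cluster assignments with an admissible
bound that adds every remaining edge's maximal possible contribution and a
fast-greedy warm start; it is provably optimal and guarded at 120 nodes
per component, though practical well below that (the test oracles
exhaustively enumerate partitions up to 8 nodes). `greedy` cuts the
fast-greedy dendrogram at the modularity-maximal community count itself,
because the library's default cut mis-handles ties on small graphs.
`spinglass` is the seeded stochastic option for larger components.
Detection runs per connected component, which is equivalent to a global
search because a module spanning components can always be split without
lowering modularity.

## Robustness layer

The stability table (selection frequency of every pair ever selected)
supports the published robustness checks: graphs re-thresholded at
20–100% cutoffs (nested by construction), rank correlations of degree and
clustering against the reference model, adjusted Rand index (ARI) of module
assignments, and an ARI background from label permutations that preserve
module sizes — the stricter null; uniform relabeling is available behind a
flag. Twin-split replication re-infers the model on the two
one-twin-per-family halves (singletons distributed randomly by seed) and
reports the fraction of reference edges recovered by the union of the two
half models.

## The synthetic generator

Because the cohort data this design was built for are access-restricted,
validation uses a latent-Gaussian generator with known structure. A sparse
truth graph (chain, modular blocks with single bridges, or random sparse)
defines a precision matrix with $-\rho$ on the edges; diagonal loading to a
minimum eigenvalue of 0.05 guarantees positive definiteness, shrinking the
realized partial correlations by at most 50% (the construction errors out
beyond that), and the implied covariance is rescaled to unit diagonal.
Binary variables are zero-thresholded latents; a per-(family, variable)
normal intercept of variance 0.2 correlates twins within each continuous
variable without distorting the cross-variable graph; missingness is
completely at random. Generator defaults mirror the target study: 510
samples, 145 variables, 178 twin pairs plus 154 singletons, moderate
missingness.

Two caveats define what passing tests show. Thresholding latents perturbs
conditional independence slightly relative to the latent graph, so
mixed-type recovery is approximate by design. And the generator produces
none of the platform realities of omics data — batch effects, skewed
technical noise, informative missingness — so recovery results certify the
estimator's behavior under its own assumptions, not performance on raw
instrument data.

## Scale of the validation studies

The package's own simulation studies run at reduced scale chosen to probe
each property with adequate power: the null FWER study uses $p = 20$,
$n = 200$, $B = 50$, 40 replicates and 30-tree impurity-importance forests
(a null error rate probes the rank-aggregation and CPSS machinery, not
forest refinement, and is insensitive to both settings); the recovery
study uses 18 variables
in six blocks of three, $n = 600$, $\rho = 0.6$ (realized partials
$\approx 0.36$ after loading), $B = 50$, `q = 30` — a budget slightly
above the 23 true edges, per the `q` guidance above. Both are frozen under
fixed seeds in the test suite; the same FWER study is what
`scripts/acceptance.R` recomputes.

## Known limitations

- The exact modularity solver's branch-and-bound degrades on large dense
  components; use `greedy`/`spinglass` beyond a few dozen nodes.
- `estimate_signs` falls back to marginal correlation signs with a warning
  when the post-dichotomization design is singular ($p \ge n$).
- The automatic `q` rule and unreported forest hyperparameters are this
  package's own defaults; analyses sensitive to them should sweep `q` and
  `rf_trees` explicitly.
- Edges are undirected conditional dependencies; nothing here orients
  edges or estimates causal direction.
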