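---
title: "Pathway-level drug similarity networks and candidate prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level drug similarity networks and candidate prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsimnet)
```

## The model

`drugsimnet` prioritizes candidate drugs for a cancer of interest by
propagating from its approved drugs over a drug–drug functional similarity
network built at the *pathway* level. The underlying assumption is that a
drug's mechanism is better summarized by how its activity across a cell-line
panel tracks pathway activities than by single-gene correlations: pathway
activity profiles are short, smooth, and coherent within tissues of origin,
so correlations computed against them are less noisy than gene-level ones.

The chain is: expression → pathway activity (ssGSEA) → pathway–drug Pearson
correlations → drug–drug correlation of those correlation profiles →
thresholded network → random walk with restart (RWR) from the seed drugs →
permutation significance → LOOCV/ROC evaluation. Each arrow is one exported
function, so any intermediate can be inspected or replaced; the YAML-driven
`run_pipeline()` composes them and records a manifest.

## Single-sample enrichment

The per-sample enrichment score is the rank-weighted running-sum statistic:
with features ranked by decreasing expression within one sample (rank values
$r_g = N..1$) and a gene set $S$,

$$ES = \sum_{i=1}^{N}\left[\frac{\sum_{g \in S,\ pos(g)\le i} r_g^\tau}
{\sum_{g \in S} r_g^\tau} - \frac{\#\{g \notin S,\ pos(g) \le i\}}{N - |S|}\right].$$

Two design points were genuinely open and are resolved as follows:

* **The weighting exponent** $\tau$ is not fixed by the method family; the
  default here is $\tau = 0.25$, exposed as a parameter. Because every
  downstream use of the activity matrix is a Pearson correlation, per-pathway
  affine rescalings are irrelevant — which is also why **no cross-sample
  normalization** of the scores is applied.
* **Ties and missing values.** Ties in expression are broken by feature ID
  after a stable sort on value, so scores are identical across platforms and
  runs; missing expression values rank below every measured value. The score
  is invariant under any strictly monotone transform of a sample's values
  (tested property).

The implementation uses a closed form of the double sum (derived by summing
each step function analytically), and the test suite checks it against a
literal position-by-position transcription of the definition.

MicroRNA pathways are built by hypergeometric overlap: microRNA $m$ joins
pathway $P$ when $P(X \ge |T_m \cap P|) < 0.05$ for a draw of $|T_m|$ from
the gene universe. The universe is the union of all pathway members and all
target genes, intersected with the measured genes in the pipeline — the
choice matters and is therefore an explicit argument. Pathways keeping a
single microRNA are retained (a minimum would be arbitrary) but counted in
a message.

## Network construction

Drugs are first reduced to the high/diverse-activity subset: IQR and maximum
activity both in the top quartile across drugs, where "top quartile" is
`value >= quantile(values, 0.75)` with the inclusive linear-interpolation
quantile (R type 7). The retained count is sensitive to the quantile
definition, so both the probability and the type are configuration. Drugs
with fewer than 4 non-missing activities are excluded before thresholds are
computed. The filter is deliberately *not* idempotent — re-applying it
re-quartiles the survivors.

The edge rule joins drug $d$ to partner $e$ when ($r_{de} \ge 0.7$ **and**
BH FDR $\le 0.05$) **or** $e$ is among $d$'s top $\lceil 0.0005\,(n-1)\rceil$
partners by decreasing correlation (ties at the cutoff included). The
union-of-rules reading was chosen because a pure conjunction with a top-0.05%
rank rule would make the correlation and FDR thresholds nearly vacuous and
could not produce a network of realistic density; both readings are available
(`rule = "union"` / `"intersect"`). The FDR pool is all unordered drug pairs
of one pathway level (mRNA and microRNA levels corrected separately, then
merged by union), and the per-drug rank rule guarantees minimum degree
$\ge \lceil 0.0005\,(n-1)\rceil$ for every drug with usable correlations.

## Random walk with restart

$$p^{t} = (1-\alpha)\,A\,p^{t-1} + \alpha\,p^{0}, \qquad p^{1} = p^{0},$$

with $A$ the column-normalized adjacency, $\alpha = 0.7$ (the walk is known
to be insensitive to $\alpha$ over a wide range), and convergence declared
when $\lVert p^t - p^{t-1}\rVert_1 < 10^{-10}$ (the norm is configuration;
L1 is the default because it bounds the distance to the fixed point by
$\tfrac{1-\alpha}{\alpha}$ times the residual). Two seed-mass conventions
are implemented: `p0_mode = "unit"` assigns each seed 1 (the binary
prior-knowledge encoding; the default) and `"normalized"` assigns
$1/|\text{seeds}|$. The steady state is linear in $p^0$, so the two differ
by the factor $|\text{seeds}|$ and all ranks, p-values, and AUROCs are
identical between them. Columns of isolated nodes are left all-zero; the
resulting slow leak of restart mass is accepted as the literal reading of
the recursion rather than patched with a teleport term. The iterative
solution is tested against the closed form
$p = \alpha\,(I-(1-\alpha)A)^{-1}p^0$ on random graphs up to 200 nodes.

## Significance and evaluation

Empirical p-values compare each drug's score to its scores on randomized
networks with the same seed IDs: $p(d) = \#\{\text{perm}:
s_{perm}(d) > s_{real}(d)\}/B$ with $B = 1000$ by default (strict `>`, the
literal count; an add-one estimator is available because $p = 0$ is awkward
downstream), followed by BH adjustment over all drugs. The default null
rewires edges by double-edge swaps (10·|E| attempts via igraph), preserving
every node's degree exactly — asserted in tests across 1000 permutations;
a node-relabeling null (degree multiset preserved, graph fixed) is also
provided, since the two standard readings of "random networks with the same
degrees but different labels" differ and neither is obviously intended.

LOOCV hides each seed in turn, reruns the walk with the remainder, and ranks
the held-out drug among itself plus all non-seed drugs. The ROC pools
held-out scores as positives; negatives are, by default, the non-seed scores
of the same rounds pooled (`negatives = "pooled"`), with a per-drug
across-round mean as the alternative — the negative-class convention is not
canonical and shifts AUROC slightly, so it is explicit. AUROC is computed by
Mann–Whitney pair counting with the 0.5 tie convention, and tested to equal
trapezoidal integration of the step curve and an independent ROC
implementation.

## The synthetic panel generator

`generate_panel()` emulates a small NCI-60-like screen with exact ground
truth, so every stage is testable offline. All randomness flows from a
single `rng_seed` (a latent-factor construction was preferred over
resampling real data precisely so that module membership is exact):

* pathway latent activity = per-tissue baseline $N(0,1)$ + per-sample noise
  $N(0, 0.5)$ — tissue coherence without tissue-specific pathway semantics;
* member genes = pathway activity + $N(0, 0.5)$; background genes pure
  noise — so ssGSEA recovers the latent factor through ranks alone;
* two microRNAs per pathway track its activity and target 60% of its genes;
* each of 4 drug modules couples 5 drugs to a disjoint 3-pathway signature:
  activity $= \beta \sum_{P \in sig} act_P + N(0, \sigma)$, defaults
  $\beta = 2$, $\sigma = 0.5$; 20 further drugs are uncoupled noise.

The defaults (60 cell lines, 9 tissues, 30 pathways of 15 genes among 600
genes, 40 drugs) are the package's standing study conditions for recovery
experiments: seeding 3 of one module's 5 drugs and asking whether the other
2 rank in the top 5 non-seeds, and whether module LOOCV AUROC exceeds 0.9,
over 50 generator replicates. What the generator does **not** emulate —
heavy-tailed GI50 distributions, missing-data patterns, correlated assay
batches, overlapping pathway memberships, chemical-structure relations —
bounds what passing tests show: they validate the machinery and its
statistical behaviour, not performance on real screening data.

## Behaviour of the permutation null on correlation networks

One property deserves honest emphasis. Under the uncoupled generator
($\beta = 0$) one might expect the permutation p-values of non-seed drugs to
be uniform. They are not, and reproducibly so (the acceptance script
computes the KS statistic at 500 drugs × 200 permutations). Two reasons:

* A thresholded correlation network is an *atypical* member of its own
  degree-preserving ensemble: top-correlation partners are mutual, so the
  real network is clustered and fragmented, while double-edge swaps
  consolidate it into a larger giant component. Restart mass therefore stays
  near the seeds in the real network and spreads in the rewired ones,
  skewing non-seed p-values upward.
* All drugs share one seed placement and one set of permutations, and drugs
  in seed-free components have score exactly 0, so the KS test's independence
  assumption is violated regardless of the null model.

This is a property of network-permutation nulls on sparse correlation
graphs, not of the implementation: the degree vector is preserved exactly in
every permutation (tested), and the same machinery applied where
exchangeability genuinely holds behaves as expected. Practically, the
permutation FDR should be read as a calibration against degree structure,
not as a uniformly calibrated frequentist p-value.

## Problem sizes and numerical choices

Test and acceptance runs use panels of 24–60 samples, 160–600 genes, 8–30
pathways and 16–500 drugs, 50 recovery replicates, 200–1000 permutations,
and random graphs up to 200 nodes for the closed-form comparison — sizes
chosen so the full pipeline is exercised end to end in well under a minute
per analysis on one core. Degenerate inputs are hard errors with classed
conditions (`dsn_*`): gene sets covering all measured features, empty seed
sets after mapping, fewer than 3 shared samples, non-convergence at
`max_iter`. Ranks break ties by drug ID everywhere, so every ranking in the
package is a deterministic function of its inputs.
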