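---
title: "Scoring causal networks with the network perturbation amplitude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring causal networks with the network perturbation amplitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npanet)
```

## The two-layer causal model

npanet implements reverse causal reasoning over a two-layer model of a
biological system. The **functional layer** is a signed directed graph
compiled from literature-curated causal statements written in a BEL 1.0
subset: nodes are biological entities at several levels of organization
(chemicals, proteins, protein activities, transcripts, microRNAs, complexes,
biological processes, pathologies), and each edge carries a sign
$\sigma_{xy} \in \{+1, -1\}$ from its relation (`increases`-type relations
map to $+1$, `decreases`-type to $-1$; `association` edges carry
$\sigma = 0$ and are kept for topology and visualization but excluded from
scoring, which needs signs). The **transcript layer** attaches to some
functional-layer nodes — the inferable nodes, or iNodes — a signed gene
signature: gene $g$ under iNode $x$ has sign $s_{xg} \in \{+1, -1\}$, the
expected direction of its differential expression when $x$ is active.

Given a differential-expression profile $\beta$ (per-gene log2
fold-changes, with optional variances), scoring proceeds in three steps.

**1. Activity inference.** The activity of iNode $x$ is the signed mean of
its measured signature genes,
$$a(x) = \frac{1}{m_x} \sum_{g \in T(x),\ \mathrm{measured}} s_{xg}\,\beta_g,$$
where $m_x$ is the number of signature genes present in the profile. Gene
matching is case-insensitive; unmeasured genes are skipped; iNodes without
any measured gene are excluded (and listed), and a profile overlapping no
iNode at all is an error.

**2. Coefficient fit.** Node coefficients $c$ over the scoring subgraph
minimize the quadratic consistency objective
$$J(c) \;=\; \sum_{(x \to y)\,:\,\sigma \ne 0} w_{xy}\,\bigl(c_y - \sigma_{xy} c_x\bigr)^2
\;+\; \lambda \sum_{x\ \mathrm{anchored}} \bigl(c_x - a(x)\bigr)^2 .$$
The first sum rewards assignments that propagate coherently along signed
edges (a harmonic fit: edge direction is used as the sign carrier, the
penalty itself is symmetric); the second anchors iNodes at their inferred
activities. $J$ is minimized exactly as one sparse symmetric
positive-definite linear system (a ridge $\varepsilon I$ keeps components
without any anchored iNode determinate; their coefficients are exactly zero
and they are reported). Activities that the topology accommodates yield
large coefficients; contradictions — including parallel edges of opposite
sign between the same pair, which contribute two penalty terms — pull the
fit toward zero.

**3. Amplitude.** The network perturbation amplitude is the node mean of
squared coefficients,
$$\mathrm{NPA} = \frac{1}{|V_b|} \sum_{x \in V_b} c(x)^2,$$
with the per-node contribution $c(x)^2 / \sum_y c(y)^2$. The scoring node
set $V_b$ comprises the endpoints of sign-carrying edges together with all
iNodes of the attached layer (so an anchored but isolated iNode is still
scored). NPA is non-negative and zero exactly when all coefficients vanish.

The published description of this scoring family is qualitative
(activities, then topology-aware node coefficients, then a scalar
amplitude) and defers the exact formulas to companion software. The forms
above are this package's own concrete choice satisfying every stated
contract — consistent activities raise the score, contradictions lower it,
and the score decomposes additively over nodes, which the leading-node
analysis requires. `compute_npa()` is isolated so an alternative quadratic
form would be a drop-in replacement.

## Uncertainty and significance

**Confidence interval.** Assuming the gene expression values are normally
distributed, each measured gene is redrawn independently as
$\beta^*_g \sim N(\beta_g, v_g)$ and the model rescored; the interval is
the empirical $(\alpha/2, 1-\alpha/2)$ band of the rescored NPAs
(`ci_draws` = 1000 by default). A resampled rather than closed-form
interval was chosen because the NPA is a quadratic form of $\beta$ whose
exact distribution is awkward, while the normality assumption itself is
the standard one for this scoring family. With all variances zero the
interval degenerates to the point estimate.

**o statistic** (transcript-layer specificity): each of $N$ permutations
redraws the gene endpoints of the transcript layer — per iNode, uniformly
without replacement from the measured gene universe, preserving signature
sizes and signs — and rescores end-to-end. **k statistic**
(functional-layer relevance): each permutation shuffles the target
endpoints among the sign-carrying edges, sources, signs and weights staying
with their edges (permutations creating self-loops are redrawn up to ten
times, then accepted and counted); the transcript layer is untouched. Both
use the add-one upper-tail convention
$p = (1 + \#\{\mathrm{NPA}_{perm} \ge \mathrm{NPA}_{obs}\}) / (1 + N)$, so
p-values live in $[1/(N+1), 1]$ and can never be zero; significance at
$\alpha = 0.05$ means the observed NPA sits in the top 5% of its permuted
distribution. Whether the backbone permutation should preserve the degree
sequence is not settled in the literature this implements; the
target-column shuffle preserves out-degrees and the edge count and is
documented here as the chosen scheme.

Treatment scores are compared across conditions as fold changes over a
vehicle control, `npa_fold_change()`: the treatment NPA and its confidence
interval are divided by the control NPA (an error if the control is
unperturbed).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 1 | weight of the activity anchors relative to edge consistency (unitless; larger values trust the transcript layer over the topology) |
| `epsilon` | 1e-9 | ridge keeping unanchored components determinate; far below any data scale |
| `permutations` | 500 | permutation count for o/k; the attainable minimum p is 1/501 |
| `alpha` | 0.05 | significance level for the interval and both permutation tests |
| `ci_draws` | 1000 | Monte Carlo draws for the confidence interval |
| `seed` | none | master seed; fans out to named substreams (`ci`, `o`, `k`) recorded in the result |

## The synthetic-data generator

`generate_network()`, `generate_transcript_layer()` and
`generate_profile()` produce complete two-layer models with known ground
truth, so every stage is testable without external data. Networks are
uniform random distinct directed edges without self-loops; signatures are
disjoint gene sets of fixed size; **consistent** profiles draw latent
coefficients $c^*$ by propagating a root value of magnitude `scale`
(random sign) along a BFS spanning forest (child = parent × edge sign;
first-visited parent wins at conflicting parallel edges) and set
$\beta_g = s_{xg} c^*(x) + N(0, \tau^2)$; **null** profiles are pure noise
with $c^* = 0$. Both modes append 50% decoy genes so permutation tests have
off-signature genes to draw, mimicking genome-wide profiles.

Two design points deserve emphasis:

* **Cycle coherence.** On a cyclic network with independently drawn edge
  signs, a globally sign-coherent $c^*$ usually does not exist: some
  non-tree edge contradicts the forest assignment, $J(c^*) > 0$, and
  "consistent" data are not exactly representable. The generator records
  this in the truth object (`coherent` flag). For studies that need exact
  representability — noise-free recovery identities, and power studies
  where the true backbone should beat rewired ones —
  `generate_network(coherent_signs = TRUE)` draws edge signs from latent
  node polarities ($\sigma_{xy} = \pi_x \pi_y$), which makes every cycle
  coherent while preserving the marginal negative-edge probability.
* **What passing tests do and do not show.** The generator emulates the
  *structure* of the real inputs (signed backbone, signed signatures,
  noisy log2 fold-changes with decoys), not the statistics of real
  transcriptomes: no count noise, no correlation between genes, no batch
  effects, equal signature sizes, and a latent truth of constant magnitude.
  Calibration and recovery results on synthetic data therefore validate
  the estimator's mechanics, not its behavior on any particular organism
  or platform.

## Numerical choices and edge cases

* The fit is solved by sparse Cholesky factorization; for the confidence
  interval and the o statistic the system matrix is factored once and
  reused across all draws/permutations (only the right-hand side changes).
* Ranked tables (degree, betweenness, contributions, leading nodes) break
  ties lexicographically by node id, making every report deterministic.
* The leading-node threshold is inclusive with a $10^{-9}$ float fuzz, so
  ten equal contributions of 0.1 yield exactly eight leading nodes at the
  80% threshold; threshold 1.0 returns all nonzero contributors.
* Degree counts parallel edges separately (each carries its own evidence);
  betweenness merges them and uses hop counts, never the bookkeeping edge
  weights, normalized by the count of ordered (directed) or unordered
  (undirected) node pairs excluding the focal node. Because published
  bottleneck tables rarely state their convention, both variants are
  computed on request and each table records its convention in a header.
* An all-zero fit has undefined contributions (flagged), and decomposing
  it is an error rather than an empty report.
* A single-edge backbone makes the k permutation the identity and
  $p_k = 1$; only a backbone with no sign-carrying edges at all is an
  error.
* Latent truths of constant sign across all anchored iNodes make the
  Pearson recovery correlation undefined (zero variance); such degenerate
  draws are excluded from recovery medians, which are reported with the
  count of informative draws.

## Problem sizes used in the shipped studies

The packaged tests exercise the estimator on 20-node / 24-edge backbones
with 10 iNodes of 10 genes each ($\tau = 0.1$): 200 null replicates for
o-statistic calibration, 20 generator seeds for power and recovery, and 50
random models (4–12 nodes) for the solver-versus-brute-force check. The
test suite runs the permutation statistics at $N = 200$; the acceptance
script (`scripts/acceptance.R`) runs the same studies at the default
$N = 500$. These sizes were chosen as the smallest at which the calibration
band and power expectations are statistically meaningful.

## Known limitations

* The activity metric and NPA functional form are this package's own
  (documented above); other members of the scoring family weight genes or
  nodes differently, so absolute NPA values are not comparable across
  implementations — nor across different networks, where comparability is
  an open question in the field. Fold changes within one network and
  dataset are the intended use.
* The BEL grammar covers the nine term functions and five relations that
  curated toxicology networks use; BEL 2.x syntax and namespace resolution
  against online vocabularies are out of scope, and unsupported tokens
  fail loudly by design.
* Orthology mapping and automatic transcript-layer construction from
  knowledgebases are out of scope: layers are supplied as TSV.
* The subnetwork extractor's "indirect" edges summarize one shortest
  signed path (up to a configurable length cap); equal-length paths with
  conflicting sign products are reported as ambiguous rather than
  resolved.

## A worked run

```{r example, eval = FALSE}
net <- generate_network(20, 24, p_negative = 0.3, seed = 1,
                        coherent_signs = TRUE)
layer <- generate_transcript_layer(net, frac_inodes = 0.5,
                                   genes_per_inode = 10, seed = 1)
model <- attach_transcript_layer(net, layer)
prof <- generate_profile(model, "consistent", tau = 0.1, seed = 1)$profile

fit <- npa(model, prof, npa_control(seed = 42))
summary(fit)
leading_nodes(fit, threshold = 0.8)
```
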