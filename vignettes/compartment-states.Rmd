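---
title: "Inferring nuclear compartmentalization states with spinmrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nuclear compartmentalization states with spinmrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinmrf)
```

## The problem and the model

TSA-seq and DamID measure, per genomic bin, how close (TSA-seq, a gradually
decaying cytological distance signal) or how often in molecular contact
(DamID) chromatin is with a nuclear landmark — nuclear speckles, the nuclear
lamina, nucleoli. Hi-C measures which loci contact each other. Loci that
interact more often than expected tend to share a spatial environment, so a
joint annotation should borrow strength across both kinds of evidence.

`spinmrf` casts this as a hidden Markov random field. Nodes are fixed-width
bins (default 25 kb, balancing the resolution limit of TSA-seq/DamID against
the resolution at which compartmentalization is meaningful). The hidden
state $H_i$ of bin $i$ generates its observation vector
$O_i \in \mathbb{R}^d$ (the $d$ signal channels) as a multivariate Gaussian
$N(\mu_h, \Sigma_h)$ with a full covariance per state. Edges carry a
compatibility $P_E(H_i, H_j) \propto t(H_i, H_j)$; the joint is the usual
product of node and edge potentials with an intractable normalizer that is
never evaluated.

Assumptions worth stating plainly: emissions are Gaussian given the state
(log-ratio tracks are roughly symmetric and unimodal per state, but heavy
tails are not modeled); one compatibility matrix is shared by all edge kinds
(a genomic-adjacency edge and a trans Hi-C edge count the same); bins with a
missing value in any channel are removed from the graph entirely, because
the emission term needs the complete $d$-vector.

## Signal front end

Raw tracks become scores in three steps:

* **Enrichment**: `log2((sample/depth_s + c) / (control/depth_c + c))` on
  sliding windows (20 kb windows at 1 kb step for TSA-seq/DamID). The
  pseudocount is expressed in read units and scaled by each library's depth;
  the default is 1 read, which avoids log-of-zero while vanishing for deep
  libraries. With `pseudocount = 0`, zero-control windows become missing
  instead. The pseudocount and the edge policy below are configurable
  because neither is forced by the method; both defaults are documented
  choices, not recovered constants.
* **Smoothing**: a Hanning window of length 21 (weights
  $0.5 - 0.5\cos(2\pi n/20)$, normalized to sum to 1), applied per
  chromosome so windows never mix chromosomes. At chromosome edges the
  window is truncated and renormalized — this preserves constants exactly
  and keeps the smoother linear, at the cost of slightly higher variance in
  the first/last 10 positions.
* **Re-binning**: the arithmetic mean of the fine-grid values inside each
  bin. The mean is the natural aggregator for ratio tracks (it preserves
  constant signals and commutes with the smoother's linearity); a bin with
  no covered values is masked.

Repli-seq fractions are divided bin-wise by a G1 control (zero-G1 bins are
unmappable and masked) and expressed as percent of the seven-fraction sum,
so unmasked bins always sum to 100.

## Hi-C front end

Contact matrices are accepted already normalized (VC\_SQRT or similar); a
fallback square-root vanilla-coverage normalizer is included for raw counts.
For each chromosome the expected contact at bin-distance $s$ is the mean
observed value over *all* $n-s$ pairs at that distance, counting absent
sparse entries as zeros — including the zeros keeps the distance-decay
estimate unbiased. Trans pairs get a single uniform expectation. Scores are
$\log_2 O/E$.

Significance is called per chromosome by a maximum-likelihood Weibull fit
with survival $p(x) = \exp(-(x/\lambda)^k)$ and cutoff $p < 10^{-5}$. The
Weibull is fitted to the **positive O/E ratios**, not to the log ratios
(whose support includes negatives, incompatible with the Weibull) — the
quantity whose upper tail defines "more contact than expected". Fitting to
the normalized contact values instead is available via `fit_on = "contact"`,
since the original choice cannot be pinned down from the method's
description. Trans calls use one null per chromosome pair by default
(mirroring the per-chromosome intra treatment; a pooled alternative is a
config switch) and must pass the neighbor rule: all nine pairs
$(i \pm 1, j \pm 1)$ significant. A missing neighbor — absent entry or
chromosome boundary — fails the rule; this conservative reading means a
significant pair in the very first or last bin of a chromosome can never be
kept, which costs a negligible number of candidate edges.

Degenerate inputs: a chromosome whose fit fails (or whose values are all
identical — the shape parameter would diverge) is skipped with a warning
rather than aborting the genome-wide call.

## Inference and estimation numerics

All potentials live in log space. Loopy belief propagation uses a
synchronous flooding schedule: every directed message is recomputed from the
previous sweep's incoming messages, normalized to sum to 1, until the
largest belief change drops below `1e-6` (probability scale) or 500 sweeps.
Initial messages are uniform. Optional damping (`damping`, default 0) blends
consecutive log-messages for stability on dense loopy graphs; it is off by
default because the default graphs (a chain plus sparse Hi-C edges)
converge without it. On tree-shaped graphs this schedule reaches the exact
marginals — the test suite verifies beliefs against brute-force enumeration
to `1e-6`.

The mixture weights $\pi$ enter the node potential as an additive
$\log \pi_h$ term, consistent with the Gaussian-mixture initialization; a
config flag (`use_mixture_weights`) removes them, since the belief update
can be written either way and the original convention is not recoverable.

EM alternates LBP inference, a mean-field E-step
($P(H_i = a) \propto P(O_i | a) \prod_{j \in N(i)} t(a, \hat h_j)$ with
$\hat h_j$ the current hard estimates), and an M-step of posterior-weighted
moments. The compatibility update accumulates expected co-occurrence
$\sum_{(i,j) \in E} q_i q_j^\top$ (both orientations). EM stops when fewer
than 0.1% of hard labels change, or after 30 iterations; mean-field EM has
no monotonicity guarantee, so the per-iteration label-change counts are
returned in the fit's `trace` rather than hidden.

Numerical guards: every covariance gets a ridge of
$10^{-6} \cdot \mathrm{tr}(\Sigma)/d$ on the diagonal (full covariances at
$d = 4$ can approach singularity when a state collapses onto a signal
manifold); a state whose total posterior weight falls below $d + 1$ keeps
its previous covariance; ties in argmax decisions always break toward the
lowest state index, making every code path deterministic given the seed.

The stored compatibility matrix is required to be both **symmetric** (an
undirected edge has no orientation, so the edge potential must be) and
**row-stochastic** (so rows are comparable and interpretable as conditional
transition profiles). Plain row normalization of a symmetric matrix breaks
symmetry, so the raw co-occurrence matrix is projected with a symmetric
diagonal scaling $D W D$ (Sinkhorn iterations plus a Newton polish on the
scaling vector) onto the set of symmetric matrices with unit row sums. The
initial compatibility from hard labels computes the co-occurrence ratio
(ordered-pair numerator counting both orientations over endpoint-label
counts — this ratio is deliberately exposed raw in an attribute, then
projected the same way). Only relative values matter in the potentials, so
the projection changes no probability statement, just the scale.

States are finally renumbered by ascending mean of the speckle channel
(1 = most lamina-like, $k$ = most speckle-like), which makes labels stable
across runs and gives the replication-timing analysis its integer encoding.

## Choosing the number of states

For each candidate $k$ the package reports the k-means within-cluster sum
of squares (best of 10 restarts) and the AIC/BIC of a fitted HMRF with
$\ln L = \sum_i \log b_i(\hat h_i)$ (the sum of log beliefs of the assigned
states) and
$K = kd + k\,d(d+1)/2 + k(k-1)/2 + (k-1)$ — means, full covariances, the
symmetric normalized compatibility, and the mixture. This parameter count is
a documented convention (configurable in spirit: the table exposes $K$, so
any other count is a constant shift of the curves).

The automatic recommendation is an elbow rule designed to be scale-free and
noise-tolerant, which mattered in practice:

* The belief-product $\ln L$ is a *confidence*, not a fit quality: on
  well-separated data beliefs are near 1 for every $k \le k_{true}$ (merged
  states face no competition), so AIC/BIC rise monotonically with $k$ and
  carry no elbow. Curves therefore only vote when they are **informative**
  — predominantly decreasing over the range (total drop at least 70% of
  total variation). WSS always is; AIC/BIC typically become informative on
  noisy, overlapping real data where extra states genuinely sharpen
  beliefs.
* A threshold relative to the *initial* slope is scale-sensitive (it
  misfires when between-state variance is small relative to the
  within-state WSS floor). Instead, candidate $k$ is flat when **every
  remaining per-step drop is at most 20% of the mean per-step drop
  accumulated before it**; the recommendation is the smallest flat $k$,
  maximized over informative curves. The full score table is always
  returned: the automatic pick is a starting point, and on real data the
  final choice should weigh the biology (interpretability and stability of
  the resulting states) as the original 10-state annotation did.

## What the synthetic generator does and does not emulate

`simulate_dataset()` plants: a first-order Markov state sequence per
chromosome (stay probability 0.95 — mean block length 20 bins, 500 kb at
25 kb, the domain scale of compartment blocks); Gaussian emissions over four
channels named for the four assays, with unit variances, common 0.3
correlation, and state means following a lamina-to-speckle gradient
(speckle channel ascending, lamina channels descending, nucleolus channel
peaked mid-rank) plus alternating offsets that keep all states mutually
separated by at least ~4 channel SDs up to $k = 10$; and Poisson contacts
with $\mathrm{distance}^{-1}$ decay, a 4× same-state boost, and an expected
neighbor-bin count of 300 — a deeply sequenced map. Coverage is the noise
dial: at shallow depth the significance tail is dominated by isolated 1–2
read pairs at long range and the called edges lose their same-state
meaning, which is a real property of sparse Hi-C, not an artifact.

It does **not** emulate: heavy-tailed or skewed emission noise,
copy-number and mappability artifacts (masking is exercised synthetically,
not mechanistically), TAD-scale contact structure, A/B checkerboard
patterns beyond the state boost, or inter-assay resolution differences.
Passing the planted-recovery tests therefore demonstrates correctness of
the estimation machinery under the model's own assumptions — it does not
certify performance on real K562-like data, where state overlap,
non-Gaussian tails and coverage artifacts all bite.

Problem sizes used by the test suite and acceptance script — 2,000-bin
genomes for pipeline recovery, 1,500 bins for model selection and
replication-timing prediction, 450-bin dense matrices (101,025 pairs) for
significance calibration, trees up to 12 nodes for exact-inference checks —
are the package's reference conditions: large enough that binomial/CLT
tolerances are meaningful, small enough that the whole suite re-runs in
minutes on one core.

## Replication timing and downstream summaries

`rt_predict()` regresses the 7-fraction Repli-seq percentage vector on the
speckle-ranked state plus histone-mark channels with a random forest (1,000
trees, $\sqrt{p}$ features per split, depth cap 100 — one forest per
fraction), scored by leave-one-chromosome-out cross-validation: the $R^2$
per fraction is averaged within a fold, then across folds (per-fold
averaging, since pooling across folds would let chromosome size reweight
the score). Bins missing any input are discarded. Feature importances are
impurity-based, summed over the seven per-fraction forests and normalized.

`fold_enrichment()` stratifies per-bin annotation categories across states
as observed/expected against genome-wide marginals (so the state-weighted
mean of every category column is exactly 1), and `boundary_profile()`
averages a track in a ±200 kb window around state transition boundaries,
mirroring symmetric transition types onto a canonical orientation before
pooling. Interval annotations are rasterized to bins by majority overlap
(ties broken by category name for determinism).

## Known limitations

* Loopy BP has no convergence guarantee on cyclic graphs; non-convergence
  is reported via the `converged` flag and can usually be fixed with
  damping.
* The pseudo-likelihood used for AIC/BIC is a confidence measure; its
  information criteria should never be read in isolation (see above).
* The Weibull null is fitted to the same data it tests, so extremely
  heavy-tailed contact distributions shift the effective type-I rate; the
  calibration test covers the i.i.d. case only.
* One compatibility matrix for all edge kinds; per-kind potentials would
  need a different M-step.
* `.cool`/HDF5 contact input is not read directly; use triplet TSV or the
  5-column chrom/start format.
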