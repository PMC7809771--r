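# spinmrf

Genome-wide annotation of **nuclear compartmentalization states** ("SPIN
states") from multiple 1D proximity signals and Hi-C, for chromatin and
nuclear-organization researchers. Given per-bin TSA-seq and DamID tracks
(distance to nuclear speckles, the nuclear lamina, and nucleoli) together
with a binned Hi-C contact matrix, the package assigns every fixed-size
genomic bin (default 25 kb) a hidden state describing its preferred spatial
position in the nucleus — from lamina-associated to speckle-proximal.

## The model

The genome is a graph `G = (V, E)`: nodes are usable bins; edges join
(1) consecutive bins on a chromosome, (2) bin pairs with significantly
enriched Hi-C contacts, and (3) optional structural-variant junctions.
States are inferred under a **hidden Markov random field**:

```
P(H, O) ∝ (1/Z) ∏_{i ∈ V} P_V(O_i | H_i) ∏_{(i,j) ∈ E} P_E(H_i, H_j)
```

with multivariate Gaussian node potentials `P_V(O_i | H_i = h) =
N(O_i; μ_h, Σ_h)` over the `d` signal channels and an edge potential
`P_E(H_i, H_j) ∝ t(H_i, H_j)` given by a symmetric state-compatibility
matrix. Emissions are initialized by a Gaussian mixture fit; marginal state
probabilities ("beliefs") come from **loopy belief propagation** (synchronous
message passing in log space, messages normalized per edge); parameters are
re-estimated by **mean-field EM** (posterior-weighted moments; compatibility
from expected edge co-occurrence). Hi-C edges are called per chromosome by
fitting a Weibull null to observed/expected contact ratios and keeping pairs
with upper-tail `p < 1e-5`; trans pairs additionally require their full 3×3
neighborhood to be significant. The number of states is chosen by an elbow
on the k-means within-cluster sum of squares plus AIC/BIC
(`AIC = −2 ln L + 2K`, `BIC = −2 ln L + K ln n`, with `ln L` the sum of log
beliefs of the assigned states).

Everything is testable offline: a planted-truth simulator generates
correlated Gaussian signal tracks over a Markov state sequence and a
distance-decay, within-state-enriched Poisson contact matrix in the exact
input formats the pipeline reads.

## Worked example

```r
library(spinmrf)

ds  <- simulate_dataset(n_bins_total = 1000, n_chrom = 2, k = 4, seed = 42)
res <- spin_pipeline(ds$signals, ds$contacts, k = 4, seed = 42)

res$graph
#> interaction_graph: 1000 nodes, 1041 edges (adjacency:998, hic_intra:43)
res$fit$assignment
#> state_assignment: 1000 bins, 4 states
#> state
#>   1   2   3   4
#> 306 201 176 317
round(res$fit$model$means, 2)
#>      SON_TSA LaminB1_TSA LaminB1_DamID AP3_DamID
#> [1,]   -4.47        4.46          1.38      2.98
#> [2,]   -1.38        1.54          3.52     -2.56
#> [3,]    1.44       -1.43         -3.47      0.53
#> [4,]    4.51       -4.57         -1.34      3.02

mm <- match_labels(ds$labels[res$fit$assignment$nodes + 1],
                   res$fit$assignment$labels)
sprintf("label accuracy after matching: %.3f", mm$accuracy)
#> [1] "label accuracy after matching: 1.000"
```

The graph combines the adjacency chain with 43 significant Hi-C edges; the
fitted state means recover the planted lamina-to-speckle gradient (state 1:
low SON TSA-seq, high Lamin-B1 — lamina-like; state 4 the reverse —
speckle-like, since `spin_pipeline()` speckle-ranks states), and every bin
is relabeled correctly up to the state matching.

A command-line front end wraps the same functions
(`inst/cli/spinmrf simulate|graph|fit|select-k|enrich|boundary|rt-predict`);
every run writes its resolved configuration next to its outputs.

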