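# seedpath

Seed-based candidate gene discovery on weighted protein–protein interaction
networks.

## The problem and the method

Given a biological process with a handful of experimentally annotated genes
(*seed genes*) and a confidence-scored protein interaction network (STRING
style: integer combined scores S(p1, p2) in 150–999), which other genes are
likely involved? `seedpath` implements a two-stage network prioritization:

**Graph.** Interactions become an undirected simple graph G = (V, E) with edge
weights w(e) = 1000 − S(p1, p2), so high-confidence interactions are short.
Duplicate orientations collapse to one edge keeping the maximum score.

**Stage I — shortest-path discovery.** For every unordered pair of seed genes,
all minimum-weight paths are found with Dijkstra's algorithm. Every non-seed
gene that is an *inner node* of at least one such path becomes a candidate,
scored by its **path betweenness**: the number of seed-pair shortest paths
through it. With σ_s(v) the count of shortest paths from s to v, the per-pair
contribution of v is σ_s(v)·σ_t(v) whenever d_s(v) + d_v(t) = d_s(t) — no path
enumeration is needed. A `one_path` mode that credits a single deterministic
path per pair is also provided.

**Stage II — permutation filter.** The betweenness of each candidate is
recomputed on `n_sets` (default 500) random gene sets of the same size as the
seed set. The **permutation FDR** of a candidate is the fraction of random
sets on which its betweenness *strictly exceeds* the observed value;
candidates with FDR < 0.05 are called significant.

**Enrichment.** Significant candidates can be tested against named gene-set
collections (GMT) with the exact hypergeometric upper tail
P(X ≥ x) = Σ_{k≥x} C(K,k)·C(N−K,n−k) / C(N,n).

A synthetic-network generator (`simulate_network()`) plants seed modules
connected through known "bridge" genes in a heavy-tailed background, so the
whole pipeline is testable end to end with known ground truth.

## Worked example

```r
library(seedpath)

# synthetic network: 300 background nodes, 10 planted seeds joined through
# 3 high-confidence bridge genes
sim <- simulate_network(synthetic_spec())

fit <- seedpath(sim$network, sim$truth$seed_ids, n_sets = 200, rng_seed = 42)
summary(fit)
```

```
Seed-based shortest-path gene discovery

Network: 313 nodes, 646 edges
Seeds:   10 mapped / 10 requested
Stage I: 3 candidate genes (mode all_paths, 0 unreachable seed pairs)
Stage II: 200 random sets of size 10 from 313 nodes (rng_seed 42)
Significant candidates (permutation FDR < 0.05): 3

      gene betweenness fdr
1 BRIDGE01          45   0
2 BRIDGE02          45   0
3 BRIDGE03          45   0
```

The three planted bridges are recovered exactly: each lies on one of the three
tied shortest paths between every one of the C(10, 2) = 45 seed pairs, giving
betweenness 45, and no random seed set ever beats that, giving permutation
FDR 0. `coef(fit)` returns the betweenness vector, `select_significant(fit)`
the filtered table, `simulate(fit, nsim)` fresh draws from the permutation
null, and `plot(fit)` betweenness against FDR.

File-based runs use the same machinery:

```r
run_pipeline(list(network = "links.txt", seeds = "seeds.txt",
                  out_dir = "out", n_sets = 500, rng_seed = 1))
```

writing `network.tsv`, `candidates.tsv`, `permutation.tsv`, `significant.tsv`,
optional `enrichment.tsv`, a JSON run report and the resolved configuration.
`inst/cli/seedpath.R` wraps this for shell use.

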