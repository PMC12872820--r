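# temporalmapper

Attractor transition networks from multivariate time series.

Systems like a patient–therapist dyad, coded continuously on the
interpersonal circumplex (warmth and dominance for both people, a 4-D state
sampled every 0.5 s on [−1000, 1000]), show *dwell–escape* dynamics: the
state lingers near one configuration, then shifts suddenly to another.
`temporalmapper` reconstructs the organization of those metastable states
without knowing any equations of motion, for researchers of interaction
dynamics, psychotherapy microprocesses, and more generally anyone with a
uniformly sampled multivariate series exhibiting sudden regime switches.

## Method

Given a series *x₁ … x_T* ∈ ℝᴰ:

1. **STKNN graph.** A directed graph on the T time points: temporal edges
   *t → t+1* (the arrow of time), plus bidirectional spatial edges between
   points that are reciprocal k-nearest neighbors in state space
   (Euclidean, default *k = 7*).
2. **Contraction.** With *dist(i→j)* the directed unit-weight shortest-path
   length (minimal number of time steps to transition), points *i, j* merge
   iff *dist(i→j) ≤ d* **and** *dist(j→i) ≤ d* (default *d = 3*); clusters
   are connected components of this relation. Edges between clusters carry
   transition counts.

On the resulting network, **node size** (member count = total dwell time)
measures local stability of a state, and **loop length** (edges on the
shortest directed cycle through a node) measures global stability — how
many transitions a state needs to recur. Interval-coded annotation tracks
(e.g., alliance-rupture ratings, 1–5 every 30 s) overlay onto nodes as
member-point means. A two-level nonparametric design compares stability
with behavior: within sessions, Spearman correlations of node size against
node-average variables, tested at the group level with a one-sample
Wilcoxon signed-rank test against median zero; between sessions, Spearman
correlations of session-average node size and loop length against
session-average variables. A seeded multistable generator with ground-truth
labels makes every stage testable.

## Worked example

```r
library(temporalmapper)

ps  <- preset_config("easy-3-state", seed = 42)      # 3 attractors on a cycle
sim <- simulate_session(ps$config, session_id = "demo")
track <- coupled_annotation(sim$ground_truth, sim$session, ps$annotation$levels,
                            noise_sd = 0.3, seed = 43, track_name = "confrontation")

g   <- build_stknn(sim$session, k = 7)
net <- contract(g, d = 3)
net <- attach_overlays(net, sim$session, list(track))
net
#> <transition_network 'demo': 31 nodes, 60 edges (T=3000, k=7, d=3)>

tab <- node_metrics_table(net)
head(tab[order(-tab$size), c("node_id", "size", "dwell_seconds", "loop_length",
                             "patient_warmth", "confrontation")], 5)
#>   node_id size dwell_seconds loop_length patient_warmth confrontation
#> 1       0 1018           509           2        597.306          1.40
#> 6       5 1010           505           2          0.567          4.65
#> 2       1  934           467           2       -594.085          2.93
#> 8       7    6             3           2        243.362          3.02
#> 4       3    4             2           4       -447.299          3.26

summarize_session(net, list(confrontation = expand_annotation(track, sim$session)))
#>   session_id n_nodes n_edges mean_node_size mean_loop_length n_loop_undefined mean_confrontation
#> 1       demo      31      60          96.77            2.387                0              2.994

recovery_score(net, sim$ground_truth)
#> adjusted Rand index 0.987, edge recall 1.00
```

Reading the output: the three planted attractors appear as the three large
nodes (sizes 1018/1010/934 — about 8.5 min of dwell each), each with loop
length 2 (the shortest return passes through one other state); the
remaining tiny nodes are transition-path points and stray outliers. The
node-average overlays show each attractor's characteristic patient warmth
and its confrontation level (1.4 / 4.65 / 2.93, recovering the planted
levels 1/5/3), and the partition matches the hidden state labels almost
perfectly (adjusted Rand index 0.987, all realized transitions recovered
as edges).

The statistics layer works the same way from data frames:

```r
spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
#> $rho 0.6, $p 0.417 (exact permutation), n = 4
```

A thin command-line wrapper covers the same pipeline
(`inst/cli/temporalmapper.R` with subcommands `simulate`, `build`,
`stats`, `sweep`), and `run_build()` / `run_stats()` / `run_simulate()` /
`run_sweep()` write all artifacts (GraphML + JSON + TSV tables) with a
manifest of config, seed and content hashes.

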