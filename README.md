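# netrank

Network-based prioritization of prognostic marker genes from tumor
expression profiles.

## The problem

Outcome prediction from tumor gene expression is a weak-signal problem:
with a few dozen patients and thousands of genes, the sample correlation of
any single gene with survival time is dominated by chance, and signatures
picked by correlation alone replicate poorly. `netrank` regularizes the
ranking with prior knowledge. Each gene *i* is seeded with
`c_i = |cor(expression_i, survival time)|` (training samples only; genes
failing the expression filters keep seed 0 but stay in the graph), and the
seeds are propagated through a gene–gene network — transcription
factor–target relations, protein–protein interactions, or a thresholded
co-expression matrix — via the PageRank-style fixed point

```
r_i = (1 - d) * c_i + d * sum_j A_ij * r_j / deg_j
```

equivalently `(I - d A D^-1) r = (1 - d) c`, solved exactly by sparse LU.
The damping factor `d` in [0, 1] mixes expression evidence (`d = 0`: `r =
c`) with network topology (`d = 1`: degree-proportional scores) and is
chosen by nested cross-validation over the grid 0, 0.1, …, 1.0. The top-k
genes form the signature; a balanced Monte Carlo cross-validation engine
with a support-vector-machine classifier benchmarks the ranking against
fold change, Student's t, Pearson/Spearman correlation, the SAM moderated
statistic, a direct-neighbor variant, topology-only ranking, and a random
control. Tools for validating dichotomized immunohistochemistry markers
(median cut-offs, backward elimination under leave-one-out
cross-validation, ROC AUC) round out the workflow.

The package is aimed at computational biologists benchmarking
network-guided feature selection for survival signatures, and ships a
synthetic-data generator (scale-free networks with a planted prognostic
module and realistic noise/uninformative gene strata) so every stage runs
and is tested without patient data.

## Worked example

```r
library(netrank)

net  <- simulate_network(n_genes = 1000, topology = "scale-free", seed = 42)
sim  <- simulate_cohort(net, n_samples = 30, seed = 42)   # planted 5-driver module
mask <- compute_filter_mask(sim$expr)                     # mean >= 6, sd >= 0.5
sum(mask$selected)
#> [1] 500

universe <- align_universe(net, sim$expr$gene)
seeds    <- correlation_seed(sim$expr, sim$clinical$survival_months, universe, mask)
ranking  <- netrank_solve(universe, seeds, d = 0.3)
head(tidy(ranking), 7)
#> # A tibble: 7 × 4
#>   gene    seed score  rank
#>   <chr>  <dbl> <dbl> <int>
#> 1 g00012 0.189 0.891     1
#> 2 g00003 0.319 0.714     2
#> 3 g00009 0.499 0.628     3
#> 4 g00002 0     0.458     4
#> 5 g00016 0.510 0.389     5
#> 6 g00370 0.511 0.367     6
#> 7 g00001 0     0.367     7
sim$drivers
#> [1] "g00003" "g00009" "g00012" "g00015" "g00016"
```

Four of the seven top-ranked genes are planted drivers, including `g00012`,
whose own correlation (seed 0.189) is far below the chance level — its rank
comes from a consistently correlated network neighborhood. Genes with seed
0 (`g00002`, `g00001`) were filtered out of the expression data but still
collect scores; `top_k_signature(ranking, mask$gene[mask$selected], 7)`
restricts a signature to measured genes.

The benchmark engine compares rankers on identical balanced splits, with
the damping factor re-chosen inside every training set:

```r
cv <- monte_carlo_cv(sim$expr, sim$clinical, net,
                     methods = c("netrank", "pearson", "random"),
                     k = 7, train_sizes = c(12, 24), repeats = 50,
                     base_seed = 1, mask = mask)
summary(cv)
#> # A tibble: 6 × 7
#>   method  train_size     k repeats mean_accuracy    sem mean_chosen_d
#>   <chr>        <dbl> <dbl>   <int>         <dbl>  <dbl>         <dbl>
#> 1 netrank         12     7      50         0.592 0.0158         0.56
#> 2 netrank         24     7      50         0.677 0.0279         0.532
#> 3 pearson         12     7      50         0.55  0.0160       NaN
#> 4 pearson         24     7      50         0.553 0.0283       NaN
#> 5 random          12     7      50         0.494 0.0137       NaN
#> 6 random          24     7      50         0.493 0.0286       NaN
```

Network propagation beats the correlation ranking at both training sizes,
the random control sits at chance, and `autoplot(cv)` draws the accuracy
curves. `tidy(cv)` exposes every repeat with its recorded seed;
`mc_cv_replay()` reproduces a report bit-exactly from those records.

A thin command-line interface over the same functions lives in
`inst/cli/netrank.R` (`simulate`, `filter`, `rank`, `score`, `evaluate`,
`validate-markers`).

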