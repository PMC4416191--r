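# cernanet

Competing endogenous RNA (ceRNA) network construction and cross-cancer
comparison from miRNA-target predictions and expression profiles.

## The problem

MicroRNAs repress mRNAs by binding their 3' UTRs. Two genes that share
targeting miRNAs can regulate each other *indirectly*: when one transcript
rises it soaks up the shared miRNAs (the pair's **miRNA program**, miRP)
and thereby de-represses its partner. This competition couples the two
expression profiles, and the coupling strength depends on measurable
conditions: how many miRNAs the pair shares, how many binding sites those
miRNAs have on the pair (#miRPBS), how abundant the miRP is (too little:
nothing to compete for; too much: competition is saturated), and how highly
the two genes themselves are expressed.

`cernanet` implements this analysis end to end for anyone with a
gene-by-miRNA targeting table (e.g. a TargetScan summary) and matched
mRNA/miRNA expression matrices:

1. **Pair enumeration** — build the binary targeting matrix
   `T` (genes × miRNAs) and enumerate putative ceRNA pairs as the non-zero
   off-diagonal entries of `P = T Tᵀ`; `P[a, b]` is the pair's miRP size,
   and `#miRPBS = Σ_{m ∈ miRP} (s_am + s_bm)` sums the shared miRNAs'
   binding sites on both genes.
2. **Factor stratification** — compute each pair's Pearson correlation `r`
   across samples, stratify pairs into quartiles of miRP size, #miRPBS and
   miRP expression and into expression-state combinations (H/M/L bands
   with the extreme 5% trimmed), and compare the correlation CDFs of the
   strata with two-sample Kolmogorov–Smirnov tests
   (`D = sup_x |F̂₁(x) − F̂₂(x)|`).
3. **Optimal network** — select pairs satisfying the optimal conjunction
   (miRP size Q4, #miRPBS Q4, miRP expression Q3, both genes H), build the
   optimal ceRNA network, rank hubs, extract function subnetworks.
4. **Pan-cancer comparison** — re-evaluate the optimal pairs in other
   cohorts, call **core pairs** (right-tail correlation p < 0.05), compare
   core ceRNA rosters across datasets (Venn regions, top-hub prefixes),
   and quantify intra-function stability with the population coefficient
   of variation `CV = 100 · σ_pop / μ`.
5. **Synthetic data** — a seeded generator with known shared-miRNA coupling
   (`y_g = b_g − λ Σ_m s_gm (x_m − μ_m) + ε`) whose closed-form pair
   correlations make every stage testable offline.

## Worked example

```r
library(cernanet)

dir <- tempfile()
paths <- make_fixture_suite("graded", dir)          # synthetic inputs on disk
tm  <- build_target_matrix(read_targets(paths$targets))
pt  <- enumerate_cerna_pairs(tm)
ann <- annotate_pairs(pt, read_expression(paths$gene_expr),
                      read_expression(paths$mirna_expr))
strat <- stratify_and_test(ann)
subset(attr(strat, "group_summary"), factor == "mirp_size")
#>     factor group    n   median_r
#>  mirp_size    Q1 1516 0.08349918
#>  mirp_size    Q2 1231 0.12632414
#>  mirp_size    Q3 2544 0.16277816
#>  mirp_size    Q4 1828 0.22647220
```

Median coexpression rises monotonically with shared-program size — the
coupling the generator built in — and the extreme strata separate sharply
(`D = 0.538`, p below double precision, reported as 0 with an underflow
flag):

```r
subset(strat, factor == "mirp_size" & group_a == "Q1" & group_b == "Q4")
#>     factor group_a group_b  n_a  n_b     ks_D ks_p underflow
#>  mirp_size      Q1      Q4 1516 1828 0.538032    0      TRUE

net <- build_network(select_optimal_pairs(ann))
net
#> cerna_network: 25 ceRNAs, 39 regulation pairs, mean degree 3.1
hub_table(net, 5)
#>  gene degree pct_of_pairs
#>  g108      9     23.07692
#>  g020      7     17.94872
#>  ...
call_core_pairs(select_optimal_pairs(ann), read_expression(paths$gene_expr),
                label = "self")
#> core_set 'self': 31 core pairs (alpha = 0.05) over 24 genes; 39 pairs evaluated, 0 dropped
```

`hub_table` shares are each hub's percentage of all optimal pairs
(degree / total pairs); `core_set` counts the pairs whose positive
correlation is significant in the queried dataset.

A subcommand CLI wraps the same functions
(`inst/exec/cernanet simulate|enumerate|stratify|optimal|pancancer|report`);
every output table carries a provenance header and fixed-seed runs are
byte-identical.

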