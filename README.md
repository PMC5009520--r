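# phenowalk

Disease-gene prioritization by random walk with restart on a three-layer
phenotype–gene heterogeneous network, with the complete evaluation suite
such rankings need: leave-one-out cross validation, binned enrichment
with permutation p-values, precision–recall curves, and top-k pathway
scoring.

## The problem and the method

Known disease genes are few; candidate genes are the whole genome. A
productive way to close that gap is to combine what is known about a
disease's *phenotype* (which other diseases look clinically similar)
with what is known about gene *function* (which genes work together).
phenowalk operationalizes this on a heterogeneous graph:

* a gene functional network **G** (weighted functional associations),
* two disease–disease phenotype-similarity networks **P1**
  (manifestation-based) and **P2** (phenotype-ontology-based),
* bipartite disease–gene association links from G to each phenotype
  layer, and identifier-map links between P1 and P2.

Seeds — the disease's known genes plus its disease nodes in both
phenotype layers — receive the initial probability mass *p₀*, and the
random walk with restart

  *p*ₖ₊₁ = (1 − γ) *M*ᵀ *p*ₖ + γ *p₀*

is iterated to its fixed point, where *M* is the row-stochastic block
transition matrix over all three layers (intra-layer blocks on the
diagonal, normalized bipartite blocks off it; nodes with both edge types
jump layers with probability λ). Genes are then ranked by their
steady-state visiting probability; a gene ranks high when it is close,
through any combination of functional and phenotypic routes, to what is
already known about the disease. An exact linear-solve oracle
γ(I − (1 − γ)Mᵀ)⁻¹p₀ backs the iterative solver.

## Worked example

The package ships a synthetic benchmark generator that plants a 10-gene
functional module, a disease cluster in each phenotype layer, and
bipartite links between them inside background noise — ground truth for
every stage of the pipeline:

```r
library(phenowalk)

gen <- generate_synthetic(synthetic_spec(rng_seed = 1))
gen$graph
#> <het_graph: |G|=200 |P1|=40 |P2|=40, 280 total nodes>

fit <- prioritize(gen$graph, gen$seeds)
fit$walk
#> <rwr_result: 280 nodes, 17 iterations, residual 3.89e-11>
head(fit$ranking, 3)
#>   gene      score rank percentage
#> 1 g008 0.03602428    1        0.5
#> 2 g009 0.03356024    2        1.0
#> 3 g002 0.03205286    3        1.5
```

The ten planted genes (g001–g010) occupy the top ten ranks; the
`percentage` column is the rank as a share of all 200 ranked genes.
Leave-one-out cross validation withholds each seed gene and its
disease links in turn and asks where the walk re-ranks it:

```r
lo <- loocv(gen$graph, gen$seeds)
summarize_ranks(lo$rank, attr(lo, "n_genes"), rank_cutoffs = 20, pct_cutoffs = 10)
#> $mean_rank
#> [1] 10
#> $counts
#> rank<=20  pct<=10
#>       10       10
```

Every withheld gene is recovered at rank 10 (top 5 %) — just behind the
nine seeds that remain. Seeding from the disease nodes alone and scoring
the planted genes as a "validation set" exercises the enrichment
machinery:

```r
dseeds <- seed_set(disease_seeds_p1 = gen$truth$p1,
                   disease_seeds_p2 = gen$truth$p2)
rep <- enrichment_report(prioritize(gen$graph, dseeds)$ranking,
                         gen$truth$genes, k = 20, bin_size = 20,
                         B = 10000, rng_seed = 2)
rep[c("hits", "n_valid", "N", "fold", "p_value")]
#> $hits      [1] 10
#> $n_valid   [1] 10
#> $N         [1] 200
#> $fold      [1] 10
#> $p_value   [1] 9.999e-05
```

All ten planted genes land in the top 20 of 200 — a 10-fold enrichment
over a random ranking, at the smallest p-value 10,000 permutations can
report (1/10001).

## Command line

A thin wrapper (`inst/cli/phenowalk.R`) exposes the pipeline as
subcommands over edge-list TSV inputs:

```sh
Rscript inst/cli/phenowalk.R simulate --outdir fixture --seed 1
Rscript inst/cli/phenowalk.R rank     --config run.cfg --gamma 0.7
Rscript inst/cli/phenowalk.R loocv    --config run.cfg
Rscript inst/cli/phenowalk.R enrich   --config run.cfg --permutations 10000
Rscript inst/cli/phenowalk.R pathways --config run.cfg --top-n 100
```

Configuration is a flat `key = value` file (input paths, γ, λ,
tolerance, bin size, seeds); command-line flags override it, every run
writes a JSON provenance log, and reruns are byte-identical.

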