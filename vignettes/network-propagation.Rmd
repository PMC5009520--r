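---
title: "Propagation on a phenotype-gene multilayer network: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagation on a phenotype-gene multilayer network: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenowalk)
```

## The model

phenowalk ranks candidate disease genes by how easily a random walker,
repeatedly restarted from what is already known about a disease, reaches
them through a heterogeneous network. The graph has three layers:

* **G** — a gene functional network (e.g. protein interactions, pathway
  co-membership, co-expression), weighted by confidence;
* **P1** — a disease-disease similarity network built from clinical
  manifestation profiles;
* **P2** — a disease-disease similarity network built from semantic
  similarity of phenotype-ontology annotations.

Three bipartite link sets join the layers: curated disease-gene
associations connect G to each phenotype layer, and cross-vocabulary
identifier maps connect the disease nodes of P1 and P2. Seeds are the
known disease genes plus the nodes representing the disease in each
phenotype layer, so phenotypic similarity and genetic association
contribute jointly to every gene's score.

The walk iterates

$$p_{k+1} = (1 - \gamma)\, M^{\mathsf T} p_k + \gamma\, p_0,$$

where $p_0$ is the restart (seed) distribution, $\gamma \in (0, 1]$ the
restart probability, and $M$ the row-stochastic transition matrix of the
whole heterogeneous graph: three intra-layer blocks on the diagonal and
six bipartite blocks off it. The fixed point
$p = \gamma (I - (1-\gamma) M^{\mathsf T})^{-1} p_0$ exists and is unique
for any $\gamma > 0$ because the iteration map is a contraction with
factor $1 - \gamma$ in the $L_1$ norm; `rwr_exact()` computes it by a
dense direct solve and serves as the oracle against which the iterative
path is tested.

## Normalizing the blocks

Turning the weighted adjacencies into one stochastic matrix requires a
rule for splitting each node's unit of outgoing mass between staying in
its layer and jumping across. phenowalk uses a jump parameter
$\lambda \in [0, 1]$ and fills row $i$ by four mutually exclusive cases,
writing $f(i)$ for the number of foreign layers node $i$ reaches through
at least one bipartite link:

1. intra-layer edges only: the full mass goes to intra-layer neighbours,
   proportional to edge weight;
2. intra-layer edges and $f(i) \ge 1$ linked foreign layers: mass
   $1 - \lambda$ to intra-layer neighbours and $\lambda / f(i)$ into
   each linked foreign layer, proportional to bipartite weight within
   that layer;
3. bipartite links only: mass $1 / f(i)$ per linked foreign layer;
4. fully isolated: a self-loop of mass 1.

Splitting $\lambda$ equally among linked foreign layers is the symmetric
generalization of the classical two-layer jump scheme to three layers;
it reduces to the two-layer rule whenever a node links into a single
foreign layer, and a single global $\lambda$ governs both disease-gene
and disease-disease (identifier-map) jumps. The self-loop repair in case
4 is what makes the matrix *exactly* stochastic, which in turn makes
conservation of probability mass a testable invariant of every iterate
rather than an approximation.

Two smaller conventions matter for reproducibility. The global node
order is fixed — gene block first, then P1, then P2, ids sorted with
locale-independent C collation inside each block — so the matrix, the
summation order of the iteration, and therefore every score and rank are
bit-identical across runs and across permutations of input file lines.
And bipartite weights participate in the proportional split, so curated
association lists loaded with the default weight 1 spread jump mass
uniformly over a node's associations.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.7 | restart probability per step; dimensionless. Larger values keep mass near the seeds, smaller values reward global connectivity. Every correctness property holds for any $\gamma \in (0,1)$; 0.7 is the conventional choice in the restart-walk gene-prioritization literature. |
| `lambda` | 0.5 | inter-layer jump probability for nodes that have both intra-layer edges and bipartite links; 0.5 weighs the layers evenly. |
| `tol` | 1e-10 | $L_1$ stopping tolerance on successive iterates. With contraction factor $1-\gamma$ the iteration gains roughly $-\log_{10}(1-\gamma)$ digits per step, so convergence takes a few dozen iterations at most. |
| `max_iter` | 1000 | hard cap; exceeding it returns the last iterate with a warning flag. |
| `bin_size` | 500 | ranks per window in the binned enrichment count. |
| `top_n` | 100 | prefix size for the pathway score. |
| `B` | 10000 | random rankings per permutation p-value; the +1-corrected minimum reportable p is $1/(B+1) < 10^{-4}$. |

The seed distribution splits its mass equally over the non-empty seed
groups (genes, P1 diseases, P2 diseases) and uniformly within each
group. Nothing in the formulation forces that balance — it is the
symmetric, parameter-free default, and `layer_weights` exposes it.

## Evaluation semantics

**Leave-one-out.** Each seed gene in turn is removed from the seed list
and its bipartite associations *to the disease seed nodes* in both
phenotype layers are deleted; its functional-network edges and its
associations to other diseases stay. Deleting more (say, the gene's
whole row) would test a different, harsher question than "can the
remaining knowledge recover this association". The withheld gene's rank
among all genes is recorded; ranks use competition ranking (rank = 1 +
number of strictly better genes), matching how integer ranks are
conventionally reported, with lexicographic display order among ties.
By default the remaining seed genes stay in the ranking universe; the
`exclude_seeds` option removes them.

**Enrichment.** For a validation gene list, hits are counted per
`bin_size`-rank window, the top-$k$ fold enrichment is
$(\mathrm{hits}/k)/(n_{\mathrm{valid}}/N)$ with $N$ the number of ranked
genes, and the permutation p-value draws $B$ random rankings —
equivalently, hypergeometric draws of the top-$k$ hit count, which is
what the implementation samples. The exact hypergeometric tail is kept
out of the implementation on purpose: it is the independent closed-form
oracle the test suite compares the Monte-Carlo p-values against (within
three Monte-Carlo standard errors). Validation genes absent from the
ranking universe are dropped and reported, so $n_{\mathrm{valid}}$
always refers to the universe actually ranked.

**Pathway score.** A gene set's score is the fraction of its members in
the top `top_n` of the ranking. The denominator is the set's full
membership, members outside the ranking universe included — the literal
reading of "divided by the total number of genes in this pathway";
`restrict_universe = TRUE` switches to the in-universe denominator. The
score is a descriptive screen, not a test, so no multiple-testing
correction is attached.

## The synthetic benchmark

`generate_synthetic()` builds a three-layer graph with known ground
truth: an independent-edge background graph per layer, a dense planted
module of `module_genes = 10` genes (edge probability `p_intra_module =
0.6` inside vs `p_background = 0.02` outside), a planted cluster of 5
disease nodes in each phenotype layer with the same densities, bipartite
links between planted genes and planted diseases at
`bipartite_link_rate = 0.5`, identifier-map links between the two
planted disease clusters at the same rate, and sparse background
cross-layer links at rate 0.002. Weights are uniform on (0.1, 1],
mirroring similarity/confidence scores. Default layer sizes are 200
genes and 40 + 40 disease nodes — large enough that a planted gene's
top-decile recovery is statistically meaningful, small enough that the
full property suite (including one hundred transition matrices and
sixty generator-plus-walk replicates for the monotonicity trend) runs in
seconds.

What the generator does *not* emulate: the heavy-tailed degree
distributions of real interactomes, the near-clique redundancy of
semantic-similarity networks, ascertainment bias in curated association
lists, and their sheer scale. Passing recovery tests on planted modules
therefore demonstrates that the machinery propagates and ranks
correctly, not that any particular biological prediction is right.

## Numerical choices and degenerate inputs

* All-zero adjacency rows become self-loops (case 4), never renormalized
  noise; `row_normalize()` by itself leaves zero rows zero and the
  repair happens only in the block assembly.
* Convergence is declared on the $L_1$ difference of iterates;
  residuals are non-increasing after the first step, which the suite
  asserts, so a stall cannot masquerade as convergence.
* `rwr_exact()` refuses graphs above 2000 nodes rather than silently
  densifying a large sparse matrix.
* Score ties rank by competition ranking and display lexicographically;
  pathway-score ties order by pathway name. No randomness is involved
  in ranking, so reruns are byte-identical.
* A walk at $\gamma = 1$ returns $p_0$ exactly; a seedless $p_0$ is an
  error rather than a uniform fallback.
* Isolated nodes survive edge-list round trips via single-field lines,
  so a disease node whose only connection is bipartite keeps its
  identity in written fixtures.

## Limitations

* The restart probability and jump probability of the original analyses
  of this design are not published; defaults here are the field's
  conventional values and both are exposed as parameters, so reported
  ranks should always be read alongside the (γ, λ) that produced them.
* Identifier mapping between disease vocabularies is consumed as a
  pre-built link file, never computed.
* Networks are undirected and static; directed or time-resolved
  propagation is out of scope.
* The pathway score intentionally has no null model; use the
  enrichment machinery when a p-value is needed.
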