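test_that("rank summaries report mean, percentage and cutoff counts", {
  s <- summarize_ranks(c(10, 20, 60), N = 100,
                       rank_cutoffs = c(15, 50), pct_cutoffs = c(25))
  expect_equal(s$mean_rank, 30)
  expect_equal(s$mean_rank_raw, 30)
  expect_equal(s$mean_rank_pct, 30.0)
  expect_equal(unname(s$counts), c(1L, 2L, 2L))
  expect_error(summarize_ranks(c(5, 200), N = 100), "exceeds")
  expect_error(summarize_ranks(integer(), N = 100))
})

mk_ranking <- function(n, top_genes = character()) {
  ids <- sprintf("g%03d", seq_len(n))
  g <- weighted_network(nodes = ids, layer = "G")
  hg <- assemble(list(g, weighted_network(layer = "P1"),
                      weighted_network(layer = "P2")), list())
  rank_genes(scores_for(hg, top_genes), hg)
}

test_that("bin counts partition the validation hits by rank window", {
  rk <- mk_ranking(10, top_genes = sprintf("g%03d", 8:10))
  bc <- bin_counts(rk, sprintf("g%03d", 8:10), bin_size = 5)
  expect_equal(bc$counts, c(3L, 0L))
  expect_equal(bc$n_in_universe, 3L)
  # disjoint validation set: all-zero bins, everything reported ignored
  bc <- bin_counts(rk, c("x1", "x2"), bin_size = 5)
  expect_equal(bc$counts, c(0L, 0L))
  expect_equal(sort(bc$ignored), c("x1", "x2"))
  # saturated: every full bin holds bin_size genes
  bc <- bin_counts(rk, rk$gene, bin_size = 4)
  expect_equal(bc$counts, c(4L, 4L, 2L))
  expect_equal(sum(bc$counts), 10L)
})

test_that("bin counts sum to the in-universe validation size for any bin size", {
  rk <- mk_ranking(37)
  set.seed(21)
  valid <- sample(rk$gene, 11)
  for (b in c(1, 3, 10, 37, 100))
    expect_equal(sum(bin_counts(rk, valid, b)$counts), 11L)
})

test_that("fold enrichment is the hit-rate ratio and is linear in hits", {
  # expectation case: observed = expected hit count gives fold 1
  expect_equal(fold_enrichment(hits = 50 * 10 / 100, k = 50,
                               n_valid = 10, N = 100), 1.0)
  expect_equal(fold_enrichment(6, 50, 10, 100),
               2 * fold_enrichment(3, 50, 10, 100))
  expect_error(fold_enrichment(1, 0, 10, 100), "positive")
  expect_error(fold_enrichment(1, 50, 0, 100), "positive")
  expect_error(fold_enrichment(60, 50, 70, 100), "hits")
})

test_that("permutation p-values track the exact hypergeometric tail", {
  cases <- list(c(hits = 5, k = 20, n = 15, N = 200),
                c(hits = 2, k = 50, n = 10, N = 500),
                c(hits = 8, k = 30, n = 40, N = 300))
  B <- 10000L
  for (cs in cases) {
    p_mc <- permutation_pvalue(cs["hits"], cs["k"], cs["n"], cs["N"],
                               B = B, rng_seed = 42)
    p_exact <- phyper(cs["hits"] - 1, cs["n"], cs["N"] - cs["n"], cs["k"],
                      lower.tail = FALSE)
    se <- sqrt(p_exact * (1 - p_exact) / B)
    expect_lt(abs(p_mc - p_exact), 3 * se + 2 / B)
  }
})

test_that("permutation p-value hits its degenerate bounds", {
  expect_equal(permutation_pvalue(0, 20, 15, 200, B = 500, rng_seed = 1), 1)
  # all validation genes in the top k, tiny tail: smallest reportable p
  B <- 2000L
  expect_equal(permutation_pvalue(5, 5, 5, 10000, B = B, rng_seed = 3),
               1 / (B + 1))
})

test_that("identical seeds give identical p-values without touching the RNG", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  p1 <- permutation_pvalue(3, 20, 10, 200, B = 200, rng_seed = 7)
  after <- runif(1)
  p2 <- permutation_pvalue(3, 20, 10, 200, B = 200, rng_seed = 7)
  expect_identical(p1, p2)
  expect_identical(before, after)  # global RNG stream undisturbed
})

test_that("precision-recall emits one point per validation hit", {
  # perfect ranking: precision 1 at every point
  rk <- mk_ranking(10, top_genes = sprintf("g%03d", c(4, 7, 9)))
  pr <- precision_recall(rk, sprintf("g%03d", c(4, 7, 9)))
  expect_equal(pr$precision, c(1, 1, 1))
  expect_equal(pr$recall, c(1, 2, 3) / 3)
  # single validation gene at rank r: one point (1, 1/r)
  rk <- mk_ranking(20)
  gene_at_r <- rk$gene[7]
  pr <- precision_recall(rk, gene_at_r)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$recall, 1)
  expect_equal(pr$precision, 1 / 7)
  # validation reaching the bottom of the list: terminal precision n/N
  valid <- rk$gene[c(3, 20)]
  pr <- precision_recall(rk, valid)
  expect_equal(pr$precision[nrow(pr)], 2 / 20)
  expect_error(precision_recall(rk, "absent"), "no validation gene")
})

test_that("leave-one-out recovers planted genes near the top", {
  gen <- generate_synthetic(synthetic_spec(rng_seed = 1))
  res <- loocv(gen$graph, gen$seeds)
  expect_equal(nrow(res), length(gen$seeds$gene_seeds))
  expect_setequal(res$gene, gen$seeds$gene_seeds)
  expect_true(all(res$rank >= 1 & res$rank <= attr(res, "n_genes")))
  # planted module recovery: held-out genes stay in the top decile
  expect_true(all(res$percentage < 10))
})

test_that("interchangeable held-out genes earn identical ranks", {
  # swapping gA and gB is a graph automorphism fixing everything else
  g <- weighted_network(edges = data.frame(from = "gA", to = "gB", weight = 1),
                        nodes = c("gA", "gB", "gC"), layer = "G")
  p1 <- weighted_network(nodes = "d1", layer = "P1")
  p2 <- weighted_network(nodes = "h1", layer = "P2")
  hg <- assemble(list(g, p1, p2),
                 list(bipartite_links(data.frame(a = c("gA", "gB"),
                                                 b = c("d1", "d1")), "G", "P1")))
  seeds <- seed_set(gene_seeds = c("gA", "gB"), disease_seeds_p1 = "d1")
  res <- loocv(hg, seeds)
  expect_equal(res$rank[res$gene == "gA"], res$rank[res$gene == "gB"])
})

test_that("a gene isolated by link removal is still ranked", {
  # gZ's only connection is its association to the disease seed; the fold
  # that holds it out severs it entirely, yet it must receive a rank
  g <- weighted_network(edges = data.frame(from = "gA", to = "gB", weight = 1),
                        nodes = c("gA", "gB", "gZ"), layer = "G")
  p1 <- weighted_network(nodes = "d1", layer = "P1")
  p2 <- weighted_network(nodes = "h1", layer = "P2")
  hg <- assemble(list(g, p1, p2),
                 list(bipartite_links(data.frame(a = c("gA", "gZ"),
                                                 b = c("d1", "d1")), "G", "P1")))
  seeds <- seed_set(gene_seeds = c("gA", "gZ"), disease_seeds_p1 = "d1")
  res <- loocv(hg, seeds)
  expect_equal(nrow(res), 2)
  expect_true(all(is.finite(res$rank)))
})

test_that("leave-one-out preconditions are enforced", {
  gen <- small_gen(2)
  expect_error(loocv(gen$graph, seed_set(gene_seeds = gen$truth$genes[1],
                                         disease_seeds_p1 = gen$truth$p1)),
               "at least 2")
})

test_that("the enrichment report ties hits, fold and p together", {
  rk <- mk_ranking(100)
  valid <- rk$gene[c(2, 5, 9, 50)]  # three hits inside the top 10
  rep <- enrichment_report(rk, valid, k = 10, bin_size = 10,
                           B = 2000, rng_seed = 5)
  expect_equal(rep$hits, 3L)
  expect_equal(rep$N, 100L)
  expect_equal(rep$fold, (3 / 10) / (4 / 100))
  expect_equal(sum(rep$bins$counts), 4L)
  expect_lt(rep$p_value, 0.05)
})
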