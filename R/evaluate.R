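#' Leave-one-out cross validation over the gene seeds
#'
#' For each seed gene in turn: the gene is removed from the seed list and
#' its bipartite associations to the disease seed nodes in both phenotype
#' layers are deleted (its functional-network edges and its links to
#' other diseases are left intact), the transition matrix is rebuilt, the
#' walk is re-run from the reduced seeds, and the recovered rank of the
#' held-out gene among all genes is recorded.
#'
#' @param hg a [het_graph][assemble()].
#' @param seeds a [seed_set()] with at least two gene seeds.
#' @param walk_cfg a [walk_config()].
#' @param trans_cfg a [transition_config()].
#' @param exclude_seeds if `TRUE`, the remaining seed genes are dropped
#'   from the ranking universe of each fold; by default every gene is
#'   ranked.
#' @return a `loocv_result`: data.frame with one row per held-out gene
#'   (`gene`, `rank`, `percentage`), with the universe size in attribute
#'   `n_genes`.
#' @export
loocv <- function(hg, seeds, walk_cfg = walk_config(),
                  trans_cfg = transition_config(),
                  exclude_seeds = FALSE) {
  stopifnot(inherits(seeds, "seed_set"))
  gs <- seeds$gene_seeds
  if (length(gs) < 2L)
    stop("leave-one-out requires at least 2 gene seeds", call. = FALSE)
  missing <- setdiff(gs, hg$networks$G$nodes)
  if (length(missing))
    stop("held-out gene absent from gene layer: ", missing[1L], call. = FALSE)
  rows <- vector("list", length(gs))
  N <- NA_integer_
  for (i in seq_along(gs)) {
    g <- gs[i]
    fold_seeds <- seed_set(gene_seeds = setdiff(gs, g),
                           disease_seeds_p1 = seeds$disease_seeds_p1,
                           disease_seeds_p2 = seeds$disease_seeds_p2)
    hg_fold <- drop_seed_links(hg, g, seeds$disease_seeds_p1,
                               seeds$disease_seeds_p2)
    fit <- prioritize(hg_fold, fold_seeds, walk_cfg, trans_cfg,
                      exclude = if (exclude_seeds) setdiff(gs, g) else character())
    N <- attr(fit$ranking, "n_genes", exact = TRUE)
    hit <- fit$ranking[fit$ranking$gene == g, , drop = FALSE]
    rows[[i]] <- data.frame(gene = g, rank = hit$rank,
                            percentage = hit$percentage,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("loocv_result", "data.frame"), n_genes = N)
}

# remove bipartite links between one gene and the disease seed nodes,
# keeping the node set (and hence the global order) unchanged
drop_seed_links <- function(hg, gene, disease_p1, disease_p2) {
  drop_from <- function(bp, diseases) {
    lk <- bp$links
    kill <- lk$a == gene & lk$b %in% diseases
    if (!any(kill)) return(bp)
    bipartite_links(lk[!kill, , drop = FALSE], bp$layer_a, bp$layer_b)
  }
  hg$bipartite[["G:P1"]] <- drop_from(hg$bipartite[["G:P1"]], disease_p1)
  hg$bipartite[["G:P2"]] <- drop_from(hg$bipartite[["G:P2"]], disease_p2)
  hg
}

#' Summarize held-out ranks
#'
#' @param ranks positive integer ranks, each in `[1, N]`.
#' @param N size of the ranking universe.
#' @param rank_cutoffs integer rank thresholds to count against.
#' @param pct_cutoffs percentage thresholds (of `N`) to count against.
#' @return list with `mean_rank` (rounded to integer for display),
#'   `mean_rank_raw`, `mean_rank_pct` (mean rank as % of `N`, one
#'   decimal), and `counts`: named vector of how many ranks fall within
#'   each cutoff.
#' @export
summarize_ranks <- function(ranks, N, rank_cutoffs = c(50L),
                            pct_cutoffs = c(1, 10)) {
  stopifnot(length(ranks) > 0, all(ranks >= 1))
  if (any(ranks > N)) stop("rank exceeds universe size N", call. = FALSE)
  mr <- mean(ranks)
  counts <- c(
    setNames(vapply(rank_cutoffs, function(k) sum(ranks <= k), integer(1)),
             paste0("rank<=", rank_cutoffs)),
    setNames(vapply(pct_cutoffs, function(q) sum(100 * ranks / N <= q),
                    integer(1)),
             paste0("pct<=", pct_cutoffs))
  )
  list(mean_rank = round(mr), mean_rank_raw = mr,
       mean_rank_pct = round(100 * mr / N, 1), counts = counts)
}

#' Count validation genes per rank bin
#'
#' Counts how many validation genes fall in each consecutive window of
#' `bin_size` ranks, top to bottom (final partial bin included).
#' Validation ids absent from the ranking are ignored and reported.
#'
#' @param ranking a [rank_genes()] result.
#' @param validation character vector of validation gene ids.
#' @param bin_size ranks per bin.
#' @return list with `counts` (integer per bin), `ignored` (validation
#'   ids outside the ranking universe), and `n_in_universe`.
#' @export
bin_counts <- function(ranking, validation, bin_size = 500L) {
  stopifnot(bin_size >= 1)
  validation <- unique(as.character(validation))
  N <- attr(ranking, "n_genes", exact = TRUE)
  inside <- ranking$gene %in% validation
  ranks <- ranking$rank[inside]
  n_bins <- max(1L, as.integer(ceiling(N / bin_size)))
  counts <- integer(n_bins)
  if (length(ranks)) {
    b <- pmin(as.integer(ceiling(ranks / bin_size)), n_bins)
    tb <- tabulate(b, nbins = n_bins)
    counts <- as.integer(tb)
  }
  list(counts = counts,
       ignored = setdiff(validation, ranking$gene),
       n_in_universe = sum(inside))
}

#' Fold enrichment of a gene set in a top-k prefix
#'
#' `(hits / k) / (n_valid / N)`: the observed hit rate among the top `k`
#' ranked genes relative to the rate expected under a uniform random
#' ranking.
#'
#' @param hits validation genes observed in the top `k`.
#' @param k prefix length.
#' @param n_valid validation genes in the ranking universe.
#' @param N universe size.
#' @return the fold enrichment (unrounded; display convention is one
#'   decimal).
#' @export
fold_enrichment <- function(hits, k, n_valid, N) {
  if (N <= 0 || k <= 0 || n_valid <= 0)
    stop("k, n_valid and N must be positive", call. = FALSE)
  if (k > N || n_valid > N)
    stop("k and n_valid cannot exceed the universe size N", call. = FALSE)
  if (hits < 0 || hits > min(k, n_valid))
    stop("hits must be in [0, min(k, n_valid)]", call. = FALSE)
  (hits / k) / (n_valid / N)
}

#' Permutation p-value for top-k enrichment
#'
#' Draws `B` uniformly random rankings — equivalently, hypergeometric
#' draws of the number of validation genes landing in the top `k` — and
#' returns `(1 + #{draws >= observed}) / (B + 1)`. The +1 correction
#' keeps the p-value strictly positive, so the smallest reportable value
#' is `1 / (B + 1)`.
#'
#' @inheritParams fold_enrichment
#' @param B number of random rankings.
#' @param rng_seed integer seed for the draws.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(hits, k, n_valid, N, B = 10000L,
                               rng_seed = 1L) {
  if (N <= 0 || k <= 0 || n_valid <= 0 || B < 1)
    stop("k, n_valid, N and B must be positive", call. = FALSE)
  if (k > N || n_valid > N)
    stop("k and n_valid cannot exceed the universe size N", call. = FALSE)
  if (hits < 0 || hits > min(k, n_valid))
    stop("hits must be in [0, min(k, n_valid)]", call. = FALSE)
  draws <- with_local_seed(rng_seed, rhyper(B, n_valid, N - n_valid, k))
  (1 + sum(draws >= hits)) / (B + 1)
}

# run code under a temporary RNG seed, restoring global state after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Precision-recall curve over a ranked gene list
#'
#' One point per ranking position at which a validation gene is
#' encountered: precision is the fraction of the prefix that is
#' validation genes, recall the fraction of in-universe validation genes
#' recovered so far.
#'
#' @param ranking a [rank_genes()] result.
#' @param validation character vector of validation gene ids; at least
#'   one must appear in the ranking.
#' @return data.frame with columns `rank`, `recall`, `precision`.
#' @export
precision_recall <- function(ranking, validation) {
  validation <- unique(as.character(validation))
  is_hit <- ranking$gene %in% validation
  n_valid <- sum(is_hit)
  if (n_valid == 0)
    stop("no validation gene appears in the ranking", call. = FALSE)
  pos <- seq_len(nrow(ranking))
  cum_hits <- cumsum(is_hit)
  at <- which(is_hit)
  data.frame(rank = pos[at],
             recall = cum_hits[at] / n_valid,
             precision = cum_hits[at] / pos[at])
}

#' Top-k enrichment report for a validation gene set
#'
#' Bundles [bin_counts()], [fold_enrichment()] and
#' [permutation_pvalue()] for the conventional "how many validation genes
#' in the top k" analysis.
#'
#' @param ranking a [rank_genes()] result.
#' @param validation character vector of validation gene ids.
#' @param k prefix length (defaults to one bin).
#' @param bin_size ranks per bin.
#' @param B permutations.
#' @param rng_seed seed for the permutation draws.
#' @return list with `hits`, `k`, `n_valid`, `N`, `fold`, `p_value`,
#'   `bins` (the [bin_counts()] result), `B`, `rng_seed`.
#' @export
enrichment_report <- function(ranking, validation, k = bin_size,
                              bin_size = 500L, B = 10000L, rng_seed = 1L) {
  bins <- bin_counts(ranking, validation, bin_size)
  N <- attr(ranking, "n_genes", exact = TRUE)
  n_valid <- bins$n_in_universe
  if (n_valid == 0)
    stop("no validation gene appears in the ranking", call. = FALSE)
  k <- min(k, N)  # a prefix cannot be longer than the universe
  hits <- sum(ranking$rank <= k & ranking$gene %in% validation)
  list(hits = hits, k = k, n_valid = n_valid, N = N,
       fold = fold_enrichment(hits, k, n_valid, N),
       p_value = permutation_pvalue(hits, k, n_valid, N, B, rng_seed),
       bins = bins, B = B, rng_seed = rng_seed)
}
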