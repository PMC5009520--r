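#' Seed set for propagation
#'
#' The restart distribution combines known disease genes with the disease
#' phenotype nodes representing the disease in each phenotype layer.
#'
#' @param gene_seeds character vector of gene ids (layer G).
#' @param disease_seeds_p1,disease_seeds_p2 character vectors of disease
#'   node ids in layers P1 and P2.
#' @param layer_weights optional numeric of length 3 (`G`, `P1`, `P2`):
#'   share of restart mass per seed group. Defaults to an equal split
#'   among the non-empty groups. Weights on empty groups must be zero;
#'   weights are renormalized to sum to 1.
#' @return an object of class `seed_set`.
#' @export
seed_set <- function(gene_seeds = character(),
                     disease_seeds_p1 = character(),
                     disease_seeds_p2 = character(),
                     layer_weights = NULL) {
  groups <- list(G = unique(as.character(gene_seeds)),
                 P1 = unique(as.character(disease_seeds_p1)),
                 P2 = unique(as.character(disease_seeds_p2)))
  nonempty <- vapply(groups, length, integer(1)) > 0
  if (!any(nonempty)) stop("seed set is empty", call. = FALSE)
  if (is.null(layer_weights)) {
    layer_weights <- ifelse(nonempty, 1 / sum(nonempty), 0)
  } else {
    stopifnot(length(layer_weights) == 3L, all(layer_weights >= 0))
    names(layer_weights) <- LAYERS
    if (any(layer_weights[!nonempty] > 0))
      stop("positive layer weight on an empty seed group", call. = FALSE)
    if (sum(layer_weights) == 0) stop("layer weights sum to 0")
    layer_weights <- layer_weights / sum(layer_weights)
  }
  names(layer_weights) <- LAYERS
  structure(list(gene_seeds = groups$G,
                 disease_seeds_p1 = groups$P1,
                 disease_seeds_p2 = groups$P2,
                 layer_weights = layer_weights),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set: %d gene, %d P1, %d P2 seeds>\n",
              length(x$gene_seeds), length(x$disease_seeds_p1),
              length(x$disease_seeds_p2)))
  invisible(x)
}

#' Read a seed file
#'
#' TSV with two columns: layer (`G`, `P1` or `P2`) and node id. Comment
#' (`#`) and blank lines are ignored.
#'
#' @param path file path.
#' @return a [seed_set()] with default layer weights.
#' @export
read_seed_file <- function(path) {
  p <- parse_tsv_lines(path)
  df <- parse_edge_fields(p$lines, p$lineno, path)
  bad <- !df$from %in% LAYERS
  if (any(bad))
    stop(sprintf("%s: unknown layer '%s' at line %d", path,
                 df$from[bad][1L], p$lineno[bad][1L]), call. = FALSE)
  seed_set(gene_seeds = df$to[df$from == "G"],
           disease_seeds_p1 = df$to[df$from == "P1"],
           disease_seeds_p2 = df$to[df$from == "P2"])
}

#' Build the restart distribution from a seed set
#'
#' Each non-empty seed group receives its layer weight (equal split by
#' default), distributed uniformly within the group; every other node
#' gets 0. The result sums to 1.
#'
#' @param seeds a [seed_set()].
#' @param hg a [het_graph][assemble()]; every seed id must exist in its
#'   layer.
#' @return numeric vector over the global node order.
#' @export
make_seed_vector <- function(seeds, hg) {
  stopifnot(inherits(seeds, "seed_set"), inherits(hg, "het_graph"))
  p0 <- numeric(n_nodes(hg))
  put <- function(ids, layer, w) {
    if (!length(ids) || w == 0) return()
    pos <- node_position(hg, layer, ids)
    p0[pos] <<- p0[pos] + w / length(ids)
  }
  put(seeds$gene_seeds, "G", seeds$layer_weights[["G"]])
  put(seeds$disease_seeds_p1, "P1", seeds$layer_weights[["P1"]])
  put(seeds$disease_seeds_p2, "P2", seeds$layer_weights[["P2"]])
  p0
}

#' Rank genes by propagation score
#'
#' Ranks gene-layer nodes only (phenotype nodes are never ranked) by
#' descending score. Ties share a rank under competition ranking
#' (rank = 1 + number of genes with strictly greater score) and are
#' listed in lexicographic id order. The percentage column is
#' `100 * rank / N` where `N` is the number of ranked genes, reported to
#' two decimals — the "top x % of the genome" figure.
#'
#' @param p an [rwr()] result or a numeric score vector over the global
#'   order.
#' @param hg the [het_graph][assemble()] the scores were computed on.
#' @param exclude gene ids dropped before ranking (e.g. remaining seeds).
#' @return a `gene_ranking`: data.frame with columns `gene`, `score`,
#'   `rank`, `percentage`, ordered best-first.
#' @export
rank_genes <- function(p, hg, exclude = character()) {
  if (inherits(p, "rwr_result")) p <- p$p
  stopifnot(is.numeric(p), length(p) == n_nodes(hg))
  gpos <- layer_positions(hg, "G")
  ids <- hg$order$id[gpos]
  keep <- !ids %in% exclude
  ids <- ids[keep]
  scores <- p[gpos][keep]
  ord <- order(-scores, ids, method = "radix")
  ids <- ids[ord]; scores <- scores[ord]
  n <- length(ids)
  # competition rank: 1 + number of strictly greater scores
  rk <- if (n) {
    uniq <- !duplicated(scores)
    cumcount <- seq_len(n) - 1L
    rep(cumcount[uniq] + 1L, times = diff(c(which(uniq), n + 1L)))
  } else integer()
  out <- data.frame(gene = ids, score = scores, rank = rk,
                    percentage = round(100 * rk / max(n, 1L), 2),
                    stringsAsFactors = FALSE)
  structure(out, class = c("gene_ranking", "data.frame"), n_genes = n)
}

#' Write a gene ranking as TSV
#'
#' Columns `gene`, `score`, `rank`, `percentage`, with header.
#'
#' @param ranking a [rank_genes()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' End-to-end gene prioritization
#'
#' Convenience wrapper: builds the transition matrix, the seed vector,
#' runs the walk, and ranks genes.
#'
#' @param hg a [het_graph][assemble()].
#' @param seeds a [seed_set()].
#' @param walk_cfg a [walk_config()].
#' @param trans_cfg a [transition_config()].
#' @param exclude gene ids dropped before ranking.
#' @return list with `ranking` (a `gene_ranking`) and `walk` (the
#'   `rwr_result`).
#' @export
prioritize <- function(hg, seeds, walk_cfg = walk_config(),
                       trans_cfg = transition_config(),
                       exclude = character()) {
  tm <- build_transition(hg, trans_cfg)
  p0 <- make_seed_vector(seeds, hg)
  res <- rwr(tm, p0, walk_cfg)
  list(ranking = rank_genes(res, hg, exclude = exclude), walk = res)
}
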