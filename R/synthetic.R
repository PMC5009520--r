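#' Specification for a synthetic three-layer benchmark network
#'
#' Emulates, at toy scale, the structure of the real inputs: two disease
#' phenotype-similarity layers each containing a cluster of mutually
#' similar disease nodes (the planted disease), a gene layer containing a
#' densely connected functional module (the planted disease genes),
#' bipartite association links between the planted diseases and planted
#' genes, cross-vocabulary maps joining the planted disease clusters of
#' the two phenotype layers, and uniform random background edges and
#' links with weights in `weight_range`.
#'
#' @param n_genes,n_p1,n_p2 layer sizes.
#' @param module_genes,module_diseases_p1,module_diseases_p2 planted
#'   cluster sizes (the lexicographically first ids of each layer).
#' @param p_intra_module edge probability within a planted cluster; must
#'   exceed `p_background`.
#' @param p_background edge probability for all other intra-layer pairs.
#' @param bipartite_link_rate probability of a link between a planted
#'   gene and a planted disease node (and between planted disease nodes
#'   across the two phenotype layers).
#' @param cross_background_rate probability of a background bipartite
#'   link between any non-planted cross-layer pair.
#' @param weight_range interval in `(0, 1]` for uniform edge weights,
#'   mirroring similarity/confidence scores.
#' @param rng_seed integer; the generated graph is a deterministic
#'   function of the spec including this seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200L, n_p1 = 40L, n_p2 = 40L,
                           module_genes = 10L, module_diseases_p1 = 5L,
                           module_diseases_p2 = 5L,
                           p_intra_module = 0.6, p_background = 0.02,
                           bipartite_link_rate = 0.5,
                           cross_background_rate = 0.002,
                           weight_range = c(0.1, 1),
                           rng_seed = 1L) {
  stopifnot(n_genes >= 1, n_p1 >= 1, n_p2 >= 1,
            module_genes >= 1, module_diseases_p1 >= 1,
            module_diseases_p2 >= 1,
            p_intra_module >= 0, p_intra_module <= 1,
            p_background >= 0, p_background <= 1,
            p_intra_module > p_background,
            bipartite_link_rate >= 0, bipartite_link_rate <= 1,
            cross_background_rate >= 0, cross_background_rate <= 1,
            length(weight_range) == 2L, weight_range[1] > 0,
            weight_range[2] <= 1, weight_range[1] <= weight_range[2])
  if (module_genes > n_genes || module_diseases_p1 > n_p1 ||
      module_diseases_p2 > n_p2)
    stop("planted module size exceeds layer size", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_spec")
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

# independent-edge undirected graph with a dense planted block
sample_layer <- function(ids, planted, p_in, p_bg, wr, layer) {
  n <- length(ids)
  if (n < 2L)
    return(weighted_network(nodes = ids, layer = layer))
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  in_mod <- ids[pair[, 1]] %in% planted & ids[pair[, 2]] %in% planted
  p <- ifelse(in_mod, p_in, p_bg)
  keep <- runif(nrow(pair)) < p
  weighted_network(
    nodes = ids,
    edges = data.frame(from = ids[pair[keep, 1]], to = ids[pair[keep, 2]],
                       weight = runif(sum(keep), wr[1], wr[2]),
                       stringsAsFactors = FALSE),
    layer = layer)
}

# bipartite links: planted x planted pairs at rate_planted, all other
# pairs at rate_bg
sample_links <- function(ids_a, planted_a, ids_b, planted_b,
                         rate_planted, rate_bg, wr, layer_a, layer_b) {
  grid <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  both <- grid$a %in% planted_a & grid$b %in% planted_b
  keep <- runif(nrow(grid)) < ifelse(both, rate_planted, rate_bg)
  bipartite_links(
    data.frame(a = grid$a[keep], b = grid$b[keep],
               weight = runif(sum(keep), wr[1], wr[2]),
               stringsAsFactors = FALSE),
    layer_a = layer_a, layer_b = layer_b)
}

#' Generate a synthetic heterogeneous graph with planted structure
#'
#' Fully reproducible from `spec$rng_seed`; the global RNG state is left
#' untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `graph` (a [het_graph][assemble()]), `truth` (list
#'   of planted `genes`, `p1`, `p2` id vectors), and `seeds` (a
#'   [seed_set()] of the planted genes and disease nodes, the natural
#'   seeding for recovery experiments).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$rng_seed, {
    genes <- pad_ids("g", spec$n_genes)
    d1 <- pad_ids("d", spec$n_p1)
    d2 <- pad_ids("h", spec$n_p2)
    pg <- genes[seq_len(spec$module_genes)]
    pd1 <- d1[seq_len(spec$module_diseases_p1)]
    pd2 <- d2[seq_len(spec$module_diseases_p2)]
    wr <- spec$weight_range
    g_net <- sample_layer(genes, pg, spec$p_intra_module,
                          spec$p_background, wr, "G")
    p1_net <- sample_layer(d1, pd1, spec$p_intra_module,
                           spec$p_background, wr, "P1")
    p2_net <- sample_layer(d2, pd2, spec$p_intra_module,
                           spec$p_background, wr, "P2")
    gp1 <- sample_links(genes, pg, d1, pd1, spec$bipartite_link_rate,
                        spec$cross_background_rate, wr, "G", "P1")
    gp2 <- sample_links(genes, pg, d2, pd2, spec$bipartite_link_rate,
                        spec$cross_background_rate, wr, "G", "P2")
    p12 <- sample_links(d1, pd1, d2, pd2, spec$bipartite_link_rate,
                        spec$cross_background_rate, wr, "P1", "P2")
    hg <- assemble(list(g_net, p1_net, p2_net), list(gp1, gp2, p12))
    list(graph = hg,
         truth = list(genes = pg, p1 = pd1, p2 = pd2),
         seeds = seed_set(gene_seeds = pg, disease_seeds_p1 = pd1,
                          disease_seeds_p2 = pd2))
  })
}

#' Write a synthetic graph as a fixture directory
#'
#' Writes the six edge-list/link TSVs plus a seed file and a planted-truth
#' file, so downstream commands consume synthetic data exactly like real
#' data.
#'
#' @param gen a [generate_synthetic()] result.
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(dir, ...)
  paths <- c(gene_network = f("gene_network.tsv"),
             p1_network = f("p1_network.tsv"),
             p2_network = f("p2_network.tsv"),
             links_g_p1 = f("links_g_p1.tsv"),
             links_g_p2 = f("links_g_p2.tsv"),
             links_p1_p2 = f("links_p1_p2.tsv"),
             seeds = f("seeds.tsv"),
             truth = f("truth.tsv"))
  hg <- gen$graph
  write_edge_list(hg$networks$G, paths["gene_network"])
  write_edge_list(hg$networks$P1, paths["p1_network"])
  write_edge_list(hg$networks$P2, paths["p2_network"])
  write_edge_list(hg$bipartite[["G:P1"]], paths["links_g_p1"])
  write_edge_list(hg$bipartite[["G:P2"]], paths["links_g_p2"])
  write_edge_list(hg$bipartite[["P1:P2"]], paths["links_p1_p2"])
  seeds_df <- rbind(
    data.frame(layer = "G", id = gen$seeds$gene_seeds),
    data.frame(layer = "P1", id = gen$seeds$disease_seeds_p1),
    data.frame(layer = "P2", id = gen$seeds$disease_seeds_p2))
  write.table(seeds_df, paths["seeds"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  truth_df <- rbind(
    data.frame(layer = "G", id = gen$truth$genes),
    data.frame(layer = "P1", id = gen$truth$p1),
    data.frame(layer = "P2", id = gen$truth$p2))
  write.table(truth_df, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
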