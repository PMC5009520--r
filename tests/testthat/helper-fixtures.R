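# write lines to a self-cleaning temp file
tmp_tsv <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(lines, path)
  path
}

# four-node graph used across modules: two genes, one disease per layer,
# g1 linked to both disease nodes, the diseases mapped to each other
tiny_hg <- function() {
  g <- weighted_network(edges = data.frame(from = "g1", to = "g2", weight = 1),
                        layer = "G")
  p1 <- weighted_network(nodes = "d1", layer = "P1")
  p2 <- weighted_network(nodes = "h1", layer = "P2")
  assemble(list(g, p1, p2),
           list(bipartite_links(data.frame(a = "g1", b = "d1", weight = 1),
                                "G", "P1"),
                bipartite_links(data.frame(a = "g1", b = "h1", weight = 1),
                                "G", "P2"),
                bipartite_links(data.frame(a = "d1", b = "h1", weight = 1),
                                "P1", "P2")))
}

# small random heterogeneous graph for property tests
small_gen <- function(seed, ...) {
  generate_synthetic(synthetic_spec(n_genes = 60L, n_p1 = 15L, n_p2 = 15L,
                                    module_genes = 6L,
                                    module_diseases_p1 = 3L,
                                    module_diseases_p2 = 3L,
                                    rng_seed = seed, ...))
}

# score vector that puts the given genes (in order) at the top
scores_for <- function(hg, top_genes) {
  p <- numeric(n_nodes(hg))
  gpos <- layer_positions(hg, "G")
  ids <- hg$order$id[gpos]
  p[gpos] <- seq(0.5, 0.1, length.out = length(gpos))
  p[gpos[match(top_genes, ids)]] <- 1 + rev(seq_along(top_genes))
  p / sum(p)
}
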