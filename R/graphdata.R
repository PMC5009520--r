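LAYERS <- c("G", "P1", "P2")

check_layer <- function(layer) {
  if (!is.character(layer) || length(layer) != 1L || !layer %in% LAYERS)
    stop("layer must be one of ", paste(LAYERS, collapse = ", "), call. = FALSE)
  layer
}

#' Construct a weighted undirected network
#'
#' A single layer of the heterogeneous graph: either the gene functional
#' network (layer `"G"`) or one of the two disease-phenotype similarity
#' networks (`"P1"` for the manifestation-based disease network, `"P2"` for
#' the ontology-based one). Edges are undirected, unique per unordered node
#' pair, carry strictly positive weights, and self-loops are rejected.
#' Isolated nodes are permitted.
#'
#' @param nodes character vector of node identifiers (duplicates collapsed).
#' @param edges data.frame with columns `from`, `to`, `weight`; endpoints
#'   not listed in `nodes` are added automatically.
#' @param layer one of `"G"`, `"P1"`, `"P2"`.
#' @return an object of class `weighted_network`.
#' @export
weighted_network <- function(nodes = character(), edges = NULL, layer) {
  check_layer(layer)
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$from == edges$to))
    stop("self-loops are not allowed in layer ", layer, call. = FALSE)
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
    stop("edge weights must be finite and > 0", call. = FALSE)
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key))
    stop("duplicate edge (in either orientation): ",
         key[duplicated(key)][1L], call. = FALSE)
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(list(layer = layer, nodes = nodes,
                 edges = edges[order(key), , drop = FALSE]),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network layer=%s: %d nodes, %d edges>\n",
              x$layer, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Construct a set of bipartite links between two layers
#'
#' Bipartite links join nodes of two different layers: disease-gene
#' associations (gene layer to either phenotype layer) or cross-vocabulary
#' disease identifier maps (between the two phenotype layers). Weights
#' default to 1 (uniform association strength).
#'
#' @param links data.frame with columns `a`, `b` and optional `weight`.
#' @param layer_a,layer_b distinct layer labels; `a` ids live in `layer_a`.
#' @return an object of class `bipartite_links`.
#' @export
bipartite_links <- function(links = NULL, layer_a, layer_b) {
  check_layer(layer_a); check_layer(layer_b)
  if (layer_a == layer_b)
    stop("bipartite links require two distinct layers", call. = FALSE)
  if (is.null(links))
    links <- data.frame(a = character(), b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  if (is.null(links$weight)) links$weight <- rep(1.0, nrow(links))
  links$a <- as.character(links$a)
  links$b <- as.character(links$b)
  links$weight <- as.numeric(links$weight)
  if (any(!is.finite(links$weight)) || any(links$weight <= 0))
    stop("bipartite weights must be finite and > 0", call. = FALSE)
  key <- paste(links$a, links$b)
  if (anyDuplicated(key))
    stop("duplicate bipartite pair: ", key[duplicated(key)][1L], call. = FALSE)
  structure(list(layer_a = layer_a, layer_b = layer_b,
                 links = links[order(key), , drop = FALSE]),
            class = "bipartite_links")
}

#' @export
print.bipartite_links <- function(x, ...) {
  cat(sprintf("<bipartite_links %s-%s: %d links>\n",
              x$layer_a, x$layer_b, nrow(x$links)))
  invisible(x)
}

parse_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

parse_edge_fields <- function(lines, lineno, what, allow_singleton = FALSE) {
  n <- length(lines)
  from <- character(n); to <- character(n); weight <- numeric(n)
  singletons <- character()
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1L) f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (allow_singleton && length(f) == 1L && nzchar(f[1])) {
      singletons <- c(singletons, f[1])
      from[i] <- NA
      next
    }
    if (length(f) < 2L || length(f) > 3L || any(!nzchar(f[1:2])))
      stop(sprintf("%s: malformed line %d: '%s'", what, lineno[i], lines[i]),
           call. = FALSE)
    w <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3])) else 1.0
    if (is.na(w)) {
      # allow a single header line with a non-numeric third field
      if (i == 1L) { from[i] <- NA; next }
      stop(sprintf("%s: non-numeric weight at line %d: '%s'",
                   what, lineno[i], lines[i]), call. = FALSE)
    }
    from[i] <- f[1]; to[i] <- f[2]; weight[i] <- w
  }
  ok <- !is.na(from)
  structure(data.frame(from = from[ok], to = to[ok], weight = weight[ok],
                       stringsAsFactors = FALSE),
            singletons = singletons)
}

#' Read a weighted edge list from a TSV file
#'
#' Format: `node_a<TAB>node_b<TAB>weight`, weight optional (default 1).
#' Lines starting with `#` and blank lines are ignored; a single header
#' line is detected by a non-numeric third field and skipped. A line
#' holding a single id declares an isolated node, so networks with
#' unconnected nodes round-trip exactly. A pair appearing twice in either
#' orientation, a self-loop, or a non-positive weight is an error.
#'
#' @param path file path.
#' @param layer layer label for the resulting network.
#' @return a [weighted_network()].
#' @export
read_edge_list <- function(path, layer) {
  check_layer(layer)
  p <- parse_tsv_lines(path)
  df <- parse_edge_fields(p$lines, p$lineno, path, allow_singleton = TRUE)
  weighted_network(nodes = attr(df, "singletons"), edges = df, layer = layer)
}

#' Read bipartite links from a TSV file
#'
#' Same format as [read_edge_list()]: `id_a<TAB>id_b<TAB>weight`, weight
#' optional (default 1, the convention for curated disease-gene
#' association lists).
#'
#' @param path file path.
#' @param layer_a,layer_b layers of the first and second id column.
#' @return a [bipartite_links()].
#' @export
read_bipartite <- function(path, layer_a, layer_b) {
  p <- parse_tsv_lines(path)
  df <- parse_edge_fields(p$lines, p$lineno, path)
  bipartite_links(links = data.frame(a = df$from, b = df$to,
                                     weight = df$weight,
                                     stringsAsFactors = FALSE),
                  layer_a = layer_a, layer_b = layer_b)
}

#' Write a network or link set as edge-list TSV
#'
#' Isolated nodes of a `weighted_network` are written as single-field
#' lines so the node set survives the round trip.
#'
#' @param x a `weighted_network` or `bipartite_links`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "weighted_network")) {
    lines <- sprintf("%s\t%s\t%s", x$edges$from, x$edges$to,
                     format(x$edges$weight, digits = 17, trim = TRUE,
                            scientific = FALSE))
    isolated <- setdiff(x$nodes, c(x$edges$from, x$edges$to))
    writeLines(c(lines, isolated), path)
  } else if (inherits(x, "bipartite_links")) {
    writeLines(sprintf("%s\t%s\t%s", x$links$a, x$links$b,
                       format(x$links$weight, digits = 17, trim = TRUE,
                              scientific = FALSE)), path)
  } else stop("unsupported object", call. = FALSE)
  invisible(path)
}

#' Assemble the three-layer heterogeneous graph
#'
#' Combines the gene network, the two phenotype networks, and the three
#' bipartite link sets into one graph with a fixed global node ordering:
#' gene block first, then the two phenotype blocks, ids sorted
#' lexicographically (C collation) within each block. The ordering is what
#' makes transition matrices, score vectors, and ranks reproducible across
#' runs and input file permutations.
#'
#' @param networks list of three `weighted_network`s, one per layer.
#' @param bipartite list of three `bipartite_links` covering the pairs
#'   G-P1, G-P2 and P1-P2 (any order, any orientation).
#' @return an object of class `het_graph` with elements `networks` (named
#'   list by layer), `bipartite` (named `"G:P1"`, `"G:P2"`, `"P1:P2"`),
#'   `order` (data.frame of `layer`, `id` in global order) and `index`
#'   (named integer vector id -> global position, names `layer:id`).
#' @export
assemble <- function(networks, bipartite) {
  nets <- list()
  for (nw in networks) {
    if (!inherits(nw, "weighted_network")) stop("expected weighted_network")
    if (!is.null(nets[[nw$layer]])) stop("two networks for layer ", nw$layer)
    nets[[nw$layer]] <- nw
  }
  if (!setequal(names(nets), LAYERS))
    stop("need exactly one network per layer G, P1, P2", call. = FALSE)
  bps <- list()
  for (bp in bipartite) {
    if (!inherits(bp, "bipartite_links")) stop("expected bipartite_links")
    # canonical orientation: G before P1 before P2
    if (match(bp$layer_a, LAYERS) > match(bp$layer_b, LAYERS))
      bp <- bipartite_links(
        data.frame(a = bp$links$b, b = bp$links$a, weight = bp$links$weight),
        layer_a = bp$layer_b, layer_b = bp$layer_a)
    key <- paste(bp$layer_a, bp$layer_b, sep = ":")
    if (!is.null(bps[[key]])) stop("two link sets for pair ", key)
    bps[[key]] <- bp
  }
  for (key in c("G:P1", "G:P2", "P1:P2"))
    if (is.null(bps[[key]]))
      bps[[key]] <- bipartite_links(layer_a = sub(":.*", "", key),
                                    layer_b = sub(".*:", "", key))
  # dangling endpoint check
  for (key in names(bps)) {
    bp <- bps[[key]]
    miss_a <- setdiff(bp$links$a, nets[[bp$layer_a]]$nodes)
    miss_b <- setdiff(bp$links$b, nets[[bp$layer_b]]$nodes)
    if (length(miss_a))
      stop(sprintf("bipartite endpoint (%s, %s) not found",
                   bp$layer_a, miss_a[1L]), call. = FALSE)
    if (length(miss_b))
      stop(sprintf("bipartite endpoint (%s, %s) not found",
                   bp$layer_b, miss_b[1L]), call. = FALSE)
  }
  ord <- do.call(rbind, lapply(LAYERS, function(l) {
    ids <- sort_c(nets[[l]]$nodes)
    if (!length(ids)) return(NULL)
    data.frame(layer = l, id = ids, stringsAsFactors = FALSE)
  }))
  if (is.null(ord))
    ord <- data.frame(layer = character(), id = character(),
                      stringsAsFactors = FALSE)
  index <- seq_len(nrow(ord))
  names(index) <- paste(ord$layer, ord$id, sep = ":")
  structure(list(networks = nets[LAYERS], bipartite = bps[c("G:P1", "G:P2", "P1:P2")],
                 order = ord, index = index),
            class = "het_graph")
}

# locale-independent lexicographic sort
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

#' @export
print.het_graph <- function(x, ...) {
  sizes <- vapply(x$networks, function(n) length(n$nodes), integer(1))
  cat(sprintf("<het_graph: |G|=%d |P1|=%d |P2|=%d, %d total nodes>\n",
              sizes["G"], sizes["P1"], sizes["P2"], nrow(x$order)))
  invisible(x)
}

#' Number of nodes in a heterogeneous graph
#' @param hg a `het_graph`.
#' @return integer node count.
#' @export
n_nodes <- function(hg) nrow(hg$order)

#' Global positions of a layer's nodes
#' @param hg a `het_graph`.
#' @param layer layer label.
#' @return integer vector of positions in the global order.
#' @export
layer_positions <- function(hg, layer) {
  check_layer(layer)
  which(hg$order$layer == layer)
}

node_position <- function(hg, layer, ids) {
  pos <- hg$index[paste(layer, ids, sep = ":")]
  if (anyNA(pos))
    stop(sprintf("unknown node (%s, %s)", layer, ids[is.na(pos)][1L]),
         call. = FALSE)
  unname(pos)
}
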