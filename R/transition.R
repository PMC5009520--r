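#' Transition-matrix configuration
#'
#' @param lambda inter-layer jump probability in `[0, 1]`. At each step a
#'   walker on a node with both intra-layer edges and bipartite links
#'   leaves its layer with total probability `lambda`, split equally among
#'   the linked foreign layers. `lambda = 0` confines walkers with
#'   intra-layer edges to their own layer.
#' @return an object of class `transition_config`.
#' @export
transition_config <- function(lambda = 0.5) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L,
            lambda >= 0, lambda <= 1)
  structure(list(lambda = lambda), class = "transition_config")
}

#' Row-normalize a nonnegative matrix
#'
#' Divides every row with positive sum by its sum; all-zero rows are left
#' all-zero (callers that need exact stochasticity repair them with
#' self-loops, as [build_transition()] does).
#'
#' @param adjacency square nonnegative matrix, dense or `Matrix` sparse.
#' @return matrix of the same storage class with row sums in `{0, 1}`.
#' @export
row_normalize <- function(adjacency) {
  if (nrow(adjacency) != ncol(adjacency)) stop("matrix must be square")
  if (any(adjacency < 0)) stop("negative entries are not allowed")
  rs <- Matrix::rowSums(adjacency)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  if (is(adjacency, "Matrix"))
    Matrix::Diagonal(x = scale) %*% adjacency
  else
    adjacency * scale
}

intra_adjacency <- function(hg) {
  n <- n_nodes(hg)
  i <- integer(); j <- integer(); x <- numeric()
  for (l in LAYERS) {
    ed <- hg$networks[[l]]$edges
    if (!nrow(ed)) next
    a <- node_position(hg, l, ed$from)
    b <- node_position(hg, l, ed$to)
    i <- c(i, a, b); j <- c(j, b, a); x <- c(x, ed$weight, ed$weight)
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

cross_adjacency <- function(hg) {
  n <- n_nodes(hg)
  i <- integer(); j <- integer(); x <- numeric()
  for (bp in hg$bipartite) {
    lk <- bp$links
    if (!nrow(lk)) next
    a <- node_position(hg, bp$layer_a, lk$a)
    b <- node_position(hg, bp$layer_b, lk$b)
    i <- c(i, a, b); j <- c(j, b, a); x <- c(x, lk$weight, lk$weight)
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' Build the block row-stochastic transition matrix
#'
#' Assembles the full transition matrix over the global node order: three
#' normalized intra-layer blocks on the diagonal and six normalized
#' bipartite blocks off the diagonal. For node `i` let `f(i)` be the
#' number of foreign layers it reaches through at least one bipartite
#' link and `intra(i)` whether it has any intra-layer edge. Row `i` is:
#'
#' * `intra` and `f = 0`: all mass over intra-layer neighbours,
#'   proportional to edge weight;
#' * `intra` and `f >= 1`: mass `1 - lambda` over intra-layer neighbours
#'   and `lambda / f` into each linked foreign layer, proportional to
#'   bipartite weight within the layer;
#' * no intra edge and `f >= 1`: mass `1 / f` per linked foreign layer;
#' * fully isolated: a self-loop of mass 1, so the matrix is exactly
#'   stochastic and probability mass is conserved.
#'
#' @param hg an assembled [het_graph][assemble()].
#' @param cfg a [transition_config()].
#' @return an object of class `transition_matrix`: list with the sparse
#'   row-stochastic `matrix` (`dgCMatrix`), its transpose `t_matrix`
#'   (precomputed for propagation), the `lambda` used, and the graph
#'   `order`.
#' @export
build_transition <- function(hg, cfg = transition_config()) {
  stopifnot(inherits(hg, "het_graph"), inherits(cfg, "transition_config"))
  lambda <- cfg$lambda
  n <- n_nodes(hg)
  if (n == 0L) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0, 0))
    return(structure(list(matrix = m, t_matrix = m, lambda = lambda,
                          order = hg$order), class = "transition_matrix"))
  }
  W <- intra_adjacency(hg)
  B <- cross_adjacency(hg)
  d_intra <- Matrix::rowSums(W)
  # per-row bipartite mass into each (column) layer block
  cs <- vapply(LAYERS, function(l) {
    cols <- layer_positions(hg, l)
    if (!length(cols)) return(numeric(n))
    Matrix::rowSums(B[, cols, drop = FALSE])
  }, numeric(n))
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)  # n == 1 edge case
  f <- rowSums(cs > 0)
  has_intra <- d_intra > 0

  intra_coef <- numeric(n)
  intra_coef[has_intra & f == 0] <- 1
  intra_coef[has_intra & f >= 1] <- 1 - lambda
  intra_scale <- ifelse(has_intra, intra_coef / d_intra, 0)

  cross_coef <- numeric(n)                  # mass per linked foreign layer
  cross_coef[has_intra & f >= 1] <- lambda / pmax(f[has_intra & f >= 1], 1)
  cross_coef[!has_intra & f >= 1] <- 1 / f[!has_intra & f >= 1]

  M <- Matrix::Diagonal(x = intra_scale) %*% W
  Bt <- as(B, "TsparseMatrix")
  if (length(Bt@x)) {
    ri <- Bt@i + 1L; cj <- Bt@j + 1L
    col_layer <- match(hg$order$layer[cj], LAYERS)
    denom <- cs[cbind(ri, col_layer)]
    xs <- Bt@x * cross_coef[ri] / denom
    M <- M + Matrix::sparseMatrix(i = ri, j = cj, x = xs, dims = c(n, n))
  }
  isolated <- which(!has_intra & f == 0)
  if (length(isolated))
    M <- M + Matrix::sparseMatrix(i = isolated, j = isolated,
                                  x = rep(1, length(isolated)),
                                  dims = c(n, n))
  M <- Matrix::drop0(as(M, "CsparseMatrix"))
  structure(list(matrix = M, t_matrix = Matrix::t(M), lambda = lambda,
                 order = hg$order),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix: %d x %d, %d nonzeros, lambda=%g>\n",
              nrow(x$matrix), ncol(x$matrix),
              length(x$matrix@x), x$lambda))
  invisible(x)
}

#' Extract one block of a transition matrix
#'
#' @param tm a [build_transition()] result.
#' @param layer_from,layer_to row and column layer of the block.
#' @return sparse sub-matrix of rows in `layer_from`, columns in `layer_to`.
#' @export
transition_block <- function(tm, layer_from, layer_to) {
  check_layer(layer_from); check_layer(layer_to)
  ri <- which(tm$order$layer == layer_from)
  ci <- which(tm$order$layer == layer_to)
  tm$matrix[ri, ci, drop = FALSE]
}

#' Dump a transition matrix in MatrixMarket format
#'
#' @param tm a `transition_matrix`.
#' @param path output `.mtx` file path.
#' @return `path`, invisibly.
#' @export
write_transition_mtx <- function(tm, path) {
  Matrix::writeMM(tm$matrix, path)
  invisible(path)
}
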