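#' Random-walk configuration
#'
#' @param gamma restart probability in `(0, 1]`: at each step the walker
#'   returns to the seed distribution with probability `gamma`. Larger
#'   values keep scores local to the seeds; smaller values diffuse
#'   further through the network.
#' @param tol L1 convergence tolerance on successive score vectors.
#' @param max_iter hard iteration cap.
#' @return an object of class `walk_config`.
#' @export
walk_config <- function(gamma = 0.7, tol = 1e-10, max_iter = 1000L) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0, gamma <= 1,
            is.numeric(tol), tol > 0, max_iter >= 1)
  structure(list(gamma = gamma, tol = tol, max_iter = as.integer(max_iter)),
            class = "walk_config")
}

as_t_matrix <- function(M) {
  if (inherits(M, "transition_matrix")) M$t_matrix
  else Matrix::t(as(M, "CsparseMatrix"))
}

check_p0 <- function(p0, n) {
  p0 <- as.numeric(p0)
  if (length(p0) != n)
    stop(sprintf("p0 has length %d, expected %d", length(p0), n))
  if (any(p0 < 0)) stop("p0 must be nonnegative")
  s <- sum(p0)
  if (s == 0) stop("p0 is all zero: no seeds", call. = FALSE)
  if (abs(s - 1) > 1e-9) stop("p0 must sum to 1")
  p0
}

#' Random walk with restart
#'
#' Iterates `p_{k+1} = (1 - gamma) * t(M) %*% p_k + gamma * p_0` from
#' `p_0` until the L1 difference of successive iterates falls below
#' `cfg$tol` or `cfg$max_iter` is reached. Because `M` is row-stochastic
#' (isolated nodes carry self-loops), every iterate sums to 1 and the map
#' is a contraction with factor at most `1 - gamma`, so the residual is
#' non-increasing and convergence is geometric.
#'
#' @param M a [build_transition()] result (or a row-stochastic matrix).
#' @param p0 seed distribution over the global node order; nonnegative,
#'   summing to 1 (see [make_seed_vector()]).
#' @param cfg a [walk_config()].
#' @return an object of class `rwr_result`: list with `p` (the stationary
#'   score vector), `iterations`, `residual` (final L1 change), and
#'   `converged` (logical; `FALSE` raises a warning).
#' @export
rwr <- function(M, p0, cfg = walk_config()) {
  stopifnot(inherits(cfg, "walk_config"))
  Mt <- as_t_matrix(M)
  p0 <- check_p0(p0, nrow(Mt))
  gamma <- cfg$gamma
  p <- p0
  res <- Inf
  iter <- 0L
  while (iter < cfg$max_iter) {
    p_next <- as.numeric((1 - gamma) * (Mt %*% p)) + gamma * p0
    res <- sum(abs(p_next - p))
    p <- p_next
    iter <- iter + 1L
    if (res < cfg$tol) break
  }
  converged <- res < cfg$tol
  if (!converged)
    warning(sprintf("random walk did not converge in %d iterations (residual %.3g)",
                    iter, res))
  structure(list(p = p, iterations = iter, residual = res,
                 converged = converged),
            class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf("<rwr_result: %d nodes, %d iterations, residual %.3g%s>\n",
              length(x$p), x$iterations, x$residual,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Exact stationary scores by direct linear solve
#'
#' Solves `p = gamma * (I - (1 - gamma) * t(M))^{-1} p_0`, the closed form
#' of the random-walk fixed point. Dense solve; intended as the
#' brute-force oracle for [rwr()] on small graphs.
#'
#' @param M a `transition_matrix` (or row-stochastic matrix).
#' @param p0 seed distribution (sums to 1).
#' @param gamma restart probability in `(0, 1]`.
#' @param dense_cap refuse graphs larger than this many nodes.
#' @return numeric score vector.
#' @export
rwr_exact <- function(M, p0, gamma = 0.7, dense_cap = 2000L) {
  Mt <- as_t_matrix(M)
  n <- nrow(Mt)
  if (n > dense_cap)
    stop(sprintf("graph has %d nodes > dense_cap %d; use rwr()", n, dense_cap))
  p0 <- check_p0(p0, n)
  stopifnot(gamma > 0, gamma <= 1)
  A <- diag(n) - (1 - gamma) * as.matrix(Mt)
  as.numeric(gamma * solve(A, p0))
}
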