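#' Undirected gene network
#'
#' @param edges data.frame with two gene columns and an optional numeric
#'   `weight` third column (default weight 1). Edges are undirected; duplicate
#'   rows and reversed duplicates collapse (weights of duplicates are not
#'   summed, the first is kept). Self-loops are permitted.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the genes appearing in `edges`. Extra nodes are allowed (isolated).
#' @return object of class `gene_network`: list with `nodes` (character) and
#'   `edges` (data.frame a, b, weight).
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2L)
    stop("edges must be a data.frame with >= 2 columns")
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3]]) else rep(1, length(a))
  if (anyNA(w)) stop("non-numeric edge weight")
  if (any(w < 0)) stop("invalid input: negative edge weight")
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste0(lo, "\r", hi))
  ed <- data.frame(a = lo[keep], b = hi[keep], weight = w[keep])
  if (is.null(nodes)) nodes <- sort(unique(c(ed$a, ed$b)))
  else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node identifiers")
    miss <- setdiff(unique(c(ed$a, ed$b)), nodes)
    if (length(miss))
      stop("edge endpoint(s) not in node list: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = ed), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Column-stochastic transition matrix of a network
#'
#' Builds the column-normalized (weighted) adjacency matrix used by the
#' random walk: entry (i, j) is the probability of stepping from gene j to
#' gene i, `w(i,j) / sum_k w(k,j)`. Columns of degree-0 (dangling) nodes are
#' all zero and flagged; the walk handles them by restarting from the seed
#' distribution so that probability mass is conserved.
#'
#' @param network a [gene_network()].
#' @return sparse `dgCMatrix` with dimnames = nodes; attribute `dangling` is
#'   a logical vector marking zero-degree columns.
#' @export
transition_matrix <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  n <- length(network$nodes)
  if (n == 0L) stop("empty network")
  idx <- stats::setNames(seq_len(n), network$nodes)
  ed <- network$edges
  i <- idx[ed$a]; j <- idx[ed$b]
  loops <- i == j
  A <- Matrix::sparseMatrix(
    i = c(i[!loops], j[!loops], i[loops]),
    j = c(j[!loops], i[!loops], j[loops]),
    x = c(ed$weight[!loops], ed$weight[!loops], ed$weight[loops]),
    dims = c(n, n), dimnames = list(network$nodes, network$nodes))
  colsum <- Matrix::colSums(A)
  dangling <- colsum == 0
  scale <- ifelse(dangling, 0, 1 / pmax(colsum, .Machine$double.xmin))
  T <- A %*% Matrix::Diagonal(n, scale)
  dimnames(T) <- list(network$nodes, network$nodes)
  attr(T, "dangling") <- stats::setNames(as.vector(dangling), network$nodes)
  T
}

# initial probability vector: equal mass on in-network seeds
.seed_vector <- function(seeds, nodes) {
  seeds <- unique(as.character(seeds))
  inn <- intersect(seeds, nodes)
  if (!length(inn))
    stop("no seed gene is in the network; off-network seeds: ",
         paste(utils::head(setdiff(seeds, nodes), 10), collapse = ", "))
  off <- setdiff(seeds, nodes)
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[inn] <- 1 / length(inn)
  attr(p0, "off_network_seeds") <- off
  p0
}

#' Random walk with restart over a gene network
#'
#' Iterates `p_{t+1} = (1 - gamma) T p_t + gamma p_0` from the seed
#' distribution `p_0` (equal mass on each in-network seed) until the change
#' between successive iterates drops below `tol` or `max_iter` is reached.
#' The stationary vector scores every gene's proximity to the seed set and is
#' interpreted as its functional association with the fusion. Mass that steps
#' onto a dangling (degree-0) node is redistributed over the seed
#' distribution, keeping the iterates probability vectors. Deterministic
#' despite the name.
#'
#' @param seeds character vector of seed genes (at least one in-network);
#'   off-network seeds are dropped and reported via the result attribute.
#' @param network a [gene_network()].
#' @param gamma restart probability in (0, 1]; default 0.7, the customary
#'   value for gene-prioritization walks.
#' @param tol convergence threshold on the change between iterates; default
#'   `1e-30` (usually unreachable in double precision, so `max_iter`
#'   terminates the loop with a warning).
#' @param max_iter iteration cap, default 10000.
#' @param norm which norm measures the change: `"L1"` (default), `"L2"` or
#'   `"max"`.
#' @return object of class `score_vector`: list with `scores` (named numeric
#'   over all network genes, sums to 1), `seeds` (in-network seeds),
#'   `off_network_seeds`, `iterations`, `converged`, `gamma`.
#' @export
random_walk_restart <- function(seeds, network, gamma = 0.7, tol = 1e-30,
                                max_iter = 10000L, norm = c("L1", "L2", "max")) {
  stopifnot(inherits(network, "gene_network"))
  norm <- match.arg(norm)
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must be in (0, 1]")
  if (tol <= 0) stop("tolerance must be > 0")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  T <- transition_matrix(network)
  dang <- attr(T, "dangling")
  p0 <- .seed_vector(seeds, network$nodes)
  normf <- switch(norm,
                  L1 = function(v) sum(abs(v)),
                  L2 = function(v) sqrt(sum(v^2)),
                  max = function(v) max(abs(v)))
  p <- p0
  it <- 0L; delta <- Inf; stall <- 0L
  while (it < max_iter) {
    step <- as.vector(T %*% p)
    lost <- sum(p[dang])           # mass sitting on dangling columns
    pn <- (1 - gamma) * (step + lost * p0) + gamma * p0
    d_new <- normf(pn - p)
    # once the change stops shrinking we are at the double-precision fixed
    # point; tolerances below ~1e-16 (including the 1e-30 default) are not
    # reachable, so stop rather than spin to max_iter
    stall <- if (d_new >= delta) stall + 1L else 0L
    delta <- d_new
    p <- pn
    it <- it + 1L
    if (delta < tol || stall >= 10L) break
  }
  converged <- delta < tol
  if (!converged)
    warning(sprintf(
      "random walk stopped after %d iterations at the numerical floor (%s change %.3e > tol %.3e); result is the double-precision fixed point",
      it, norm, delta, tol))
  structure(
    list(scores = stats::setNames(as.vector(p), network$nodes),
         seeds = names(p0)[p0 > 0],
         off_network_seeds = attr(p0, "off_network_seeds"),
         iterations = it, converged = converged, gamma = gamma),
    class = "score_vector")
}

#' Exact stationary scores by direct linear solve
#'
#' Solves `p = gamma p0 + (1 - gamma) (T + p0 d^T) p` for the walk's fixed
#' point, where `d` marks dangling columns. Dense solve, intended as an
#' independent check of [random_walk_restart()] on small networks (n up to a
#' couple of thousand).
#'
#' @inheritParams random_walk_restart
#' @return a `score_vector` (with `iterations = NA`).
#' @export
solve_stationary_exact <- function(seeds, network, gamma = 0.7) {
  stopifnot(inherits(network, "gene_network"))
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must be in (0, 1]")
  n <- length(network$nodes)
  if (n > 4000) stop("network too large for dense solve")
  Ts <- transition_matrix(network)
  dang <- attr(Ts, "dangling")
  T <- as.matrix(Ts)
  p0 <- .seed_vector(seeds, network$nodes)
  M <- T + outer(as.vector(p0), as.numeric(dang))
  A <- diag(n) - (1 - gamma) * M
  p <- solve(A, gamma * as.vector(p0))
  structure(
    list(scores = stats::setNames(as.vector(p), network$nodes),
         seeds = names(p0)[p0 > 0],
         off_network_seeds = attr(p0, "off_network_seeds"),
         iterations = NA_integer_, converged = TRUE, gamma = gamma),
    class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat("<score_vector> ", length(x$scores), " genes, ", length(x$seeds),
      " seeds, gamma = ", x$gamma, "\n", sep = "")
  top <- utils::head(sort(x$scores, decreasing = TRUE), 5)
  cat("  top:", paste(sprintf("%s=%.3g", names(top), top), collapse = " "),
      "\n")
  invisible(x)
}
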