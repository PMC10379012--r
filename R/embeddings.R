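# Three graph-embedding scales over the weighted sample graph:
#   node      - second-order biased random walks + skip-gram (node2vec style)
#   community - leading eigenvectors of the weighted modularity matrix
#               (SocDim style)
#   global    - k-step transition-matrix factorization (GraRep style)
# Edge weights learned by FLNSA are used throughout (walk biasing, weighted
# degrees, weighted transitions).

.graph_adjacency <- function(graph) {
  if (inherits(graph, "sequence_graph")) graph$adjacency else graph
}

#' Generate second-order biased random walks
#'
#' From every node, `walks_per_node` walks of `walk_length` nodes are
#' sampled. The first step is proportional to edge weight; later steps from
#' node v with predecessor t weight each candidate edge (v, x) by w/p if
#' x = t, w if x is adjacent to t, and w/q otherwise (return and in-out
#' biases). Deterministic for a fixed seed.
#'
#' @param graph A connected `sequence_graph`.
#' @param p Return bias (> 0), default 1.
#' @param q In-out bias (> 0), default 1.
#' @param walks_per_node Walks started per node, default 10.
#' @param walk_length Nodes per walk, default 40.
#' @param seed RNG seed.
#' @return A list of class `walk_corpus`: `walks` (list of integer vectors,
#'   1-based node ids) and the parameters used.
#' @export
generate_biased_walks <- function(graph, p = 1, q = 1, walks_per_node = 10L,
                                  walk_length = 40L, seed = 1L) {
  if (p <= 0 || q <= 0) stop("p and q must be positive")
  stopifnot(walk_length >= 1L, walks_per_node >= 1L)
  A <- .graph_adjacency(graph)
  m <- nrow(A)
  nbrs <- lapply(seq_len(m), function(i) which(A[i, ] > 0))
  wts <- lapply(seq_len(m), function(i) A[i, A[i, ] > 0])
  set.seed(seed)
  walks <- cpp_biased_walks(nbrs, wts, p, q,
                            as.integer(walks_per_node),
                            as.integer(walk_length))
  structure(
    list(walks = walks,
         parameters = list(p = p, q = q, walks_per_node = walks_per_node,
                           walk_length = walk_length, seed = seed)),
    class = "walk_corpus"
  )
}

#' Node-scale embedding: skip-gram over walks
#'
#' Trains skip-gram with negative sampling on the walk corpus, treating
#' walks as sentences and nodes as words, and returns the input-embedding
#' vectors. Single-threaded and deterministic for a fixed seed.
#'
#' @param corpus A `walk_corpus`.
#' @param m Number of nodes in the graph.
#' @param dim Embedding dimension, default 64.
#' @param window Context window half-width, default 5.
#' @param epochs Training epochs, default 5.
#' @param negative Negative samples per positive pair, default 5.
#' @param alpha Initial learning rate, default 0.025.
#' @param seed RNG seed.
#' @return An `embedding_matrix`: m x dim matrix with `scale_tag = "node"`.
#' @export
skipgram_embed <- function(corpus, m, dim = 64L, window = 5L, epochs = 5L,
                           negative = 5L, alpha = 0.025, seed = 1L) {
  stopifnot(inherits(corpus, "walk_corpus"), dim >= 1L,
            length(corpus$walks) > 0L)
  set.seed(seed)
  vec <- cpp_sgns(corpus$walks, as.integer(m), as.integer(dim),
                  as.integer(window), as.integer(epochs),
                  as.integer(negative), alpha)
  new_embedding(vec, "node")
}

#' Community-scale embedding: modularity spectral vectors
#'
#' Builds the weighted modularity matrix `B = A - d d' / (2 Wtot)` (d the
#' weighted degrees, Wtot the total edge weight) and returns the
#' eigenvectors of its k largest eigenvalues. Column signs are fixed by
#' making each column's largest-magnitude entry positive, so results are
#' fully deterministic.
#'
#' @param graph A `sequence_graph`.
#' @param k Number of leading eigenvectors, `1 <= k < m`. Default 16.
#' @return An `embedding_matrix`: m x k, `scale_tag = "community"`.
#' @export
socdim_embed <- function(graph, k = 16L) {
  A <- .graph_adjacency(graph)
  m <- nrow(A)
  if (k < 1L || k >= m) stop("k must satisfy 1 <= k < m")
  B <- modularity_matrix(graph)
  eig <- eigen(B, symmetric = TRUE)
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  vec <- fix_signs(vec)
  new_embedding(vec, "community")
}

#' Weighted modularity matrix of a graph
#'
#' `B = A - d d' / (2 Wtot)` with `2 Wtot = sum(A)`; all entries of B sum
#' to zero.
#'
#' @param graph A `sequence_graph` or adjacency matrix.
#' @return Symmetric m x m matrix.
#' @export
modularity_matrix <- function(graph) {
  A <- .graph_adjacency(graph)
  d <- rowSums(A)
  A - outer(d, d) / sum(A)
}

#' Global-scale embedding: k-step transition factorization
#'
#' Forms the row-stochastic transition matrix `S = D^-1 A`, and for each
#' step t = 1..K computes `S^t`, the positive log-ratio matrix
#' `max(log(S^t_ij / colsum_j) - log(beta), 0)` with baseline
#' `beta = 1/m`, and its truncated SVD; the left singular vectors scaled by
#' the square root of the singular values give `dim_per_step` columns per
#' step, concatenated over the K steps.
#'
#' @param graph A connected `sequence_graph`.
#' @param K Maximum transition step, default 4.
#' @param dim_per_step Columns retained per step, default 16.
#' @param log_shift Baseline probability beta; `NULL` (default) uses 1/m.
#' @return An `embedding_matrix`: m x (K * dim_per_step),
#'   `scale_tag = "global"`.
#' @export
grarep_embed <- function(graph, K = 4L, dim_per_step = 16L,
                         log_shift = NULL) {
  stopifnot(K >= 1L, dim_per_step >= 1L)
  A <- .graph_adjacency(graph)
  m <- nrow(A)
  deg <- rowSums(A)
  if (any(deg == 0)) stop("graph has an isolated node; must be connected")
  beta <- if (is.null(log_shift)) 1 / m else log_shift
  if (beta <= 0) stop("log_shift must be positive")
  S <- A / deg
  St <- diag(m)
  blocks <- vector("list", K)
  for (t in seq_len(K)) {
    St <- St %*% S
    colsum <- colSums(St)
    Y <- log(sweep(St, 2, colsum, "/")) - log(beta)
    Y[Y < 0 | !is.finite(Y)] <- 0
    sv <- svd(Y)
    d_take <- min(dim_per_step, sum(sv$d > 1e-12))
    blk <- matrix(0, m, dim_per_step)
    if (d_take > 0) {
      blk[, seq_len(d_take)] <-
        sv$u[, seq_len(d_take), drop = FALSE] %*%
        diag(sqrt(sv$d[seq_len(d_take)]), d_take)
    }
    blocks[[t]] <- fix_signs(blk)
  }
  new_embedding(do.call(cbind, blocks), "global")
}

#' Concatenate embedding matrices across scales
#'
#' Joins embedding blocks columnwise in the canonical order node,
#' community, global (whatever subset is supplied, in that order
#' regardless of call order). Columns are renamed `GraphEmbeddings_k`
#' with k running 0..d_total-1.
#'
#' @param parts List of `embedding_matrix` objects sharing a row count.
#' @return An `embedding_matrix` with `scale_tag = "combined"`.
#' @export
concat_embeddings <- function(parts) {
  stopifnot(length(parts) >= 1L)
  tags <- vapply(parts, function(x) attr(x, "scale_tag"), character(1))
  ord <- order(match(tags, c("node", "community", "global")))
  parts <- parts[ord]
  ms <- vapply(parts, nrow, integer(1))
  if (length(unique(ms)) != 1L) stop("embedding row counts differ")
  new_embedding(do.call(cbind, parts), "combined")
}

new_embedding <- function(mat, scale_tag) {
  mat <- as.matrix(mat)
  colnames(mat) <- paste0("GraphEmbeddings_", seq_len(ncol(mat)) - 1L)
  attr(mat, "scale_tag") <- scale_tag
  class(mat) <- c("embedding_matrix", class(mat))
  mat
}

# Deterministic sign convention: each column's largest-magnitude entry is
# made positive (first such entry on ties).
fix_signs <- function(mat) {
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (all(col == 0)) next
    lead <- which.max(abs(col))
    if (col[lead] < 0) mat[, j] <- -col
  }
  mat
}
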