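# Linear-neighborhood similarity graph construction. Each sample row of the
# nonnegative feature matrix X (m x l) is approximated as a nonnegative
# weighted combination of its k nearest neighbors; the learned weight matrix
# W, restricted to the neighbor support C, defines the edges of the sample
# graph. W is fitted by a multiplicative update derived from the KKT
# conditions of
#     min_W 1/2 ||X - (C*W) X||_F^2 + mu/2 ||(C*W) e - e||^2 ,  W >= 0,
# whose soft constraint drives every neighbor-weight row sum toward 1.

#' Nearest-neighbor indicator matrix
#'
#' Marks, for every sample, its k nearest other samples by Euclidean
#' distance, with `k = max(1, round(neighborhood_ratio * (m - 1)))`.
#' Distance ties are broken toward the smaller index. The diagonal is zero.
#'
#' @param X Nonnegative sample matrix, one row per sample (m >= 2).
#' @param neighborhood_ratio Fraction of the other samples used as
#'   neighbors, in (0, 1). Default 0.1.
#' @return A list of class `neighbor_indicator`: binary m x m matrix `C`,
#'   the `k` used, and `neighborhood_ratio`.
#' @export
neighbor_indicator <- function(X, neighborhood_ratio = 0.1) {
  stopifnot(neighborhood_ratio > 0, neighborhood_ratio < 1)
  m <- nrow(X)
  if (is.null(m) || m < 2L) stop("need at least 2 samples")
  k <- max(1L, as.integer(round(neighborhood_ratio * (m - 1))))
  D <- as.matrix(stats::dist(X))
  C <- matrix(0L, m, m)
  for (i in seq_len(m)) {
    d <- D[i, ]
    d[i] <- Inf
    nn <- order(d, seq_len(m))[seq_len(k)]
    C[i, nn] <- 1L
  }
  structure(list(C = C, k = k, neighborhood_ratio = neighborhood_ratio),
            class = "neighbor_indicator")
}

#' Reconstruction objective of the neighborhood weights
#'
#' Evaluates `1/2 ||X - (C*W) X||_F^2 + mu/2 ||(C*W) e - e||^2`, the
#' function the multiplicative update of [flnsa_fit()] monotonically
#' decreases. The second term penalizes deviation of each neighbor-weight
#' row sum from 1 (the normalization constraint), so at a good fit it
#' vanishes.
#'
#' @param X Sample matrix m x l.
#' @param C `neighbor_indicator` (or bare binary matrix).
#' @param W m x m nonnegative weight matrix.
#' @param mu Regularization weight, > 0.
#' @return Nonnegative scalar.
#' @export
flnsa_objective <- function(X, C, W, mu) {
  Cm <- if (inherits(C, "neighbor_indicator")) C$C else C
  CW <- Cm * W
  recon <- X - CW %*% X
  0.5 * sum(recon^2) + (mu / 2) * sum((rowSums(CW) - 1)^2)
}

#' Fit linear-neighborhood reconstruction weights
#'
#' Starting from seeded positive uniform entries on the neighbor support,
#' iterates the multiplicative rule
#' `W_ij <- W_ij * (X X' + mu e e')_ij / ((C*W) X X' + mu (C*W) e e')_ij`
#' on support entries (zero elsewhere) until the largest elementwise change
#' drops below `tol` or `max_iter` is reached. The update preserves
#' nonnegativity and the support, and is non-increasing in
#' [flnsa_objective()]. A small epsilon floors the denominator so isolated
#' supports never divide by zero.
#'
#' @param X Nonnegative sample matrix m x l.
#' @param C `neighbor_indicator` from [neighbor_indicator()].
#' @param mu Regularization parameter (> 0), default 1.
#' @param tol Convergence tolerance on max |delta W|, default 1e-6.
#' @param max_iter Iteration cap, default 500.
#' @param seed RNG seed for the random initialization.
#' @param trace If TRUE, record the objective value after every iteration.
#' @return A list of class `flnsa_weights`: `W` (m x m, nonnegative,
#'   support within C), `mu`, `iterations_run`, `converged`, and
#'   `objective_trace` (numeric, empty unless `trace`).
#' @export
flnsa_fit <- function(X, C, mu = 1, tol = 1e-6, max_iter = 500L,
                      seed = 1L, trace = FALSE) {
  stopifnot(inherits(C, "neighbor_indicator"), mu > 0, tol > 0)
  if (any(X < 0)) stop("X must be nonnegative")
  Cm <- C$C
  m <- nrow(X)
  stopifnot(nrow(Cm) == m)
  eps <- 1e-12

  set.seed(seed)
  W <- matrix(0, m, m)
  W[Cm == 1L] <- stats::runif(sum(Cm), min = eps, max = 1)

  XXt <- tcrossprod(X)           # m x m, reused every iteration
  num <- XXt + mu                # X X' + mu e e'
  obj <- if (trace) numeric(max_iter) else numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    CW <- Cm * W
    den <- CW %*% XXt + mu * rowSums(CW)  # recycles column-wise: + mu*(CW)e e'
    W_new <- W * num / (den + eps)
    W_new[Cm == 0L] <- 0
    delta <- max(abs(W_new - W))
    W <- W_new
    if (trace) obj[it] <- flnsa_objective(X, Cm, W, mu)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(W = W, mu = mu, iterations_run = it, converged = converged,
         objective_trace = if (trace) obj[seq_len(it)] else numeric(0)),
    class = "flnsa_weights"
  )
}

#' Build a connected sample graph from reconstruction weights
#'
#' Symmetrizes the learned weights by elementwise max and, if the result is
#' disconnected, unions in a distance-based backbone: every node is linked
#' to its `backbone_c` nearest samples (by Euclidean distance on X) at a
#' small floor weight, and any components still separate are bridged
#' through their nearest inter-component pair. The output is always a
#' single connected component; backbone/bridge edges carry provenance
#' `"connectivity_backbone"`, learned edges `"flnsa"`.
#'
#' @param W A `flnsa_weights` object (or bare m x m matrix).
#' @param X Sample matrix used for backbone distances.
#' @param backbone_c Number of nearest neighbors in the fallback backbone
#'   (default 3).
#' @param min_edge_weight Optional threshold; learned weights strictly below
#'   it are removed before symmetrization (default 0 = keep all).
#' @return A list of class `sequence_graph`: `adjacency` (symmetric,
#'   zero-diagonal m x m), `provenance` (character matrix, "" where no
#'   edge), and `m`.
#' @export
build_graph <- function(W, X, backbone_c = 3L, min_edge_weight = 0) {
  Wm <- if (inherits(W, "flnsa_weights")) W$W else W
  m <- nrow(Wm)
  stopifnot(nrow(X) == m, backbone_c >= 1L, backbone_c < m)
  Wm[Wm < min_edge_weight] <- 0
  A <- pmax(Wm, t(Wm))
  diag(A) <- 0
  prov <- matrix("", m, m)
  prov[A > 0] <- "flnsa"

  pos <- A[A > 0]  # backbone edges get the smallest learned weight (floored)
  floor_w <- if (length(pos)) max(min(pos), 1e-6) else 1e-6

  n_comp <- function(adj) {
    g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
    igraph::components(g)$no
  }

  if (n_comp(A) > 1L) {
    D <- as.matrix(stats::dist(X))
    diag(D) <- Inf
    for (i in seq_len(m)) {
      nn <- order(D[i, ], seq_len(m))[seq_len(backbone_c)]
      for (j in nn) {
        if (A[i, j] == 0) {
          A[i, j] <- A[j, i] <- floor_w
          prov[i, j] <- prov[j, i] <- "connectivity_backbone"
        }
      }
    }
    # bridge any components the mutual-kNN union still leaves apart
    repeat {
      g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
      comp <- igraph::components(g)
      if (comp$no == 1L) break
      main <- which(comp$membership == which.max(comp$csize))
      other <- which(comp$membership != which.max(comp$csize))
      sub <- D[other, main, drop = FALSE]
      best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      i <- other[best[1]]; j <- main[best[2]]
      A[i, j] <- A[j, i] <- floor_w
      prov[i, j] <- prov[j, i] <- "connectivity_backbone"
    }
  }
  structure(list(adjacency = A, provenance = prov, m = m),
            class = "sequence_graph")
}

#' Write a sequence graph as a weighted edge list
#'
#' @param graph A `sequence_graph`.
#' @param path Output TSV path (columns node_i, node_j, weight, provenance;
#'   upper triangle only).
#' @return Invisibly, `path`.
#' @export
write_graph_edges <- function(graph, path) {
  stopifnot(inherits(graph, "sequence_graph"))
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency > 0,
               arr.ind = TRUE)
  edges <- data.frame(
    node_i = idx[, 1], node_j = idx[, 2],
    weight = graph$adjacency[idx],
    provenance = graph$provenance[idx]
  )
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
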