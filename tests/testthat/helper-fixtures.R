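# Shared fixtures: all built in code at test time.

# Random A/C/G/T string of length n under the current RNG state.
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Tiny validated dataset built directly from explicit sequences.
make_dataset <- function(seqs, labels, window_length = nchar(seqs[1]),
                         tss_index = window_length - 1L) {
  records <- data.frame(
    id = sprintf("s%03d", seq_along(seqs)),
    sequence = seqs, label = as.integer(labels),
    stringsAsFactors = FALSE
  )
  validate_dataset(records, window_length, tss_index)
}

# Adjacency of two k-cliques joined by a single bridge edge (2k nodes).
barbell_adjacency <- function(k, bridge_weight = 1) {
  m <- 2L * k
  A <- matrix(0, m, m)
  A[1:k, 1:k] <- 1
  A[(k + 1):m, (k + 1):m] <- 1
  diag(A) <- 0
  A[k, k + 1] <- A[k + 1, k] <- bridge_weight
  A
}

as_graph <- function(A) {
  structure(list(adjacency = A, provenance = matrix("", nrow(A), ncol(A)),
                 m = nrow(A)), class = "sequence_graph")
}

# Planted two-block random graph: within-block edge prob p_in, across p_out.
planted_partition <- function(m, p_in = 0.3, p_out = 0.02) {
  half <- m %/% 2
  labels <- rep(c(0L, 1L), c(half, m - half))
  A <- matrix(0, m, m)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      p <- if (labels[i] == labels[j]) p_in else p_out
      if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1
    }
  }
  # guarantee connectivity with a weak ring so embeddings are defined
  for (i in 1:m) {
    j <- if (i == m) 1L else i + 1L
    if (A[i, j] == 0) A[i, j] <- A[j, i] <- 0.05
  }
  list(adjacency = A, labels = labels)
}

# Best label agreement of a 2-means clustering with true block labels.
cluster_agreement <- function(emb, labels) {
  km <- stats::kmeans(emb, centers = 2, nstart = 10)
  pred <- km$cluster - 1L
  max(mean(pred == labels), mean((1L - pred) == labels))
}
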