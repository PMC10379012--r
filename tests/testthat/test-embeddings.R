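test_that("walks stay on edges, have the right count, and are seeded", {
  A <- barbell_adjacency(4)
  g <- as_graph(A)
  corpus <- generate_biased_walks(g, walks_per_node = 3, walk_length = 12,
                                  seed = 5)
  expect_length(corpus$walks, 3 * 8)
  for (w in corpus$walks) {
    expect_true(all(w %in% 1:8))
    if (length(w) > 1) {
      steps <- cbind(w[-length(w)], w[-1])
      expect_true(all(A[steps] > 0))
    }
  }
  corpus2 <- generate_biased_walks(g, walks_per_node = 3, walk_length = 12,
                                   seed = 5)
  expect_identical(corpus$walks, corpus2$walks)
  # walk_length 1: every walk is its start node
  c1 <- generate_biased_walks(g, walks_per_node = 1, walk_length = 1,
                              seed = 1)
  expect_equal(unlist(c1$walks), 1:8)
  expect_error(generate_biased_walks(g, p = 0), "positive")
})

test_that("unbiased walk transitions match edge-weight-normalized probabilities", {
  # weighted triangle; with p=q=1 one-step frequencies converge to w_ij/deg_i
  A <- matrix(c(0, 1, 2,
                1, 0, 4,
                2, 4, 0), 3, byrow = TRUE)
  g <- as_graph(A)
  corpus <- generate_biased_walks(g, p = 1, q = 1, walks_per_node = 150L,
                                  walk_length = 250L, seed = 3)
  trans <- matrix(0, 3, 3)
  for (w in corpus$walks) {
    for (i in seq_len(length(w) - 1)) {
      trans[w[i], w[i + 1]] <- trans[w[i], w[i + 1]] + 1
    }
  }
  emp <- trans / rowSums(trans)
  expected <- A / rowSums(A)
  expect_lt(max(rowSums(abs(emp - expected))), 0.05)
})

test_that("skip-gram embeddings separate two weakly-joined cliques", {
  A <- barbell_adjacency(10, bridge_weight = 0.1)
  g <- as_graph(A)
  corpus <- generate_biased_walks(g, walks_per_node = 20, walk_length = 20,
                                  seed = 8)
  emb <- skipgram_embed(corpus, m = 20, dim = 8, seed = 8)
  expect_equal(dim(unclass(emb)), c(20L, 8L))
  cs <- function(i, j) {
    v <- emb[i, ]; u <- emb[j, ]
    sum(v * u) / sqrt(sum(v^2) * sum(u^2))
  }
  pairs <- t(combn(20, 2))
  within <- pairs[(pairs[, 1] <= 10) == (pairs[, 2] <= 10), ]
  across <- pairs[(pairs[, 1] <= 10) != (pairs[, 2] <= 10), ]
  mean_within <- mean(apply(within, 1, function(p) cs(p[1], p[2])))
  mean_across <- mean(apply(across, 1, function(p) cs(p[1], p[2])))
  expect_gt(mean_within, mean_across)
  # determinism
  emb2 <- skipgram_embed(corpus, m = 20, dim = 8, seed = 8)
  expect_identical(unclass(emb), unclass(emb2))
})

test_that("modularity matrix sums to zero and socdim recovers planted blocks", {
  set.seed(21)
  for (rep in 1:20) {
    m <- sample(5:25, 1)
    A <- matrix(runif(m * m), m); A <- A + t(A); diag(A) <- 0
    expect_lt(abs(sum(modularity_matrix(as_graph(A)))), 1e-8)
  }
  # two 10-cliques with one bridge: top eigenvector splits the blocks
  g <- as_graph(barbell_adjacency(10))
  emb <- socdim_embed(g, k = 1)
  expect_equal(dim(unclass(emb)), c(20L, 1L))
  split_sign <- sign(emb[, 1])
  agree <- max(mean(split_sign[1:10] > 0) + mean(split_sign[11:20] < 0),
               mean(split_sign[1:10] < 0) + mean(split_sign[11:20] > 0)) / 2
  expect_gte(agree, 19 / 20)
  expect_error(socdim_embed(g, k = 20), "k must")
  # deterministic sign convention
  expect_identical(unclass(socdim_embed(g, 3)), unclass(socdim_embed(g, 3)))
})

test_that("grarep uses row-stochastic transition powers and recovers cliques", {
  g <- as_graph(barbell_adjacency(8, bridge_weight = 0.5))
  A <- g$adjacency
  S <- A / rowSums(A)
  St <- S
  for (t in 1:4) {
    expect_equal(unname(rowSums(St)), rep(1, 16), tolerance = 1e-10)
    St <- St %*% S
  }
  emb <- grarep_embed(g, K = 2, dim_per_step = 4)
  expect_equal(dim(unclass(emb)), c(16L, 8L))
  agree <- cluster_agreement(unclass(emb), rep(c(0, 1), each = 8))
  expect_gte(agree, 0.9)
  # rank-deficient request is zero-padded, not an error
  small <- as_graph(barbell_adjacency(2))
  embs <- grarep_embed(small, K = 1, dim_per_step = 10)
  expect_equal(ncol(unclass(embs)), 10L)
})

test_that("concat_embeddings canonicalizes order and renames columns", {
  e_node <- promembed:::new_embedding(matrix(1, 5, 3), "node")
  e_comm <- promembed:::new_embedding(matrix(2, 5, 2), "community")
  e_glob <- promembed:::new_embedding(matrix(3, 5, 4), "global")
  out <- concat_embeddings(list(e_glob, e_node, e_comm))
  expect_equal(ncol(out), 9L)
  expect_equal(colnames(out), paste0("GraphEmbeddings_", 0:8))
  # node block first, then community, then global, regardless of call order
  expect_equal(unname(out[1, ]), c(1, 1, 1, 2, 2, 3, 3, 3, 3))
  single <- concat_embeddings(list(e_comm))
  expect_equal(unname(unclass(single)), matrix(2, 5, 2),
               ignore_attr = TRUE)
  bad <- promembed:::new_embedding(matrix(0, 4, 2), "node")
  expect_error(concat_embeddings(list(bad, e_comm)), "row counts")
})

test_that("embeddings followed by 2-means recover planted partitions", {
  agreements <- matrix(NA_real_, 3, 3,
                       dimnames = list(c("node", "community", "global"), NULL))
  for (s in 1:3) {
    set.seed(100 + s)
    pp <- planted_partition(60, p_in = 0.3, p_out = 0.02)
    g <- as_graph(pp$adjacency)
    corpus <- generate_biased_walks(g, walks_per_node = 10, walk_length = 40,
                                    seed = s)
    en <- skipgram_embed(corpus, 60, dim = 16, seed = s)
    ec <- socdim_embed(g, k = 4)
    eg <- grarep_embed(g, K = 2, dim_per_step = 8)
    agreements["node", s] <- cluster_agreement(unclass(en), pp$labels)
    agreements["community", s] <- cluster_agreement(unclass(ec), pp$labels)
    agreements["global", s] <- cluster_agreement(unclass(eg), pp$labels)
  }
  expect_true(all(rowMeans(agreements) >= 0.85))
})
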