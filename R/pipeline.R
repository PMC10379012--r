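# End-to-end orchestration: split -> BPB fit on train -> local encoding of
# all rows -> similarity graph over all rows (transductive by default) ->
# multi-scale embeddings -> feature assembly -> boosted-tree training on
# the train rows -> evaluation on the held-out rows. One master seed fans
# out into fixed per-stage substreams so stages are independently
# reproducible.

.stage_seed <- function(seed, stage) {
  offsets <- c(split = 101L, flnsa = 202L, walks = 303L, sgns = 404L,
               train = 505L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full promoter-prediction pipeline
#'
#' Executes the complete workflow on a validated dataset and reports
#' held-out metrics. The sample graph is built over all rows (train and
#' test) by default — the transductive protocol; the classifier and the
#' BPB profiles only ever see training labels. Set `transductive = FALSE`
#' to build the graph on training rows only and give each test row the
#' embedding of its nearest training sample (a stricter, fully inductive
#' protocol; it changes what information the graph may use, not the
#' mathematics of any stage).
#'
#' @param dataset A `promoter_dataset`.
#' @param test_fraction Held-out fraction per class (default 0.2, the 4:1
#'   protocol).
#' @param parts Local feature blocks, subset of
#'   `c("NCP_ND", "EIIP", "BPB")`.
#' @param scales Embedding scales, subset of
#'   `c("node", "community", "global")`; `character(0)` skips the graph
#'   stage entirely (local features only).
#' @param flnsa List of graph-construction parameters: `ratio`, `mu`,
#'   `tol`, `max_iter`, `backbone_c`, `min_edge_weight`.
#' @param embed List with per-scale embedding parameters: `node` (dim, p,
#'   q, walks_per_node, walk_length, window, epochs, negative), `community`
#'   (k), `global` (K, dim_per_step).
#' @param training List: `iterations`, `depth`, `learning_rate`, `balance`.
#' @param threshold Decision threshold (default 0.5).
#' @param pseudocount BPB smoothing (default 1).
#' @param seed Master seed.
#' @param transductive Build the graph over all rows (default TRUE).
#' @param output_dir If non-NULL, persist metrics, graph, embeddings, BPB
#'   model, predictions and a run manifest there.
#' @return List of class `pipeline_run`: `metrics` (test-set
#'   `metrics_report`), `split`, `bpb`, `graph`, `embeddings`, `model`,
#'   `prediction`, `feature_table`, and the echoed `config`.
#' @export
run_pipeline <- function(dataset,
                         test_fraction = 0.2,
                         parts = c("NCP_ND", "EIIP", "BPB"),
                         scales = c("node", "community", "global"),
                         flnsa = list(),
                         embed = list(),
                         training = list(),
                         threshold = 0.5,
                         pseudocount = 1,
                         seed = 1L,
                         transductive = TRUE,
                         output_dir = NULL) {
  stopifnot(inherits(dataset, "promoter_dataset"))
  fl <- utils::modifyList(
    list(ratio = 0.1, mu = 1, tol = 1e-6, max_iter = 500L, backbone_c = 3L,
         min_edge_weight = 0), flnsa)
  em <- utils::modifyList(
    list(node = list(dim = 64L, p = 1, q = 1, walks_per_node = 10L,
                     walk_length = 40L, window = 5L, epochs = 5L,
                     negative = 5L),
         community = list(k = 16L),
         global = list(K = 4L, dim_per_step = 16L)), embed)
  tr <- utils::modifyList(
    list(iterations = 500L, depth = 6L, learning_rate = 0.05,
         balance = "auto"), training)
  t0 <- Sys.time()

  split <- stratified_split(dataset, test_fraction,
                            seed = .stage_seed(seed, "split"))
  labels <- dataset$records$label

  bpb <- NULL
  if ("BPB" %in% parts) {
    bpb <- fit_bpb(dataset$records[split$train_indices, , drop = FALSE],
                   dataset$window_length, pseudocount)
  }
  local_mat <- encode_dataset(dataset, model = bpb, parts = parts)

  graph <- NULL
  embeddings <- NULL
  if (length(scales) > 0L) {
    graph_rows <- if (transductive) seq_len(nrow(local_mat)) else
      split$train_indices
    Xg <- local_mat[graph_rows, , drop = FALSE]
    C <- neighbor_indicator(Xg, fl$ratio)
    Wfit <- flnsa_fit(Xg, C, mu = fl$mu, tol = fl$tol,
                      max_iter = fl$max_iter,
                      seed = .stage_seed(seed, "flnsa"))
    graph <- build_graph(Wfit, Xg, backbone_c = fl$backbone_c,
                         min_edge_weight = fl$min_edge_weight)
    parts_emb <- list()
    if ("node" %in% scales) {
      corpus <- generate_biased_walks(
        graph, p = em$node$p, q = em$node$q,
        walks_per_node = em$node$walks_per_node,
        walk_length = em$node$walk_length,
        seed = .stage_seed(seed, "walks"))
      parts_emb$node <- skipgram_embed(
        corpus, m = graph$m, dim = em$node$dim, window = em$node$window,
        epochs = em$node$epochs, negative = em$node$negative,
        seed = .stage_seed(seed, "sgns"))
    }
    if ("community" %in% scales) {
      parts_emb$community <- socdim_embed(graph, k = em$community$k)
    }
    if ("global" %in% scales) {
      parts_emb$global <- grarep_embed(graph, K = em$global$K,
                                       dim_per_step = em$global$dim_per_step)
    }
    embeddings <- concat_embeddings(unname(parts_emb))
    if (!transductive) {
      # place each held-out row at its nearest training sample
      emb_all <- matrix(0, nrow(local_mat), ncol(embeddings))
      emb_all[graph_rows, ] <- embeddings
      for (i in split$test_indices) {
        d2 <- rowSums(sweep(Xg, 2, local_mat[i, ])^2)
        emb_all[i, ] <- embeddings[which.min(d2), ]
      }
      colnames(emb_all) <- colnames(embeddings)
      embeddings <- new_embedding(emb_all, attr(embeddings, "scale_tag"))
    }
  }

  tbl <- assemble_features(local_mat, embeddings)
  model <- train_ensemble(tbl, labels, split$train_indices,
                          iterations = tr$iterations, depth = tr$depth,
                          learning_rate = tr$learning_rate,
                          balance = tr$balance,
                          seed = .stage_seed(seed, "train"))
  pred <- predict_ensemble(model, tbl, rows = split$test_indices,
                           threshold = threshold)
  metrics <- metrics_report(labels[split$test_indices], pred)

  run <- structure(
    list(metrics = metrics, split = split, bpb = bpb, graph = graph,
         embeddings = embeddings, model = model, prediction = pred,
         feature_table = tbl,
         config = list(test_fraction = test_fraction, parts = parts,
                       scales = scales, flnsa = fl, embed = em,
                       training = tr, threshold = threshold,
                       pseudocount = pseudocount, seed = seed,
                       transductive = transductive),
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_run"
  )
  if (!is.null(output_dir)) persist_run(run, dataset, output_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run (", length(x$split$train_indices), "train /",
      length(x$split$test_indices), "test )\n")
  print(x$metrics)
  invisible(x)
}

# Persist the artifacts of a run: metrics, predictions, graph edge list,
# embeddings, BPB model and a manifest (config + seeds + timing).
persist_run <- function(run, dataset, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  m <- run$metrics
  jsonlite::write_json(
    list(sen = m$sen, spe = m$spe, acc = m$acc, mcc = m$mcc, pre = m$pre,
         f1 = m$f1, auc = m$auc, kappa = m$kappa,
         counts = unclass(m$counts)),
    file.path(output_dir, "metrics.json"), digits = NA, auto_unbox = TRUE)
  ids <- dataset$records$id[run$prediction$rows]
  utils::write.table(
    data.frame(id = ids, score = run$prediction$scores,
               label = run$prediction$labels),
    file.path(output_dir, "predictions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(run$graph)) {
    write_graph_edges(run$graph, file.path(output_dir, "graph_edges.tsv"))
  }
  if (!is.null(run$embeddings)) {
    utils::write.table(
      cbind(id = dataset$records$id[seq_len(nrow(run$embeddings))],
            as.data.frame(unclass(run$embeddings))),
      file.path(output_dir, "embeddings.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(run$bpb)) {
    write_bpb(run$bpb, file.path(output_dir, "bpb_model.json"))
  }
  jsonlite::write_json(
    list(config = run$config, elapsed_s = run$elapsed_s,
         n_train = length(run$split$train_indices),
         n_test = length(run$split$test_indices),
         r_version = as.character(getRversion())),
    file.path(output_dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(output_dir)
}

#' Feature-combination ablation harness
#'
#' Reruns the pipeline over feature combinations on one or more datasets
#' (e.g. a balanced and a 1:5 imbalanced condition), holding split and
#' stage seeds fixed within a condition, and tabulates Cohen's kappa per
#' combination — the layout used to compare local-feature combinations
#' (run without any graph embedding) and embedding-scale combinations
#' (run with all local features).
#'
#' @param datasets Named list of `promoter_dataset` objects, one per
#'   condition; names become kappa column suffixes.
#' @param local_combos List of local part subsets evaluated without graph
#'   embeddings; `NULL` for none. Default: all 7 non-empty subsets.
#' @param embed_combos List of embedding scale subsets evaluated with all
#'   local parts; `NULL` for none. Default: all 7 non-empty subsets.
#' @param seed Master seed shared by every run.
#' @param ... Passed to [run_pipeline()] (e.g. `flnsa`, `embed`,
#'   `training`). Supplied before the combo arguments so that abbreviated
#'   names (like `embed`) never partially match `embed_combos`.
#' @return data.frame with indicator columns (NCP_ND, EIIP, BPB, Node2vec,
#'   SocDim, GraRep), a `stage` column (`local` / `embedding`), one
#'   `kappa_<condition>` column per dataset, and a `status` column. The
#'   full metric reports are attached as attribute `"reports"`.
#' @export
ablation_run <- function(datasets, ...,
                         local_combos = .all_subsets(c("NCP_ND", "EIIP", "BPB")),
                         embed_combos = .all_subsets(c("node", "community", "global")),
                         seed = 1L) {
  if (inherits(datasets, "promoter_dataset")) {
    datasets <- list(condition = datasets)
  }
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  rows <- list()
  if (!is.null(local_combos)) {
    for (combo in local_combos) {
      rows[[length(rows) + 1L]] <- list(stage = "local", parts = combo,
                                        scales = character(0))
    }
  }
  if (!is.null(embed_combos)) {
    for (combo in embed_combos) {
      rows[[length(rows) + 1L]] <- list(stage = "embedding",
                                        parts = c("NCP_ND", "EIIP", "BPB"),
                                        scales = combo)
    }
  }
  scale_names <- c(node = "Node2vec", community = "SocDim",
                   global = "GraRep")
  out <- data.frame()
  reports <- list()
  for (r in rows) {
    rec <- data.frame(stage = r$stage,
                      NCP_ND = as.integer("NCP_ND" %in% r$parts),
                      EIIP = as.integer("EIIP" %in% r$parts),
                      BPB = as.integer("BPB" %in% r$parts),
                      Node2vec = as.integer("node" %in% r$scales),
                      SocDim = as.integer("community" %in% r$scales),
                      GraRep = as.integer("global" %in% r$scales))
    status <- "ok"
    for (cond in names(datasets)) {
      kappa <- tryCatch({
        run <- run_pipeline(datasets[[cond]], parts = r$parts,
                            scales = r$scales, seed = seed, ...)
        reports[[paste(r$stage, paste(c(r$parts,
                                        scale_names[r$scales]),
                                      collapse = "+"), cond,
                       sep = "|")]] <- run$metrics
        run$metrics$kappa
      }, error = function(e) {
        status <<- paste0("failed: ", conditionMessage(e))
        NA_real_
      })
      rec[[paste0("kappa_", cond)]] <- kappa
    }
    rec$status <- status
    out <- rbind(out, rec)
  }
  attr(out, "reports") <- reports
  out
}

.all_subsets <- function(x) {
  out <- list()
  for (size in seq_along(x)) {
    cmb <- utils::combn(x, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
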