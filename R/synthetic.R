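# Synthetic promoter benchmark generator. Positives are i.i.d. background
# at a promoter-like GC content with a TATA-box consensus planted 25-35 bp
# upstream of the TSS; negatives emulate exon/intron sequence as a low-order
# Markov chain at a different GC content, with no planted motif. The
# generator validates the pipeline; it does not claim to reproduce real
# promoter statistics (CpG islands, Inr or CAAT elements are not modeled).

#' Configuration for the synthetic promoter generator
#'
#' Defaults describe a 300-bp \[-249, +50\] window (TSS at 0-based index
#' 249) with the "TATAAA" consensus planted uniformly 25-35 bp upstream of
#' the TSS in every positive, a promoter GC content of 0.55 and an
#' exon/intron-like negative GC content of 0.45 generated by an order-1
#' Markov chain.
#'
#' @param n_pos,n_neg Numbers of positive and negative records.
#' @param window_length Window length L in bp (default 300).
#' @param tss_index 0-based TSS position (default 249).
#' @param tata_fraction Fraction of positives carrying the planted motif
#'   (default 1).
#' @param motif Planted consensus (default "TATAAA").
#' @param motif_offset_range Upstream offsets (bp before the TSS) at which
#'   the motif start may land, inclusive (default c(25, 35)).
#' @param pos_gc,neg_gc GC contents of the two backgrounds (defaults 0.55
#'   and 0.45).
#' @param neg_order Markov order of the negative background, 0 or 1
#'   (default 1).
#' @param seed Master RNG seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 200L, n_neg = 200L,
                             window_length = 300L, tss_index = 249L,
                             tata_fraction = 1, motif = "TATAAA",
                             motif_offset_range = c(25L, 35L),
                             pos_gc = 0.55, neg_gc = 0.45,
                             neg_order = 1L, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, window_length > 0L,
            tss_index >= 0L, tss_index < window_length,
            tata_fraction >= 0, tata_fraction <= 1,
            pos_gc > 0, pos_gc < 1, neg_gc > 0, neg_gc < 1,
            neg_order %in% c(0L, 1L),
            length(motif_offset_range) == 2L,
            motif_offset_range[1] <= motif_offset_range[2])
  # motif must fit inside the window at the farthest upstream offset
  if (tss_index - motif_offset_range[2] < 0 ||
      tss_index - motif_offset_range[1] + nchar(motif) > window_length) {
    stop("motif does not fit in the window at the allowed offsets")
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         window_length = as.integer(window_length),
         tss_index = as.integer(tss_index),
         tata_fraction = tata_fraction, motif = motif,
         motif_offset_range = as.integer(motif_offset_range),
         pos_gc = pos_gc, neg_gc = neg_gc,
         neg_order = as.integer(neg_order), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

.base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

.sample_iid <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = .base_probs(gc)), collapse = "")
}

# Order-1 Markov background at the requested stationary GC content: the
# strong/weak (G+C vs A+T) group follows a sticky chain that keeps the
# previous group with probability lambda and otherwise redraws it from the
# stationary law, giving exon/intron-like compositional patchiness while
# the marginal GC content stays exactly gc; bases are uniform within group.
.sample_markov1 <- function(n, gc, lambda = 0.15) {
  g <- logical(n)
  g[1] <- stats::runif(1) < gc
  for (i in seq_len(n - 1L)) {
    g[i + 1L] <- if (stats::runif(1) < lambda) g[i] else stats::runif(1) < gc
  }
  out <- character(n)
  out[g] <- sample(c("C", "G"), sum(g), replace = TRUE)
  out[!g] <- sample(c("A", "T"), sum(!g), replace = TRUE)
  paste(out, collapse = "")
}

#' Draw one synthetic promoter sequence
#'
#' i.i.d. background at `pos_gc`; with probability `tata_fraction`, the
#' consensus motif overwrites the background starting `offset` bp upstream
#' of the TSS, with `offset` uniform on `motif_offset_range`.
#'
#' @param config `synthetic_config`. Uses the current RNG state (seed the
#'   session or use [generate_dataset()]).
#' @return List: `sequence`, `motif_start` (1-based start of the planted
#'   motif, or NA).
#' @export
sample_promoter <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  seq <- .sample_iid(config$window_length, config$pos_gc)
  motif_start <- NA_integer_
  if (stats::runif(1) < config$tata_fraction) {
    offset <- sample(seq(config$motif_offset_range[1],
                         config$motif_offset_range[2]), 1)
    # 0-based motif start = tss_index - offset; convert to 1-based
    motif_start <- config$tss_index - offset + 1L
    substr(seq, motif_start, motif_start + nchar(config$motif) - 1L) <-
      config$motif
  }
  list(sequence = seq, motif_start = motif_start)
}

#' Draw one synthetic non-promoter sequence
#'
#' Order-`neg_order` Markov background at `neg_gc`, no planted motif.
#'
#' @param config `synthetic_config`.
#' @return List: `sequence`.
#' @export
sample_non_promoter <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  seq <- if (config$neg_order == 0L) {
    .sample_iid(config$window_length, config$neg_gc)
  } else {
    .sample_markov1(config$window_length, config$neg_gc)
  }
  list(sequence = seq)
}

#' Generate a labeled synthetic promoter dataset
#'
#' Draws `n_pos` positives and `n_neg` negatives, shuffles them with the
#' seeded RNG, and returns a validated `promoter_dataset` together with a
#' ground-truth manifest of planted motif positions.
#'
#' @param config `synthetic_config`.
#' @return A `promoter_dataset` with an extra `manifest` element: a
#'   data.frame (id, label, motif_start) where motif_start is the 1-based
#'   planted position or NA.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  pos <- lapply(seq_len(config$n_pos), function(i) sample_promoter(config))
  neg <- lapply(seq_len(config$n_neg), function(i) sample_non_promoter(config))
  records <- data.frame(
    id = c(sprintf("pos_%04d", seq_len(config$n_pos)),
           sprintf("neg_%04d", seq_len(config$n_neg))),
    sequence = c(vapply(pos, `[[`, character(1), "sequence"),
                 vapply(neg, `[[`, character(1), "sequence")),
    label = c(rep(1L, config$n_pos), rep(0L, config$n_neg)),
    stringsAsFactors = FALSE
  )
  motif_start <- c(vapply(pos, `[[`, integer(1), "motif_start"),
                   rep(NA_integer_, config$n_neg))
  ord <- sample(nrow(records))
  records <- records[ord, , drop = FALSE]
  motif_start <- motif_start[ord]
  row.names(records) <- NULL
  ds <- validate_dataset(records, config$window_length, config$tss_index)
  ds$manifest <- data.frame(id = records$id, label = records$label,
                            motif_start = motif_start,
                            stringsAsFactors = FALSE)
  ds$config <- config
  ds
}

#' Write the synthetic ground-truth manifest as JSON
#'
#' @param dataset Dataset from [generate_dataset()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(dataset, path) {
  stopifnot(!is.null(dataset$manifest))
  jsonlite::write_json(
    list(config = unclass(dataset$config), manifest = dataset$manifest),
    path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}
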