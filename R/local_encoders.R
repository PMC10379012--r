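# Per-nucleotide local feature encodings: chemical property (NCP), running
# nucleotide density (ND), electron-ion interaction pseudopotential (EIIP)
# and bi-profile Bayes (BPB). All are defined over the strict {A,C,G,T}
# alphabet; validation upstream guarantees it.

.NCP_TABLE <- matrix(
  c(1, 1, 1,   # A: purine, weak H-bond, amino
    0, 0, 1,   # C: pyrimidine, strong H-bond, amino
    1, 0, 0,   # G: purine, strong H-bond, keto
    0, 1, 0),  # T: pyrimidine, weak H-bond, keto
  nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T"), c("r", "h", "f"))
)

.EIIP_TABLE <- c(T = 0.1335, A = 0.1260, G = 0.0806, C = 0.1340)

.seq_to_ints <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) {
    stop("non-ACGT character '", chars[which(is.na(idx))[1]], "' in sequence")
  }
  idx
}

#' Nucleotide chemical property (NCP) triple
#'
#' Encodes one base as the binary triple (r, h, f): ring structure
#' (1 = purine A/G), hydrogen-bond strength (1 = weak pairing A/T) and
#' functional group (1 = amino A/C). The mapping is the bijection
#' A=(1,1,1), C=(0,0,1), G=(1,0,0), T=(0,1,0).
#'
#' @param nucleotide Single character, one of A/C/G/T.
#' @return Named numeric vector `c(r=, h=, f=)`.
#' @export
encode_ncp <- function(nucleotide) {
  if (!is.character(nucleotide) || length(nucleotide) != 1L ||
      !nucleotide %in% rownames(.NCP_TABLE)) {
    stop("nucleotide must be one of A/C/G/T")
  }
  .NCP_TABLE[nucleotide, ]
}

#' Running nucleotide density (ND)
#'
#' Component i is the frequency of the base at position i among positions
#' 1..i: `count(seq[1..i] == seq[i]) / i`. Values lie in (0, 1]; a
#' homopolymer encodes to all ones.
#'
#' @param sequence A/C/G/T string of length >= 1.
#' @return Numeric vector of length `nchar(sequence)`.
#' @export
encode_nd <- function(sequence) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  idx <- .seq_to_ints(sequence)
  n <- length(idx)
  # cumulative count of each base, picked at the positions where it occurs
  counts <- matrix(0L, nrow = n, ncol = 4L)
  counts[cbind(seq_len(n), idx)] <- 1L
  cum <- counts
  for (b in 1:4) cum[, b] <- cumsum(counts[, b])
  cum[cbind(seq_len(n), idx)] / seq_len(n)
}

#' Electron-ion interaction pseudopotential (EIIP) encoding
#'
#' Position-wise substitution with the fixed pseudopotential energies
#' T = 0.1335, A = 0.1260, G = 0.0806, C = 0.1340.
#'
#' @param sequence A/C/G/T string of length >= 1.
#' @return Numeric vector of length `nchar(sequence)`.
#' @export
encode_eiip <- function(sequence) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  vals <- unname(.EIIP_TABLE[chars])
  if (anyNA(vals)) stop("non-ACGT character in sequence")
  vals
}

#' Fit a bi-profile Bayes (BPB) model
#'
#' Estimates, for every window position, the class-conditional probability
#' of each nucleotide separately from positive and negative records:
#' `p(i, n | class) = (count + pseudocount) / (n_class + 4 * pseudocount)`.
#' Must be fitted on training records only; applying the resulting model to
#' held-out records is fine, fitting on them leaks labels.
#'
#' @param records data.frame with `sequence` and `label` columns (training
#'   rows of a validated dataset).
#' @param window_length Expected sequence length.
#' @param pseudocount Additive (Laplace) smoothing count, default 1.
#' @return A `bpb_model`: list with `positive_profile` and
#'   `negative_profile` (L x 4 matrices, columns A/C/G/T, rows summing
#'   to 1), `window_length`, `pseudocount`, and `fit_ids` (the record ids
#'   used, kept so pipelines can assert the model saw no test rows).
#' @export
fit_bpb <- function(records, window_length, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  if (!all(c(0L, 1L) %in% records$label)) {
    stop("both classes must be present to fit BPB profiles")
  }
  if (any(nchar(records$sequence) != window_length)) {
    stop("all sequences must have length ", window_length)
  }
  profile_for <- function(seqs) {
    n <- length(seqs)
    mat <- matrix(unlist(lapply(seqs, .seq_to_ints), use.names = FALSE),
                  nrow = n, byrow = TRUE)
    counts <- matrix(0, nrow = ncol(mat), ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    for (b in 1:4) counts[, b] <- colSums(mat == b)
    (counts + pseudocount) / (n + 4 * pseudocount)
  }
  structure(
    list(
      positive_profile = profile_for(records$sequence[records$label == 1L]),
      negative_profile = profile_for(records$sequence[records$label == 0L]),
      window_length = as.integer(window_length),
      pseudocount = pseudocount,
      fit_ids = records$id
    ),
    class = "bpb_model"
  )
}

#' Persist / restore a BPB model as JSON
#'
#' @param model A `bpb_model`.
#' @param path JSON path.
#' @return `write_bpb` returns `path` invisibly; `read_bpb` the model.
#' @export
write_bpb <- function(model, path) {
  stopifnot(inherits(model, "bpb_model"))
  jsonlite::write_json(
    list(positive_profile = model$positive_profile,
         negative_profile = model$negative_profile,
         window_length = model$window_length,
         pseudocount = model$pseudocount,
         fit_ids = model$fit_ids),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bpb
#' @export
read_bpb <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (p in c("positive_profile", "negative_profile")) {
    x[[p]] <- as.matrix(x[[p]])
    colnames(x[[p]]) <- c("A", "C", "G", "T")
  }
  x$window_length <- as.integer(x$window_length)
  structure(x, class = "bpb_model")
}

#' BPB encoding of one sequence
#'
#' Components 1..L are the positive-profile probabilities of the observed
#' base at each position, components L+1..2L the negative-profile ones.
#'
#' @param sequence A/C/G/T string of length `model$window_length`.
#' @param model A fitted `bpb_model`.
#' @return Numeric vector of length `2 * window_length`.
#' @export
encode_bpb <- function(sequence, model) {
  stopifnot(inherits(model, "bpb_model"))
  L <- model$window_length
  if (nchar(sequence) != L) {
    stop("sequence length ", nchar(sequence), " != model window ", L)
  }
  idx <- .seq_to_ints(sequence)
  pick <- cbind(seq_len(L), idx)
  c(model$positive_profile[pick], model$negative_profile[pick])
}

#' Full local feature vector of one sequence
#'
#' Concatenates, in fixed order, the requested feature blocks:
#' \describe{
#'   \item{NCP_ND}{per base the quadruple (r, h, f, nd) — 4L values}
#'   \item{EIIP}{L values}
#'   \item{BPB}{2L values (all p+ then all p-)}
#' }
#' Feature names are `NCPND_k` / `EIIP_k` / `BPB_k` with k a 0-based flat
#' index within each block, so downstream importance reports are stable.
#'
#' @param sequence A/C/G/T string.
#' @param model `bpb_model`, required iff "BPB" is requested.
#' @param parts Non-empty subset of `c("NCP_ND", "EIIP", "BPB")`.
#' @return Named numeric vector of length `4L*[NCP_ND] + L*[EIIP] + 2L*[BPB]`.
#' @export
encode_local <- function(sequence, model = NULL,
                         parts = c("NCP_ND", "EIIP", "BPB")) {
  parts <- match.arg(parts, several.ok = TRUE)
  out <- numeric(0)
  if ("NCP_ND" %in% parts) {
    idx <- .seq_to_ints(sequence)
    ncp <- .NCP_TABLE[idx, , drop = FALSE]
    block <- as.numeric(t(cbind(ncp, nd = encode_nd(sequence))))
    names(block) <- paste0("NCPND_", seq_along(block) - 1L)
    out <- c(out, block)
  }
  if ("EIIP" %in% parts) {
    block <- encode_eiip(sequence)
    names(block) <- paste0("EIIP_", seq_along(block) - 1L)
    out <- c(out, block)
  }
  if ("BPB" %in% parts) {
    if (is.null(model)) stop("a bpb_model is required when parts include BPB")
    block <- encode_bpb(sequence, model)
    names(block) <- paste0("BPB_", seq_along(block) - 1L)
    out <- c(out, block)
  }
  out
}

#' Local feature matrix of a whole dataset
#'
#' Applies [encode_local()] to every record, preserving row order.
#'
#' @param dataset A `promoter_dataset`.
#' @param model `bpb_model` (required iff BPB requested).
#' @param parts Feature blocks, see [encode_local()].
#' @return Numeric matrix, one row per record, named columns.
#' @export
encode_dataset <- function(dataset, model = NULL,
                           parts = c("NCP_ND", "EIIP", "BPB")) {
  stopifnot(inherits(dataset, "promoter_dataset"))
  rows <- lapply(dataset$records$sequence, encode_local,
                 model = model, parts = parts)
  mat <- do.call(rbind, rows)
  rownames(mat) <- dataset$records$id
  mat
}
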