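#' Read labeled sequence records from a FASTA file
#'
#' Reads every entry of a (optionally gzip-compressed) FASTA file, uppercases
#' the sequence and attaches a single binary class label to all records in
#' the file. Labels are file-level because promoter benchmarks ship positives
#' and negatives as separate FASTA files.
#'
#' No length or alphabet checks are performed here; ambiguous bases (e.g. N)
#' are retained so that [validate_dataset()] can apply a single, explicit
#' policy. Record order is preserved.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @param label Binary class label for every record in the file
#'   (1 = promoter, 0 = non-promoter).
#' @return A data.frame with columns `id` (character), `sequence` (character,
#'   uppercased) and `label` (integer).
#' @export
read_fasta <- function(path, label) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("empty FASTA input: ", path)
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("FASTA entry with empty sequence in ", path)
  }
  data.frame(
    id = names(seqs),
    sequence = toupper(as.character(seqs)),
    label = rep(label, length(seqs)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a promoter dataset back to FASTA
#'
#' Writes positives and negatives to two FASTA files so that reading them
#' back with [read_fasta()] round-trips sequences and labels exactly.
#'
#' @param dataset A `promoter_dataset`.
#' @param pos_path,neg_path Output FASTA paths for label-1 and label-0
#'   records.
#' @return Invisibly, a list with the two paths.
#' @export
write_fasta <- function(dataset, pos_path, neg_path) {
  stopifnot(inherits(dataset, "promoter_dataset"))
  rec <- dataset$records
  for (lab in c(1L, 0L)) {
    sel <- rec$label == lab
    ss <- Biostrings::DNAStringSet(rec$sequence[sel])
    names(ss) <- rec$id[sel]
    Biostrings::writeXStringSet(ss, if (lab == 1L) pos_path else neg_path)
  }
  invisible(list(pos = pos_path, neg = neg_path))
}

#' Validate records into a fixed-window promoter dataset
#'
#' Enforces the two dataset invariants: every sequence has exactly
#' `window_length` characters and contains only A/C/G/T. Records with
#' ambiguous bases are handled per `ambiguous_policy`: `"drop"` removes them
#' (counted in the attached validation report), `"error"` aborts. A wrong
#' length is always an error, because a truncated window has no defined TSS
#' coordinate.
#'
#' @param records data.frame as returned by [read_fasta()] (possibly several
#'   rbind-ed files).
#' @param window_length Window length L in bp.
#' @param tss_index 0-based position of the TSS within the window, e.g. 249
#'   for a \[-249, +50\] 300-bp window.
#' @param ambiguous_policy `"drop"` (default) or `"error"`.
#' @return A `promoter_dataset`: list with `records` (data.frame id/sequence/
#'   label), `window_length`, `tss_index`, and a `dropped` data.frame
#'   (id, reason) describing removed records.
#' @export
validate_dataset <- function(records, window_length, tss_index,
                             ambiguous_policy = c("drop", "error")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  stopifnot(window_length > 0, tss_index >= 0, tss_index < window_length)
  if (nrow(records) == 0L) stop("no records to validate")

  lens <- nchar(records$sequence)
  if (any(lens != window_length)) {
    bad <- records$id[lens != window_length][1L]
    stop("record '", bad, "' has length ", lens[lens != window_length][1L],
         ", expected ", window_length)
  }
  clean <- grepl("^[ACGT]+$", records$sequence)
  if (!all(clean)) {
    if (ambiguous_policy == "error") {
      stop("record '", records$id[!clean][1L],
           "' contains non-ACGT characters")
    }
    message(sum(!clean), " record(s) dropped for ambiguous bases")
  }
  dropped <- data.frame(
    id = records$id[!clean],
    reason = rep("ambiguous_base", sum(!clean)),
    stringsAsFactors = FALSE
  )
  kept <- records[clean, , drop = FALSE]
  row.names(kept) <- NULL
  if (nrow(kept) == 0L) stop("all records dropped during validation")
  structure(
    list(records = kept, window_length = as.integer(window_length),
         tss_index = as.integer(tss_index), dropped = dropped),
    class = "promoter_dataset"
  )
}

#' @export
print.promoter_dataset <- function(x, ...) {
  cat("promoter_dataset:", nrow(x$records), "records,",
      "window", x$window_length, "bp, TSS at index", x$tss_index, "\n")
  cat("  positives:", sum(x$records$label == 1L),
      " negatives:", sum(x$records$label == 0L), "\n")
  invisible(x)
}

#' Write the validation report as tab-separated text
#'
#' @param dataset A `promoter_dataset`.
#' @param path Output TSV path (columns: id, reason).
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(dataset, path) {
  stopifnot(inherits(dataset, "promoter_dataset"))
  utils::write.table(dataset$dropped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits record indices into disjoint train and test sets, stratified by
#' class. The per-class test count is `round(class_size * test_fraction)`
#' (round-half-to-even), so class proportions in both parts match the full
#' dataset to within one record per class. Deterministic for a fixed seed.
#'
#' @param dataset A `promoter_dataset`.
#' @param test_fraction Fraction of each class assigned to the test set;
#'   the 4:1 protocol corresponds to 0.2.
#' @param seed Integer RNG seed.
#' @return A list with integer vectors `train_indices` and `test_indices`
#'   (1-based row indices into `dataset$records`), class `data_split`.
#' @export
stratified_split <- function(dataset, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "promoter_dataset"),
            test_fraction > 0, test_fraction < 1)
  labels <- dataset$records$label
  test_idx <- integer(0)
  for (cls in sort(unique(labels))) {
    members <- which(labels == cls)
    if (length(members) < 2L) {
      stop("class ", cls, " has fewer than 2 members; cannot stratify")
    }
    n_test <- round(length(members) * test_fraction)
    n_test <- max(1L, min(length(members) - 1L, as.integer(n_test)))
    test_idx <- c(test_idx, local({
      set.seed(seed + cls)  # per-class substream, still fully seeded
      sample(members, n_test)
    }))
  }
  test_idx <- sort(test_idx)
  structure(
    list(train_indices = setdiff(seq_along(labels), test_idx),
         test_indices = test_idx),
    class = "data_split"
  )
}
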