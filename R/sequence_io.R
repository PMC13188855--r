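#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the accepted alphabet
#' (20 canonical amino acids plus the ambiguity / nonstandard codes
#' X, B, Z, U, O). Record order is preserved.
#'
#' @param path Path to a FASTA file (multi-line records allowed).
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   each header) and `sequence`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "MKTAYIAK", ">s2", "gvsae"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("failed to parse FASTA '%s': %s",
                                      path, conditionMessage(e)))
  )
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) abort("FASTA contains an empty header")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as.character(set)
  seqs <- mapply(.validate_sequence, seqs, ids, USE.NAMES = FALSE)
  tibble(id = ids, sequence = seqs)
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for wrapping sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(toupper(records$sequence), records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a multi-label annotation table
#'
#' The table is comma-delimited with a header and columns `id` and
#' `labels`; multiple labels per sequence are joined with `;`
#' (e.g. `"PET;PCL"`). An empty label field marks a negative sequence
#' (all-zero label vector).
#'
#' @param path Path to the CSV label table.
#' @param records Optional tibble of records (from [read_fasta()]); when
#'   supplied, every record id must be present in the table, and table
#'   rows for unknown ids are dropped with a warning.
#' @return A tibble with column `id` plus one 0/1 indicator column per
#'   class, in canonical label order ([plastic_labels()]).
#' @export
read_labels <- function(path, records = NULL) {
  if (!file.exists(path)) abort(sprintf("label table not found: %s", path))
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("id", "labels") %in% names(tbl))) {
    abort("label table must have columns 'id' and 'labels'")
  }
  if (anyDuplicated(tbl$id)) {
    abort(sprintf("duplicate id row(s) in label table: %s",
                  paste(unique(tbl$id[duplicated(tbl$id)]), collapse = ", ")))
  }
  tbl$labels[is.na(tbl$labels)] <- ""
  lab_sets <- strsplit(tbl$labels, ";", fixed = TRUE)
  lab_sets <- lapply(lab_sets, function(x) trimws(x[nzchar(trimws(x))]))
  unknown <- setdiff(unique(unlist(lab_sets)), plastic_labels())
  if (length(unknown) > 0) {
    abort(sprintf("unknown label(s) %s; valid labels are: %s",
                  paste(unknown, collapse = ", "),
                  paste(plastic_labels(), collapse = ", ")))
  }
  out <- labels_to_tibble(tbl$id, lab_sets)
  if (!is.null(records)) {
    missing <- setdiff(records$id, out$id)
    if (length(missing) > 0) {
      abort(sprintf("no label row for record id(s): %s",
                    paste(missing, collapse = ", ")))
    }
    extra <- setdiff(out$id, records$id)
    if (length(extra) > 0) {
      warn(sprintf("%d label row(s) without a matching record skipped: %s",
                   length(extra), paste(head(extra, 5), collapse = ", ")))
      out <- out[out$id %in% records$id, , drop = FALSE]
    }
    out <- out[match(records$id, out$id), , drop = FALSE]
  }
  out
}

# ids + list of label character vectors -> wide 0/1 tibble
labels_to_tibble <- function(ids, label_sets) {
  mat <- matrix(0L, nrow = length(ids), ncol = length(plastic_labels()),
                dimnames = list(NULL, plastic_labels()))
  for (i in seq_along(label_sets)) {
    if (length(label_sets[[i]]) > 0) mat[i, label_sets[[i]]] <- 1L
  }
  dplyr::bind_cols(tibble(id = ids), as_tibble(mat))
}

#' Extract the binary label matrix from a label tibble
#'
#' @param labels Tibble as returned by [read_labels()].
#' @return Integer matrix (sequences x 9) with `id` as rownames.
#' @export
label_matrix <- function(labels) {
  stopifnot(all(plastic_labels() %in% names(labels)))
  mat <- as.matrix(labels[, plastic_labels()])
  storage.mode(mat) <- "integer"
  rownames(mat) <- labels$id
  mat
}

#' One-hot encode a protein sequence
#'
#' Produces the fixed-size input consumed by the network: a 1000 x 21
#' binary matrix whose first `effective_length` rows are one-hot over 21
#' channels (20 canonical amino acids, one shared channel for the
#' ambiguity codes X, B, Z, U, O) and whose remaining rows are all zero.
#' Sequences longer than `input_length` are truncated at the C-terminus
#' (the first `input_length` residues are kept).
#'
#' @param sequence A single amino-acid sequence string.
#' @param id Optional source identifier stored on the result.
#' @param input_length Number of rows of the encoding (default 1000).
#' @return An `encoded_sequence`: the binary matrix with attributes
#'   `effective_length` and `source_id`.
#' @export
#' @examples
#' enc <- encode_one_hot("MKTAYIAK")
#' attr(enc, "effective_length")
encode_one_hot <- function(sequence, id = "", input_length = 1000L) {
  stopifnot(length(sequence) == 1L)
  sequence <- .validate_sequence(sequence, if (nzchar(id)) id else "<unnamed>")
  chans <- .seq_to_channels(sequence)
  leff <- min(length(chans), input_length)
  mat <- matrix(0L, nrow = input_length, ncol = 21L,
                dimnames = list(NULL, c(.aa_canonical, "other")))
  mat[cbind(seq_len(leff), chans[seq_len(leff)] + 1L)] <- 1L
  structure(mat,
            effective_length = leff,
            source_id = id,
            class = c("encoded_sequence", class(mat)))
}

# records tibble -> internal batch: list of 0-based channel vectors,
# truncated to input_length, plus effective lengths
.encode_batch <- function(records, input_length = 1000L) {
  seqs <- lapply(records$sequence, function(s) {
    ch <- .seq_to_channels(.validate_sequence(s, "<record>"))
    if (length(ch) > input_length) ch <- ch[seq_len(input_length)]
    as.integer(ch)
  })
  list(seqs = seqs,
       leff = vapply(seqs, length, integer(1)),
       ids = records$id)
}
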