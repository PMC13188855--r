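#' Read a BLAST tabular hit file
#'
#' Parses the standard 12-column tabular output (`-outfmt 6`: qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore), optionally extended with qlen and slen as
#' columns 13-14. When the length columns are absent they can be filled
#' from companion FASTA records via `query_records` / `subject_records`.
#'
#' @param path Path to the tab-separated hit file (no header).
#' @param query_records,subject_records Optional record tibbles (from
#'   [read_fasta()]) used to supply `query_length` / `subject_length`
#'   when the file has only 12 columns.
#' @return Tibble of hits: `query_id`, `subject_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`,
#'   and (when available) `query_length`, `subject_length`.
#' @export
read_blast_hits <- function(path, query_records = NULL,
                            subject_records = NULL) {
  if (!file.exists(path)) abort(sprintf("hit file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), align_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  e_value = numeric(), bit_score = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (!all(ncols %in% c(12L, 14L)) || length(unique(ncols)) != 1) {
    bad <- which(!(ncols %in% c(12L, 14L)) | ncols != ncols[1])[1]
    abort(sprintf("malformed hit row at line %d: expected 12 or 14 tab-separated fields, found %d",
                  bad, ncols[bad]))
  }
  num_cols <- c(3:12, if (ncols[1] == 14L) 13:14)
  mat <- do.call(rbind, fields)
  nums <- suppressWarnings(apply(mat[, num_cols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, nrow = nrow(mat))
  if (anyNA(nums)) {
    bad <- which(apply(nums, 1, anyNA))[1]
    abort(sprintf("malformed numeric field at line %d", bad))
  }
  hits <- tibble(query_id = mat[, 1], subject_id = mat[, 2],
                 percent_identity = nums[, 1],
                 align_length = as.integer(nums[, 2]),
                 mismatches = as.integer(nums[, 3]),
                 gap_opens = as.integer(nums[, 4]),
                 q_start = as.integer(nums[, 5]),
                 q_end = as.integer(nums[, 6]),
                 s_start = as.integer(nums[, 7]),
                 s_end = as.integer(nums[, 8]),
                 e_value = nums[, 9], bit_score = nums[, 10])
  if (ncols[1] == 14L) {
    hits$query_length <- as.integer(nums[, 11])
    hits$subject_length <- as.integer(nums[, 12])
  } else {
    if (!is.null(query_records)) {
      hits$query_length <- nchar(query_records$sequence)[
        match(hits$query_id, query_records$id)]
    }
    if (!is.null(subject_records)) {
      hits$subject_length <- nchar(subject_records$sequence)[
        match(hits$subject_id, subject_records$id)]
    }
  }
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    abort("percent identity outside [0, 100]")
  }
  hits
}

#' Filter alignment hits for dataset expansion
#'
#' A hit survives iff its bit-score is at least `min_bitscore` AND its
#' percent identity is at least `min_identity` (both bounds inclusive)
#' AND the subject's length differs from the query's by at most
#' `max_length_ratio` of the query length. The three filters are
#' independent, so the result is order-invariant and filtering is
#' idempotent.
#'
#' @param hits Hit tibble from [read_blast_hits()], with
#'   `query_length` / `subject_length` columns (or supplied via
#'   `query_records` / `subject_records` there).
#' @param min_bitscore Minimum bit-score (default 100, inclusive).
#' @param min_identity Minimum percent identity (default 85, inclusive).
#' @param max_length_ratio Maximum allowed
#'   `|subject_length - query_length| / query_length` (default 0.2);
#'   set `NULL` to skip the length filter.
#' @return The surviving hits (a subset of the input rows, order
#'   preserved).
#' @export
filter_hits <- function(hits, min_bitscore = 100, min_identity = 85,
                        max_length_ratio = 0.2) {
  if (nrow(hits) == 0) return(hits)
  keep <- hits$bit_score >= min_bitscore &
    hits$percent_identity >= min_identity
  if (!is.null(max_length_ratio)) {
    if (!all(c("query_length", "subject_length") %in% names(hits))) {
      abort("length filter requires query_length and subject_length columns")
    }
    if (any(hits$query_length < 1 | hits$subject_length < 1)) {
      abort("sequence lengths must be >= 1")
    }
    keep <- keep & (abs(hits$subject_length - hits$query_length) /
                      hits$query_length) <= max_length_ratio
  }
  hits[keep, , drop = FALSE]
}

#' Unique subjects surviving the hit filters
#'
#' Identity filtering is applied per hit; this helper deduplicates the
#' surviving subject ids afterwards (a subject hit by several queries is
#' reported once).
#'
#' @param hits Filtered hit tibble.
#' @return Character vector of unique subject ids, in first-appearance
#'   order.
#' @export
surviving_subjects <- function(hits) unique(hits$subject_id)

#' Exclude candidates overlapping a reference set
#'
#' A candidate is removed iff any of its alignments against the
#' reference set shows identity strictly above `identity_threshold`
#' (a candidate at exactly the threshold is retained). Candidates with
#' no row in the identity table are retained with a warning.
#'
#' @param candidates Tibble with an `id` column (e.g. records), or a
#'   character vector of ids.
#' @param identity_table Tibble of candidate-vs-reference alignments
#'   with columns `query_id` (candidate) and `percent_identity`
#'   (alignment itself is external, e.g. BLASTp).
#' @param identity_threshold Exclusion threshold in percent (default
#'   80, strict).
#' @return The retained candidates, same type as the input.
#' @export
exclude_overlap <- function(candidates, identity_table,
                            identity_threshold = 80) {
  ids <- if (is.data.frame(candidates)) candidates$id else candidates
  if (nrow(identity_table) == 0) {
    best <- setNames(rep(NA_real_, length(ids)), ids)
  } else {
    agg <- identity_table |>
      dplyr::group_by(.data$query_id) |>
      dplyr::summarise(best = max(.data$percent_identity), .groups = "drop")
    best <- setNames(agg$best, agg$query_id)[ids]
  }
  missing <- ids[is.na(best)]
  if (length(missing) > 0) {
    warn(sprintf("%d candidate(s) absent from the identity table retained: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  keep <- is.na(best) | best <= identity_threshold
  if (is.data.frame(candidates)) candidates[keep, , drop = FALSE] else ids[keep]
}
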