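#' Published per-class sequence counts of the reference datasets
#'
#' The per-class positive counts of the two datasets the reference
#' classifier was developed on: the experimentally curated set (181
#' non-redundant sequences) and the similarity-expanded model
#' development set (5,927 sequences). Sequences are multi-labelled, so
#' counts sum to more than the number of sequences.
#'
#' @return List with `counts` (tibble `class`, `count`) and
#'   `n_sequences` (the dataset size used as the percentage
#'   denominator).
#' @export
curated_dataset_counts <- function() {
  list(counts = .read_counts("curated_class_counts.csv"),
       n_sequences = 181L)
}

#' @rdname curated_dataset_counts
#' @export
development_dataset_counts <- function() {
  list(counts = .read_counts("development_class_counts.csv"),
       n_sequences = 5927L)
}

.read_counts <- function(file) {
  path <- system.file("extdata", file, package = "pdecnn", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    class = readr::col_character(), count = readr::col_integer()))
}

#' Per-class composition of a multi-label dataset
#'
#' Recomputes each class's share of sequences,
#' `percent = 100 * count / n_sequences` (multi-label, so shares do not
#' sum to 100).
#'
#' @param counts Tibble with columns `class` and `count`, or a list as
#'   returned by [curated_dataset_counts()].
#' @param n_sequences Number of sequences in the dataset (taken from
#'   the list when `counts` is one).
#' @return Tibble: `class`, `count`, `percent`.
#' @export
#' @examples
#' class_composition(curated_dataset_counts())
class_composition <- function(counts, n_sequences = NULL) {
  if (is.list(counts) && !is.data.frame(counts) &&
      all(c("counts", "n_sequences") %in% names(counts))) {
    n_sequences <- counts$n_sequences
    counts <- counts$counts
  }
  if (is.null(n_sequences) || n_sequences < 1) {
    abort("n_sequences must be supplied and positive")
  }
  dplyr::mutate(counts, percent = 100 * .data$count / n_sequences)
}
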