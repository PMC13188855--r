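#' Assemble a prediction table
#'
#' Binds per-sequence class probabilities, thresholded 0/1 calls and
#' true labels into one object the metric functions consume. A call is
#' positive iff its probability is at least the class threshold.
#'
#' @param probabilities Tibble from [predict.pde_cnn()] (`id` + one
#'   probability column per class) or a bare matrix.
#' @param truth Label tibble (see [read_labels()]) or binary matrix
#'   aligned with the probability rows.
#' @param thresholds Per-class decision thresholds (default uniform
#'   0.5).
#' @return A `prediction_table` list with matrices `probs`, `calls`,
#'   `truth` and the `thresholds`.
#' @export
prediction_table <- function(probabilities, truth, thresholds = NULL) {
  if (is.data.frame(probabilities)) {
    ids <- probabilities$id %||% as.character(seq_len(nrow(probabilities)))
    probs <- as.matrix(probabilities[, setdiff(names(probabilities), "id")])
  } else {
    probs <- as.matrix(probabilities)
    ids <- rownames(probs) %||% as.character(seq_len(nrow(probs)))
  }
  truth_m <- if (is.data.frame(truth)) {
    label_matrix(truth)[ids, colnames(probs), drop = FALSE]
  } else {
    as.matrix(truth)
  }
  if (!all(dim(probs) == dim(truth_m))) {
    abort("probabilities and truth shapes differ")
  }
  if (nrow(probs) == 0) abort("empty prediction table")
  thresholds <- thresholds %||% rep(0.5, ncol(probs))
  if (length(thresholds) != ncol(probs)) {
    abort("one threshold per class required")
  }
  calls <- sweep(probs, 2, thresholds, `>=`) * 1L
  structure(list(ids = ids, probs = probs, calls = calls,
                 truth = truth_m, thresholds = as.numeric(thresholds)),
            class = "prediction_table")
}

#' Micro-averaged precision, recall and F1
#'
#' True/false positives and false negatives are pooled over all
#' sequence-class pairs; precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 their harmonic mean. A zero denominator yields 0 with a warning.
#'
#' @param table A [prediction_table()].
#' @return One-row tibble: `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `fn`.
#' @export
micro_metrics <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  cnt <- .micro_counts(table$calls, table$truth)
  precision <- if (cnt[["tp"]] + cnt[["fp"]] == 0) {
    warn("no positive calls; precision set to 0")
    0
  } else cnt[["tp"]] / (cnt[["tp"]] + cnt[["fp"]])
  recall <- if (cnt[["tp"]] + cnt[["fn"]] == 0) {
    warn("no positive labels; recall set to 0")
    0
  } else cnt[["tp"]] / (cnt[["tp"]] + cnt[["fn"]])
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble(precision = precision, recall = recall, f1 = f1,
         tp = cnt[["tp"]], fp = cnt[["fp"]], fn = cnt[["fn"]])
}

#' False discovery rate on a negative set
#'
#' Defined here as the fraction of known-negative sequences (true label
#' vector all zero) that receive at least one positive class call. This
#' per-sequence any-label definition is used because the negative set
#' carries no positive labels at all, so the classical FP/(FP+TP) ratio
#' is not computable on it.
#'
#' @param table A [prediction_table()] whose rows are all-negative
#'   sequences (rows with positive true labels are an error).
#' @return Fraction in \[0, 1\].
#' @export
false_discovery_rate <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  if (nrow(table$truth) == 0) abort("empty negative table")
  if (any(rowSums(table$truth) > 0)) {
    abort("false_discovery_rate expects only sequences with all-zero true labels")
  }
  mean(rowSums(table$calls) > 0)
}

#' Paired comparison of repeated metric values
#'
#' Two-sided Wilcoxon signed-rank test on paired per-repeat metric
#' vectors (e.g. micro-F1 of two models across the same repeated
#' hold-out splits). By default zero differences are dropped and the
#' exact null distribution is used for up to 25 non-zero pairs (normal
#' approximation beyond, or when ties are present); the Pratt variant
#' ranks zeros before discarding them and always uses the normal
#' approximation.
#'
#' @param scores_a,scores_b Equal-length paired metric vectors
#'   (length >= 5).
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @return One-row tibble: `statistic` (V, sum of positive ranks),
#'   `p_value`, `n`, `n_zero`, `method`.
#' @export
paired_comparison <- function(scores_a, scores_b,
                              zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(scores_a) != length(scores_b)) {
    abort("paired vectors must have equal length")
  }
  if (length(scores_a) < 5) abort("need at least 5 paired values")
  d <- scores_a - scores_b
  n_zero <- sum(d == 0)
  if (all(d == 0)) {
    warn("all paired differences are zero; p = 1")
    return(tibble(statistic = 0, p_value = 1, n = length(d),
                  n_zero = n_zero, method = zero_method))
  }
  if (zero_method == "drop") {
    dz <- d[d != 0]
    exact <- length(dz) <= 25 && !anyDuplicated(abs(dz))
    res <- suppressWarnings(
      stats::wilcox.test(scores_a, scores_b, paired = TRUE,
                         exact = exact, correct = TRUE)
    )
    return(tibble(statistic = unname(res$statistic),
                  p_value = res$p.value, n = length(d),
                  n_zero = n_zero, method = "drop"))
  }
  # Pratt: rank |d| with zeros included, discard zero ranks from the
  # statistic, normal approximation with tie correction
  r <- rank(abs(d))
  nz <- d != 0
  v <- sum(r[nz & d > 0])
  n <- length(d)
  mu <- n * (n + 1) / 4 - n_zero * (n_zero + 1) / 4
  ties <- table(r[nz])
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    n_zero * (n_zero + 1) * (2 * n_zero + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (v - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  tibble(statistic = v, p_value = min(1, p), n = n,
         n_zero = n_zero, method = "pratt")
}

#' Summarize a metric across repeated hold-out experiments
#'
#' Mean with a t-based 95% confidence interval,
#' mean \eqn{\pm t_{0.975, n-1} \cdot \mathrm{SE}}.
#'
#' @param values Numeric vector of per-repeat metric values (length
#'   >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `n`, `mean`, `sd`, `se`, `ci_lower`,
#'   `ci_upper`, `ci_half_width`.
#' @export
summarize_repeats <- function(values, conf_level = 0.95) {
  if (length(values) < 2) abort("need at least 2 repeat values")
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  se <- s / sqrt(n)
  hw <- qt(1 - (1 - conf_level) / 2, df = n - 1) * se
  tibble(n = n, mean = m, sd = s, se = se,
         ci_lower = m - hw, ci_upper = m + hw, ci_half_width = hw)
}
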