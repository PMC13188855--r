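#' Rank activation maps by gradient importance
#'
#' For a single sequence and target class, computes the importance
#' \eqn{\alpha_m = \partial y_c / \partial \beta_m} of every
#' convolutional filter: the exact gradient of the pre-sigmoid class
#' logit \eqn{y_c} with respect to the filter's 1-max-pooled activation
#' \eqn{\beta_m}, obtained by backpropagation through the fully
#' connected head. Maps are ranked by descending signed \eqn{\alpha_m}
#' within each kernel length.
#'
#' @param model A fitted `pde_cnn`.
#' @param record Single-row records tibble, or one sequence string.
#' @param class_c Target class: label name or index.
#' @return An `activation_ranking`: list with `table` (tibble:
#'   `kernel_length`, `filter`, `alpha`, `beta`, `rank`), the per-branch
#'   activation maps `phi` (post-ReLU, one column per filter, one row
#'   per window position, length `input_length - l + 1`), the class, the
#'   effective length, and the class logit.
#' @export
rank_activation_maps <- function(model, record, class_c) {
  stopifnot(inherits(model, "pde_cnn"))
  if (is.character(record)) record <- tibble(id = "query", sequence = record)
  stopifnot(nrow(record) == 1L)
  ci <- .resolve_class(model, class_c)
  batch <- .encode_batch(record, model$config$input_length)
  detail <- .cpp_cnn_detail(model$ptr, batch$seqs[[1]], batch$leff[[1]])
  alpha <- as.numeric(.cpp_cnn_alpha(model$ptr, batch$seqs[[1]],
                                     batch$leff[[1]], ci - 1L))
  klens <- model$config$kernel_lengths
  F <- model$config$filters_per_branch
  tab <- purrr::map_dfr(seq_along(klens), function(bi) {
    a <- alpha[(bi - 1L) * F + seq_len(F)]
    tibble(kernel_length = klens[bi],
           filter = seq_len(F),
           alpha = a,
           beta = as.numeric(detail$beta[[bi]]))
  })
  tab <- tab |>
    dplyr::group_by(.data$kernel_length) |>
    dplyr::arrange(dplyr::desc(.data$alpha), .data$filter,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  phi <- detail$phi
  names(phi) <- as.character(klens)
  structure(list(table = tab, phi = phi,
                 kernel_lengths = klens,
                 filters_per_branch = F,
                 class = model$labels[ci],
                 effective_length = batch$leff[[1]],
                 input_length = model$config$input_length,
                 sequence = record$sequence[[1]],
                 id = record$id[[1]],
                 logit = unname(detail$logits[ci])),
            class = "activation_ranking")
}

.resolve_class <- function(model, class_c) {
  if (is.character(class_c)) {
    ci <- match(class_c, model$labels)
    if (is.na(ci)) {
      abort(sprintf("unknown class '%s'; valid classes: %s",
                    class_c, paste(model$labels, collapse = ", ")))
    }
    return(ci)
  }
  ci <- as.integer(class_c)
  if (ci < 1L || ci > model$config$n_classes) {
    abort(sprintf("class index %d out of range [1, %d]",
                  ci, model$config$n_classes))
  }
  ci
}

#' Sum the top-K activation maps per kernel length
#'
#' For each kernel length, the K maps with the highest positive
#' importance \eqn{\alpha_m} are selected and their post-ReLU activation
#' vectors summed position-wise into the window contribution
#' \eqn{\zeta^l}. Maps with \eqn{\alpha_m \le 0} are never selected
#' (they argue against the prediction); K is capped at the number of
#' filters per branch with a warning.
#'
#' @param ranking An `activation_ranking`.
#' @param K Number of maps per kernel length (default 50).
#' @param alpha_weighted Weight each selected map by its \eqn{\alpha_m}
#'   (non-default variant; the reference procedure sums activations
#'   unweighted).
#' @return Named list of numeric vectors \eqn{\zeta^l}, one per kernel
#'   length, each of window-extent length `input_length - l + 1`, all
#'   entries non-negative (when `alpha_weighted = FALSE`).
#' @export
window_contributions <- function(ranking, K = 50L, alpha_weighted = FALSE) {
  stopifnot(inherits(ranking, "activation_ranking"))
  if (K <= 0) abort("K must be >= 1")
  F <- ranking$filters_per_branch
  if (K > F) {
    warn(sprintf("K = %d exceeds the %d filters per branch; using K = %d",
                 K, F, F))
    K <- F
  }
  out <- lapply(as.character(ranking$kernel_lengths), function(lc) {
    phi <- ranking$phi[[lc]]
    sel <- ranking$table |>
      dplyr::filter(.data$kernel_length == as.integer(lc),
                    .data$rank <= K, .data$alpha > 0)
    zeta <- numeric(nrow(phi))
    if (nrow(sel) > 0) {
      w <- if (alpha_weighted) sel$alpha else rep(1, nrow(sel))
      zeta <- as.numeric(phi[, sel$filter, drop = FALSE] %*% w)
    }
    zeta
  })
  names(out) <- as.character(ranking$kernel_lengths)
  out
}

#' Redistribute window contributions onto residues
#'
#' Each window's contribution \eqn{\zeta^l_s} covers `l` consecutive
#' residues; the per-residue score averages over all valid windows
#' containing residue i:
#' \deqn{\tau^l_i = \frac{1}{l} \sum_{s = \max(1, i-l+1)}^{\min(i,\,L-l+1)} \zeta^l_s}
#' Terminal residues are covered by fewer than `l` windows and so
#' receive proportionally smaller mass (the 1/l factor is constant).
#' When the content spans the full input, total mass is conserved:
#' \eqn{\sum_i \tau^l_i = \sum_s \zeta^l_s}.
#'
#' @param zeta Window contribution vector for one kernel length.
#' @param l The kernel length.
#' @param effective_length Number of residues to score (padding
#'   positions are dropped).
#' @return Numeric vector \eqn{\tau^l} of length `effective_length`.
#' @export
#' @examples
#' residue_scores(c(1, 2), l = 2, effective_length = 3) # 0.5, 1.5, 1.0
residue_scores <- function(zeta, l, effective_length) {
  map_len <- length(zeta)
  if (effective_length > map_len + l - 1) {
    abort("effective_length exceeds the extent covered by the windows")
  }
  cs <- c(0, cumsum(zeta))
  i <- seq_len(effective_length)
  lo <- pmax(1L, i - l + 1L)
  hi <- pmin(i, map_len)
  (cs[hi + 1L] - cs[lo]) / l
}

#' Aggregate per-kernel residue scores into a contribution profile
#'
#' Element-wise sum across kernel lengths:
#' \eqn{\tau_i = \sum_l \tau^l_i}.
#'
#' @param taus Named list of per-kernel residue score vectors (names are
#'   kernel lengths), all of the same length.
#' @param class Target class label to record.
#' @param K The K used for map selection.
#' @return A `contribution_profile` tibble: `position`, one `tau_<l>`
#'   column per kernel length, and the aggregate `tau`.
#' @export
aggregate_profile <- function(taus, class = NA_character_, K = NA_integer_) {
  lens <- lengths(taus)
  if (length(unique(lens)) != 1) {
    abort("per-kernel score vectors differ in length")
  }
  out <- tibble(position = seq_len(lens[[1]]))
  for (nm in names(taus)) out[[paste0("tau_", nm)]] <- taus[[nm]]
  out$tau <- Reduce(`+`, taus)
  structure(out, class = c("contribution_profile", class(out)),
            target_class = class, K = K)
}

#' Residue-level contribution scores for one sequence
#'
#' The full interpretation pipeline: rank all activation maps by
#' \eqn{\alpha_m} ([rank_activation_maps()]), select the top-K maps of
#' each kernel length and sum their activations into window
#' contributions \eqn{\zeta^l} ([window_contributions()]), redistribute
#' each \eqn{\zeta^l} onto residues ([residue_scores()]), and aggregate
#' across kernel lengths ([aggregate_profile()]). Deterministic in
#' inference mode.
#'
#' @inheritParams rank_activation_maps
#' @param K Number of activation maps selected per kernel length.
#' @param alpha_weighted See [window_contributions()].
#' @return A `contribution_profile` tibble with columns `position`,
#'   `residue`, `tau_<l>` per kernel length, and `tau`, one row per
#'   residue of the (possibly truncated) sequence.
#' @export
interpret <- function(model, record, class_c, K = 50L,
                      alpha_weighted = FALSE) {
  ranking <- rank_activation_maps(model, record, class_c)
  zetas <- window_contributions(ranking, K = K,
                                alpha_weighted = alpha_weighted)
  leff <- ranking$effective_length
  taus <- purrr::imap(zetas, function(z, lc) {
    residue_scores(z, as.integer(lc), leff)
  })
  prof <- aggregate_profile(taus, class = ranking$class, K = K)
  residues <- strsplit(toupper(ranking$sequence), "", fixed = TRUE)[[1]]
  prof <- dplyr::mutate(prof, residue = residues[.data$position],
                        .after = "position")
  attr(prof, "id") <- ranking$id
  attr(prof, "logit") <- ranking$logit
  prof
}

#' Write a contribution profile to CSV
#'
#' Columns: `position`, `residue`, one `tau_<l>` per kernel length, and
#' `tau_total`.
#'
#' @param profile A `contribution_profile` from [interpret()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- as_tibble(profile)
  names(out)[names(out) == "tau"] <- "tau_total"
  readr::write_csv(out, path)
  invisible(path)
}
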