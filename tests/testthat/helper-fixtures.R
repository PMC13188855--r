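# Shared fixtures: tiny deterministic models and datasets built in code.

# a small fully specified configuration used across tests
tiny_config <- function(...) {
  args <- list(kernel_lengths = c(2L, 3L), filters_per_branch = 4L,
               fc_sizes = c(5L), n_classes = 3L, input_length = 12L,
               dropout = 0)
  do.call(model_config, utils::modifyList(args, list(...)))
}

# model with every weight and bias set to zero
zero_model <- function(config = tiny_config(), labels = NULL) {
  m <- build_model(config, seed = 1, labels = labels)
  p <- model_parameters(m)
  p$branches <- lapply(p$branches, function(b) { b$W[] <- 0; b$b[] <- 0; b })
  p$fc <- lapply(p$fc, function(f) { f$W[] <- 0; f$b[] <- 0; f })
  set_model_parameters(m, p)
}

# R replica of the fully connected head (inference mode), for
# finite-difference oracles that perturb the pooled vector
fc_logit_oracle <- function(params, pooled, class_idx) {
  h <- pooled
  L <- length(params$fc)
  for (i in seq_len(L)) {
    z <- drop(t(params$fc[[i]]$W) %*% h + params$fc[[i]]$b)
    h <- if (i < L) pmax(z, 0) else z
  }
  h[class_idx]
}

# brute-force sliding-window convolution + ReLU over a one-hot matrix:
# the independent oracle for activation maps
conv_oracle <- function(onehot, W, b, l) {
  input_length <- nrow(onehot)
  channels <- ncol(onehot)
  n_filters <- ncol(W)
  map_len <- input_length - l + 1
  phi <- matrix(0, map_len, n_filters)
  for (k in seq_len(map_len)) {
    window <- as.numeric(t(onehot[k:(k + l - 1), , drop = FALSE]))
    # rows of W are ordered position-major: (j - 1) * channels + channel
    z <- drop(window %*% W) + b
    phi[k, ] <- pmax(z, 0)
  }
  phi
}

# direct enumeration of the residue redistribution formula (per-residue
# average over all valid covering windows), the oracle for residue_scores
residue_scores_oracle <- function(zeta, l, effective_length) {
  map_len <- length(zeta)
  vapply(seq_len(effective_length), function(i) {
    s <- max(1, i - l + 1):min(i, map_len)
    sum(zeta[s]) / l
  }, numeric(1))
}

# construct an activation_ranking by hand (documented structure), used to
# test the window-contribution arithmetic in isolation
manual_ranking <- function(phi_list, alpha_list, kernel_lengths,
                           effective_length) {
  F <- ncol(phi_list[[1]])
  tab <- purrr::map_dfr(seq_along(kernel_lengths), function(bi) {
    tibble::tibble(kernel_length = kernel_lengths[bi], filter = seq_len(F),
                   alpha = alpha_list[[bi]], beta = apply(phi_list[[bi]], 2, max))
  })
  tab <- tab |>
    dplyr::group_by(kernel_length) |>
    dplyr::arrange(dplyr::desc(alpha), filter, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  names(phi_list) <- as.character(kernel_lengths)
  structure(list(table = tab, phi = phi_list,
                 kernel_lengths = kernel_lengths, filters_per_branch = F,
                 class = "PET", effective_length = effective_length,
                 input_length = nrow(phi_list[[1]]) + kernel_lengths[1] - 1,
                 sequence = "", id = "manual", logit = 0),
            class = "activation_ranking")
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

write_temp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
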