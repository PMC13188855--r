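#' Model architecture configuration
#'
#' Hyperparameters of the three-branch convolutional multi-label
#' classifier. The defaults reproduce the reference architecture: three
#' parallel 1D convolutions with kernel lengths 4, 8 and 16 positions
#' (each kernel spans all 21 input channels), 128 filters per branch with
#' ReLU, 1-max pooling, concatenation into a 384-dimensional feature
#' vector, fully connected layers of sizes 512 and 512 with ReLU and
#' dropout 0.1, and a final sigmoid layer with one output per class.
#'
#' @param kernel_lengths Integer vector of kernel lengths (positions).
#' @param filters_per_branch Filters per convolutional branch.
#' @param fc_sizes Sizes of the hidden fully connected layers.
#' @param n_classes Number of output classes.
#' @param dropout Dropout fraction applied after each hidden FC layer
#'   during training.
#' @param input_length Fixed number of input positions.
#' @param channels Number of input channels.
#' @return A `model_config` list.
#' @export
model_config <- function(kernel_lengths = c(4L, 8L, 16L),
                         filters_per_branch = 128L,
                         fc_sizes = c(512L, 512L),
                         n_classes = 9L,
                         dropout = 0.1,
                         input_length = 1000L,
                         channels = 21L) {
  kernel_lengths <- as.integer(kernel_lengths)
  if (length(kernel_lengths) == 0) abort("kernel_lengths must be non-empty")
  if (any(kernel_lengths < 1L) || any(kernel_lengths > input_length)) {
    abort("each kernel length must lie in [1, input_length]")
  }
  if (filters_per_branch < 1L) abort("filters_per_branch must be >= 1")
  if (n_classes < 1L) abort("n_classes must be >= 1")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(list(kernel_lengths = kernel_lengths,
                 filters_per_branch = as.integer(filters_per_branch),
                 fc_sizes = as.integer(fc_sizes),
                 n_classes = as.integer(n_classes),
                 dropout = dropout,
                 input_length = as.integer(input_length),
                 channels = as.integer(channels)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Multi-kernel 1D CNN configuration\n")
  cat("  input:", x$input_length, "x", x$channels, "one-hot\n")
  cat("  branches:", paste0("l=", x$kernel_lengths, collapse = ", "),
      "with", x$filters_per_branch, "filters each\n")
  cat("  pooled feature dim:",
      x$filters_per_branch * length(x$kernel_lengths), "\n")
  cat("  head:", paste(c(x$fc_sizes, x$n_classes), collapse = " -> "),
      sprintf("(dropout %.2f)\n", x$dropout))
  invisible(x)
}

#' Build the convolutional classifier
#'
#' Creates the network with deterministic parameter initialization:
#' weights are drawn uniformly on \eqn{\pm\sqrt{1/\mathrm{fan~in}}}
#' under the given seed; biases start at zero. The scale is deliberately
#' smaller than ReLU-gain (He) initialization: with 1-max pooling the
#' network only learns shared motif features (rather than memorizing
#' individual training sequences) in the small-initialization regime —
#' see the methods vignette. The same seed always yields bit-identical
#' initial parameters.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialization.
#' @param labels Class names attached to the model outputs (default
#'   [plastic_labels()] when `n_classes` is 9).
#' @return A `pde_cnn` model object.
#' @export
build_model <- function(config = model_config(), seed = 1L, labels = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(labels)) {
    labels <- if (config$n_classes == 9L) plastic_labels()
              else paste0("class", seq_len(config$n_classes))
  }
  if (length(labels) != config$n_classes) {
    abort("length(labels) must equal n_classes")
  }
  ptr <- .cpp_cnn_create(config$kernel_lengths, config$filters_per_branch,
                         config$fc_sizes, config$n_classes,
                         config$input_length, config$channels)
  withr::with_seed(as.integer(seed), .cpp_cnn_init(ptr))
  structure(list(ptr = ptr, config = config, labels = labels,
                 seed = as.integer(seed), trained = FALSE,
                 thresholds = NULL, log = NULL),
            class = "pde_cnn")
}

#' @export
print.pde_cnn <- function(x, ...) {
  print(x$config)
  cat("  classes:", paste(x$labels, collapse = ", "), "\n")
  cat("  state:", if (x$trained) "trained" else "initialized (untrained)", "\n")
  if (!is.null(x$thresholds)) {
    cat("  calibrated thresholds:",
        paste(sprintf("%.2f", x$thresholds), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract or restore model parameters
#'
#' Parameters are plain R matrices/vectors, so a parameter list is
#' serializable and checkpoints survive across sessions.
#'
#' @param model A `pde_cnn`.
#' @return `model_parameters()`: a list with elements `branches` (per
#'   branch: `l`, `W`, `b`) and `fc` (per layer: `W`, `b`).
#' @export
model_parameters <- function(model) {
  stopifnot(inherits(model, "pde_cnn"))
  .cpp_cnn_get_params(model$ptr)
}

#' @rdname model_parameters
#' @param params Parameter list as returned by [model_parameters()].
#' @export
set_model_parameters <- function(model, params) {
  stopifnot(inherits(model, "pde_cnn"))
  .cpp_cnn_set_params(model$ptr, params)
  model
}

# normalise the many accepted input forms into the internal batch format
.as_batch <- function(x, config) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    return(.encode_batch(x, config$input_length))
  }
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(.encode_batch(tibble(id = ids, sequence = unname(x)),
                         config$input_length))
  }
  if (inherits(x, "encoded_sequence")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "encoded_sequence"))) {
    seqs <- lapply(x, function(m) {
      leff <- attr(m, "effective_length")
      if (nrow(m) != config$input_length || ncol(m) != config$channels) {
        abort("encoded matrix shape does not match model input")
      }
      as.integer(max.col(m[seq_len(leff), , drop = FALSE], "first") - 1L)
    })
    return(list(seqs = seqs,
                leff = vapply(x, attr, integer(1), "effective_length"),
                ids = vapply(x, function(m) attr(m, "source_id") %||% "",
                             character(1))))
  }
  abort("unsupported input: supply a records tibble, character vector, or encoded sequences")
}

#' Run the network forward
#'
#' @param model A `pde_cnn`.
#' @param newdata Records tibble (`id`, `sequence`), named character
#'   vector of sequences, or encoded sequences from [encode_one_hot()].
#' @param training Logical; when `TRUE`, dropout is active (stochastic
#'   under the session RNG). Inference mode (`FALSE`, default) is
#'   deterministic.
#' @param details Logical; when `TRUE` (single sequence only) also return
#'   per-branch activation maps `phi`, pooled values `beta`, the
#'   concatenated pooled vector, and pre-sigmoid logits.
#' @return A tibble `id` + one probability column per class; or, with
#'   `details = TRUE`, a list with elements `probs`, `logits`, `phi`,
#'   `beta`, `pooled`.
#' @export
forward <- function(model, newdata, training = FALSE, details = FALSE) {
  stopifnot(inherits(model, "pde_cnn"))
  batch <- .as_batch(newdata, model$config)
  if (details) {
    if (length(batch$seqs) != 1L) {
      abort("details = TRUE requires a single sequence")
    }
    d <- .cpp_cnn_detail(model$ptr, batch$seqs[[1]], batch$leff[[1]])
    names(d$phi) <- paste0("l", d$kernel_lengths)
    names(d$beta) <- paste0("l", d$kernel_lengths)
    d$probs <- setNames(as.numeric(d$probs), model$labels)
    d$logits <- setNames(as.numeric(d$logits), model$labels)
    d$effective_length <- batch$leff[[1]]
    return(d)
  }
  probs <- .cpp_cnn_predict(model$ptr, batch$seqs, batch$leff,
                            training, model$config$dropout)
  colnames(probs) <- model$labels
  dplyr::bind_cols(tibble(id = batch$ids), as_tibble(probs))
}

#' Predict class probabilities or thresholded calls
#'
#' @param object A `pde_cnn`.
#' @param newdata Sequences (see [forward()]).
#' @param type `"prob"` for probabilities, `"call"` for 0/1 calls under
#'   `thresholds`.
#' @param thresholds Per-class decision thresholds; defaults to the
#'   model's calibrated thresholds, or uniform 0.5 if none.
#' @param ... Unused.
#' @return A tibble `id` + one column per class.
#' @export
predict.pde_cnn <- function(object, newdata, type = c("prob", "call"),
                            thresholds = NULL, ...) {
  type <- match.arg(type)
  probs <- forward(object, newdata)
  if (type == "prob") return(probs)
  thresholds <- thresholds %||% object$thresholds %||%
    rep(0.5, object$config$n_classes)
  mat <- as.matrix(probs[, object$labels])
  calls <- sweep(mat, 2, thresholds, `>=`) * 1L
  dplyr::bind_cols(probs["id"], as_tibble(calls))
}

#' Mean binary cross-entropy loss
#'
#' Mean of the per-entry binary cross-entropy over every sequence-class
#' pair, the training objective of the multi-label classifier.
#'
#' @param probabilities Numeric matrix (or tibble of probability columns)
#'   in (0, 1).
#' @param labels Binary matrix of the same shape.
#' @param eps Clipping floor guarding `log(0)`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' bce_loss(matrix(0.5, 2, 3), matrix(c(1, 0), 2, 3)) # = log(2)
bce_loss <- function(probabilities, labels, eps = 1e-12) {
  p <- as.matrix(probabilities)
  y <- as.matrix(labels)
  if (!all(dim(p) == dim(y))) abort("probabilities and labels shapes differ")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Save / load a fitted model
#'
#' The checkpoint is a native R serialization of the parameter list, with
#' a sidecar JSON (`<path>.json`) holding the architecture configuration,
#' canonical label order, calibrated thresholds and a version stamp, so a
#' checkpoint is self-describing.
#'
#' @param model A `pde_cnn`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `save_model()`: `path` invisibly; `load_model()`: a `pde_cnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pde_cnn"))
  saveRDS(model_parameters(model), path)
  sidecar <- list(
    package = "pdecnn",
    version = as.character(utils::packageVersion("pdecnn")),
    config = unclass(model$config),
    labels = model$labels,
    thresholds = model$thresholds,
    seed = model$seed,
    trained = model$trained
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    abort(sprintf("checkpoint '%s' (and sidecar '%s.json') must both exist",
                  path, path))
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  cfg <- model_config(kernel_lengths = sc$config$kernel_lengths,
                      filters_per_branch = sc$config$filters_per_branch,
                      fc_sizes = sc$config$fc_sizes,
                      n_classes = sc$config$n_classes,
                      dropout = sc$config$dropout,
                      input_length = sc$config$input_length,
                      channels = sc$config$channels)
  model <- build_model(cfg, seed = sc$seed %||% 1L, labels = sc$labels)
  model <- set_model_parameters(model, readRDS(path))
  model$trained <- isTRUE(sc$trained)
  if (!is.null(sc$thresholds) && length(sc$thresholds) > 0) {
    model$thresholds <- as.numeric(sc$thresholds)
  }
  model
}
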