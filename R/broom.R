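#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training log of a fitted model
#'
#' @param x A `pde_cnn`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_micro_f1`, `best`.
#' @export
tidy.pde_cnn <- function(x, ...) {
  x$log %||% tibble(epoch = integer(), train_loss = numeric(),
                    val_micro_f1 = numeric(), best = logical())
}

#' One-row summary of a fitted model
#'
#' @param x A `pde_cnn`.
#' @param ... Unused.
#' @return Tibble: `n_parameters`, `trained`, `epochs`,
#'   `best_val_micro_f1`, `calibrated`.
#' @export
glance.pde_cnn <- function(x, ...) {
  params <- model_parameters(x)
  n_par <- sum(vapply(params$branches, function(b) length(b$W) + length(b$b),
                      numeric(1))) +
    sum(vapply(params$fc, function(f) length(f$W) + length(f$b), numeric(1)))
  log <- tidy(x)
  tibble(n_parameters = n_par,
         trained = x$trained,
         epochs = nrow(log),
         best_val_micro_f1 = if (nrow(log)) max(log$val_micro_f1) else NA_real_,
         calibrated = !is.null(x$thresholds))
}

#' @rdname run_benchmark
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @export
tidy.benchmark_result <- function(x, ...) x$results

#' @rdname run_benchmark
#' @export
glance.benchmark_result <- function(x, ...) {
  s <- x$summary
  out <- tibble(n_repeats = nrow(x$results))
  for (i in seq_len(nrow(s))) {
    out[[s$metric[i]]] <- s$mean[i]
    out[[paste0(s$metric[i], "_ci")]] <- s$ci_half_width[i]
  }
  out
}
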