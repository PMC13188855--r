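#' Plot a residue contribution profile
#'
#' Aggregate contribution score along the sequence, optionally with the
#' planted / annotated motif spans shaded.
#'
#' @param object A `contribution_profile` from [interpret()].
#' @param highlight Optional tibble of spans to shade (`start`, `end`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contribution_profile <- function(object, highlight = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$position, y = .data$tau))
  if (!is.null(highlight) && nrow(highlight) > 0) {
    p <- p + ggplot2::geom_rect(
      data = highlight,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
      ymin = -Inf, ymax = Inf, fill = "goldenrod", alpha = 0.25,
      inherit.aes = FALSE)
  }
  p + ggplot2::geom_area(fill = "firebrick", alpha = 0.6) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(
      x = "residue position",
      y = expression(tau[i]),
      title = sprintf("Residue contributions (%s, K = %s)",
                      attr(object, "target_class"), attr(object, "K"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot training curves of a fitted model
#'
#' Training loss and validation micro-F1 per epoch.
#'
#' @param object A trained `pde_cnn`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pde_cnn <- function(object, ...) {
  log <- tidy(object)
  if (nrow(log) == 0) abort("model has no training log")
  long <- tidyr::pivot_longer(log, c("train_loss", "val_micro_f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training curves") +
    ggplot2::theme_minimal()
}

#' Plot benchmark metric distributions across repeats
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$results,
                              c("f1", "precision", "recall", "fdr"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Held-out metrics across repeats") +
    ggplot2::theme_minimal()
}
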