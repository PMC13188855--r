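#' Run the repeated hold-out benchmark
#'
#' Executes the full protocol per repeat: stratified 80/10/10 split,
#' training with early stopping, per-class threshold calibration on the
#' validation split, and evaluation on the held-out test split — micro
#' precision/recall/F1 on the test sequences carrying at least one
#' positive label, and the false discovery rate on the all-negative
#' test sequences. Repeat r uses seed `seed + r - 1` for split,
#' initialization and training, so every repeat is an independent
#' hold-out experiment and the whole run is reproducible from its seed.
#'
#' @param dataset A `synthetic_dataset` (from [simulate_dataset()] /
#'   [read_dataset()]) or a list with `records` and `labels` tibbles.
#' @param n_repeats Number of repeated hold-out experiments.
#' @param seed Base seed.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()] (its `seed`/`n_repeats` fields
#'   are overridden per repeat).
#' @param outdir Optional run directory; per-repeat metrics are written
#'   as `repeat_<r>/metrics.json` and finished repeats are reused on
#'   rerun unless `force = TRUE`.
#' @param force Recompute repeats whose metrics already exist.
#' @param verbose Print progress.
#' @return A `benchmark_result`: list with `results` (one row per
#'   repeat: `repeat_id`, `f1`, `precision`, `recall`, `fdr`,
#'   `epochs`, `val_micro_f1`) and `summary` (per metric: mean and 95%
#'   confidence interval across repeats).
#' @export
run_benchmark <- function(dataset, n_repeats = 20L, seed = 1L,
                          model_cfg = model_config(),
                          train_cfg = train_config(),
                          outdir = NULL, force = FALSE,
                          verbose = FALSE) {
  records <- dataset$records
  labels <- dataset$labels
  if (is.null(records) || is.null(labels)) {
    abort("dataset must provide records and labels")
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_run_manifest(outdir, command = "benchmark",
                       config = list(n_repeats = n_repeats, seed = seed,
                                     model = unclass(model_cfg),
                                     train = unclass(train_cfg)))
  }
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rseed <- as.integer(seed) + r - 1L
    mfile <- if (!is.null(outdir)) {
      file.path(outdir, sprintf("repeat_%02d", r), "metrics.json")
    }
    if (!is.null(mfile) && file.exists(mfile) && !force) {
      rows[[r]] <- as_tibble(jsonlite::read_json(mfile, simplifyVector = TRUE))
      if (verbose) message(sprintf("repeat %d: reusing %s", r, mfile))
      next
    }
    fit <- run_single_experiment(records, labels, seed = rseed,
                                 model_cfg = model_cfg,
                                 train_cfg = train_cfg, verbose = verbose)
    row <- tibble(repeat_id = r, seed = rseed,
                  f1 = fit$metrics$f1, precision = fit$metrics$precision,
                  recall = fit$metrics$recall, fdr = fit$fdr,
                  epochs = nrow(fit$model$log),
                  val_micro_f1 = attr(fit$thresholds, "micro_f1"))
    if (!is.null(mfile)) {
      dir.create(dirname(mfile), recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(as.list(row), mfile, auto_unbox = TRUE,
                           digits = NA)
      readr::write_csv(
        tibble(id = unlist(fit$split, use.names = FALSE),
               split = rep(names(fit$split), lengths(fit$split))),
        file.path(dirname(mfile), "splits.csv"))
      jsonlite::write_json(as.list(fit$thresholds),
                           file.path(dirname(mfile), "thresholds.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    rows[[r]] <- row
    if (verbose) {
      message(sprintf("repeat %d/%d: F1 %.4f, FDR %.4f",
                      r, n_repeats, row$f1, row$fdr))
    }
  }
  results <- dplyr::bind_rows(rows)
  metrics <- c("f1", "precision", "recall", "fdr")
  summary <- purrr::map_dfr(metrics, function(m) {
    if (nrow(results) >= 2) {
      dplyr::mutate(summarize_repeats(results[[m]]), metric = m,
                    .before = 1)
    } else {
      tibble(metric = m, n = nrow(results), mean = mean(results[[m]]),
             sd = NA_real_, se = NA_real_, ci_lower = NA_real_,
             ci_upper = NA_real_, ci_half_width = NA_real_)
    }
  })
  out <- structure(list(results = results, summary = summary,
                        n_repeats = n_repeats, seed = seed),
                   class = "benchmark_result")
  if (!is.null(outdir)) {
    readr::write_csv(results, file.path(outdir, "results.csv"))
    readr::write_csv(summary, file.path(outdir, "summary.csv"))
  }
  out
}

#' One full split/train/calibrate/evaluate experiment
#'
#' The unit the benchmark repeats. Exposed so single runs (and the
#' interpreter, which needs a fitted model plus its test split) are
#' scriptable.
#'
#' @inheritParams run_benchmark
#' @param records,labels Data tibbles.
#' @param seed Seed for split, initialization and training.
#' @return List: fitted `model`, `split` (id lists), `thresholds`,
#'   `metrics` (test micro metrics on positive-labelled sequences),
#'   `fdr` (on all-negative test sequences, `NA` if none), and the
#'   test `table` (a [prediction_table()]).
#' @export
run_single_experiment <- function(records, labels, seed = 1L,
                                  model_cfg = model_config(),
                                  train_cfg = train_config(),
                                  verbose = FALSE) {
  split <- stratified_split(labels, train_cfg$split_fractions, seed = seed)
  model <- build_model(model_cfg, seed = seed)
  cfg <- train_cfg
  cfg$seed <- as.integer(seed)
  model <- train_model(model, records, labels, split$train,
                       split$validation, cfg, verbose = verbose)
  thresholds <- calibrate_thresholds(model, records, labels,
                                     split$validation)
  model$thresholds <- as.numeric(thresholds)
  test_records <- records[records$id %in% split$test, , drop = FALSE]
  probs <- forward(model, test_records)
  truth <- label_matrix(labels)[probs$id, model$labels, drop = FALSE]
  is_pos <- rowSums(truth) > 0
  pos_tab <- prediction_table(as.matrix(probs[is_pos, model$labels]),
                              truth[is_pos, , drop = FALSE],
                              model$thresholds)
  metrics <- micro_metrics(pos_tab)
  fdr <- NA_real_
  if (any(!is_pos)) {
    neg_tab <- prediction_table(as.matrix(probs[!is_pos, model$labels]),
                                truth[!is_pos, , drop = FALSE],
                                model$thresholds)
    fdr <- false_discovery_rate(neg_tab)
  }
  full_tab <- prediction_table(as.matrix(probs[, model$labels]), truth,
                               model$thresholds)
  list(model = model, split = split, thresholds = thresholds,
       metrics = metrics, fdr = fdr, table = full_tab)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Repeated hold-out benchmark (%d repeat(s), base seed %d)\n",
              nrow(x$results), x$seed))
  print(x$summary)
  invisible(x)
}

#' Score recovery of planted motifs by the interpreter
#'
#' For each requested positive sequence, computes the contribution
#' profile for its highest-probability true class and measures how
#' strongly the top-scoring residues enrich for the planted motif
#' positions of that class: with T the top `top_frac` fraction of
#' residues by aggregate score and M the planted positions,
#' `enrichment = (|T intersect M| / |T|) / (|M| / L)` — the precision
#' of the top set relative to what uniformly random residue selection
#' would achieve.
#'
#' @param model A fitted `pde_cnn`.
#' @param dataset A `synthetic_dataset` (needs `records`, `labels`,
#'   `truth`).
#' @param ids Sequence ids to score (default: all positives).
#' @param K Activation maps per kernel length (default 50).
#' @param top_frac Fraction of residues forming the top set (default
#'   0.1).
#' @return Tibble: `id`, `class`, `leff`, `n_top`, `n_motif`,
#'   `overlap`, `enrichment`.
#' @export
motif_recovery <- function(model, dataset, ids = NULL, K = 50L,
                           top_frac = 0.1) {
  truth <- dataset$truth
  Y <- label_matrix(dataset$labels)
  if (is.null(ids)) ids <- dataset$labels$id[rowSums(Y) > 0]
  recs <- dataset$records[match(ids, dataset$records$id), , drop = FALSE]
  probs <- forward(model, recs)
  purrr::map_dfr(seq_along(ids), function(i) {
    id <- ids[i]
    true_classes <- model$labels[Y[id, ] == 1]
    p <- as.numeric(probs[i, true_classes])
    cl <- true_classes[which.max(p)]
    prof <- interpret(model, recs[i, , drop = FALSE], cl, K = K)
    leff <- nrow(prof)
    n_top <- max(1L, floor(top_frac * leff))
    top <- order(prof$tau, decreasing = TRUE)[seq_len(n_top)]
    spans <- truth[truth$id == id & truth$class == cl, , drop = FALSE]
    motif <- unique(unlist(purrr::map2(spans$start, spans$end, seq)))
    motif <- motif[motif <= leff]
    overlap <- length(intersect(top, motif))
    enr <- if (length(motif) == 0) NA_real_ else {
      (overlap / n_top) / (length(motif) / leff)
    }
    tibble(id = id, class = cl, leff = leff, n_top = n_top,
           n_motif = length(motif), overlap = overlap, enrichment = enr)
  })
}

#' Interpret every sequence of a FASTA file
#'
#' Loads a checkpoint, computes one contribution profile per sequence
#' for the requested class and writes `<id>.csv` per sequence plus an
#' `index.csv` (id, file, effective length, class probability).
#'
#' @param model_path Checkpoint path (see [save_model()]), or a fitted
#'   `pde_cnn` directly.
#' @param fasta Path to the FASTA file to interpret.
#' @param class_c Target class label.
#' @param K Activation maps per kernel length.
#' @param outdir Output directory.
#' @param force Overwrite an existing non-empty output directory.
#' @return The index tibble, invisibly.
#' @export
run_interpret_batch <- function(model_path, fasta, class_c, K = 50L,
                                outdir, force = FALSE) {
  model <- if (inherits(model_path, "pde_cnn")) model_path else {
    load_model(model_path)
  }
  .resolve_class(model, class_c)
  records <- read_fasta(fasta)
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !force) {
    abort(sprintf("output directory '%s' is not empty; use force = TRUE to overwrite",
                  outdir))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  probs <- forward(model, records)
  index <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    prof <- interpret(model, records[i, , drop = FALSE], class_c, K = K)
    fname <- paste0(gsub("[^A-Za-z0-9_.-]", "_", records$id[i]), ".csv")
    write_profile(prof, file.path(outdir, fname))
    tibble(id = records$id[i], file = fname, effective_length = nrow(prof),
           probability = probs[[class_c]][i])
  })
  readr::write_csv(index, file.path(outdir, "index.csv"))
  write_run_manifest(outdir, command = "interpret",
                     config = list(class = class_c, K = K),
                     inputs = fasta)
  invisible(index)
}

#' Write a reproducibility manifest into a run directory
#'
#' Records the command, the full configuration snapshot, input file
#' MD5 digests, the package version and a timestamp as
#' `manifest.json` (one per run directory).
#'
#' @param outdir Run directory.
#' @param command Subcommand / operation name.
#' @param config Configuration list (seeds included).
#' @param inputs Paths whose digests should be recorded.
#' @return Path of the manifest, invisibly.
#' @export
write_run_manifest <- function(outdir, command, config = list(),
                               inputs = character(0)) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(
    command = command,
    config = config,
    input_digests = digests,
    package = "pdecnn",
    version = as.character(utils::packageVersion("pdecnn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
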