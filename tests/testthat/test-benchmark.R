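# a miniature benchmark everything here shares: 2 motif classes, short
# sequences, small model, few epochs
mini_bench <- function() {
  list(
    ds = simulate_dataset(n_per_class = 12, length_range = c(40, 80),
                          motif_specs = motif_bank()[c(1, 8), ],
                          multilabel_rate = 0, n_negatives = 12, seed = 5),
    model_cfg = model_config(kernel_lengths = c(4L, 8L),
                             filters_per_branch = 8L, fc_sizes = 16L,
                             n_classes = 9L, input_length = 80L),
    train_cfg = train_config(learning_rate = 1e-3, batch_size = 8L,
                             max_epochs = 15L, patience = 15L)
  )
}

test_that("the repeated hold-out harness is deterministic and complete", {
  mb <- mini_bench()
  r1 <- run_benchmark(mb$ds, n_repeats = 2, seed = 3,
                      model_cfg = mb$model_cfg, train_cfg = mb$train_cfg)
  expect_equal(nrow(r1$results), 2L)
  expect_equal(r1$results$repeat_id, 1:2)
  expect_setequal(r1$summary$metric, c("f1", "precision", "recall", "fdr"))
  expect_true(all(r1$summary$ci_half_width >= 0))
  r2 <- run_benchmark(mb$ds, n_repeats = 2, seed = 3,
                      model_cfg = mb$model_cfg, train_cfg = mb$train_cfg)
  expect_equal(r1$results, r2$results)

  g <- glance(r1)
  expect_equal(g$f1, mean(r1$results$f1))
  expect_equal(nrow(tidy(r1)), 2L)
})

test_that("benchmark runs resume from written repeat metrics", {
  mb <- mini_bench()
  outdir <- withr::local_tempdir()
  r1 <- run_benchmark(mb$ds, n_repeats = 2, seed = 3,
                      model_cfg = mb$model_cfg, train_cfg = mb$train_cfg,
                      outdir = outdir)
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  expect_true(file.exists(file.path(outdir, "repeat_01", "metrics.json")))
  expect_true(file.exists(file.path(outdir, "repeat_01", "splits.csv")))
  # tamper with a stored metric: a resumed run must reuse, not recompute
  mpath <- file.path(outdir, "repeat_02", "metrics.json")
  rec <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  rec$f1 <- 0.123
  jsonlite::write_json(rec, mpath, auto_unbox = TRUE, digits = NA)
  r2 <- run_benchmark(mb$ds, n_repeats = 2, seed = 3,
                      model_cfg = mb$model_cfg, train_cfg = mb$train_cfg,
                      outdir = outdir)
  expect_equal(r2$results$f1[2], 0.123)
  # force recomputes and restores the true value
  r3 <- run_benchmark(mb$ds, n_repeats = 2, seed = 3,
                      model_cfg = mb$model_cfg, train_cfg = mb$train_cfg,
                      outdir = outdir, force = TRUE)
  expect_equal(r3$results$f1[2], r1$results$f1[2])
})

test_that("single experiments expose split, thresholds and test table", {
  mb <- mini_bench()
  fit <- run_single_experiment(mb$ds$records, mb$ds$labels, seed = 2,
                               model_cfg = mb$model_cfg,
                               train_cfg = mb$train_cfg)
  expect_setequal(unlist(fit$split, use.names = FALSE), mb$ds$records$id)
  expect_length(fit$thresholds, 9L)
  expect_true(all(fit$thresholds > 0 & fit$thresholds < 1))
  expect_s3_class(fit$metrics, "tbl_df")
  expect_true(fit$fdr >= 0 && fit$fdr <= 1)
  expect_s3_class(fit$model$log, "tbl_df")
})

test_that("batch interpretation writes per-sequence profiles and an index", {
  mb <- mini_bench()
  m <- build_model(mb$model_cfg, seed = 1)
  fasta <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(mb$ds$records[1:3, ], fasta)
  outdir <- file.path(withr::local_tempdir(), "profiles")
  idx <- run_interpret_batch(m, fasta, "PET", K = 4, outdir = outdir)
  expect_equal(nrow(idx), 3L)
  expect_true(all(file.exists(file.path(outdir, idx$file))))
  expect_true(file.exists(file.path(outdir, "index.csv")))
  expect_true(file.exists(file.path(outdir, "manifest.json")))

  # refuses to overwrite without force, with force it reruns
  expect_error(run_interpret_batch(m, fasta, "PET", K = 4, outdir = outdir),
               "force")
  idx2 <- run_interpret_batch(m, fasta, "PET", K = 4, outdir = outdir,
                              force = TRUE)
  expect_equal(idx2$file, idx$file)

  expect_error(run_interpret_batch(m, fasta, "PETT", K = 4,
                                   outdir = file.path(tempdir(), "x")),
               "PHA.*PU|valid classes")
})

test_that("motif recovery scores enrichment against planted positions", {
  # a hand-wired detector for the PHA pattern "GYSAGK": enrichment of
  # the top residues must be far above chance for PHA positives
  ds <- simulate_dataset(n_per_class = 6, length_range = c(60, 80),
                         motif_specs = tibble::tibble(class = "PHA",
                                                      pattern = "GYSAGK"),
                         multilabel_rate = 0, n_negatives = 0, seed = 8)
  cfg <- model_config(kernel_lengths = 6L, filters_per_branch = 1L,
                      fc_sizes = integer(0), n_classes = 9L,
                      input_length = 80L)
  m <- zero_model(cfg)
  p <- model_parameters(m)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  motif <- strsplit("GYSAGK", "")[[1]]
  for (j in seq_along(motif)) {
    p$branches[[1]]$W[(j - 1) * 21 + match(motif[j], aa), 1] <- 1
  }
  p$branches[[1]]$b[1] <- -4.5
  p$fc[[1]]$W[1, 1] <- 1    # wire the filter to the PHA output only
  m <- set_model_parameters(m, p)
  rec <- motif_recovery(m, ds, K = 1, top_frac = 0.1)
  expect_equal(nrow(rec), 6L)
  expect_equal(unique(rec$class), "PHA")
  expect_true(all(rec$enrichment > 3))
})

test_that("run manifests record config, digests and version", {
  outdir <- withr::local_tempdir()
  f <- withr::local_tempfile(); writeLines("x", f)
  write_run_manifest(outdir, "simulate", list(seed = 7), inputs = f)
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$command, "simulate")
  expect_equal(man$config$seed, 7)
  expect_equal(length(man$input_digests), 1L)
  expect_equal(man$package, "pdecnn")
})
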