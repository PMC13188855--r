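# random multi-label set with controlled per-class positives
random_labels <- function(n, pos_per_class, seed) {
  withr::with_seed(seed, {
    Y <- matrix(0L, n, 9, dimnames = list(paste0("r", seq_len(n)),
                                          plastic_labels()))
    for (c_ in 1:9) Y[sample(n, pos_per_class), c_] <- 1L
    Y
  })
}

test_that("stratified splits partition the ids exactly and are seeded", {
  Y <- random_labels(200, 40, seed = 1)
  sp <- stratified_split(Y, c(0.8, 0.1, 0.1), seed = 5)
  all_ids <- sort(unlist(sp, use.names = FALSE))
  expect_equal(all_ids, sort(rownames(Y)))
  expect_equal(sum(lengths(sp)), 200L)
  expect_identical(stratified_split(Y, c(0.8, 0.1, 0.1), seed = 5), sp)
  expect_false(identical(stratified_split(Y, c(0.8, 0.1, 0.1), seed = 6), sp))
})

test_that("stratification preserves per-class positive fractions", {
  # one class with 50 of 100 positives: 40/5/5 within +-1
  Y <- matrix(0L, 100, 9, dimnames = list(paste0("r", 1:100),
                                          plastic_labels()))
  withr::with_seed(2, Y[sample(100, 50), "PET"] <- 1L)
  sp <- stratified_split(Y, c(0.8, 0.1, 0.1), seed = 3)
  pos_in <- vapply(sp, function(ids) sum(Y[ids, "PET"]), numeric(1))
  expect_true(all(abs(pos_in - c(40, 5, 5)) <= 1))

  # 900 records, 9 classes: every class's train fraction within 2 points
  Y9 <- random_labels(900, 100, seed = 7)
  sp9 <- stratified_split(Y9, c(0.8, 0.1, 0.1), seed = 11)
  for (c_ in plastic_labels()) {
    frac <- sum(Y9[sp9$train, c_]) / sum(Y9[, c_])
    expect_true(abs(frac - 0.8) <= 0.02, label = c_)
  }

  # a class rarer than the number of splits is an error naming it
  Yr <- Y
  Yr[, "PU"] <- 0L; Yr[1:2, "PU"] <- 1L
  expect_error(stratified_split(Yr, c(0.8, 0.1, 0.1), seed = 1), "PU")
})

test_that("max_epochs = 0 returns the model unchanged with an empty log", {
  ds <- simulate_dataset(n_per_class = 3, length_range = c(30, 50),
                         motif_specs = motif_bank()[1:2, ],
                         n_negatives = 4, seed = 2)
  sp <- stratified_split(ds$labels, c(0.5, 0.25, 0.25), seed = 1)
  m <- build_model(tiny_config(input_length = 50L, n_classes = 9L), seed = 3)
  p0 <- model_parameters(m)
  m2 <- train_model(m, ds$records, ds$labels, sp$train, sp$validation,
                    train_config(max_epochs = 0))
  expect_identical(model_parameters(m2), p0)
  expect_equal(nrow(m2$log), 0L)
})

test_that("training is deterministic and reduces the loss on a separable toy set", {
  specs <- tibble::tibble(class = c("PET", "PCL"),
                          pattern = c("GWSDGHW", "PKTCSNY"))
  ds <- simulate_dataset(n_per_class = 10, length_range = c(40, 60),
                         motif_specs = specs, multilabel_rate = 0,
                         n_negatives = 0, seed = 6)
  sp <- stratified_split(ds$labels, c(0.6, 0.2, 0.2), seed = 2)
  cfg <- model_config(kernel_lengths = c(4L, 8L), filters_per_branch = 16L,
                      fc_sizes = 32L, n_classes = 9L, input_length = 60L)
  tc <- train_config(learning_rate = 1e-3, batch_size = 4L,
                     max_epochs = 30L, patience = 30L, seed = 4)
  m1 <- train_model(build_model(cfg, seed = 4), ds$records, ds$labels,
                    sp$train, sp$validation, tc)
  m2 <- train_model(build_model(cfg, seed = 4), ds$records, ds$labels,
                    sp$train, sp$validation, tc)
  expect_identical(m1$log, m2$log)
  expect_identical(model_parameters(m1), model_parameters(m2))
  # loss decreases over the first epochs
  expect_lt(m1$log$train_loss[10], m1$log$train_loss[1])
  expect_lt(min(m1$log$train_loss), 0.5 * m1$log$train_loss[1])
  expect_true(m1$trained)
  expect_error(train_model(build_model(cfg, seed = 1), ds$records,
                           ds$labels, character(0), sp$validation, tc),
               "non-empty")
})

test_that("threshold calibration matches an exhaustive grid oracle", {
  # exhaustive enumeration over the full grid is the global optimum for
  # a single class; the coordinate-ascent result must attain it
  grid <- seq(0.01, 0.99, by = 0.01)
  withr::with_seed(42, {
    for (fixture in 1:20) {
      n <- sample(20:60, 1)
      truth <- matrix(rbinom(n, 1, runif(1, 0.2, 0.6)), ncol = 1)
      if (sum(truth) == 0) truth[1] <- 1
      scores <- matrix(runif(n) * 0.5 + 0.5 * truth * runif(n), ncol = 1)
      oracle_f1 <- max(vapply(grid, function(t) {
        pdecnn:::.micro_f1(scores, truth, t)
      }, numeric(1)))
      th <- calibrate_thresholds(scores, truth)
      expect_equal(attr(th, "micro_f1"), oracle_f1, tolerance = 1e-12)
    }
  })
})

test_that("calibration tie-breaks toward the lower threshold", {
  # perfectly separated scores: positives >= 0.9, negatives <= 0.1 in
  # every class; every threshold in (0.1, 0.9] attains F1 = 1 and the
  # lowest grid value doing so is 0.11
  scores <- matrix(c(0.9, 0.95, 0.1, 0.05), 4, 3)
  truth <- matrix(c(1, 1, 0, 0), 4, 3)
  th <- calibrate_thresholds(scores, truth)
  expect_equal(as.numeric(th), rep(0.11, 3))
  expect_equal(attr(th, "micro_f1"), 1)
})

test_that("calibration never scores below the uniform-0.5 baseline", {
  withr::with_seed(55, {
    for (rep in 1:10) {
      scores <- matrix(runif(200), 40, 5)
      truth <- matrix(rbinom(200, 1, 0.25), 40, 5)
      if (sum(truth) == 0) truth[1] <- 1
      th <- calibrate_thresholds(scores, truth)
      expect_gte(attr(th, "micro_f1") + 1e-12,
                 pdecnn:::.micro_f1(scores, truth, rep(0.5, 5)))
      expect_true(all(th > 0 & th < 1))
    }
  })
  expect_error(calibrate_thresholds(matrix(runif(10), ncol = 1),
                                    matrix(0, 10, 1)),
               "no positive")
})

test_that("a degenerate constant-0.5 scorer calibrates to the all-positive F1", {
  # every score 0.5: thresholds <= 0.5 call everything positive, and the
  # achievable optimum is the all-positive predictor's micro-F1
  truth <- matrix(c(rep(1, 6), rep(0, 14)), ncol = 1)
  scores <- matrix(0.5, 20, 1)
  th <- calibrate_thresholds(scores, truth)
  expect_lte(unname(th), 0.5)
  allpos_f1 <- 2 * 6 / (2 * 6 + 14 + 0)
  expect_equal(attr(th, "micro_f1"), allpos_f1)
})
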