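test_that("the default architecture has the documented shapes", {
  m <- build_model(model_config(), seed = 1)
  d <- forward(m, random_aa_string(50), details = TRUE)
  expect_length(d$pooled, 384L)   # 128 filters x 3 kernel lengths
  expect_equal(vapply(d$phi, nrow, integer(1), USE.NAMES = FALSE),
               c(997L, 993L, 985L))   # 1000 - l + 1
  expect_length(d$probs, 9L)
  expect_true(all(d$probs > 0 & d$probs < 1))
  expect_equal(names(d$probs), plastic_labels())
})

test_that("a minimal single-branch model runs end to end", {
  cfg <- model_config(kernel_lengths = 4L, filters_per_branch = 2L,
                      fc_sizes = 4L, n_classes = 1L, input_length = 30L)
  m <- build_model(cfg, seed = 2)
  out <- forward(m, "ACDEFGHIKL")
  expect_equal(dim(out), c(1L, 2L))  # id + one probability
  expect_true(out[[2]] > 0 && out[[2]] < 1)
  expect_error(model_config(kernel_lengths = 40L, input_length = 30L),
               "kernel")
})

test_that("initialization and inference are deterministic under a seed", {
  m1 <- build_model(tiny_config(), seed = 7)
  m2 <- build_model(tiny_config(), seed = 7)
  expect_identical(model_parameters(m1), model_parameters(m2))
  m3 <- build_model(tiny_config(), seed = 8)
  expect_false(identical(model_parameters(m1), model_parameters(m3)))

  s <- random_aa_string(12)
  expect_identical(forward(m1, s), forward(m1, s))
})

test_that("zero parameters give logit 0 and probability 0.5 everywhere", {
  m <- zero_model()
  d <- forward(m, "ACDEFGHIKLMN", details = TRUE)
  expect_equal(unname(d$logits), rep(0, 3))
  expect_equal(unname(d$probs), rep(0.5, 3))
})

test_that("activation maps match a hand-rolled sliding-window convolution", {
  cfg <- model_config(kernel_lengths = 3L, filters_per_branch = 2L,
                      fc_sizes = 4L, n_classes = 2L, input_length = 10L)
  m <- build_model(cfg, seed = 5)
  s <- "ACDEFGHIKL"
  d <- forward(m, s, details = TRUE)
  p <- model_parameters(m)
  oracle <- conv_oracle(unclass(encode_one_hot(s, input_length = 10L)),
                        p$branches[[1]]$W, p$branches[[1]]$b, 3L)
  expect_equal(d$phi[[1]], oracle, tolerance = 1e-12)
  # pooled value is exactly the map maximum
  expect_equal(as.numeric(d$beta[[1]]), apply(oracle, 2, max))
})

test_that("a hand-set kernel matching a planted window pools its dot product", {
  cfg <- model_config(kernel_lengths = 4L, filters_per_branch = 1L,
                      fc_sizes = 3L, n_classes = 1L, input_length = 20L)
  m <- zero_model(cfg)
  p <- model_parameters(m)
  # weight 5 on the exact channels of the window "GVSA" at its position
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  motif <- c("G", "V", "S", "A")
  for (j in seq_along(motif)) {
    p$branches[[1]]$W[(j - 1) * 21 + match(motif[j], aa), 1] <- 5
  }
  m <- set_model_parameters(m, p)
  s <- paste0("CCCCC", "GVSA", "CCCCCCC")   # motif at positions 6-9
  d <- forward(m, s, details = TRUE)
  expect_equal(as.numeric(d$beta[[1]]), 20)     # 4 matches x weight 5
  expect_equal(which.max(d$phi[[1]][, 1]), 6L)  # window start
})

test_that("binary cross-entropy matches closed forms", {
  expect_lt(bce_loss(matrix(c(1, 0), 1, 2), matrix(c(1, 0), 1, 2)), 1e-10)
  expect_equal(bce_loss(matrix(0.5, 3, 4), matrix(rbinom(12, 1, 0.5), 3, 4)),
               log(2))
  expect_equal(bce_loss(matrix(0.8), matrix(1)), -log(0.8))
  expect_equal(-log(0.8), 0.2231, tolerance = 1e-3)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 2)), "shape")
})

test_that("logit gradients with respect to pooled values match finite differences", {
  m <- build_model(tiny_config(), seed = 9)
  s <- "ACDEFGHIKLMN"
  d <- forward(m, s, details = TRUE)
  params <- model_parameters(m)
  batch <- pdecnn:::.encode_batch(tibble::tibble(id = "x", sequence = s), 12L)
  for (cls in 1:3) {
    alpha <- as.numeric(pdecnn:::.cpp_cnn_alpha(m$ptr, batch$seqs[[1]],
                                                batch$leff[[1]], cls - 1L))
    eps <- 1e-5
    fd <- vapply(seq_along(d$pooled), function(j) {
      up <- d$pooled; up[j] <- up[j] + eps
      dn <- d$pooled; dn[j] <- dn[j] - eps
      (fc_logit_oracle(params, up, cls) -
         fc_logit_oracle(params, dn, cls)) / (2 * eps)
    }, numeric(1))
    expect_equal(alpha, fd, tolerance = 1e-4)
  }
})

test_that("training gradients match central finite differences of the loss", {
  cfg <- model_config(kernel_lengths = c(2L, 3L), filters_per_branch = 3L,
                      fc_sizes = 4L, n_classes = 2L, input_length = 10L,
                      dropout = 0)
  m <- build_model(cfg, seed = 8)
  recs <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = c("ACDEFGHIKL", "MNPQRST", "WYACD"))
  b <- pdecnn:::.encode_batch(recs, 10L)
  Y <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE) * 1.0
  g <- pdecnn:::.cpp_cnn_grads(m$ptr, b$seqs, b$leff, Y)
  p0 <- model_parameters(m)
  loss_at <- function(params) {
    m2 <- set_model_parameters(build_model(cfg, seed = 8), params)
    bce_loss(pdecnn:::.cpp_cnn_predict(m2$ptr, b$seqs, b$leff, FALSE, 0), Y)
  }
  eps <- 1e-6
  withr::with_seed(10, {
    for (loc in list(list("branches", 1, "W"), list("branches", 2, "W"),
                     list("fc", 1, "W"), list("fc", 2, "b"))) {
      arr <- p0[[loc[[1]]]][[loc[[2]]]][[loc[[3]]]]
      for (j in sample(length(arr), min(5, length(arr)))) {
        pp <- p0; pp[[loc[[1]]]][[loc[[2]]]][[loc[[3]]]][j] <- arr[j] + eps
        pm <- p0; pm[[loc[[1]]]][[loc[[2]]]][[loc[[3]]]][j] <- arr[j] - eps
        fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        an <- g[[loc[[1]]]][[loc[[2]]]][[loc[[3]]]][j]
        expect_equal(an, fd, tolerance = 1e-4)
      }
    }
  })
})

test_that("checkpoints round-trip through save_model / load_model", {
  m <- build_model(tiny_config(), seed = 4,
                   labels = c("PET", "PCL", "PLA"))
  m$trained <- TRUE
  m$thresholds <- c(0.2, 0.5, 0.7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  s <- random_aa_string(12)
  expect_equal(forward(m, s), forward(m2, s))
  expect_equal(m2$labels, c("PET", "PCL", "PLA"))
  expect_equal(m2$thresholds, c(0.2, 0.5, 0.7))
})

test_that("prediction with calls applies per-class thresholds", {
  m <- zero_model(tiny_config(), labels = c("PET", "PCL", "PLA"))
  calls <- predict(m, random_aa_string(10), type = "call",
                   thresholds = c(0.4, 0.5, 0.6))
  # probability is exactly 0.5 everywhere: >= threshold rule
  expect_equal(unname(as.matrix(calls[, -1])), matrix(c(1L, 1L, 0L), 1))
})
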