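# model with a single conv branch feeding a LINEAR head (no hidden FC
# layers) whose class-1 logit is 2*beta_1 + 0*beta_2: alpha is analytic
linear_head_model <- function() {
  cfg <- model_config(kernel_lengths = 2L, filters_per_branch = 2L,
                      fc_sizes = integer(0), n_classes = 1L,
                      input_length = 8L)
  m <- build_model(cfg, seed = 1)
  p <- model_parameters(m)
  p$branches[[1]]$W[] <- 0.5   # every filter responds to everything
  p$branches[[1]]$b[] <- 0
  p$fc[[1]]$W[] <- c(2, 0)
  p$fc[[1]]$b[] <- 0
  set_model_parameters(m, p)
}

test_that("alpha is the analytic head gradient and maps rank by signed alpha", {
  m <- linear_head_model()
  rk <- rank_activation_maps(m, "ACDEFGHI", 1L)
  expect_equal(rk$table$alpha, c(2, 0))
  expect_equal(rk$table$filter[rk$table$rank == 1], 1L)
  expect_error(rank_activation_maps(m, "ACDEFGHI", 5L), "out of range")
  expect_error(rank_activation_maps(m, "ACDEFGHI", "PETT"), "PETT")
})

test_that("alpha agrees with central finite differences on a fixed model", {
  m <- build_model(tiny_config(), seed = 31)
  rk <- rank_activation_maps(m, "MKTAYIAKQRQI", "class2")
  params <- model_parameters(m)
  d <- forward(m, "MKTAYIAKQRQI", details = TRUE)
  eps <- 1e-5
  tab <- dplyr::arrange(rk$table, kernel_length, filter)
  F <- 4L
  for (r in seq_len(nrow(tab))) {
    j <- (match(tab$kernel_length[r], c(2L, 3L)) - 1L) * F + tab$filter[r]
    up <- d$pooled; up[j] <- up[j] + eps
    dn <- d$pooled; dn[j] <- dn[j] - eps
    fd <- (fc_logit_oracle(params, up, 2L) -
             fc_logit_oracle(params, dn, 2L)) / (2 * eps)
    expect_equal(tab$alpha[r], fd, tolerance = 1e-4)
  }
})

test_that("a branch the head ignores gets alpha exactly zero", {
  m <- build_model(tiny_config(), seed = 12)
  p <- model_parameters(m)
  p$fc[[1]]$W[5:8, ] <- 0    # rows fed by the second (l = 3) branch
  m <- set_model_parameters(m, p)
  rk <- rank_activation_maps(m, "ACDEFGHIKLMN", 1L)
  expect_true(all(rk$table$alpha[rk$table$kernel_length == 3] == 0))
})

test_that("window contributions sum the top-K positive-alpha maps", {
  phi <- matrix(c(1, 2, 3,
                  9, 9, 9), ncol = 2)   # two maps of length 3
  # K = 1: only the higher-alpha map is used, identity on its vector
  rk1 <- manual_ranking(list(phi), list(c(0.9, 0.1)), 2L, 4L)
  expect_equal(window_contributions(rk1, K = 1)[["2"]], c(1, 2, 3))

  # K = 2 with maps [1,0,2] and [0,1,1] sums position-wise
  phi2 <- matrix(c(1, 0, 2, 0, 1, 1), ncol = 2)
  rk2 <- manual_ranking(list(phi2), list(c(0.5, 0.4)), 2L, 4L)
  expect_equal(window_contributions(rk2, K = 2)[["2"]], c(1, 1, 3))

  # negative-alpha maps are never selected, whatever their magnitude
  rk3 <- manual_ranking(list(phi2), list(c(0.5, -50)), 2L, 4L)
  expect_equal(window_contributions(rk3, K = 2)[["2"]], c(1, 0, 2))

  # K above the filter count caps with a warning
  expect_warning(z <- window_contributions(rk2, K = 500), "exceeds")
  expect_equal(z[["2"]], c(1, 1, 3))
  expect_error(window_contributions(rk2, K = 0), "K")

  # alpha-weighted variant scales each selected map
  zw <- window_contributions(rk2, K = 2, alpha_weighted = TRUE)
  expect_equal(zw[["2"]], 0.5 * c(1, 0, 2) + 0.4 * c(0, 1, 1))
})

test_that("residue redistribution matches direct enumeration and conserves mass", {
  # l = 2 over a length-3 content region: [a, b] -> [a/2, (a+b)/2, b/2]
  expect_equal(residue_scores(c(1, 2), l = 2, effective_length = 3),
               c(0.5, 1.5, 1))
  expect_equal(residue_scores(rep(0, 9), l = 4, effective_length = 12),
               rep(0, 12))

  withr::with_seed(17, {
    for (rep in 1:25) {
      l <- sample(c(2L, 3L, 5L), 1)
      map_len <- 20L
      input_length <- map_len + l - 1L
      zeta <- runif(map_len)
      leff <- sample(l:input_length, 1)
      got <- residue_scores(zeta, l, leff)
      expect_equal(got, residue_scores_oracle(zeta, l, leff))
      expect_true(all(got >= 0))
      # full-length case conserves total mass exactly
      full <- residue_scores(zeta, l, input_length)
      expect_equal(sum(full), sum(zeta), tolerance = 1e-9)
    }
  })
})

test_that("profiles aggregate element-wise across kernel lengths", {
  expect_equal(aggregate_profile(list(`4` = c(0, 0), `8` = c(0, 0)))$tau,
               c(0, 0))
  prof <- aggregate_profile(list(`4` = c(1, 1), `8` = c(0, 2),
                                 `16` = c(3, 0)), class = "PET", K = 50L)
  expect_equal(prof$tau, c(4, 3))
  expect_equal(prof$tau_4, c(1, 1))
  expect_error(aggregate_profile(list(`4` = 1:3, `8` = 1:2)), "length")

  withr::with_seed(23, {
    for (rep in 1:100) {
      taus <- list(`4` = runif(6), `8` = runif(6), `16` = runif(6))
      tau <- aggregate_profile(taus)$tau
      for (t_l in taus) expect_true(all(tau >= t_l - 1e-15))
    }
  })
})

test_that("interpret is deterministic, non-negative, and zero for a zero model", {
  mz <- zero_model(tiny_config(), labels = c("PET", "PCL", "PLA"))
  prof <- interpret(mz, "ACDEFGHIKL", "PET", K = 4)
  expect_equal(prof$tau, rep(0, 10))
  expect_equal(nrow(prof), 10L)   # padding dropped

  m <- build_model(tiny_config(), seed = 3,
                   labels = c("PET", "PCL", "PLA"))
  p1 <- interpret(m, "MKTAYIAKQRQI", "PCL", K = 3)
  p2 <- interpret(m, "MKTAYIAKQRQI", "PCL", K = 3)
  expect_identical(p1, p2)
  expect_true(all(p1$tau >= 0))
  expect_equal(p1$tau, p1$tau_2 + p1$tau_3)
  expect_equal(p1$residue, strsplit("MKTAYIAKQRQI", "")[[1]])
})

test_that("a filter wired to a motif concentrates contributions on it", {
  # single filter exactly matching "GVSA", head passing it straight
  # through: the profile mass must sit on the motif window
  cfg <- model_config(kernel_lengths = 4L, filters_per_branch = 1L,
                      fc_sizes = integer(0), n_classes = 1L,
                      input_length = 30L)
  m <- zero_model(cfg)
  p <- model_parameters(m)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  motif <- c("G", "V", "S", "A")
  for (j in seq_along(motif)) {
    p$branches[[1]]$W[(j - 1) * 21 + match(motif[j], aa), 1] <- 1
  }
  p$branches[[1]]$b[1] <- -3   # only a >= 4-residue match activates
  p$fc[[1]]$W[] <- 1
  m <- set_model_parameters(m, p)
  s <- paste0(strrep("C", 10), "GVSA", strrep("C", 10))
  prof <- interpret(m, s, 1L, K = 1)
  expect_equal(which(prof$tau > 0), 11:14)
  expect_equal(sum(prof$tau), 1)   # ReLU(4 - 3) redistributed over l = 4
})

test_that("profile CSV export writes the documented columns", {
  m <- build_model(tiny_config(), seed = 3, labels = c("PET", "PCL", "PLA"))
  prof <- interpret(m, tibble::tibble(id = "q1", sequence = "ACDEFGHIKL"),
                    "PET", K = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(names(back),
               c("position", "residue", "tau_2", "tau_3", "tau_total"))
  expect_equal(back$tau_total, prof$tau)
})
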