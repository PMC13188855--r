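#' Default bank of class-distinguishing degenerate motifs
#'
#' One degenerate pattern per plastic class, eight residues with `.`
#' matching any canonical residue, sized like real conserved blocks
#' (PROSITE-style patterns around catalytic residues typically span
#' 8-10 positions). Fixed positions are chosen pairwise incompatible
#' (every pattern pair disagrees at shared fixed positions) and the
#' banks share no fixed 4-mer sub-window, so no convolution kernel can
#' confuse two classes and the classes are separable in principle. The
#' PET pattern carries a Gly-X-Ser-X-Gly core mimicking the nucleophile
#' elbow of the alpha/beta-hydrolase fold, so interpretation tests
#' probe exactly the kind of motif the real classifier is expected to
#' highlight.
#'
#' @return Tibble with columns `class` and `pattern`.
#' @export
motif_bank <- function() {
  tibble(
    class = plastic_labels(),
    pattern = c(
      PHA  = "AKDW.EGR",
      PHB  = "CEHM.DPW",
      PBAT = "WQNF.YMT",
      PBS  = "MRKC.HTD",
      PBSA = "FDTN.EWK",
      PLA  = "YEQV.DRH",
      PCL  = "PTSK.NYC",
      PET  = "AG.S.GWE",
      PU   = "HWCM.AEY"
    )[plastic_labels()]
  )
}

# per-class planted copy counts (MotifSpec "copies"); default one
.spec_copies <- function(motif_specs) {
  copies <- if ("copies" %in% names(motif_specs)) {
    as.integer(motif_specs$copies)
  } else rep(1L, nrow(motif_specs))
  if (any(copies < 1L)) abort("copies per positive must be >= 1")
  setNames(copies, motif_specs$class)
}

# normalise a degenerate pattern: X and . are wildcards; fixed positions
# must be canonical residues
.check_pattern <- function(pattern) {
  p <- gsub("X", ".", toupper(pattern), fixed = TRUE)
  chars <- strsplit(p, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(.aa_canonical, "."))
  if (length(bad) > 0) {
    abort(sprintf("pattern '%s' may only use canonical residues and the wildcard . or X",
                  pattern))
  }
  p
}

# Swiss-Prot-like background residue frequencies, channel order
.aa_background <- function(background = c("uniform", "swissprot")) {
  background <- match.arg(background)
  if (background == "uniform") {
    return(setNames(rep(1 / 20, 20), .aa_canonical))
  }
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.36, V = 6.86,
         W = 1.10, Y = 2.92)
  f[.aa_canonical] / sum(f)
}

# uniform draw from an inclusive integer range (robust to lo == hi,
# where sample(n, 1) would draw from 1:n instead)
.draw_length <- function(range) {
  if (range[1] == range[2]) return(as.integer(range[1]))
  sample(seq(range[1], range[2]), 1)
}

.random_background <- function(length, freqs) {
  paste(sample(names(freqs), length, replace = TRUE, prob = freqs),
        collapse = "")
}

.instantiate_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  wild <- chars == "."
  chars[wild] <- sample(.aa_canonical, sum(wild), replace = TRUE)
  paste(chars, collapse = "")
}

.matches_any <- function(sequence, patterns) {
  any(vapply(patterns, function(p) grepl(p, sequence), logical(1)))
}

#' Generate a seeded motif-planted multi-label sequence dataset
#'
#' Backgrounds are drawn i.i.d. from the chosen residue frequency
#' table; each positive sequence carries one planted instance of its
#' class pattern (wildcards instantiated at random) at a uniformly
#' random position, overwritten onto the background, and a
#' `multilabel_rate` fraction of positives additionally carries a
#' second class's motif (and both labels). Negative sequences are
#' rejection-sampled until they match no class pattern anywhere, so a
#' negative set is clean for false-discovery evaluation; positive
#' backgrounds are likewise rejected if a foreign class pattern occurs
#' by chance, keeping labels and planted placements exactly consistent.
#' Byte-identical output under a fixed seed.
#'
#' @param n_per_class Positive sequences per class (default 100).
#' @param length_range Inclusive sequence-length range (default
#'   `c(150, 600)`).
#' @param motif_specs Tibble `class`, `pattern`, and optionally
#'   `copies` (planted instances per positive, default 1; real
#'   hydrolases carry their catalytic motif once, so one copy is the
#'   realistic default). `.` or `X` in a pattern matches any canonical
#'   residue; default bank is [motif_bank()].
#' @param multilabel_rate Fraction of positives carrying motifs (and
#'   labels) of two classes (default 0.1).
#' @param n_negatives Number of motif-free negative sequences (default
#'   500).
#' @param background `"uniform"` (default) or `"swissprot"` residue
#'   frequencies.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap per sequence; exceeding
#'   it (a pattern so permissive that clean backgrounds are
#'   unreachable) is an error.
#' @return A `synthetic_dataset`: list with `records` (tibble `id`,
#'   `sequence`), `labels` (tibble `id` + 9 indicator columns),
#'   `truth` (tibble `id`, `class`, `start`, `end`, `instance`), and
#'   `config`.
#' @export
simulate_dataset <- function(n_per_class = 100L,
                             length_range = c(150L, 600L),
                             motif_specs = motif_bank(),
                             multilabel_rate = 0.1,
                             n_negatives = 500L,
                             background = c("uniform", "swissprot"),
                             seed = 7L,
                             max_attempts = 1000L) {
  background <- match.arg(background)
  stopifnot(nrow(motif_specs) >= 1, all(c("class", "pattern") %in% names(motif_specs)))
  if (!all(motif_specs$class %in% plastic_labels())) {
    abort("motif classes must be drawn from plastic_labels()")
  }
  patterns <- setNames(vapply(motif_specs$pattern, .check_pattern,
                              character(1)), motif_specs$class)
  copies <- .spec_copies(motif_specs)
  if (max(nchar(patterns)) > min(length_range)) {
    abort("pattern longer than the minimum sequence length")
  }
  freqs <- .aa_background(background)
  classes <- motif_specs$class

  withr::with_seed(as.integer(seed), {
    ids <- character(0); seqs <- character(0)
    label_sets <- list()
    truth <- list()
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        id <- sprintf("pos_%s_%03d", cl, i)
        planted_classes <- cl
        if (length(classes) > 1 && stats::runif(1) < multilabel_rate) {
          planted_classes <- c(cl, sample(setdiff(classes, cl), 1))
        }
        L <- .draw_length(length_range)
        foreign <- unname(patterns[setdiff(classes, planted_classes)])
        for (attempt in seq_len(max_attempts)) {
          s <- .random_background(L, freqs)
          placements <- list()
          occupied <- integer(0)
          ok <- TRUE
          for (pc in planted_classes) {
            for (copy in seq_len(copies[[pc]])) {
              inst <- .instantiate_pattern(patterns[[pc]])
              w <- nchar(inst)
              placed <- FALSE
              for (try_ in seq_len(50)) {
                start <- sample(L - w + 1L, 1)
                span <- start:(start + w - 1L)
                if (!any(span %in% occupied)) {
                  substr(s, start, start + w - 1L) <- inst
                  occupied <- c(occupied, span)
                  placements[[length(placements) + 1L]] <-
                    list(class = pc, start = start,
                         end = start + w - 1L, instance = inst)
                  placed <- TRUE
                  break
                }
              }
              if (!placed) { ok <- FALSE; break }
            }
            if (!ok) break
          }
          if (ok && length(foreign) > 0 && .matches_any(s, foreign)) ok <- FALSE
          # planting the second motif may not destroy the first
          if (ok) {
            ok <- all(vapply(placements, function(p) {
              grepl(patterns[[p$class]],
                    substr(s, p$start, p$end))
            }, logical(1)))
          }
          if (ok) break
          if (attempt == max_attempts) {
            abort(sprintf("could not place motifs cleanly for '%s' after %d attempts; pattern too permissive?",
                          id, max_attempts))
          }
        }
        ids <- c(ids, id); seqs <- c(seqs, s)
        label_sets[[id]] <- planted_classes
        for (p in placements) {
          truth[[length(truth) + 1L]] <-
            tibble(id = id, class = p$class, start = p$start,
                   end = p$end, instance = p$instance)
        }
      }
    }
    for (i in seq_len(n_negatives)) {
      id <- sprintf("neg_%04d", i)
      L <- .draw_length(length_range)
      done <- FALSE
      for (attempt in seq_len(max_attempts)) {
        s <- .random_background(L, freqs)
        if (!.matches_any(s, unname(patterns))) { done <- TRUE; break }
      }
      if (!done) {
        abort(sprintf("could not sample a motif-free negative after %d attempts; pattern too permissive?",
                      max_attempts))
      }
      ids <- c(ids, id); seqs <- c(seqs, s)
      label_sets[[id]] <- character(0)
    }
    records <- tibble(id = ids, sequence = seqs)
    labels <- labels_to_tibble(ids, label_sets[ids])
    truth_tbl <- if (length(truth) > 0) dplyr::bind_rows(truth) else {
      tibble(id = character(), class = character(), start = integer(),
             end = integer(), instance = character())
    }
    structure(list(records = records, labels = labels, truth = truth_tbl,
                   config = list(n_per_class = n_per_class,
                                 length_range = as.integer(length_range),
                                 motif_specs = as.list(patterns),
                                 multilabel_rate = multilabel_rate,
                                 n_negatives = as.integer(n_negatives),
                                 background = background,
                                 seed = as.integer(seed))),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  npos <- sum(rowSums(label_matrix(x$labels)) > 0)
  cat("Synthetic motif-planted dataset:",
      nrow(x$records), "sequences (", npos, "positives,",
      nrow(x$records) - npos, "negatives ),",
      nrow(x$truth), "planted motifs\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `sequences.fasta`, `labels.csv` (columns `id`, `labels` with
#' `;`-joined multi-labels), `truth_motifs.csv` (one row per planted
#' motif copy) and `config.yaml`. The files round-trip through
#' [read_fasta()] / [read_labels()] with identical content.
#'
#' @param dataset A `synthetic_dataset`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create directory %s", outdir))
  if (nrow(dataset$records) == 0) {
    warn("writing an empty dataset")
  }
  write_fasta(dataset$records, file.path(outdir, "sequences.fasta"))
  mat <- label_matrix(dataset$labels)
  lab_str <- apply(mat, 1, function(r) {
    paste(colnames(mat)[r == 1], collapse = ";")
  })
  readr::write_csv(tibble(id = dataset$labels$id, labels = unname(lab_str)),
                   file.path(outdir, "labels.csv"))
  readr::write_csv(dataset$truth, file.path(outdir, "truth_motifs.csv"))
  yaml::write_yaml(dataset$config, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Read a written synthetic dataset back
#'
#' @param dir Directory produced by [write_dataset()].
#' @return A `synthetic_dataset` (config as stored in `config.yaml`).
#' @export
read_dataset <- function(dir) {
  records <- read_fasta(file.path(dir, "sequences.fasta"))
  labels <- read_labels(file.path(dir, "labels.csv"), records)
  truth <- readr::read_csv(
    file.path(dir, "truth_motifs.csv"),
    col_types = readr::cols(id = readr::col_character(),
                            class = readr::col_character(),
                            start = readr::col_integer(),
                            end = readr::col_integer(),
                            instance = readr::col_character()),
    progress = FALSE)
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  structure(list(records = records, labels = labels, truth = truth,
                 config = config),
            class = "synthetic_dataset")
}
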