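# Candidate library construction, phospho-evidence filtering, ranking
# rules, and validation-panel selection.

test_that("the candidate library covers every S/T exactly once", {
  lib <- build_candidate_library(c(toy = "MSTAS"))
  expect_identical(nrow(lib), 3L)
  expect_identical(lib$site, c(2L, 3L, 5L))
  expect_identical(lib$sequence[1], "XXXXXXM(pS)TASXXXX")

  # window count equals an independent regex count of S/T
  set.seed(61)
  prs <- lapply(1:4, function(i)
    generate_protein(sample(60:200, 1), st_density = runif(1, 0.05, 0.3),
                     seed = i, id = paste0("p", i)))
  seqs <- vapply(prs, `[[`, character(1), "sequence")
  names(seqs) <- vapply(prs, `[[`, character(1), "id")
  lib <- build_candidate_library(seqs)
  regex_count <- sum(lengths(gregexpr("[ST]", seqs)))
  expect_identical(nrow(lib), regex_count)

  # a protein without S/T contributes nothing
  expect_identical(nrow(build_candidate_library(c(none = "AAAGGGAAA"))), 0L)
  expect_error(build_candidate_library(character(0)), "no protein")
})

test_that("phospho-evidence filtering keeps exactly the annotated sites", {
  lib <- build_candidate_library(c(p1 = "MSTASAAAAST", p2 = "AATAA"))
  ann <- data.frame(protein = c("p1", "p1"), site = c(2L, 10L))
  expect_message(kept <- filter_phosphorylated(lib, ann), "retained")
  expect_identical(kept$site, c(2L, 10L))
  expect_identical(unique(kept$protein), "p1")

  all_ann <- lib[c("protein", "site")]
  expect_message(everything <- filter_phosphorylated(lib, all_ann), "0 of")
  expect_identical(everything$sequence, lib$sequence)

  none <- suppressMessages(
    filter_phosphorylated(lib, data.frame(protein = character(0),
                                          site = integer(0))))
  expect_identical(nrow(none), 0L)

  bad <- data.frame(protein = "p1", site = 4L)  # residue A, not S/T
  expect_error(filter_phosphorylated(lib, bad), "not at an S/T")
})

test_that("ranking is vote-major, mean-minor with a lexicographic tie-break", {
  # hand-traced toy ordering: vote dominates the mean score
  votes <- c(3L, 2L, 3L)
  means <- c(0.7, 0.99, 0.9)
  seqs <- c("b", "c", "a")
  ord <- screen_order(votes, means, seqs)
  expect_identical(ord, c(3L, 1L, 2L))   # (3,0.9), (3,0.7), then vote 2
  # exact tie on (vote, mean): sequence text decides, deterministically
  ord2 <- screen_order(c(2L, 2L), c(0.5, 0.5), c("B", "A"))
  expect_identical(ord2, c(2L, 1L))
  # permutation invariance of the resulting order
  set.seed(67)
  v <- sample(0:3, 20, replace = TRUE)
  m <- round(runif(20), 2)
  s <- replicate(20, paste(sample(LETTERS, 8), collapse = ""))
  ref <- data.frame(v, m, s)[screen_order(v, m, s), ]
  perm <- sample(20)
  shuffled <- data.frame(v = v[perm], m = m[perm], s = s[perm])
  reordered <- shuffled[screen_order(shuffled$v, shuffled$m, shuffled$s), ]
  expect_identical(reordered$s, ref$s)
})

test_that("known binders are excluded from ranks but kept for audit", {
  d <- generate_dataset(n = 40, seed = 71)
  cfgs <- lapply(c(mlp = "mlp", cnn = "cnn", gru = "gru"), function(a)
    model_config(a, max_epochs = 2L, n_restarts = 1L))
  ens <- fit_binding_ensemble(d[1:30, ], d[31:40, ], seed = 5, configs = cfgs)
  pr <- generate_protein(80, st_density = 0.25, seed = 73, id = "scan")
  lib <- build_candidate_library(stats::setNames(pr$sequence, pr$id))
  known <- data.frame(protein = "scan", site = lib$site[1:2])
  rk <- rank_candidates(lib, ens, known)
  expect_identical(sum(rk$known_binder_excluded), 2L)
  expect_true(all(is.na(rk$rank[rk$known_binder_excluded])))
  ranked <- rk[!rk$known_binder_excluded, ]
  expect_identical(ranked$rank, seq_len(nrow(ranked)))
  # ranked rows follow the vote/mean order
  expect_identical(screen_order(ranked$vote, ranked$mean_score, ranked$sequence),
                   seq_len(nrow(ranked)))
  # per-record consistency with member scores
  sc <- as.matrix(ranked[c("score_mlp", "score_cnn", "score_gru")])
  expect_equal(ranked$mean_score, unname(rowMeans(sc)), tolerance = 1e-12)
  expect_identical(ranked$vote, as.integer(rowSums(sc > 0.5)))
  f <- tempfile(fileext = ".csv")
  write_screen_csv(rk, f)
  out <- read.csv(f)
  expect_identical(nrow(out), nrow(rk))
  expect_true(all(c("rank", "predicted_outcome", "mean_score", "vote")
                  %in% names(out)))
})

test_that("the validation panel takes the ranking's head and tail", {
  rk <- data.frame(rank = 1:10, sequence = letters[1:10],
                   known_binder_excluded = FALSE)
  panel <- select_validation_panel(rk)
  expect_identical(nrow(panel), 10L)
  expect_identical(panel$panel, rep(c("candidate", "control"), c(8, 2)))
  expect_identical(panel$rank[panel$panel == "control"], 9:10)
  expect_length(intersect(panel$sequence[panel$panel == "candidate"],
                          panel$sequence[panel$panel == "control"]), 0L)
  zero_top <- select_validation_panel(rk, n_top = 0, n_controls = 2)
  expect_identical(zero_top$panel, c("control", "control"))
  expect_error(select_validation_panel(rk[1:5, ]), "at least 10")
})
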