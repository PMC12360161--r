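# Split protocol with leakage control, metric formulas, replicate
# aggregation and the paired Wilcoxon comparison.

test_that("split plan fractions, stratification and determinism hold", {
  d <- generate_dataset(n = 715, seed = 17)
  plan <- make_split_plan(d, seed = 17)
  expect_length(plan$replicates, 10L)
  n1 <- sum(d$label == 1)
  for (rp in plan$replicates) {
    test_full <- c(rp$test, rp$test_removed)
    expect_identical(length(rp$train) + length(rp$val) + length(test_full), 715L)
    expect_length(intersect(rp$train, rp$val), 0L)
    expect_length(intersect(rp$train, test_full), 0L)
    expect_length(intersect(rp$val, test_full), 0L)
    expect_true(length(test_full) %in% 70:72)  # 10% folds, +-1 per class
    expect_true(abs(length(rp$train) - 0.675 * 715) <= 2)
    # class ratio within one window of the dataset ratio, per set
    for (set in list(rp$train, rp$val, test_full)) {
      expected <- length(set) * n1 / 715
      expect_lte(abs(sum(d$label[set] == 1) - expected), 1)
    }
  }
  # every window is tested exactly once across the 10 folds
  all_test <- sort(unlist(lapply(plan$replicates,
                                 function(r) c(r$test, r$test_removed))))
  expect_identical(all_test, 1:715)
  plan2 <- make_split_plan(d, seed = 17)
  expect_identical(plan, plan2)
  expect_error(make_split_plan(d[d$label == 1, ], seed = 1), "2 windows per class")
})

test_that("leaky test windows are removed, not reassigned", {
  base <- generate_dataset(n = 60, seed = 23)
  # plant exact duplicates: whenever a duplicate pair is split between
  # test and train/val, the test copy must go
  d <- rbind(base, base[1:10, ])
  rownames(d) <- NULL
  plan <- make_split_plan(d, seed = 23)
  removed_total <- 0L
  for (rp in plan$replicates) {
    removed_total <- removed_total + length(rp$test_removed)
    if (length(rp$test)) {
      dmat <- peptide_edit_matrix(d$sequence[rp$test],
                                  d$sequence[c(rp$train, rp$val)])
      expect_gt(min(dmat), 4L)
    }
  }
  expect_gt(removed_total, 0L)
  # distance exactly 5 is retained, 4 is not, relative to the same plan
  expect_true(all(vapply(plan$replicates, function(rp)
    all(apply(peptide_edit_matrix(d$sequence[rp$test_removed],
                                  d$sequence[c(rp$train, rp$val)]), 1, min) <= 4),
    logical(1))))
})

test_that("confusion counting matches a brute-force oracle", {
  expect_error(confusion(c(0, 1), 0.5), "equal length")
  cc <- confusion(c(1, 1, 0, 0), c(.9, .8, .1, .2))
  expect_identical(unlist(cc), c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  # all-zero scores on mixed labels yield no positive calls
  cc0 <- confusion(c(1, 0, 1), c(0, 0, 0))
  expect_identical(cc0$TP + cc0$FP, 0L)

  set.seed(31)
  y <- sample(0:1, 500, replace = TRUE)
  s <- runif(500)
  cc <- confusion(y, s)
  tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
  for (i in 1:500) {
    pred <- s[i] > 0.5
    if (pred && y[i] == 1) tp <- tp + 1L
    if (!pred && y[i] == 0) tn <- tn + 1L
    if (pred && y[i] == 0) fp <- fp + 1L
    if (!pred && y[i] == 1) fn <- fn + 1L
  }
  expect_identical(unlist(cc), c(TP = tp, TN = tn, FP = fp, FN = fn))
  # raising the threshold never increases TP or FP
  prev <- confusion(y, s, 0.1)
  for (th in seq(0.2, 0.9, by = 0.1)) {
    cur <- confusion(y, s, th)
    expect_lte(cur$TP, prev$TP)
    expect_lte(cur$FP, prev$FP)
    prev <- cur
  }
})

test_that("metric formulas match an independent oracle to 1e-12", {
  set.seed(37)
  for (i in 1:1000) {
    cc <- as.list(sample(0:60, 4, replace = TRUE))
    names(cc) <- c("TP", "TN", "FP", "FN")
    orc <- metric_oracle(cc$TP, cc$TN, cc$FP, cc$FN)
    met <- suppressWarnings(classification_metrics(cc))
    for (k in c("Pr", "Rc", "Sp", "BA", "F1")) {
      if (is.finite(orc[[k]])) {
        expect_equal(met[[k]], 100 * orc[[k]], tolerance = 1e-12)
      }
    }
    if (!anyNA(met[c("Rc", "Sp")]))
      expect_equal(met[["BA"]], (met[["Rc"]] + met[["Sp"]]) / 2,
                   tolerance = 1e-12)
  }
  m <- classification_metrics(list(TP = 58, TN = 34, FP = 0, FN = 0))
  expect_equal(unname(m[c("Pr", "Rc", "Sp", "BA", "F1")]), rep(100, 5))
  w <- capture_warnings(
    und <- classification_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0)))
  expect_match(w, "undefined", all = TRUE)
  expect_length(w, 2L)                      # both Rc and Pr are undefined
  expect_true(is.na(und[["Pr"]]))
  expect_true(is.na(und[["Rc"]]))
  expect_true(is.na(und[["BA"]]))
})

test_that("replicate aggregation gives means and sample SDs", {
  agg <- aggregate_replicates(data.frame(BA = c(70, 80)))
  expect_equal(agg["mean", "BA"], 75)
  expect_equal(agg["sd", "BA"], sd(c(70, 80)), tolerance = 1e-12)
  same <- aggregate_replicates(data.frame(BA = rep(64.2, 5)))
  expect_equal(same["sd", "BA"], 0)
  set.seed(41)
  x <- data.frame(a = rnorm(10), b = runif(10))
  agg2 <- aggregate_replicates(x)
  expect_equal(unlist(agg2["mean", ]), c(a = mean(x$a), b = mean(x$b)),
               tolerance = 1e-12)
  expect_equal(unlist(agg2["sd", ]), c(a = sd(x$a), b = sd(x$b)),
               tolerance = 1e-12)
  expect_warning(aggregate_replicates(data.frame(BA = c(1, NA, 3))), "excluded")
  expect_error(aggregate_replicates(data.frame(BA = 1)), "at least 2")
})

test_that("paired Wilcoxon matches exact sign enumeration", {
  a <- c(71, 72, 73, 74, 75, 76)
  expect_identical(compare_models_paired(a, a)$p.value, 1)
  expect_false(compare_models_paired(a, a)$significant)

  b <- a - c(1, 2, 3, 4, 5, 6) / 10
  res <- compare_models_paired(a, b)
  expect_equal(res$p.value, 2 / 64, tolerance = 1e-12)
  expect_true(res$significant)

  set.seed(43)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    x <- rnorm(n)
    y <- x + rnorm(n)      # continuous: no ties, no zeros
    res <- compare_models_paired(x, y)
    expect_equal(res$p.value, wilcoxon_enum_p(x - y), tolerance = 1e-12)
  }
  expect_error(compare_models_paired(1:3, 4:6), "at least 5")
  expect_error(compare_models_paired(1:6, 1:5), "equal length")
})
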