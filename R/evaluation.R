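# Leakage-aware split construction, the confusion/metric suite,
# replicate aggregation, and paired model comparison.

# Stratified assignment of each class to 10 folds (sizes within 1).
stratified_folds <- function(labels, k = 10L) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified split of `idx` into two parts with proportion `p` in the
# first; per class, counts use largest-remainder rounding.
stratified_two_way <- function(idx, labels, p) {
  first <- integer(0)
  for (cl in unique(labels)) {
    cl_idx <- sample(idx[labels == cl])
    n_first <- round(p * length(cl_idx))
    first <- c(first, cl_idx[seq_len(n_first)])
  }
  list(first = first, second = setdiff(idx, first))
}

#' Build the 10-replicate evaluation split plan
#'
#' The dataset is divided by 10-fold stratified cross-validation: in each
#' replicate one fold (10%) is the test set and the remaining 90% is
#' stratified 75/25 into training (67.5% of the total) and validation
#' (22.5%). Test windows lying within `leakage_threshold` edits of any
#' window they could have been learned from are then removed from the
#' test set (not reassigned), preventing train/test leakage through
#' near-duplicate peptides.
#'
#' @param data Labelled window data frame (`sequence`, `label`); at least
#'   two windows per class.
#' @param seed Integer seed; the full plan is reproducible from it.
#' @param leakage_threshold Maximum edit distance treated as leaky
#'   (default 4: test windows at distance <= 4 are removed).
#' @param filter_against `"train_val"` (default, conservative) screens
#'   test windows against both training and validation sequences;
#'   `"train"` against training only.
#' @return Object of class `split_plan`: a list with `replicates` (each
#'   holding integer index vectors `train`, `val`, `test`, and
#'   `test_removed`), plus the fractions, threshold and seed used.
#' @export
make_split_plan <- function(data, seed = 1L, leakage_threshold = 4L,
                            filter_against = c("train_val", "train")) {
  check_dataset(data)
  filter_against <- match.arg(filter_against)
  if (length(unique(data$label)) < 2L || min(table(data$label)) < 2L)
    stop("need at least 2 windows per class for stratified splitting")
  set.seed(seed)
  n <- nrow(data)
  fold <- stratified_folds(data$label, 10L)
  replicates <- lapply(seq_len(10L), function(k) {
    test <- which(fold == k)
    rest <- which(fold != k)
    tv <- stratified_two_way(rest, data$label[rest], 0.75)
    train <- sort(tv$first); val <- sort(tv$second)
    ref <- if (filter_against == "train_val") c(train, val) else train
    dmat <- peptide_edit_matrix(data$sequence[test], data$sequence[ref])
    leaky <- apply(dmat, 1L, min) <= leakage_threshold
    list(train = train, val = val,
         test = sort(test[!leaky]), test_removed = sort(test[leaky]))
  })
  structure(list(replicates = replicates,
                 fractions = c(train = 0.675, val = 0.225, test = 0.10),
                 leakage_threshold = as.integer(leakage_threshold),
                 filter_against = filter_against, seed = as.integer(seed),
                 n = n),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$replicates, function(r)
    c(train = length(r$train), val = length(r$val), test = length(r$test),
      removed = length(r$test_removed)), numeric(4L))
  cat("Split plan:", length(x$replicates), "replicates of", x$n, "windows",
      "(67.5/22.5/10, leakage threshold", x$leakage_threshold, "vs",
      x$filter_against, ")\n")
  print(t(sizes))
  invisible(x)
}

#' Serialize a split plan to JSON for audit
#'
#' @param plan A `split_plan`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Confusion counts at a strict probability threshold
#'
#' @param y_true 0/1 labels.
#' @param y_score Predicted probabilities (or hard 0/1 calls).
#' @param threshold Scores strictly above it are called binders.
#' @return Named list `TP`, `TN`, `FP`, `FN` (class `confusion_counts`);
#'   the four counts sum to `length(y_true)`.
#' @export
confusion <- function(y_true, y_score, threshold = 0.5) {
  if (length(y_true) != length(y_score))
    stop("labels and scores must have equal length")
  pred <- y_score > threshold
  out <- list(TP = sum(pred & y_true == 1), TN = sum(!pred & y_true == 0),
              FP = sum(pred & y_true == 0), FN = sum(!pred & y_true == 1))
  class(out) <- "confusion_counts"
  out
}

#' Classification metrics from confusion counts
#'
#' Computes recall `Rc = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' precision `Pr = TP/(TP+FP)`, balanced accuracy `BA = (Rc+Sp)/2` and
#' `F1 = 2*Pr*Rc/(Pr+Rc)`, reported as percentages. A metric whose
#' denominator is zero is reported as `NA` with a warning, never as 0.
#'
#' @param counts A `confusion_counts` object or a list/vector with
#'   elements `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `Pr`, `Rc`, `Sp`, `BA`, `F1`, `n`
#'   (metrics in percent).
#' @examples
#' classification_metrics(list(TP = 53, TN = 20, FP = 14, FN = 5))
#' @export
classification_metrics <- function(counts) {
  cc <- as.list(counts)
  tp <- cc$TP; tn <- cc$TN; fp <- cc$FP; fn <- cc$FN
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("metric ", what, " undefined (zero denominator); reported as NA")
      return(NA_real_)
    }
    num / den
  }
  rc <- safe_div(tp, tp + fn, "Rc")
  sp <- safe_div(tn, tn + fp, "Sp")
  pr <- safe_div(tp, tp + fp, "Pr")
  ba <- (rc + sp) / 2
  f1 <- if (is.na(pr) || is.na(rc)) NA_real_
        else if (pr + rc == 0) NA_real_
        else 2 * pr * rc / (pr + rc)
  c(Pr = 100 * pr, Rc = 100 * rc, Sp = 100 * sp, BA = 100 * ba,
    F1 = 100 * f1, n = tp + tn + fp + fn)
}

#' Aggregate per-replicate metric reports
#'
#' @param reports A data frame (or matrix) with one row per replicate and
#'   metric columns, e.g. rbind-ed results of
#'   [classification_metrics()].
#' @return Data frame with rows `mean` and `sd` (sample SD); `NA` metric
#'   values are excluded per column with a warning.
#' @export
aggregate_replicates <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) < 2L) stop("need at least 2 replicates to aggregate")
  if (anyNA(reports))
    warning("undefined metric values excluded from replicate aggregation")
  out <- rbind(mean = vapply(reports, mean, numeric(1L), na.rm = TRUE),
               sd   = vapply(reports, stats::sd, numeric(1L), na.rm = TRUE))
  as.data.frame(out)
}

#' Paired Wilcoxon comparison of two models over replicates
#'
#' Two-sided paired Wilcoxon signed-rank test on per-replicate metric
#' values, exact for small samples. Zero differences are dropped before
#' testing (Wilcoxon's original treatment); if every difference is zero
#' the comparison carries no signal and `p = 1` is returned.
#'
#' @param a,b Equal-length paired metric vectors (one entry per
#'   replicate).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic` (V), `p.value`, `significant`, and `n`
#'   (non-zero pairs used).
#' @export
compare_models_paired <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 5L) stop("need at least 5 paired replicates")
  d <- a - b
  nz <- d != 0
  if (!any(nz))
    return(list(statistic = NA_real_, p.value = 1, significant = FALSE, n = 0L))
  wt <- suppressWarnings(
    stats::wilcox.test(a[nz], b[nz], paired = TRUE,
                       exact = sum(nz) <= 12L && !any(duplicated(abs(d[nz])))))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       significant = wt$p.value < alpha, n = sum(nz))
}

#' Benchmark models on the replicates of a split plan
#'
#' Fits the three default architecture/encoding pairs and the ensemble on
#' every requested replicate of a split plan and reports test-set
#' metrics, in the layout of a benchmarking table (one row per model and
#' replicate plus aggregate rows).
#'
#' @param data Labelled window data frame.
#' @param plan A [make_split_plan()] for `data`.
#' @param seed Base seed for member training.
#' @param replicates Which replicates to run (default: all).
#' @return Data frame with columns `model`, `replicate`, `BA`, `Pr`,
#'   `Rc`, `Sp`, `F1`, `n`; aggregate rows have `replicate = NA` and
#'   carry the mean, with a matching `sd_` column set.
#' @export
benchmark_models <- function(data, plan, seed = 1L,
                             replicates = seq_along(plan$replicates)) {
  rows <- list()
  for (r in replicates) {
    rp <- plan$replicates[[r]]
    tr <- data[rp$train, , drop = FALSE]
    va <- data[rp$val, , drop = FALSE]
    te <- data[rp$test, , drop = FALSE]
    ens <- fit_binding_ensemble(tr, va, seed = seed + r)
    pr <- predict(ens, te)
    scores <- list(mlp = pr$score_mlp, cnn = pr$score_cnn,
                   gru = pr$score_gru, ensemble = pr$mean_score)
    for (m in names(scores)) {
      met <- classification_metrics(confusion(te$label, scores[[m]]))
      rows[[length(rows) + 1L]] <-
        data.frame(model = m, replicate = r, t(met))
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$model), function(g) {
    s <- aggregate_replicates(g[c("Pr", "Rc", "Sp", "BA", "F1", "n")])
    data.frame(model = g$model[1L], replicate = NA_integer_,
               Pr = s["mean", "Pr"], Rc = s["mean", "Rc"],
               Sp = s["mean", "Sp"], BA = s["mean", "BA"],
               F1 = s["mean", "F1"], n = s["mean", "n"],
               sd_BA = s["sd", "BA"])
  }))
  out$sd_BA <- NA_real_
  rbind(out, agg)
}
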