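# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the edit-distance oracle is a hand-rolled DP,
# the metric oracle re-codes the formulas, and the Wilcoxon oracle
# enumerates sign assignments exhaustively.

# Tokenize an inline window string without the package parser.
oracle_tokens <- function(s) {
  s <- gsub("(pS)", "s", s, fixed = TRUE)
  s <- gsub("(pT)", "t", s, fixed = TRUE)
  strsplit(s, "", fixed = TRUE)[[1L]]
}

# Quadratic dynamic-programming Levenshtein distance over token vectors.
dp_edit_distance <- function(sa, sb) {
  a <- oracle_tokens(sa)
  b <- oracle_tokens(sb)
  n <- length(a); m <- length(b)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, rep(0L, m))
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Straight re-coding of the metric formulas (fractions, not percent).
metric_oracle <- function(tp, tn, fp, fn) {
  rc <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  pr <- tp / (tp + fp)
  c(Pr = pr, Rc = rc, Sp = sp, BA = (rc + sp) / 2,
    F1 = 2 * pr * rc / (pr + rc))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the |difference| ranks (no ties, no zeros assumed).
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  all_v <- vapply(0:(2^n - 1L), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
  }, numeric(1L))
  p_ge <- mean(all_v >= v_obs)
  p_le <- mean(all_v <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Single-rule reference classifier for the planted motif (R at -3 or P at
# +2 predicts binder).
one_rule_scores <- function(sequences) {
  m <- do.call(rbind, lapply(sequences, oracle_tokens))
  as.numeric(m[, 5] == "R" | m[, 10] == "P")
}

# Random valid inline windows (centered phosphosite).
random_windows <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    left <- paste(sample(aa, 7, replace = TRUE), collapse = "")
    right <- paste(sample(aa, 7, replace = TRUE), collapse = "")
    center <- sample(c("(pS)", "(pT)"), 1L)
    paste0(left, center, right)
  }, character(1L))
}
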