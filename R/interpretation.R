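# Positional-perturbation ("virtual mutation") interpretation study:
# shuffle the residues observed at one window position across peptides,
# re-predict, and measure how much the model's output moves.

#' Shuffle one window position across a peptide set
#'
#' Permutes the tokens occurring at column `position` across all windows
#' (preserving that position's empirical residue distribution); every
#' other column is untouched. The phospho center (column 8) is never
#' shuffled.
#'
#' @param sequences Inline-notation window strings.
#' @param position Column index 1..15; with `relative = TRUE`, a relative
#'   coordinate -7..+7 (0, the phospho center, is forbidden).
#' @param relative Interpret `position` as a relative coordinate.
#' @return Character vector of perturbed windows, same length and order.
#' @export
shuffle_position <- function(sequences, position, relative = FALSE) {
  if (relative) position <- rel_to_col(position)
  position <- as.integer(position)
  if (position < 1L || position > WINDOW_LENGTH)
    stop("position must be a window column in 1..", WINDOW_LENGTH)
  tk <- tokenize_peptides(sequences)
  if (any(tk$phospho_pos == position))
    stop("the phospho center (column ", position, ") is never shuffled")
  tokens <- tk$tokens
  tokens[, position] <- tokens[sample.int(nrow(tokens)), position]
  apply(tokens, 1L, format_peptide)
}

#' Positional impact profile of a trained classifier
#'
#' For every non-center window position, the residues observed at that
#' position are shuffled across the evaluated peptides `n_shuffles`
#' times; the raw change is the mean absolute difference between
#' perturbed and original predicted probabilities, and impacts are
#' expressed as a percentage of the largest raw change (0 = no impact,
#' 100 = maximum impact). The phospho center carries no impact value.
#'
#' @param model A fitted `bind14_model` or `bind14_ensemble` (the
#'   ensemble uses its mean score), or a plain function mapping a
#'   character vector of windows to scores (useful for analytic
#'   reference models).
#' @param data Window data frame or character vector to evaluate on
#'   (typically the training peptides).
#' @param n_shuffles Number of independent shuffles per position
#'   (default 15).
#' @param seed Integer seed for the permutations.
#' @return Data frame of class `position_impact` with columns `position`
#'   (labels -7..+7 with `P` at the center), `column`, `raw_change` and
#'   `impact` (percent; `NA` at the center).
#' @export
position_impact <- function(model, data, n_shuffles = 15L, seed = 1L) {
  if (!inherits(model, c("bind14_model", "bind14_ensemble")) &&
      !is.function(model))
    stop("`model` must be a fitted bind14_model/bind14_ensemble or a function")
  sequences <- if (is.data.frame(data)) data$sequence else data
  if (length(sequences) == 0L) stop("no windows to evaluate")
  score <- function(seqs) {
    if (is.function(model)) model(seqs)
    else if (inherits(model, "bind14_ensemble")) predict(model, seqs, type = "prob")
    else predict(model, seqs)
  }
  base <- score(sequences)
  set.seed(seed)
  raw <- rep(NA_real_, WINDOW_LENGTH)
  for (p in setdiff(seq_len(WINDOW_LENGTH), CENTER_POS)) {
    deltas <- vapply(seq_len(n_shuffles), function(i) {
      mean(abs(score(shuffle_position(sequences, p)) - base))
    }, numeric(1L))
    raw[p] <- mean(deltas)
  }
  mx <- max(raw, na.rm = TRUE)
  impact <- if (mx > 0) 100 * raw / mx else ifelse(is.na(raw), NA_real_, 0)
  structure(data.frame(position = position_labels(),
                       column = seq_len(WINDOW_LENGTH),
                       raw_change = raw, impact = impact),
            class = c("position_impact", "data.frame"),
            n_shuffles = as.integer(n_shuffles), seed = as.integer(seed))
}

#' @export
print.position_impact <- function(x, ...) {
  ns <- attr(x, "n_shuffles")
  cat("Positional impact profile (",
      if (!is.null(ns)) paste0(ns, " shuffles per position; ") else "",
      "impact in % of maximum change)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot a positional impact profile
#'
#' Barplot of per-position impact (percent of the maximum change); the
#' phospho center is shown empty.
#'
#' @param x A `position_impact` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.position_impact <- function(x, ...) {
  h <- x$impact
  h[is.na(h)] <- 0
  graphics::barplot(h, names.arg = x$position, ylab = "impact (% of max)",
                    xlab = "window position", ...)
  invisible(x)
}

#' Write an impact profile to CSV
#'
#' @param profile A `position_impact` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_impact_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
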