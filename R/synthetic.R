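# Motif-planted synthetic phosphopeptide data and toy proteins.
#
# The generator emulates the statistical structure the classifiers
# assume: 15-mer windows centered on pS/pT, roughly balanced binary
# labels, and binder-enriched residues at signature motif positions. The
# default spec plants arginine at -3 and proline at +2 -- the most common
# 14-3-3 binding motif -- with probability 0.9 in binders against the
# background rate in non-binders.

#' Specify a planted binding motif
#'
#' @param positions Relative motif positions (-7..+7, excluding 0).
#' @param residues Motif residue per position.
#' @param p_binder Probability of the motif residue at its position in
#'   binders.
#' @param p_nonbinder Same probability in non-binders.
#' @param background Named probability vector over the 20 canonical
#'   residues used everywhere else (default uniform).
#' @param phospho_mix Fractions of pS vs pT at the center
#'   (default 0.8/0.2).
#' @return A `motif_spec` list.
#' @details At a motif position the planted residue appears with exactly
#'   the class probability: with probability `1 - p` the position is
#'   filled from the background renormalized to exclude that residue, so
#'   the nominal probabilities are also the realized residue frequencies.
#' @export
motif_spec <- function(positions = c(-3L, 2L),
                       residues = c("R", "P"),
                       p_binder = 0.9, p_nonbinder = 0.05,
                       background = NULL,
                       phospho_mix = c(pS = 0.8, pT = 0.2)) {
  if (length(positions) != length(residues))
    stop("`positions` and `residues` must have equal length")
  if (any(positions == 0L))
    stop("motif positions must exclude 0 (the phospho center)")
  p_binder <- rep_len(p_binder, length(positions))
  p_nonbinder <- rep_len(p_nonbinder, length(positions))
  if (any(c(p_binder, p_nonbinder) < 0 | c(p_binder, p_nonbinder) > 1))
    stop("motif probabilities must lie in [0, 1]")
  if (!all(residues %in% AA20)) stop("motif residues must be canonical AAs")
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), AA20)
  background <- background[AA20] / sum(background[AA20])
  if (all(p_binder == p_nonbinder))
    warning("motif probabilities identical across classes: ",
            "labels are uninformative")
  structure(list(positions = as.integer(positions), residues = residues,
                 p_binder = p_binder, p_nonbinder = p_nonbinder,
                 background = background,
                 phospho_mix = phospho_mix / sum(phospho_mix)),
            class = "motif_spec")
}

#' Generate a labelled synthetic phosphopeptide dataset
#'
#' Draws `round(n * balance)` binders and the remainder non-binders. Each
#' window is 15 tokens: the center is pS/pT per the spec's phospho mix;
#' motif positions carry the planted residue with the class-specific
#' probability (falling back to the background otherwise); every other
#' non-center position is drawn from the background.
#'
#' @param n Number of windows (>= 2).
#' @param spec A [motif_spec()].
#' @param balance Binder fraction in (0, 1); counts are rounded.
#' @param seed Integer seed (optional).
#' @return Data frame with `sequence` (inline notation) and `label`,
#'   rows in shuffled order.
#' @examples
#' d <- generate_dataset(n = 10, seed = 1)
#' table(d$label)
#' @export
generate_dataset <- function(n = 715L, spec = motif_spec(), balance = 0.5,
                             seed = NULL) {
  if (n < 2L) stop("need n >= 2")
  if (balance <= 0 || balance >= 1) stop("`balance` must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_bind <- round(n * balance)
  labels <- rep(c(1L, 0L), c(n_bind, n - n_bind))
  cols <- match(spec$positions + CENTER_POS, seq_len(WINDOW_LENGTH))
  make_window <- function(label) {
    tokens <- sample(AA20, WINDOW_LENGTH, replace = TRUE, prob = spec$background)
    p <- if (label == 1L) spec$p_binder else spec$p_nonbinder
    hit <- stats::runif(length(cols)) < p
    tokens[cols[hit]] <- spec$residues[hit]
    for (j in which(!hit)) {
      bg <- spec$background[setdiff(AA20, spec$residues[j])]
      tokens[cols[j]] <- sample(names(bg), 1L, prob = bg)
    }
    tokens[CENTER_POS] <- if (stats::runif(1) < spec$phospho_mix[["pS"]])
      TOK_PS else TOK_PT
    format_peptide(tokens)
  }
  out <- data.frame(sequence = vapply(labels, make_window, character(1L)),
                    label = labels, stringsAsFactors = FALSE)
  out <- out[sample.int(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a random toy protein with known S/T sites
#'
#' @param length Protein length (>= 15).
#' @param st_density Probability that a residue is serine or threonine
#'   (split evenly).
#' @param seed Integer seed (optional).
#' @param id Protein identifier for the FASTA record.
#' @return List with `id`, `sequence` and `sites` (1-based positions of
#'   every S/T; the ground truth for window-count checks).
#' @export
generate_protein <- function(length = 200L, st_density = 0.12, seed = NULL,
                             id = "synthetic_protein") {
  if (length < WINDOW_LENGTH) stop("protein length must be >= ", WINDOW_LENGTH)
  if (!is.null(seed)) set.seed(seed)
  other <- setdiff(AA20, c("S", "T"))
  chars <- ifelse(stats::runif(length) < st_density,
                  sample(c("S", "T"), length, replace = TRUE),
                  sample(other, length, replace = TRUE))
  list(id = id, sequence = paste(chars, collapse = ""),
       sites = which(chars %in% c("S", "T")))
}

#' Write protein records to FASTA
#'
#' @param proteins A list from [generate_protein()], a list of such
#'   lists, or a named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  if (is.list(proteins) && !is.null(proteins$sequence)) proteins <- list(proteins)
  if (is.list(proteins)) {
    seqs <- vapply(proteins, `[[`, character(1L), "sequence")
    names(seqs) <- vapply(proteins, `[[`, character(1L), "id")
    proteins <- seqs
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}
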