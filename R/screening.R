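# Prospective phosphosite screening: candidate library construction from
# protein sequences, phospho-annotation filtering, known-site exclusion,
# and ensemble ranking with validation-panel selection.

#' Build the candidate window library from protein sequences
#'
#' Localizes every serine and threonine residue in the supplied proteins
#' and extracts the 15-residue window around each (padding at the
#' termini).
#'
#' @param proteins Named character vector of protein sequences (e.g. from
#'   [read_protein_fasta()]) or a path to a FASTA file.
#' @return Data frame with columns `protein`, `site` (1-based) and
#'   `sequence`; one row per S/T residue across all proteins.
#' @export
build_candidate_library <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins))
    proteins <- read_protein_fasta(proteins)
  if (length(proteins) == 0L) stop("no protein sequences supplied")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("protein_", seq_along(proteins))
  out <- do.call(rbind, lapply(names(proteins), function(id)
    all_st_windows(proteins[[id]], id)))
  rownames(out) <- NULL
  out
}

#' Read a phosphosite annotation table
#'
#' CSV with columns `protein`, `site` (1-based residue position) and
#' optionally `source` (e.g. literature vs database evidence).
#'
#' @param path CSV path.
#' @return Data frame with `protein`, `site`, `source`.
#' @export
read_phosphosite_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("protein", "site") %in% names(df)))
    stop("annotation CSV must have `protein` and `site` columns: ", path)
  if (!"source" %in% names(df)) df$source <- "annotation-table"
  df$site <- as.integer(df$site)
  df[c("protein", "site", "source")]
}

#' Retain only candidate windows with phospho evidence
#'
#' Keeps the library windows whose (protein, site) pair appears in the
#' annotation table; everything else is dropped (the number dropped is
#' messaged). Annotations pointing at a position that is not an S/T site
#' of a supplied protein are an error.
#'
#' @param library Candidate data frame from [build_candidate_library()].
#' @param annotations Data frame with `protein` and `site` columns.
#' @return The filtered subset of `library`.
#' @export
filter_phosphorylated <- function(library, annotations) {
  key <- function(p, s) paste(p, s, sep = "@")
  lib_keys <- key(library$protein, library$site)
  ann <- annotations[annotations$protein %in% library$protein, , drop = FALSE]
  bad <- !key(ann$protein, ann$site) %in% lib_keys
  if (any(bad))
    stop("annotation(s) not at an S/T residue of the supplied proteins: ",
         paste(utils::head(key(ann$protein, ann$site)[bad]), collapse = ", "))
  keep <- lib_keys %in% key(annotations$protein, annotations$site)
  message(sum(!keep), " of ", nrow(library),
          " candidate windows dropped (no phospho evidence); ",
          sum(keep), " retained")
  out <- library[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screening rank order
#'
#' The total order used to rank a screen: majority vote (descending),
#' then mean ensemble score (descending), then the formatted sequence
#' (lexicographic, as a deterministic tie-break).
#'
#' @param vote,mean_score,sequence Parallel vectors of record fields.
#' @return Integer permutation ordering the records best-first.
#' @export
screen_order <- function(vote, mean_score, sequence) {
  order(-vote, -mean_score, sequence, method = "radix")
}

#' Rank candidate phosphosites with the ensemble
#'
#' Scores every candidate window with the three ensemble members,
#' excludes known binding sites from the ranking (they are kept, rankless
#' and flagged, for audit), and orders the rest by majority vote
#' (descending), then mean score (descending), then formatted sequence
#' (lexicographic tie-break). Ranks are 1-based and unique.
#'
#' @param library Candidate data frame (`protein`, `site`, `sequence`).
#' @param ensemble A fitted `bind14_ensemble`.
#' @param known_sites Optional data frame with `protein` and `site`
#'   columns listing known binders to exclude.
#' @return Data frame of class `screen_ranking`: library columns plus
#'   per-member scores, `mean_score`, `score_sd`, `vote`,
#'   `classification` (mean score strictly above 0.5),
#'   `known_binder_excluded` and `rank` (`NA` for excluded rows).
#'   Ordered ranked rows first.
#' @export
rank_candidates <- function(library, ensemble, known_sites = NULL) {
  if (!inherits(ensemble, "bind14_ensemble"))
    stop("`ensemble` must be a fitted bind14_ensemble")
  if (nrow(library) == 0L) stop("candidate library is empty")
  pred <- predict(ensemble, library$sequence)
  out <- cbind(library, pred)
  out$known_binder_excluded <- FALSE
  if (!is.null(known_sites) && nrow(known_sites)) {
    key <- function(p, s) paste(p, s, sep = "@")
    out$known_binder_excluded <-
      key(out$protein, out$site) %in% key(known_sites$protein, known_sites$site)
  }
  out <- out[screen_order(out$vote, out$mean_score, out$sequence), , drop = FALSE]
  out$rank <- NA_integer_
  ranked <- !out$known_binder_excluded
  out$rank[ranked] <- seq_len(sum(ranked))
  out <- out[order(out$known_binder_excluded, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screen_ranking", "data.frame")
  out
}

#' Select the wet-lab validation panel from a ranking
#'
#' Picks the top-scoring candidates and the bottom-scoring negative
#' controls from the ranked (non-excluded) records.
#'
#' @param ranking A `screen_ranking` from [rank_candidates()].
#' @param n_top Number of top-ranked candidates (default 8).
#' @param n_controls Number of bottom-ranked negative controls
#'   (default 2).
#' @return Subset of `ranking` with an added `panel` column
#'   (`"candidate"` / `"control"`).
#' @export
select_validation_panel <- function(ranking, n_top = 8L, n_controls = 2L) {
  ranked <- ranking[!is.na(ranking$rank), , drop = FALSE]
  if (nrow(ranked) < n_top + n_controls)
    stop("ranking has ", nrow(ranked), " records; need at least ",
         n_top + n_controls)
  head_part <- ranked[seq_len(n_top), , drop = FALSE]
  tail_part <- ranked[seq(nrow(ranked) - n_controls + 1L, length.out = n_controls), ,
                      drop = FALSE]
  if (n_top == 0L) head_part <- ranked[0L, , drop = FALSE]
  if (n_controls == 0L) tail_part <- ranked[0L, , drop = FALSE]
  panel <- rbind(head_part, tail_part)
  panel$panel <- rep(c("candidate", "control"),
                     c(nrow(head_part), nrow(tail_part)))
  rownames(panel) <- NULL
  panel
}

#' Write a ranked screen to CSV
#'
#' Mirrors the reporting layout of a prospective screen: protein, site,
#' sequence, predicted outcome, mean score with across-member SD,
#' per-member scores, vote and rank; excluded known binders are included
#' at the bottom for audit.
#'
#' @param ranking A `screen_ranking`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(ranking, path) {
  df <- as.data.frame(ranking)
  df$predicted_outcome <- ifelse(df$classification == 1, "Binding", "No binding")
  cols <- c("rank", "protein", "site", "sequence", "predicted_outcome",
            "mean_score", "score_sd", "score_mlp", "score_cnn", "score_gru",
            "vote", "known_binder_excluded")
  utils::write.csv(df[cols], path, row.names = FALSE)
  invisible(path)
}
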