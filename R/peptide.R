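# Parsing, formatting and construction of 15-residue binding windows, the
# edit-distance primitive used for leakage control, and Kd-based label
# curation.

#' Parse an inline-notation phosphopeptide string
#'
#' Converts a 15-residue window written in inline notation -- e.g.
#' `"GLMQRSS(pS)FPYTTKG"` -- into its token form. Exactly one `(pS)` or
#' `(pT)` marker must be present; the marker contributes a single phospho
#' token. `(ps)`/`(pt)` and bare lower-case `s`/`t` are accepted on input
#' for robustness; `X` denotes terminal padding.
#'
#' @param text A single inline-notation string.
#' @return A list with elements `tokens` (character vector of length 15)
#'   and `phospho_pos` (1-based column of the phospho token, normally 8).
#' @examples
#' w <- parse_peptide("GLMQRSS(pS)FPYTTKG")
#' w$tokens[w$phospho_pos]   # "s"
#' @seealso [format_peptide()] for the inverse.
#' @export
parse_peptide <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single string")
  s <- gsub("\\(p[Ss]\\)", TOK_PS, text)
  s <- gsub("\\(p[Tt]\\)", TOK_PT, s)
  tokens <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- setdiff(tokens, TOKENS)
  if (length(bad))
    stop("unknown residue letter(s) in peptide string: ",
         paste(unique(bad), collapse = ", "))
  n_phos <- sum(is_phospho_token(tokens))
  if (n_phos == 0L)
    stop("no (pS)/(pT) phospho marker found in: ", text)
  if (n_phos > 1L)
    stop("more than one phospho marker found in: ", text)
  if (length(tokens) != WINDOW_LENGTH)
    stop("peptide window must have exactly ", WINDOW_LENGTH,
         " residues, got ", length(tokens))
  if (tokens[1L] == TOK_PAD && which(is_phospho_token(tokens)) == 0L)
    stop("padding cannot be the phospho center")  # unreachable guard
  list(tokens = tokens, phospho_pos = which(is_phospho_token(tokens)))
}

#' Format a token vector back to inline notation
#'
#' @param tokens Character vector of window tokens (see
#'   [peptide_alphabet()]), or the list returned by [parse_peptide()].
#' @return A single inline-notation string, with the phospho token written
#'   as `(pS)` or `(pT)`.
#' @examples
#' format_peptide(parse_peptide("EEAGIGD(pT)PSLEDEA"))
#' @export
format_peptide <- function(tokens) {
  if (is.list(tokens)) tokens <- tokens$tokens
  out <- tokens
  out[out == TOK_PS] <- "(pS)"
  out[out == TOK_PT] <- "(pT)"
  paste(out, collapse = "")
}

# Vectorised tokenizer: n inline strings -> n x 15 token matrix plus the
# phospho column of each row. Internal workhorse for the encoders.
tokenize_peptides <- function(sequences) {
  parsed <- lapply(sequences, parse_peptide)
  tokens <- do.call(rbind, lapply(parsed, `[[`, "tokens"))
  phospho_pos <- vapply(parsed, `[[`, integer(1L), "phospho_pos")
  list(tokens = tokens, phospho_pos = phospho_pos)
}

# Compact single-character form used for edit distances (phospho tokens are
# already single characters, so this is just marker removal).
peptide_token_string <- function(sequences) {
  s <- gsub("\\(p[Ss]\\)", TOK_PS, sequences)
  gsub("\\(p[Tt]\\)", TOK_PT, s)
}

#' Extract the 15-residue binding window around a phosphosite
#'
#' Takes the seven residues on either side of a serine/threonine at
#' `site` (1-based); positions beyond the protein termini are padded with
#' `X`. The central residue is converted to its phospho token.
#'
#' @param sequence Protein amino-acid string (canonical letters).
#' @param site 1-based residue position; the residue there must be S or T.
#' @return Inline-notation window string (use [parse_peptide()] for the
#'   token form).
#' @examples
#' extract_window("AAAASAAAA", 5)
#' @export
extract_window <- function(sequence, site) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("`sequence` must be a single string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  site <- as.integer(site)
  if (is.na(site) || site < 1L || site > length(chars))
    stop("`site` ", site, " out of range 1..", length(chars))
  center <- chars[site]
  if (!center %in% c("S", "T"))
    stop("residue at site ", site, " is '", center,
         "', not S or T: cannot be a phosphosite")
  idx <- (site - 7L):(site + 7L)
  tokens <- ifelse(idx >= 1L & idx <= length(chars), chars[pmax(pmin(idx, length(chars)), 1L)], TOK_PAD)
  tokens[CENTER_POS] <- if (center == "S") TOK_PS else TOK_PT
  bad <- setdiff(tokens, TOKENS)
  if (length(bad))
    stop("protein contains non-canonical letter(s): ",
         paste(unique(bad), collapse = ", "))
  format_peptide(tokens)
}

#' All serine/threonine windows of a protein
#'
#' Emits one 15-residue binding window per S/T residue of the protein.
#'
#' @param sequence Protein amino-acid string.
#' @param protein Identifier recorded with each window.
#' @return A data frame with columns `protein`, `site` (1-based) and
#'   `sequence` (inline notation); one row per S/T residue.
#' @export
all_st_windows <- function(sequence, protein = NA_character_) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sites <- which(chars %in% c("S", "T"))
  data.frame(
    protein  = rep(protein, length(sites)),
    site     = sites,
    sequence = vapply(sites, function(p) extract_window(sequence, p), character(1L)),
    stringsAsFactors = FALSE
  )
}

#' Levenshtein distance between phosphopeptide windows
#'
#' Edit distance over the 15-token form: phospho tokens are distinct from
#' their parent residues (pS vs S is one substitution) and padding is an
#' ordinary token. `peptide_edit_distance` compares two windows;
#' `peptide_edit_matrix` returns the full cross-distance matrix and is
#' what the leakage filter uses.
#'
#' @param a,b Inline-notation window strings.
#' @param x,y Character vectors of inline-notation windows.
#' @return An integer distance (`peptide_edit_distance`) or a
#'   `length(x)` by `length(y)` integer matrix (`peptide_edit_matrix`).
#' @examples
#' peptide_edit_distance("AAAAAAA(pS)AAAAAAA", "AAAAAAA(pT)AAAAAAA")  # 1
#' @export
peptide_edit_distance <- function(a, b) {
  as.integer(utils::adist(peptide_token_string(a), peptide_token_string(b)))
}

#' @rdname peptide_edit_distance
#' @export
peptide_edit_matrix <- function(x, y) {
  m <- utils::adist(peptide_token_string(x), peptide_token_string(y))
  storage.mode(m) <- "integer"
  m
}

#' Curate a binary binder label from dissociation constants
#'
#' A site measured against several 14-3-3 isoforms is labelled by its
#' strongest (minimum) Kd: binder if that Kd is strictly below the
#' threshold, non-binder otherwise (a Kd exactly at the threshold is a
#' non-binder).
#'
#' @param kd Numeric vector of per-isoform dissociation constants (uM);
#'   all values must be positive.
#' @param threshold Binder cutoff in uM (default 200).
#' @return `1L` (binder) or `0L` (non-binder).
#' @examples
#' label_from_kd(c(gamma = 250, sigma = 180))  # 1: minimum 180 < 200
#' label_from_kd(200)                          # 0: strict threshold
#' @export
label_from_kd <- function(kd, threshold = 200) {
  kd <- kd[!is.na(kd)]
  if (length(kd) == 0L) stop("no Kd values supplied")
  if (any(kd <= 0)) stop("Kd values must be positive")
  as.integer(min(kd) < threshold)
}

# "gamma:150;sigma:180" or a bare number -> named numeric vector.
parse_kd_field <- function(text) {
  parts <- strsplit(trimws(text), ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  vals <- vapply(parts, function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
    as.numeric(kv[length(kv)])
  }, numeric(1L))
  names(vals) <- vapply(parts, function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
    if (length(kv) > 1L) trimws(kv[1L]) else ""
  }, character(1L))
  vals
}

#' Read a labelled phosphopeptide dataset from CSV
#'
#' The CSV dialect has a `sequence` column (inline notation) and either a
#' binary `label` column or a `kd_um` column of semicolon-separated
#' `isoform:value` pairs that is curated with [label_from_kd()]. Optional
#' `protein` and `site` columns are carried through. Duplicate
#' (sequence, label) pairs are collapsed; sequences appearing with both
#' labels are dropped with a warning.
#'
#' @param path CSV file path.
#' @param kd_threshold Binder cutoff in uM used when labels come from Kd.
#' @return Data frame with columns `sequence`, `label` and, when present,
#'   `protein`, `site`. All sequences are validated 15-mers.
#' @export
read_peptide_csv <- function(path, kd_threshold = 200) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sequence" %in% names(df))
    stop("dataset CSV must have a `sequence` column: ", path)
  if (!"label" %in% names(df)) {
    if (!"kd_um" %in% names(df))
      stop("dataset CSV needs a `label` or `kd_um` column: ", path)
    df$label <- vapply(df$kd_um, function(x)
      label_from_kd(parse_kd_field(x), kd_threshold), integer(1L))
  }
  if (!all(df$label %in% c(0L, 1L)))
    stop("labels must be 0/1; offending rows: ",
         paste(utils::head(which(!df$label %in% c(0L, 1L))), collapse = ", "))
  invisible(tokenize_peptides(df$sequence))  # validates every window
  keep <- c("sequence", "label", intersect(c("protein", "site"), names(df)))
  df <- df[keep]
  df <- unique(df)
  conflict <- unique(df$sequence[duplicated(df$sequence)])
  if (length(conflict)) {
    warning(length(conflict),
            " sequence(s) with conflicting labels dropped during curation")
    df <- df[!df$sequence %in% conflict, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a phosphopeptide dataset to CSV
#'
#' @param data Data frame with at least `sequence` and `label`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}
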