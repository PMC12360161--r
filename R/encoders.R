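# The four numeric representations of a 15-residue binding window.
#
# Shape contract (rows are window positions, always 15):
#   onehot         15 x 23   binary indicator per token; PAD rows all-zero
#   embedding_ids  15 x 1    vocabulary index per token (embedding vectors
#                            live in the model and are learned)
#   blosum62_flag  15 x 22   20 BLOSUM62 substitution scores of the parent
#                            residue + [1,0]/[0,1] pS/pT flag
#   descriptors    15 x 20   18 physico-chemical descriptors + phospho flag
#
# All encoders are deterministic pure functions of the window.

ENCODING_SCHEMES <- c("onehot", "embedding_ids", "blosum62_flag", "descriptors")

.enc_env <- new.env(parent = emptyenv())

# 20x20 BLOSUM62 block (canonical residues, alphabetical order), taken from
# the substitution matrix shipped with Biostrings.
blosum62_matrix <- function() {
  if (is.null(.enc_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .enc_env$blosum62 <- e$BLOSUM62[AA20, AA20]
  }
  .enc_env$blosum62
}

#' Load a per-residue descriptor table
#'
#' `default_descriptor_table()` returns the table bundled with the package:
#' 18 widely used physico-chemical scales per canonical amino acid
#' (Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, residue mass,
#' volume, net charge at pH 7, isoelectric point, Grantham polarity,
#' Chou-Fasman helix/sheet/turn propensities, Bhaskaran-Ponnuswamy
#' flexibility, Zimmerman bulkiness, refractivity, accessible surface
#' area, side-chain heavy atoms, H-bond donors/acceptors, aromaticity).
#' Any complete 20-residue table with the same layout can be substituted
#' via `read_descriptor_table()`.
#'
#' @param path CSV with an `aa` column (20 canonical letters) and one
#'   numeric column per descriptor.
#' @return Numeric matrix, 20 rows (amino acids) by D descriptors.
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"aa" %in% names(df)) stop("descriptor CSV must have an `aa` column")
  m <- as.matrix(df[setdiff(names(df), "aa")])
  rownames(m) <- df$aa
  missing <- setdiff(AA20, rownames(m))
  if (length(missing))
    stop("descriptor table incomplete; missing residues: ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(m[AA20, ])))
    stop("descriptor table contains non-finite values")
  m[AA20, , drop = FALSE]
}

#' @rdname read_descriptor_table
#' @export
default_descriptor_table <- function() {
  if (is.null(.enc_env$descriptors)) {
    path <- system.file("extdata", "aa_descriptors_default.csv",
                        package = "phos1433", mustWork = TRUE)
    .enc_env$descriptors <- read_descriptor_table(path)
  }
  .enc_env$descriptors
}

# Accept an inline string or a pre-parsed token vector.
as_window_tokens <- function(w) {
  if (is.list(w)) return(w$tokens)
  if (is.character(w) && length(w) == 1L && nchar(w) > WINDOW_LENGTH)
    return(parse_peptide(w)$tokens)
  if (is.character(w) && length(w) == WINDOW_LENGTH) return(w)
  if (is.character(w) && length(w) == 1L) return(parse_peptide(w)$tokens)
  stop("cannot interpret `w` as a peptide window")
}

#' Encode a binding window
#'
#' Numeric representations of a 15-residue phosphopeptide window; see the
#' scheme-specific shape contracts in Details.
#'
#' @details
#' * `encode_onehot()`: 15 x 23 binary matrix, one column per alphabet
#'   token; phospho tokens have their own columns; padding rows are
#'   all-zero.
#' * `encode_token_ids()`: 15 x 1 integer matrix of vocabulary indices
#'   (1..23, the order of [peptide_alphabet()]); the learnable embedding
#'   vectors themselves live in the model.
#' * `encode_blosum62()`: 15 x 22 matrix; columns 1-20 are the BLOSUM62
#'   substitution scores of the (parent) residue against the 20 canonical
#'   residues, columns 21-22 the phospho flag: `[1,0]` for pS, `[0,1]`
#'   for pT, `[0,0]` otherwise. Padding rows are all-zero.
#' * `encode_descriptors()`: 15 x 20 matrix; columns 1-18 the descriptor
#'   values of the (parent) residue, columns 19-20 the same phospho flag.
#'   Padding rows are all-zero. When used inside a model the descriptor
#'   columns are standardized with training-set statistics
#'   (see [descriptor_scaler()]).
#'
#' @param w An inline-notation window string or a 15-token vector.
#' @param table Descriptor matrix from [read_descriptor_table()].
#' @param scaler Optional scaler from [descriptor_scaler()]; when given,
#'   descriptor columns of non-padding rows are standardized.
#' @return A numeric matrix with 15 rows; `attr(, "scheme")` names the
#'   scheme and column names label the features.
#' @examples
#' m <- encode_blosum62("AAAAAAA(pS)AAAAAAA")
#' m[8, 21:22]   # phosphoserine flag [1, 0]
#' @export
encode_onehot <- function(w) {
  tokens <- as_window_tokens(w)
  m <- matrix(0, WINDOW_LENGTH, length(TOKENS),
              dimnames = list(position_labels(), TOKENS))
  keep <- tokens != TOK_PAD
  m[cbind(which(keep), match(tokens[keep], TOKENS))] <- 1
  structure(m, scheme = "onehot")
}

#' @rdname encode_onehot
#' @export
encode_token_ids <- function(w) {
  tokens <- as_window_tokens(w)
  m <- matrix(match(tokens, TOKENS), WINDOW_LENGTH, 1L,
              dimnames = list(position_labels(), "token_id"))
  structure(m, scheme = "embedding_ids")
}

phospho_flag_rows <- function(tokens) {
  cbind(ps = as.numeric(tokens == TOK_PS),
        pt = as.numeric(tokens == TOK_PT))
}

#' @rdname encode_onehot
#' @export
encode_blosum62 <- function(w) {
  tokens <- as_window_tokens(w)
  B <- blosum62_matrix()
  m <- matrix(0, WINDOW_LENGTH, 22L,
              dimnames = list(position_labels(),
                              c(paste0("blosum_", AA20), "flag_ps", "flag_pt")))
  keep <- tokens != TOK_PAD
  m[keep, 1:20] <- B[parent_residue(tokens[keep]), , drop = FALSE]
  m[, 21:22] <- phospho_flag_rows(tokens)
  structure(m, scheme = "blosum62_flag")
}

#' @rdname encode_onehot
#' @export
encode_descriptors <- function(w, table = default_descriptor_table(),
                               scaler = NULL) {
  tokens <- as_window_tokens(w)
  if (ncol(table) != 18L)
    stop("descriptor table must have exactly 18 descriptor columns, got ",
         ncol(table))
  vals <- table
  if (!is.null(scaler))
    vals <- sweep(sweep(vals, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
  m <- matrix(0, WINDOW_LENGTH, 20L,
              dimnames = list(position_labels(),
                              c(colnames(table), "flag_ps", "flag_pt")))
  keep <- tokens != TOK_PAD
  m[keep, 1:18] <- vals[parent_residue(tokens[keep]), , drop = FALSE]
  m[, 19:20] <- phospho_flag_rows(tokens)
  structure(m, scheme = "descriptors")
}

#' Training-set standardization statistics for the descriptor encoding
#'
#' Computes the per-descriptor mean and standard deviation over all
#' non-padding residues of the training sequences, so that test/screening
#' windows can be standardized without information leaking from them.
#'
#' @param sequences Training windows in inline notation.
#' @param table Descriptor matrix.
#' @return List with numeric vectors `mean` and `sd` (length 18); columns
#'   with zero spread get `sd = 1`.
#' @export
descriptor_scaler <- function(sequences, table = default_descriptor_table()) {
  tk <- tokenize_peptides(sequences)$tokens
  res <- parent_residue(tk[tk != TOK_PAD])
  vals <- table[res, , drop = FALSE]
  mu <- colMeans(vals)
  sdv <- apply(vals, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

#' Encode a set of windows under a named scheme
#'
#' @param sequences Inline-notation window strings.
#' @param scheme One of `"onehot"`, `"embedding_ids"`, `"blosum62_flag"`,
#'   `"descriptors"`.
#' @inheritParams encode_onehot
#' @return A numeric array of dimension `n x 15 x D` with
#'   `attr(, "scheme")` set (`D = 1` integer ids for `embedding_ids`).
#' @export
encode_dataset <- function(sequences, scheme, table = default_descriptor_table(),
                           scaler = NULL) {
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  enc1 <- switch(scheme,
    onehot        = encode_onehot,
    embedding_ids = encode_token_ids,
    blosum62_flag = encode_blosum62,
    descriptors   = function(w) encode_descriptors(w, table, scaler))
  mats <- lapply(sequences, enc1)
  D <- ncol(mats[[1L]])
  arr <- array(0, dim = c(length(sequences), WINDOW_LENGTH, D),
               dimnames = list(NULL, position_labels(), colnames(mats[[1L]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  structure(arr, scheme = scheme)
}

#' Write an encoding to a dense matrix file
#'
#' @param m Matrix from one of the `encode_*` functions.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_encoding_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
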