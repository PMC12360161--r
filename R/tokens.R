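# Token alphabet for 15-residue phosphopeptide binding windows.
#
# Internally every window is a vector of 15 single-character tokens:
# the 20 canonical amino acids (upper case), "s" = phosphoserine,
# "t" = phosphothreonine, and "X" = padding beyond the protein terminus.
# The lower-case phospho tokens are distinct from "S"/"T": a phosphosite
# and its unmodified parent residue never compare equal, and substituting
# one for the other costs one edit.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

TOK_PS  <- "s"
TOK_PT  <- "t"
TOK_PAD <- "X"

TOKENS <- c(AA20, TOK_PS, TOK_PT, TOK_PAD)

WINDOW_LENGTH <- 15L
CENTER_POS    <- 8L   # 1-based column of the phosphosite (-7..+7 window)

#' Phosphopeptide token alphabet
#'
#' The 23 tokens used to represent binding windows: the 20 canonical amino
#' acids, `"s"` (phosphoserine), `"t"` (phosphothreonine) and `"X"`
#' (terminal padding).
#'
#' @return Character vector of length 23.
#' @examples
#' peptide_alphabet()
#' @export
peptide_alphabet <- function() TOKENS

# Parent (unmodified) residue of a token; phospho tokens map to S/T,
# everything else to itself.
parent_residue <- function(tokens) {
  out <- tokens
  out[out == TOK_PS] <- "S"
  out[out == TOK_PT] <- "T"
  out
}

is_phospho_token <- function(tokens) tokens %in% c(TOK_PS, TOK_PT)

# Relative position labels -7..-1, P, +1..+7 for the 15 window columns.
position_labels <- function() {
  c(paste0("-", 7:1), "P", paste0("+", 1:7))
}

# Column index (1..15) for a relative position (-7..+7, 0 = phosphosite).
rel_to_col <- function(rel) {
  rel <- as.integer(rel)
  if (any(rel < -7L | rel > 7L)) stop("relative position must be in -7..+7")
  rel + CENTER_POS
}
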