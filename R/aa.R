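# Amino-acid code tables shared across the package.

#' The 20 standard amino acids
#'
#' One-letter codes in the fixed order used by the node one-hot encoding.
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Non-standard residues with a close standard analogue are encoded as that
# analogue; everything else becomes X (unknown).
AA_NONSTANDARD <- c(
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", MLY = "K", M3L = "K",
  CSO = "C", CSS = "C", CME = "C", OCS = "C", SEP = "S", TPO = "T",
  PTR = "Y", KCX = "K", LLP = "K", CGU = "E", PCA = "Q", SAR = "G",
  AIB = "A", DAL = "A", FME = "M", MLE = "L", NLE = "L", ORN = "K"
)

#' Convert a 3-letter residue name to a 1-letter code
#'
#' Standard residues map to their usual code; non-standard residues with a
#' close standard analogue (e.g. selenomethionine `MSE`) map to that
#' analogue's code; anything else maps to `"X"`.
#'
#' @param resid Character vector of 3-letter residue names.
#' @return Character vector of 1-letter codes.
#' @export
#' @examples
#' aa_one_letter(c("ALA", "MSE", "UNK"))
aa_one_letter <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- AA_THREE_TO_ONE[resid]
  ns <- is.na(out)
  out[ns] <- AA_NONSTANDARD[resid[ns]]
  out[is.na(out)] <- "X"
  unname(out)
}

# One-hot slot (1..21) for a 1-letter code; X and anything unrecognised -> 21.
aa_slot <- function(one_letter) {
  idx <- match(one_letter, AA_STANDARD)
  idx[is.na(idx)] <- 21L
  idx
}
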