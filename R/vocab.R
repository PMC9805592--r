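#' Residue vocabulary and physicochemical lookup tables
#'
#' The 20 canonical amino acids in fixed alphabetical order of their 3-letter
#' codes. This ordering defines the residue-type one-hot encoding and the
#' column order of PSSM profiles throughout the package.
#'
#' @format Character vector of length 20 (3-letter codes).
#' @export
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' One-letter codes matching [AA3] position by position
#' @format Character vector of length 20.
#' @export
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Formal side-chain charge at pH 7. HIS is partially protonated at
# physiological pH; +0.1 is the conventional approximation used here.
.AA_CHARGE <- c(ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0,
                GLU = -1, GLY = 0, HIS = 0.1, ILE = 0, LEU = 0, LYS = 1,
                MET = 0, PHE = 0, PRO = 0, SER = 0, THR = 0, TRP = 0,
                TYR = 0, VAL = 0)

#' Polarity classes used for the 4-way one-hot polarity feature
#' @format Character vector of length 4.
#' @export
POLARITY_CLASSES <- c("apolar", "polar", "positive", "negative")

.AA_POLARITY <- c(ALA = "apolar", ARG = "positive", ASN = "polar",
                  ASP = "negative", CYS = "polar", GLN = "polar",
                  GLU = "negative", GLY = "apolar", HIS = "polar",
                  ILE = "apolar", LEU = "apolar", LYS = "positive",
                  MET = "apolar", PHE = "apolar", PRO = "apolar",
                  SER = "polar", THR = "polar", TRP = "apolar",
                  TYR = "polar", VAL = "apolar")

#' Test whether 3-letter residue names are canonical amino acids
#' @param resid Character vector of 3-letter residue names.
#' @return Logical vector.
#' @export
is_canonical <- function(resid) toupper(resid) %in% AA3

aa3_to_aa1 <- function(resid) {
  i <- match(toupper(resid), AA3)
  out <- AA1[i]
  out[is.na(i)] <- "X"
  out
}

# internal condition constructors ------------------------------------------

grappi_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "grappi_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
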