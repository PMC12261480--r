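# Shared residue-name tables and small helpers.

# 3-letter -> 1-letter amino acid map; selenomethionine folds into M so that
# chains with MSE remain alignable against their unmodified relatives.
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

.AA20 <- sort(unique(unname(.AA3TO1[names(.AA3TO1) != "MSE"])))

.NUC_RESID <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI")

.SOLVENT_RESID <- c("HOH", "DOD", "WAT")

aa3to1 <- function(res3) {
  out <- .AA3TO1[res3]
  out[is.na(out)] <- "X"
  unname(out)
}

# One-letter code for a residue name in either polymer class.
residue_letter <- function(res3, molecule_class) {
  if (molecule_class == "nucleic") {
    one <- sub("^D", "", res3)
    ifelse(nchar(one) == 1L & one %in% c("A", "C", "G", "T", "U", "I"), one, "N")
  } else {
    aa3to1(res3)
  }
}

is_nucleic_resid <- function(res3) res3 %in% .NUC_RESID

.AA1TO3 <- local({
  m <- .AA3TO1[names(.AA3TO1) != "MSE"]
  out <- names(m)
  names(out) <- unname(m)
  out
})

aa1to3 <- function(aa, molecule_class = "protein") {
  if (molecule_class == "nucleic") return(paste0("D", ifelse(aa == "N", "N", aa)))
  out <- .AA1TO3[aa]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Chain key
#'
#' Canonical identifier for one chain of one structure, used to key
#' annotations, cluster members and dataset records.
#'
#' @param structure_id 4-character structure entry identifier.
#' @param chain_id Author chain identifier.
#' @return A string of the form \code{"<structure_id>_<chain_id>"}.
#' @export
chain_key <- function(structure_id, chain_id) {
  paste(structure_id, chain_id, sep = "_")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
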