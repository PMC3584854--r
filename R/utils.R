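# Internal helpers shared across modules.

# Three-letter <-> one-letter amino-acid tables. MSE is selenomethionine,
# read as methionine; anything else non-standard maps to "X".
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)
.AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)
.AA20 <- names(.AA1TO3)[1:20]

#' Build a residue key
#'
#' Residues are addressed throughout the package by a compact key
#' `"<chain>:<res_seq><icode>"` built from the author chain label, author
#' residue number and insertion code (blank when absent), e.g. `"A:33"`.
#'
#' @param chain_id single-character chain label
#' @param res_seq integer author residue number
#' @param icode insertion code, `""` when absent
#' @return character vector of keys
#' @export
residue_key <- function(chain_id, res_seq, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain_id, ":", res_seq, icode)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Nearest integer with halves rounded away from zero (base round() is
# round-half-even, which would print 81.5 -> 82 but also 80.5 -> 80).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
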