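# BLOSUM62 in half-bit integers, NCBI convention for the ambiguity code X
# (X-A/S/T = 0, X-C/P/W = -2, all other X pairs including X-X = -1).
# Transcribed by hand; the test suite checks the 20x20 block entrywise
# against an independent copy.
.BLOSUM62_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                       "L","K","M","F","P","S","T","W","Y","V","X")

.BLOSUM62 <- local({
  v <- c(
  #  A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V  X
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0, 0, # A
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, # R
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,-1, # N
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,-1, # D
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-2, # C
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,-1, # Q
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,-1, # E
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1, # G
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,-1, # H
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-1, # I
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-1, # L
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,-1, # K
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-1, # M
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-1, # F
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2, # P
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, # S
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0, 0, # T
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-2, # W
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-1, # Y
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-1, # V
     0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1  # X
  )
  m <- matrix(as.integer(v), nrow = 21, byrow = TRUE,
              dimnames = list(.BLOSUM62_LETTERS, .BLOSUM62_LETTERS))
  stopifnot(identical(m, t(m)))
  m
})

#' BLOSUM62 substitution score
#'
#' Standard BLOSUM62 half-bit integer scores over the 20 amino-acid letters
#' plus the ambiguity code `X` (NCBI convention: `X` scores 0 against
#' A/S/T, -2 against C/P/W, and -1 against everything else including
#' itself). Unpredicted residues in a site row are scored as `X`, so this
#' convention is load-bearing for match scores.
#'
#' @param a,b one-letter amino-acid codes (vectors recycle as usual)
#' @return integer vector of substitution scores
#' @examples
#' blosum62("D", "D")  # 6
#' blosum62("H", "X")  # -1
#' @export
blosum62 <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  bad <- unique(c(a, b))
  bad <- bad[!bad %in% .BLOSUM62_LETTERS]
  if (length(bad))
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  .BLOSUM62[cbind(a, b)]
}

#' Full BLOSUM62 matrix used by the package
#'
#' @return 21 x 21 integer matrix (20 standard letters plus `X`)
#' @export
blosum62_matrix <- function() .BLOSUM62
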