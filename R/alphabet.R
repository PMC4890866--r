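#' @keywords internal
"_PACKAGE"

#' Canonical 20-letter amino-acid alphabet
#'
#' Integer codes used internally throughout the package: 0 = gap,
#' 1..20 = position in `AA_ALPHABET`. All other symbols are normalized
#' to gap on read.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Background amino-acid distribution
#'
#' Amino-acid frequencies estimated over a non-redundant database of
#' protein sequences (the standard SCA background table); ordered as
#' [AA_ALPHABET], sums to 1.
#' @export
AA_BACKGROUND <- c(A = 0.073, C = 0.025, D = 0.050, E = 0.061, F = 0.042,
                   G = 0.072, H = 0.023, I = 0.053, K = 0.064, L = 0.089,
                   M = 0.023, N = 0.043, P = 0.052, Q = 0.040, R = 0.052,
                   S = 0.073, T = 0.056, V = 0.063, W = 0.013, Y = 0.033)

## Symbols accepted on input but outside the canonical alphabet.
NONCANONICAL <- c("B", "Z", "X", "U", "O", "J", "*")

#' Encode alignment rows as an integer matrix
#'
#' @param rows character vector of equal-length alignment rows.
#' @return integer matrix, M x L, 0 = gap, 1..20 = index in [AA_ALPHABET].
#' @keywords internal
encode_rows <- function(rows) {
  L <- unique(nchar(rows))
  stopifnot(length(L) == 1L)
  chars <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(rows), ncol = L, byrow = TRUE)
  codes <- match(chars, AA_ALPHABET, nomatch = 0L)
  matrix(as.integer(codes), nrow = length(rows), ncol = L)
}

#' Decode an integer alignment matrix back to rows
#' @param A integer matrix (0 = gap).
#' @return character vector of rows.
#' @keywords internal
decode_rows <- function(A) {
  lut <- c("-", AA_ALPHABET)
  apply(A, 1L, function(r) paste(lut[r + 1L], collapse = ""))
}
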