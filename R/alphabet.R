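#' Canonical amino-acid alphabet
#'
#' Ordered 20-letter amino-acid alphabet used throughout the package
#' (`ARNDCQEGHILKMFPSTWYV`). Every Potts model records its alphabet so that
#' field and coupling indices never mix orders between models.
#'
#' @format A character scalar of 20 letters.
#' @export
AA_ALPHABET <- "ARNDCQEGHILKMFPSTWYV"

#' Background amino-acid frequencies
#'
#' Fixed background frequency table f0 over the canonical alphabet, used for
#' the background field v0 (log-frequencies centered to zero sum) that is
#' subtracted from field vectors before scoring and assigned to re-inserted
#' gappy columns. Values are the Robinson & Robinson (1991) amino-acid
#' frequencies estimated from a large set of protein sequences, the standard
#' background of BLAST-family tools; they are renormalized to sum exactly
#' to 1.
#'
#' @format Named numeric vector of length 20, names in [AA_ALPHABET] order.
#' @references Robinson AB, Robinson LR (1991) PNAS 88:8880-8884.
#' @export
AA_BACKGROUND <- local({
  f <- c(
    A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
    Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
    L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
    S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441
  )
  f <- f[strsplit(AA_ALPHABET, "")[[1]]]
  f / sum(f)
})

#' Gap character used in alignments
#' @keywords internal
GAP_CHAR <- "-"

# split an alphabet string into its ordered symbols
alphabet_symbols <- function(alphabet) strsplit(alphabet, "")[[1]]

#' Background frequencies for an arbitrary alphabet
#'
#' Returns [AA_BACKGROUND] when `alphabet` is the canonical 20-letter
#' amino-acid alphabet, and the uniform distribution otherwise (synthetic
#' alphabets have no meaningful composition prior).
#'
#' @param alphabet Alphabet string.
#' @return Numeric vector of length `nchar(alphabet)` summing to 1.
#' @export
background_frequencies <- function(alphabet = AA_ALPHABET) {
  if (identical(alphabet, AA_ALPHABET)) {
    return(unname(AA_BACKGROUND))
  }
  q <- nchar(alphabet)
  rep(1 / q, q)
}
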