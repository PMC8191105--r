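#' Extract residue pairs from a 2-row aligned FASTA
#'
#' Walks the columns of a pairwise alignment and emits one `(posA, posB)`
#' pair per column in which both rows carry a residue; positions are
#' 1-based indices into the ungapped sequences.
#'
#' @param msa A `potts_msa` with exactly 2 rows (e.g. from [read_msa()]).
#' @return Integer matrix with columns `posA`, `posB`, both strictly
#'   increasing.
#' @export
aligned_pairs <- function(msa) {
  if (msa$N != 2) stop("reference alignment must have exactly 2 rows", call. = FALSE)
  r1 <- msa$matrix[1, ]
  r2 <- msa$matrix[2, ]
  p1 <- cumsum(r1 > 0L)
  p2 <- cumsum(r2 > 0L)
  both <- r1 > 0L & r2 > 0L
  cbind(posA = p1[both], posB = p2[both])
}

#' Precision, recall and F1 of a computed alignment
#'
#' A computed pair is correct iff it appears identically in the reference
#' (exact pair identity, no column tolerance). `P = correct / computed`,
#' `R = correct / reference`, `F1 = 2PR / (P + R)`; each ratio is 0 when
#' its denominator is 0.
#'
#' @param computed,reference Two-column matrices of (posA, posB) pairs (as
#'   from [aligned_pairs()] or an alignment's `pairs`).
#' @return List of class `eval_report`: `n_correct`, `n_computed`,
#'   `n_reference`, `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(computed, reference) {
  key <- function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    if (nrow(m) == 0) character(0) else paste(m[, 1], m[, 2], sep = ":")
  }
  ck <- key(computed)
  rk <- key(reference)
  n_correct <- length(intersect(ck, rk))
  n_computed <- length(unique(ck))
  n_reference <- length(unique(rk))
  P <- if (n_computed > 0) n_correct / n_computed else 0
  R <- if (n_reference > 0) n_correct / n_reference else 0
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(
    list(
      n_correct = n_correct, n_computed = n_computed,
      n_reference = n_reference, precision = P, recall = R, f1 = f1
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "precision %.4f  recall %.4f  F1 %.4f  (%d/%d computed, %d reference)\n",
    x$precision, x$recall, x$f1, x$n_correct, x$n_computed, x$n_reference
  ))
  invisible(x)
}

#' Project an alignment of two models onto sequences as 2-row FASTA
#'
#' Renders a pair list as a gapped 2-row alignment of the given sequences
#' (typically the query sequences the models were built from).
#'
#' @param pairs n x 2 matrix of matched positions (1-based).
#' @param seqA,seqB Ungapped character strings.
#' @return Character vector of 2 aligned rows of equal length.
#' @export
project_alignment <- function(pairs, seqA, seqB) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  pairs <- matrix(as.integer(pairs), ncol = 2)
  rowA <- character(0)
  rowB <- character(0)
  ia <- 1L
  ib <- 1L
  emit <- function(upA, upB) {
    # emit unaligned stretches as mutually gapped columns
    while (ia < upA) {
      rowA <<- c(rowA, a[ia])
      rowB <<- c(rowB, "-")
      ia <<- ia + 1L
    }
    while (ib < upB) {
      rowA <<- c(rowA, "-")
      rowB <<- c(rowB, b[ib])
      ib <<- ib + 1L
    }
  }
  if (nrow(pairs) > 0) {
    for (t in seq_len(nrow(pairs))) {
      emit(pairs[t, 1], pairs[t, 2])
      rowA <- c(rowA, a[ia])
      rowB <- c(rowB, b[ib])
      ia <- ia + 1L
      ib <- ib + 1L
    }
  }
  emit(length(a) + 1L, length(b) + 1L)
  c(paste(rowA, collapse = ""), paste(rowB, collapse = ""))
}
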