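#' Multiple sequence alignment container
#'
#' A light S3 container for an MSA over a finite alphabet plus the gap
#' character `-`. Rows are stored as an N x L integer matrix with entries in
#' `1..q` (alphabet index) or `0` for a gap, which is the representation all
#' downstream code (frequency counting, pseudo-likelihood fitting) consumes.
#'
#' @param sequences Character vector of equal-length aligned sequences.
#' @param ids Optional per-row identifiers (default `seq1`, `seq2`, ...).
#' @param alphabet Ordered alphabet string (default [AA_ALPHABET]).
#' @return An object of class `potts_msa` with elements `matrix` (N x L
#'   integer, 0 = gap), `ids`, `alphabet`, `L`, `N`, `q`.
#' @examples
#' msa <- new_msa(c("AC-D", "ACAD"))
#' msa$L # 4
#' @export
new_msa <- function(sequences, ids = NULL, alphabet = AA_ALPHABET) {
  if (length(sequences) == 0) {
    stop("empty MSA: no sequences", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("ragged rows: sequence lengths differ (", paste(unique(lens), collapse = ", "), ")",
      call. = FALSE
    )
  }
  L <- lens[1]
  if (L < 1) stop("empty MSA: zero-length rows", call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  syms <- alphabet_symbols(alphabet)
  chars <- matrix(unlist(strsplit(toupper(sequences), "")),
    nrow = length(sequences), ncol = L, byrow = TRUE
  )
  idx <- match(chars, c(syms))
  idx[chars == GAP_CHAR | chars == "."] <- 0L
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    warning(
      "characters outside alphabet treated as gaps: ",
      paste(bad, collapse = " ")
    )
    idx[is.na(idx)] <- 0L
  }
  structure(
    list(
      matrix = matrix(as.integer(idx), nrow = length(sequences), ncol = L),
      ids = ids, alphabet = alphabet,
      L = L, N = length(sequences), q = length(syms)
    ),
    class = "potts_msa"
  )
}

#' @export
print.potts_msa <- function(x, ...) {
  cat(
    "Multiple sequence alignment: N =", x$N, "sequences, L =", x$L,
    "columns, q =", x$q, "\n"
  )
  invisible(x)
}

#' Recover the row strings of an MSA
#' @param msa A `potts_msa`.
#' @return Character vector of aligned rows.
#' @export
msa_sequences <- function(msa) {
  syms <- c(GAP_CHAR, alphabet_symbols(msa$alphabet))
  apply(msa$matrix, 1, function(r) paste(syms[r + 1L], collapse = ""))
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or A3M file. For A3M, lowercase letters and `.`
#' denote insert states relative to the master sequence and are removed
#' before the rectangular matrix is built. Residues are uppercased.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"a3m"`.
#' @param alphabet Alphabet string (default [AA_ALPHABET]).
#' @return A [new_msa()] object.
#' @export
read_msa <- function(path, format = c("fasta", "a3m"), alphabet = AA_ALPHABET) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty-input: no sequences in ", path, call. = FALSE)
  seqs <- as.character(set)
  if (format == "a3m") {
    # drop insert states (lowercase and '.') before the alignment check
    seqs <- vapply(seqs, function(s) gsub("[a-z.]", "", s), character(1))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("format error: ragged rows after ", format, " normalization", call. = FALSE)
  }
  new_msa(unname(seqs), ids = names(set), alphabet = alphabet)
}

#' Write an MSA as aligned FASTA
#' @param msa A `potts_msa`.
#' @param path Output path.
#' @export
write_msa <- function(msa, path) {
  set <- Biostrings::BStringSet(msa_sequences(msa))
  names(set) <- msa$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# pairwise identity: matches / min(ungapped lengths); gap-gap columns ignored
pairwise_identity <- function(r1, r2) {
  both <- r1 > 0L & r2 > 0L
  n1 <- sum(r1 > 0L)
  n2 <- sum(r2 > 0L)
  denom <- min(n1, n2)
  if (denom == 0) {
    return(0)
  }
  sum(r1[both] == r2[both]) / denom
}

#' Filter an MSA at a maximum pairwise identity
#'
#' Greedy redundancy filter: rows are scanned top to bottom and a row is kept
#' iff its identity to every already-kept row is at most `max_identity`. The
#' first row (the query) is always retained. Identity between two rows is the
#' number of identical aligned residues divided by the shorter ungapped
#' length; columns gapped in both rows are ignored.
#'
#' @param msa A `potts_msa`.
#' @param max_identity Fraction in (0, 1]; default 0.80.
#' @return Filtered `potts_msa`.
#' @export
filter_identity <- function(msa, max_identity = 0.80) {
  if (!is.numeric(max_identity) || max_identity <= 0 || max_identity > 1) {
    stop("max_identity must be in (0, 1]", call. = FALSE)
  }
  keep <- 1L
  if (msa$N > 1) {
    for (n in 2:msa$N) {
      ok <- TRUE
      for (k in keep) {
        if (pairwise_identity(msa$matrix[n, ], msa$matrix[k, ]) > max_identity) {
          ok <- FALSE
          break
        }
      }
      if (ok) keep <- c(keep, n)
    }
  }
  subset_msa(msa, rows = keep)
}

#' Keep only the first rows of an MSA
#' @param msa A `potts_msa`.
#' @param n_max Maximum number of rows to retain (default 1000).
#' @return `potts_msa` with the first `min(N, n_max)` rows, order preserved.
#' @export
cap_depth <- function(msa, n_max = 1000) {
  if (n_max < 1) stop("n_max must be >= 1", call. = FALSE)
  subset_msa(msa, rows = seq_len(min(msa$N, n_max)))
}

subset_msa <- function(msa, rows = seq_len(msa$N), cols = seq_len(msa$L)) {
  m <- msa$matrix[rows, cols, drop = FALSE]
  structure(
    list(
      matrix = m, ids = msa$ids[rows], alphabet = msa$alphabet,
      L = ncol(m), N = nrow(m), q = msa$q
    ),
    class = "potts_msa"
  )
}

#' Remove gap-rich columns
#'
#' Drops every column whose gap fraction is strictly greater than
#' `max_gap_fraction` and records the surviving columns so that trimmed
#' positions can be re-inserted into the inferred model later.
#'
#' @param msa A `potts_msa`.
#' @param max_gap_fraction Columns with gap fraction strictly above this are
#'   removed (default 0.50).
#' @return List with elements `msa` (trimmed `potts_msa`) and `trim` (a
#'   `trim_record`: `kept_columns`, 1-based original indices, and
#'   `original_length`).
#' @export
trim_gappy_columns <- function(msa, max_gap_fraction = 0.50) {
  gap_frac <- colMeans(msa$matrix == 0L)
  kept <- which(gap_frac <= max_gap_fraction)
  if (length(kept) == 0) {
    stop("empty-model: all columns exceed the gap fraction threshold", call. = FALSE)
  }
  list(
    msa = subset_msa(msa, cols = kept),
    trim = trim_record(kept, msa$L)
  )
}

#' Column bookkeeping for trimmed MSAs
#' @param kept_columns Strictly increasing 1-based original column indices.
#' @param original_length Number of columns before trimming.
#' @return A `trim_record`.
#' @export
trim_record <- function(kept_columns, original_length) {
  kept_columns <- as.integer(kept_columns)
  stopifnot(
    all(diff(kept_columns) > 0), all(kept_columns >= 1),
    all(kept_columns <= original_length)
  )
  structure(
    list(kept_columns = kept_columns, original_length = as.integer(original_length)),
    class = "trim_record"
  )
}

#' Empirical single and pair frequencies of an MSA
#'
#' Counts use the q amino-acid states only: gaps contribute to no state, so
#' single-site rows sum to the fraction of non-gap rows at that column
#' (at most 1). Pair frequencies are symmetric,
#' `f_pair[i, j, a, b] == f_pair[j, i, b, a]`.
#'
#' @param msa A `potts_msa`.
#' @return List with `f_single` (L x q), `f_pair` (L x L x q x q),
#'   `f_background` (length q, sums to 1).
#' @export
compute_frequencies <- function(msa) {
  L <- msa$L
  q <- msa$q
  N <- msa$N
  X <- msa$matrix
  f_single <- matrix(0, L, q)
  for (i in seq_len(L)) {
    tab <- tabulate(X[, i], nbins = q)
    f_single[i, ] <- tab / N
  }
  f_pair <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j < i) next
      cnt <- matrix(0, q, q)
      xi <- X[, i]
      xj <- X[, j]
      ok <- xi > 0L & xj > 0L
      if (any(ok)) {
        tt <- table(factor(xi[ok], levels = 1:q), factor(xj[ok], levels = 1:q))
        cnt <- matrix(as.numeric(tt), q, q)
      }
      f_pair[i, j, , ] <- cnt / N
      f_pair[j, i, , ] <- t(cnt) / N
    }
  }
  list(
    f_single = f_single,
    f_pair = f_pair,
    f_background = background_frequencies(msa$alphabet)
  )
}
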