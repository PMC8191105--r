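#' Potts model container
#'
#' A Potts model over sequences of length `L` with `q` states per position:
#' fields `v` (L x q matrix, positional propensities) and couplings `w`
#' (L x L x q x q array, pair compatibilities) with the symmetry
#' `w[i, j, , ] == t(w[j, i, , ])` and `w[i, i, , ] == 0`. The model assigns
#' a sequence x the probability `exp(sum_i v_i(x_i) + sum_{i<j} w_ij(x_i, x_j)) / Z`;
#' the normalizer Z is never computed.
#'
#' @param v L x q numeric matrix of fields.
#' @param w L x L x q x q numeric array of couplings, or `NULL` for an
#'   independent-site model (all couplings zero).
#' @param alphabet Ordered alphabet string of `q` symbols.
#' @param provenance Free-form list of metadata (inference settings etc.).
#' @return An object of class `potts_model`.
#' @export
potts_model <- function(v, w = NULL, alphabet = AA_ALPHABET, provenance = list()) {
  v <- as.matrix(v)
  L <- nrow(v)
  q <- ncol(v)
  if (nchar(alphabet) != q) {
    stop("alphabet length does not match q = ", q, call. = FALSE)
  }
  if (is.null(w)) w <- array(0, dim = c(L, L, q, q))
  stopifnot(identical(dim(w), as.integer(c(L, L, q, q))))
  for (i in seq_len(L)) {
    if (any(w[i, i, , ] != 0)) stop("diagonal coupling blocks must be zero", call. = FALSE)
  }
  structure(
    list(L = L, q = q, v = v, w = w, alphabet = alphabet, provenance = provenance),
    class = "potts_model"
  )
}

#' @export
print.potts_model <- function(x, ...) {
  nb <- 0
  for (i in seq_len(x$L - 1)) {
    for (j in (i + 1):x$L) {
      if (any(x$w[i, j, , ] != 0)) nb <- nb + 1
    }
  }
  cat(
    "Potts model: L =", x$L, ", q =", x$q, ",", nb,
    "nonzero coupling blocks\n"
  )
  invisible(x)
}

# enforce w[j,i] = t(w[i,j]) from the upper triangle
symmetrize_couplings <- function(w) {
  L <- dim(w)[1]
  for (i in seq_len(L)) {
    w[i, i, , ] <- 0
    if (i < L) {
      for (j in (i + 1):L) w[j, i, , ] <- t(w[i, j, , ])
    }
  }
  w
}

#' Frobenius norms of all coupling blocks
#' @param model A `potts_model`.
#' @return L x L matrix of `||w_ij||_F` (zero diagonal).
#' @export
coupling_norms <- function(model) {
  L <- model$L
  out <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i != j) out[i, j] <- sqrt(sum(model$w[i, j, , ]^2))
    }
  }
  out
}

#' Fix the zero-sum gauge of a Potts model
#'
#' The Potts likelihood is invariant under per-pair shifts of couplings
#' compensated in the fields; the zero-sum gauge picks the unique
#' representative with `sum_a v_i(a) = 0` and every row and column of every
#' coupling block summing to zero. Implemented by double-centering each
#' `w_ij` and absorbing the removed row means into `v_i` (the grand mean and
#' the column means shift every per-position conditional by a constant, so
#' conditional distributions are unchanged).
#'
#' @param model A `potts_model`.
#' @return Gauge-fixed `potts_model`.
#' @export
zero_sum_gauge <- function(model) {
  L <- model$L
  v <- model$v
  w <- model$w
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      blk <- w[i, j, , ]
      rm <- rowMeans(blk)
      cm <- colMeans(blk)
      g <- mean(blk)
      w[i, j, , ] <- blk - outer(rm, rep(1, model$q)) - outer(rep(1, model$q), cm) + g
      # row means of w_ij (couplings seen from position i) move into v_i
      v[i, ] <- v[i, ] + (rm - g)
    }
  }
  v <- v - rowMeans(v)
  potts_model(v, w, alphabet = model$alphabet, provenance = model$provenance)
}

#' Energy of a sequence under a Potts model
#'
#' Returns `-(sum_i v_i(x_i) + sum_{i<j} w_ij(x_i, x_j))`, the negative of
#' the model's linear score of the sequence; lower energy means higher
#' probability. Gap characters are rejected: the model has no gap state.
#'
#' @param model A `potts_model`.
#' @param sequence Character string of length `model$L` over the model
#'   alphabet, or an integer vector of state indices in `1..q`.
#' @return Numeric scalar.
#' @export
sequence_energy <- function(model, sequence) {
  if (is.character(sequence)) {
    syms <- alphabet_symbols(model$alphabet)
    x <- match(strsplit(toupper(sequence), "")[[1]], syms)
    if (anyNA(x)) stop("sequence contains characters outside the model alphabet", call. = FALSE)
  } else {
    x <- as.integer(sequence)
    if (any(x < 1 | x > model$q)) stop("state indices out of range", call. = FALSE)
  }
  if (length(x) != model$L) stop("sequence length does not match model length", call. = FALSE)
  s <- sum(model$v[cbind(seq_len(model$L), x)])
  if (model$L > 1) {
    for (i in seq_len(model$L - 1)) {
      for (j in (i + 1):model$L) {
        s <- s + model$w[i, j, x[i], x[j]]
      }
    }
  }
  -s
}

#' Re-insert trimmed columns into a Potts model
#'
#' Positions removed before inference (gap-rich columns) are restored with
#' background fields `v0` and zero couplings to every other position, so the
#' returned model has the original, untrimmed length and coordinates.
#'
#' @param model A `potts_model` of length `length(trim$kept_columns)`.
#' @param trim A [trim_record()].
#' @param v0 Length-q background field vector (zero-sum), e.g.
#'   [background_field()] of the background frequencies.
#' @return `potts_model` of length `trim$original_length`.
#' @export
reinsert_columns <- function(model, trim, v0 = background_field(background_frequencies(model$alphabet))) {
  if (model$L != length(trim$kept_columns)) {
    stop("model length does not match trim record", call. = FALSE)
  }
  if (length(v0) != model$q) stop("v0 length does not match q", call. = FALSE)
  L0 <- trim$original_length
  q <- model$q
  v <- matrix(rep(v0, each = L0), nrow = L0, ncol = q)
  w <- array(0, dim = c(L0, L0, q, q))
  kc <- trim$kept_columns
  v[kc, ] <- model$v
  w[kc, kc, , ] <- model$w
  potts_model(v, w, alphabet = model$alphabet, provenance = model$provenance)
}

#' Write a Potts model to a text file
#'
#' Serialization is a single JSON document: header (`L`, `q`, `alphabet`,
#' `provenance`), the field matrix, and the upper-triangular coupling blocks
#' (one column-major q*q vector per pair i<j). Numbers are written with full
#' double precision so
#' that a write/read round-trip reproduces the model exactly.
#'
#' @param model A `potts_model`.
#' @param path Output path.
#' @export
write_potts <- function(model, path) {
  L <- model$L
  q <- model$q
  blocks <- list()
  if (L > 1) {
    k <- 1
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        blocks[[k]] <- as.vector(model$w[i, j, , ])
        k <- k + 1
      }
    }
  }
  # numbers go through %.17g strings so that read-back is bit-exact
  obj <- list(
    format = "potts-model-json-1",
    L = L, q = q, alphabet = model$alphabet,
    provenance = model$provenance,
    v = sprintf("%.17g", as.vector(model$v)),
    w_upper = lapply(blocks, function(b) sprintf("%.17g", b))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a Potts model written by [write_potts()]
#' @param path Path to the model file.
#' @return A `potts_model`.
#' @export
read_potts <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
  L <- obj$L
  q <- obj$q
  v <- matrix(as.numeric(obj$v), L, q)
  w <- array(0, dim = c(L, L, q, q))
  if (L > 1) {
    wu <- obj$w_upper
    # jsonlite simplifies a list of equal-length vectors to a matrix
    get_block <- if (is.matrix(wu)) {
      function(k) as.numeric(wu[k, ])
    } else {
      function(k) as.numeric(wu[[k]])
    }
    k <- 1
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        w[i, j, , ] <- matrix(get_block(k), q, q)
        k <- k + 1
      }
    }
    w <- symmetrize_couplings(w)
  }
  prov <- obj$provenance
  if (is.null(prov)) prov <- list()
  potts_model(v, w, alphabet = obj$alphabet, provenance = as.list(prov))
}
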