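#' Alignment configuration
#'
#' Hyperparameters of the Potts-to-Potts alignment objective and solver.
#' Defaults are the trained values: coupling coefficient `alpha_w = 6`, gap
#' open 13, gap extend 0, per-aligned-pair offset `gamma = 1`, certified
#' relative precision `epsilon = 0.02`.
#'
#' @param alpha_w Nonnegative weight of the coupling similarity term.
#' @param gap_open Nonnegative penalty per internal gap segment.
#' @param gap_extend Nonnegative penalty per gapped column in a segment.
#' @param offset_gamma Nonnegative penalty subtracted from every positional
#'   similarity (prevents greedy over-alignment).
#' @param epsilon Certified relative optimality gap in (0, 1]:
#'   the solver stops once `2 * (UB - LB) / (s(A,A) + s(B,B)) <= epsilon`.
#' @param w_norm_threshold Coupling sparsification cutoff: pairs whose
#'   Frobenius norm does not exceed it on both sides are dropped from the
#'   coupling score table. Default 0 keeps every pair (the reference
#'   behaviour); any positive value is a tractability knob for long models.
#' @param free_end_gaps Logical; terminal gaps are unpenalized (default
#'   TRUE, global alignment with free ends).
#' @param time_limit_seconds Wall-clock budget for the solver (default
#'   21600 s; practical runs finish in seconds to minutes).
#' @return List of class `align_config`.
#' @export
align_config <- function(alpha_w = 6, gap_open = 13, gap_extend = 0,
                         offset_gamma = 1.0, epsilon = 0.02,
                         w_norm_threshold = 0, free_end_gaps = TRUE,
                         time_limit_seconds = 21600) {
  if (min(alpha_w, gap_open, gap_extend, offset_gamma, w_norm_threshold) < 0) {
    stop("alignment penalties and weights must be nonnegative", call. = FALSE)
  }
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must lie in (0, 1]", call. = FALSE)
  structure(
    list(
      alpha_w = alpha_w, gap_open = gap_open, gap_extend = gap_extend,
      offset_gamma = offset_gamma, epsilon = epsilon,
      w_norm_threshold = w_norm_threshold, free_end_gaps = free_end_gaps,
      time_limit_seconds = time_limit_seconds
    ),
    class = "align_config"
  )
}

#' Positional similarity of two field vectors
#'
#' Scalar product of the background-corrected fields,
#' `<v_i^A - v0, v_k^B - v0>` (a log-odds analogue: a position similar to
#' background contributes nothing).
#'
#' @param vA_i,vB_k Length-q field vectors.
#' @param v0 Length-q background field.
#' @return Numeric scalar.
#' @export
field_similarity <- function(vA_i, vB_k, v0) {
  if (length(vA_i) != length(vB_k) || length(vA_i) != length(v0)) {
    stop("field vectors must share q", call. = FALSE)
  }
  sum((vA_i - v0) * (vB_k - v0))
}

#' Coupling similarity of two coupling blocks
#'
#' Frobenius inner product `sum_{a,b} wA_ij(a,b) * wB_kl(a,b)`.
#'
#' @param wA_ij,wB_kl q x q matrices.
#' @return Numeric scalar.
#' @export
coupling_similarity <- function(wA_ij, wB_kl) {
  if (!all(dim(wA_ij) == dim(wB_kl))) {
    stop("coupling blocks must share dimensions", call. = FALSE)
  }
  sum(wA_ij * wB_kl)
}

#' Precompute similarity score tables for a model pair
#'
#' Builds the positional table `sv[i, k] = <v_i^A - v0, v_k^B - v0> - gamma`
#' (the per-pair offset is folded in here) and the coupling table
#' `sw[i, k, j, l] = <wA_ij, wB_kl>` for `i < j`, `k < l`, restricted to
#' pairs whose blocks both exceed `w_norm_threshold` in Frobenius norm.
#' Also records the self scores `s(A,A)` and `s(B,B)` (identity-alignment
#' scores under the same offset, threshold and `alpha_w`) used by the
#' epsilon optimality certificate.
#'
#' @param A,B `potts_model`s with identical `q` and alphabet.
#' @param v0 Length-q background field (default from the shared alphabet).
#' @param config An [align_config()].
#' @return Object of class `score_tables`: `sv` (L_A x L_B), `sw`
#'   (L_A x L_B x L_A x L_B dense array, entries populated only for
#'   i < j, k < l), `self_score_A`, `self_score_B`, `offset_applied`,
#'   `L_A`, `L_B`.
#' @export
score_tables <- function(A, B, v0 = background_field(background_frequencies(A$alphabet)),
                         config = align_config()) {
  if (A$q != B$q || !identical(A$alphabet, B$alphabet)) {
    stop("models must share alphabet", call. = FALSE)
  }
  q <- A$q
  LA <- A$L
  LB <- B$L
  dvA <- sweep(A$v, 2, v0)
  dvB <- sweep(B$v, 2, v0)
  sv <- dvA %*% t(dvB) - config$offset_gamma

  pairsA <- pair_index(LA)
  pairsB <- pair_index(LB)
  sw <- array(0, dim = c(LA, LB, LA, LB))
  normsA2 <- normsB2 <- numeric(0)
  keepA <- keepB <- logical(0)
  if (nrow(pairsA) > 0 && nrow(pairsB) > 0) {
    MA <- t(vapply(
      seq_len(nrow(pairsA)),
      function(k) as.vector(A$w[pairsA[k, 1], pairsA[k, 2], , ]), numeric(q * q)
    ))
    MB <- t(vapply(
      seq_len(nrow(pairsB)),
      function(k) as.vector(B$w[pairsB[k, 1], pairsB[k, 2], , ]), numeric(q * q)
    ))
    normsA2 <- rowSums(MA^2)
    normsB2 <- rowSums(MB^2)
    thr <- config$w_norm_threshold
    keepA <- if (thr == 0) rep(TRUE, nrow(MA)) else sqrt(normsA2) > thr
    keepB <- if (thr == 0) rep(TRUE, nrow(MB)) else sqrt(normsB2) > thr
    if (any(keepA) && any(keepB)) {
      S <- MA[keepA, , drop = FALSE] %*% t(MB[keepB, , drop = FALSE])
      ia <- which(keepA)
      ib <- which(keepB)
      for (a in seq_along(ia)) {
        pa <- pairsA[ia[a], ]
        for (b in seq_along(ib)) {
          pb <- pairsB[ib[b], ]
          sw[pa[1], pb[1], pa[2], pb[2]] <- S[a, b]
        }
      }
    }
  }
  self_A <- sum(rowSums(dvA^2) - config$offset_gamma) +
    config$alpha_w * sum(normsA2[keepA])
  self_B <- sum(rowSums(dvB^2) - config$offset_gamma) +
    config$alpha_w * sum(normsB2[keepB])
  structure(
    list(
      sv = sv, sw = sw, L_A = LA, L_B = LB,
      self_score_A = self_A, self_score_B = self_B,
      offset_applied = config$offset_gamma,
      w_norm_threshold = config$w_norm_threshold
    ),
    class = "score_tables"
  )
}

#' Re-evaluate the alignment objective for a given set of pairs
#'
#' Computes `sum sv + alpha_w * sum sw - gap costs` for an explicit list of
#' matched pairs, directly from the score tables. Used to verify solver
#' score certificates.
#'
#' @param tables A [score_tables()] object.
#' @param pairs n x 2 matrix of matched (i, k) with both columns strictly
#'   increasing.
#' @param config An [align_config()].
#' @return Numeric scalar (0 for an empty alignment).
#' @export
alignment_objective <- function(tables, pairs, config = align_config()) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  n <- nrow(pairs)
  if (n == 0) {
    return(0)
  }
  if (n > 1 && (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) <= 0))) {
    stop("pairs must be strictly increasing in both coordinates", call. = FALSE)
  }
  s <- sum(tables$sv[pairs])
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        s <- s + config$alpha_w *
          tables$sw[pairs[a, 1], pairs[a, 2], pairs[b, 1], pairs[b, 2]]
      }
    }
    dA <- diff(pairs[, 1]) - 1L
    dB <- diff(pairs[, 2]) - 1L
    s <- s - sum(ifelse(dA > 0, config$gap_open + config$gap_extend * dA, 0)) -
      sum(ifelse(dB > 0, config$gap_open + config$gap_extend * dB, 0))
  }
  if (!config$free_end_gaps) {
    lead_A <- pairs[1, 1] - 1L
    lead_B <- pairs[1, 2] - 1L
    trail_A <- tables$L_A - pairs[n, 1]
    trail_B <- tables$L_B - pairs[n, 2]
    for (g in c(lead_A, lead_B, trail_A, trail_B)) {
      if (g > 0) s <- s - (config$gap_open + config$gap_extend * g)
    }
  }
  s
}
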