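#' Alignment graph of two model lengths
#'
#' The candidate-match graph: one node `i.k` per pair of positions, one
#' directed edge `(i.k, j.l)` for every `i < j`, `k < l`. An alignment is a
#' strictly increasing node set (an increasing path). For small sizes the
#' edge list is materialized; for larger problems only the counts are
#' reported (the solver never builds the explicit edge list).
#'
#' @param L_A,L_B Model lengths (>= 1).
#' @param materialize_edges Return the explicit edge list when the edge
#'   count does not exceed `1e6` (default TRUE).
#' @return List with `n_nodes`, `n_edges`, and (optionally) `edges`, a
#'   matrix with columns `i, k, j, l`.
#' @export
alignment_graph <- function(L_A, L_B, materialize_edges = TRUE) {
  stopifnot(L_A >= 1, L_B >= 1)
  n_edges <- choose(L_A, 2) * choose(L_B, 2)
  out <- list(n_nodes = L_A * L_B, n_edges = n_edges)
  if (materialize_edges && n_edges <= 1e6 && n_edges > 0) {
    pa <- pair_index(L_A)
    pb <- pair_index(L_B)
    edges <- cbind(
      i = rep(pa[, 1], each = nrow(pb)),
      k = rep(pb[, 1], times = nrow(pa)),
      j = rep(pa[, 2], each = nrow(pb)),
      l = rep(pb[, 2], times = nrow(pa))
    )
    out$edges <- edges
  } else if (n_edges == 0) {
    out$edges <- matrix(integer(0), ncol = 4, dimnames = list(NULL, c("i", "k", "j", "l")))
  }
  out
}

#' Mutually contradicting node sets of the alignment graph
#'
#' `row_ik(j)` is the maximal antichain of heads at row `j` reachable from
#' node `i.k` (for `j > i`: all `j.l` with `l > k`); `col_ik(l)` its column
#' analogue. No two members lie on a common increasing path. These families
#' define the activation constraints of the integer programming formulation.
#'
#' @param i,k Node coordinates. @param j Target row. @param l Target column.
#' @param L_A,L_B Grid dimensions.
#' @return Two-column matrix of nodes (row, col).
#' @export
row_set <- function(i, k, j, L_B) {
  stopifnot(j != i)
  ls <- if (j > i) setdiff(seq_len(L_B), seq_len(k)) else seq_len(k - 1)
  cbind(row = rep(as.integer(j), length(ls)), col = as.integer(ls))
}

#' @rdname row_set
#' @export
col_set <- function(i, k, l, L_A) {
  stopifnot(l != k)
  js <- if (l > k) setdiff(seq_len(L_A), seq_len(i)) else seq_len(i - 1)
  cbind(row = as.integer(js), col = rep(as.integer(l), length(js)))
}

#' Build an alignment problem instance
#'
#' Assembles the opaque instance handed to the solver: grid dimensions,
#' positional and coupling score tables, and the gap/offset/precision
#' configuration. Objective and constraints are those of the
#' alignment-graph integer program (binary node variables on an increasing
#' path, edge variables equal to products of their endpoints), solved
#' exactly by branch and bound.
#'
#' @param tables A [score_tables()] object.
#' @param config An [align_config()].
#' @return List of class `alignment_problem`.
#' @export
build_alignment_problem <- function(tables, config = align_config()) {
  stopifnot(inherits(tables, "score_tables"))
  structure(list(tables = tables, config = config), class = "alignment_problem")
}

#' Solve an alignment problem over precomputed score tables
#'
#' Branch-and-bound maximization of
#' `sum sv(i,k) + alpha_w * sum sw(i,k,j,l) - gap costs` over strictly
#' increasing match sets, certified to within
#' `2(UB - LB) / (s(A,A) + s(B,B)) <= epsilon`.
#'
#' @param problem An [build_alignment_problem()] instance, or a
#'   [score_tables()] object.
#' @param config An [align_config()] (ignored when `problem` is an
#'   `alignment_problem`, which carries its own).
#' @param node_limit Optional cap on explored search nodes (0 = none).
#' @return Object of class `potts_alignment`: `pairs` (n x 2, 1-based,
#'   strictly increasing), `score` (LB), `UB`, `LB`, `relative_gap`,
#'   `status` (`optimal`, `epsilon_optimal` or `timeout`), `n_aligned`,
#'   `gap_cost_paid`, `nodes`.
#' @export
solve_alignment_problem <- function(problem, config = align_config(), node_limit = 0) {
  if (inherits(problem, "alignment_problem")) {
    tables <- problem$tables
    config <- problem$config
  } else {
    tables <- problem
    stopifnot(inherits(tables, "score_tables"))
  }
  denom <- tables$self_score_A + tables$self_score_B
  eps_abs <- max(0, config$epsilon * denom / 2)
  has_couplings <- config$alpha_w > 0 && any(tables$sw != 0)
  res <- .solve_alignment_cpp(
    tables$sv,
    if (has_couplings) tables$sw else NULL,
    config$alpha_w, config$gap_open, config$gap_extend,
    eps_abs, config$free_end_gaps,
    config$time_limit_seconds, node_limit
  )
  pairs <- res$pairs
  LBnd <- res$score
  UBnd <- res$UB
  gap <- UBnd - LBnd
  relative_gap <- if (denom > 0) 2 * gap / denom else ifelse(gap <= 1e-9, 0, Inf)
  status <- if (res$aborted) {
    "timeout"
  } else if (gap <= 1e-9 * max(1, abs(LBnd))) {
    "optimal"
  } else {
    "epsilon_optimal"
  }
  gap_paid <- 0
  if (nrow(pairs) > 1) {
    dA <- diff(pairs[, 1]) - 1L
    dB <- diff(pairs[, 2]) - 1L
    gap_paid <- sum(ifelse(dA > 0, config$gap_open + config$gap_extend * dA, 0)) +
      sum(ifelse(dB > 0, config$gap_open + config$gap_extend * dB, 0))
  }
  structure(
    list(
      pairs = pairs, score = LBnd, LB = LBnd, UB = UBnd,
      relative_gap = relative_gap, status = status,
      n_aligned = nrow(pairs), gap_cost_paid = gap_paid,
      nodes = res$nodes,
      self_score_A = tables$self_score_A, self_score_B = tables$self_score_B,
      config = config
    ),
    class = "potts_alignment"
  )
}

#' @export
print.potts_alignment <- function(x, ...) {
  cat(
    "Potts model alignment:", x$n_aligned, "aligned pairs, score",
    format(x$score, digits = 6), "\n  status:", x$status,
    " relative gap:", format(x$relative_gap, digits = 3),
    " (UB", format(x$UB, digits = 6), ")\n"
  )
  invisible(x)
}

#' Align two Potts models
#'
#' End-to-end alignment: builds the score tables (background-corrected
#' field scalar products with the per-pair offset, Frobenius inner products
#' of coupling blocks) and solves the alignment problem to the requested
#' certified precision.
#'
#' @param A,B `potts_model`s sharing `q` and alphabet.
#' @param v0 Background field subtracted from fields before scoring
#'   (default from the shared alphabet's background frequencies).
#' @param config An [align_config()].
#' @param node_limit Optional solver node cap (0 = none).
#' @return A `potts_alignment` (see [solve_alignment_problem()]).
#' @examples
#' m <- random_potts_model(L = 5, q = 4, seed = 1, n_coupled_pairs = 1)
#' aln <- align_potts(m, m, config = align_config(offset_gamma = 0.1))
#' aln$pairs # identity alignment
#' @export
align_potts <- function(A, B, v0 = background_field(background_frequencies(A$alphabet)),
                        config = align_config(), node_limit = 0) {
  tables <- score_tables(A, B, v0, config)
  solve_alignment_problem(tables, config, node_limit = node_limit)
}

# tie rule shared by the oracles: fewer pairs first, then lexicographically
# smaller (i1, k1, i2, k2, ...)
tie_rank_better <- function(pairs_new, pairs_old) {
  n <- nrow(pairs_new)
  m <- nrow(pairs_old)
  if (n != m) {
    return(n < m)
  }
  if (n == 0) {
    return(FALSE)
  }
  a <- as.vector(t(pairs_new))
  b <- as.vector(t(pairs_old))
  d <- which(a != b)
  if (length(d) == 0) {
    return(FALSE)
  }
  a[d[1]] < b[d[1]]
}

#' Brute-force alignment oracle
#'
#' Exhaustively enumerates every strictly increasing set of matched pairs,
#' scores each with [alignment_objective()], and returns the maximum. Ties
#' are broken by fewest pairs, then lexicographic order of the pair list.
#' Refuses grids larger than 8 x 8. Independent of the branch-and-bound
#' code path; used to verify it.
#'
#' @param tables A [score_tables()] object.
#' @param config An [align_config()].
#' @return List with `pairs` (n x 2), `score`, `n_aligned`.
#' @export
brute_force_align <- function(tables, config = align_config()) {
  LA <- tables$L_A
  LB <- tables$L_B
  if (LA > 8 || LB > 8) {
    stop("brute-force oracle restricted to L_A, L_B <= 8", call. = FALSE)
  }
  best_score <- 0
  best_pairs <- matrix(integer(0), ncol = 2)
  consider <- function(pairs) {
    s <- alignment_objective(tables, pairs, config)
    if (s > best_score + 1e-12 ||
      (abs(s - best_score) <= 1e-12 && tie_rank_better(pairs, best_pairs))) {
      best_score <<- s
      best_pairs <<- pairs
    }
  }
  rec <- function(pairs, min_i, min_k) {
    consider(pairs)
    for (i in min_i:LA) {
      if (i > LA) break
      for (k in min_k:LB) {
        if (k > LB) break
        rec(rbind(pairs, c(i, k)), i + 1L, k + 1L)
      }
    }
  }
  if (LA >= 1 && LB >= 1) rec(matrix(integer(0), ncol = 2), 1L, 1L)
  list(
    pairs = matrix(as.integer(best_pairs), ncol = 2), score = best_score,
    n_aligned = nrow(best_pairs)
  )
}

#' Affine-gap dynamic-programming alignment of positional scores
#'
#' Optimal alignment for the independent-site objective (couplings ignored):
#' maximizes `sum sv(i,k) - gap costs` with affine gaps and free end gaps,
#' by the standard three-state recursion with traceback. For `alpha_w = 0`
#' this is provably the same optimum as the branch-and-bound solver.
#'
#' @param sv L_A x L_B matrix of positional scores (offset already
#'   included, as produced by [score_tables()]).
#' @param gap_open,gap_extend Affine gap penalties (a gap of g columns
#'   costs `gap_open + gap_extend * g`).
#' @param free_end_gaps Terminal gaps unpenalized (default TRUE).
#' @return List with `pairs` (n x 2), `score`, `n_aligned`.
#' @export
dp_align <- function(sv, gap_open = 13, gap_extend = 0, free_end_gaps = TRUE) {
  sv <- as.matrix(sv)
  LA <- nrow(sv)
  LB <- ncol(sv)
  NEG <- -1e300
  gapc <- function(d) ifelse(d > 0, gap_open + gap_extend * d, 0)
  # M[a,b]: best solution whose last match is exactly (a,b)
  M <- matrix(NEG, LA, LB)
  X <- matrix(NEG, LA, LB) # row-gap open (last match in an earlier row, col b)
  Y <- matrix(NEG, LA, LB) # col-gap open, may follow a row gap
  A1 <- matrix(NEG, LA, LB)
  fromM <- matrix(0L, LA, LB) # 0: start, 1: diagonal A2 predecessor
  fromX <- matrix(0L, LA, LB) # 1: opened from M above, 2: extended
  fromY <- matrix(0L, LA, LB)
  fromA1 <- matrix(0L, LA, LB) # 1: M, 2: X
  fromA2 <- matrix(0L, LA, LB) # 1: A1, 2: Y
  A2 <- matrix(NEG, LA, LB)
  for (a in seq_len(LA)) {
    for (b in seq_len(LB)) {
      lead <- if (free_end_gaps) 0 else -(gapc(a - 1) + gapc(b - 1))
      prev <- lead
      from <- 0L
      if (a > 1 && b > 1 && A2[a - 1, b - 1] > prev) {
        prev <- A2[a - 1, b - 1]
        from <- 1L
      }
      M[a, b] <- sv[a, b] + prev
      fromM[a, b] <- from
      if (a > 1) {
        op <- M[a - 1, b] - gap_open - gap_extend
        ex <- X[a - 1, b] - gap_extend
        if (op >= ex) {
          X[a, b] <- op
          fromX[a, b] <- 1L
        } else {
          X[a, b] <- ex
          fromX[a, b] <- 2L
        }
      }
      if (M[a, b] >= X[a, b]) {
        A1[a, b] <- M[a, b]
        fromA1[a, b] <- 1L
      } else {
        A1[a, b] <- X[a, b]
        fromA1[a, b] <- 2L
      }
      if (b > 1) {
        op <- A1[a, b - 1] - gap_open - gap_extend
        ex <- Y[a, b - 1] - gap_extend
        if (op >= ex) {
          Y[a, b] <- op
          fromY[a, b] <- 1L
        } else {
          Y[a, b] <- ex
          fromY[a, b] <- 2L
        }
      }
      if (A1[a, b] >= Y[a, b]) {
        A2[a, b] <- A1[a, b]
        fromA2[a, b] <- 1L
      } else {
        A2[a, b] <- Y[a, b]
        fromA2[a, b] <- 2L
      }
    }
  }
  endv <- M
  if (!free_end_gaps) {
    for (a in seq_len(LA)) {
      for (b in seq_len(LB)) {
        endv[a, b] <- M[a, b] - gapc(LA - a) - gapc(LB - b)
      }
    }
  }
  best <- max(endv)
  if (best <= 0) {
    return(list(pairs = matrix(integer(0), ncol = 2), score = 0, n_aligned = 0L))
  }
  # traceback from the best end match; among ties pick the lexicographically
  # smallest end cell
  idx <- which(endv == best, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  a <- idx[1, 1]
  b <- idx[1, 2]
  pairs <- matrix(c(a, b), ncol = 2)
  repeat {
    if (fromM[a, b] == 0L) break
    a2 <- a - 1L
    b2 <- b - 1L
    state <- "A2"
    while (TRUE) {
      if (state == "A2") {
        state <- if (fromA2[a2, b2] == 1L) "A1" else "Y"
      } else if (state == "Y") {
        b2 <- b2 - 1L
        state <- if (fromY[a2, b2 + 1L] == 1L) "A1" else "Y"
      } else if (state == "A1") {
        state <- if (fromA1[a2, b2] == 1L) "M" else "X"
      } else if (state == "X") {
        a2 <- a2 - 1L
        state <- if (fromX[a2 + 1L, b2] == 1L) "M" else "X"
      } else {
        break
      }
    }
    a <- a2
    b <- b2
    pairs <- rbind(c(a, b), pairs)
  }
  list(
    pairs = matrix(as.integer(pairs), ncol = 2), score = best,
    n_aligned = nrow(pairs)
  )
}
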