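#' Inference configuration
#'
#' Settings for regularized pseudo-likelihood maximization. The field
#' regularization pulls `v` towards the independent-site solution `v*`
#' (softmax(v*_i) equals the empirical single-site frequencies), the coupling
#' regularization is a plain ridge on `w`:
#' `R(v, w) = lambda_v * ||v - v*||^2 + lambda_w * ||w||^2`.
#'
#' @param lambda_v Field regularization weight (default 10, the common
#'   pseudo-likelihood DCA default).
#' @param lambda_w Coupling regularization weight; `NULL` (default) means
#'   `0.2 * (L - 1)`, the usual length-scaled coupling ridge.
#' @param max_iterations L-BFGS iteration cap (default 500).
#' @param gradient_tolerance Convergence tolerance passed to the optimizer
#'   (projected-gradient tolerance, default 1e-6).
#' @param pseudocount_epsilon Small count added to single-site frequencies
#'   before inverting the softmax for `v*` (default 1e-6), avoiding log(0)
#'   at absent states.
#' @return List of class `inference_config`.
#' @export
inference_config <- function(lambda_v = 10, lambda_w = NULL,
                             max_iterations = 500, gradient_tolerance = 1e-6,
                             pseudocount_epsilon = 1e-6) {
  if (lambda_v < 0 || (!is.null(lambda_w) && lambda_w < 0)) {
    stop("regularization weights must be nonnegative", call. = FALSE)
  }
  structure(
    list(
      lambda_v = lambda_v, lambda_w = lambda_w,
      max_iterations = max_iterations,
      gradient_tolerance = gradient_tolerance,
      pseudocount_epsilon = pseudocount_epsilon
    ),
    class = "inference_config"
  )
}

#' Independent-site prior fields v*
#'
#' Inverts the softmax on regularized single-site frequencies so that
#' `softmax(v*_i) == f_i` exactly, with the zero-sum (centered log) gauge:
#' `v*_i(a) = log f_i(a) - mean_b log f_i(b)`. Frequencies are regularized by
#' adding `epsilon` and renormalizing; with `epsilon = 0`, any zero frequency
#' is an error.
#'
#' @param f_single L x q matrix of single-site frequencies (rows may sum to
#'   less than 1 when gaps carry mass; rows are renormalized over the q
#'   states).
#' @param epsilon Pseudocount added to each entry before renormalization.
#' @return L x q matrix, each row zero-sum.
#' @export
field_prior <- function(f_single, epsilon = 1e-6) {
  f <- as.matrix(f_single) + epsilon
  if (any(f <= 0)) {
    stop("degenerate-frequency: zero frequency with epsilon = 0", call. = FALSE)
  }
  f <- f / rowSums(f)
  lf <- log(f)
  lf - rowMeans(lf)
}

#' Background field v0 from background frequencies
#'
#' `v0(a) = log f0(a) - mean_b log f0(b)`; zero-sum by construction. Used
#' both as the field of re-inserted gap-rich columns and as the reference
#' subtracted from fields before similarity scoring.
#'
#' @param f0 Strictly positive length-q vector summing to 1.
#' @return Length-q zero-sum vector.
#' @export
background_field <- function(f0 = background_frequencies()) {
  if (any(f0 <= 0)) stop("background frequencies must be strictly positive", call. = FALSE)
  lf <- log(f0)
  lf - mean(lf)
}

# --- pseudo-likelihood objective ------------------------------------------

# Pack/unpack: theta = c(v (L*q), w upper blocks (P*q*q, pairs in row-major
# order over i<j, each block column-major)).
pl_unpack <- function(theta, L, q) {
  nv <- L * q
  v <- matrix(theta[seq_len(nv)], L, q)
  P <- L * (L - 1) / 2
  wu <- if (P > 0) array(theta[nv + seq_len(P * q * q)], dim = c(q, q, P)) else NULL
  list(v = v, wu = wu)
}

pair_index <- function(L) {
  if (L < 2) {
    return(matrix(integer(0), ncol = 2))
  }
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  idx
}

# Negative penalized log-pseudo-likelihood and its gradient.
# X: N x L integer matrix (0 = gap). Positions holding a gap contribute no
# conditional term and do not appear as conditioning neighbours.
pl_objective <- function(theta, X, q, lambda_v, lambda_w, vstar, grad = FALSE) {
  N <- nrow(X)
  L <- ncol(X)
  up <- pl_unpack(theta, L, q)
  v <- up$v
  wu <- up$wu
  pairs <- pair_index(L)
  pmap <- matrix(0L, L, L)
  if (nrow(pairs) > 0) pmap[pairs] <- seq_len(nrow(pairs))

  nll <- 0
  if (grad) {
    gv <- matrix(0, L, q)
    gw <- if (!is.null(wu)) array(0, dim = dim(wu)) else NULL
  }
  for (i in seq_len(L)) {
    Z <- matrix(v[i, ], N, q, byrow = TRUE)
    for (j in seq_len(L)) {
      if (j == i) next
      # orient the block so contribution to logits at i is W[a, x_j]
      W <- if (i < j) wu[, , pmap[i, j]] else t(wu[, , pmap[j, i]])
      xj <- X[, j]
      ok <- xj > 0L
      if (any(ok)) Z[ok, ] <- Z[ok, ] + t(W[, xj[ok], drop = FALSE])
    }
    zmax <- apply(Z, 1, max)
    E <- exp(Z - zmax)
    sE <- rowSums(E)
    xi <- X[, i]
    obs <- xi > 0L
    if (any(obs)) {
      lp <- (Z[cbind(seq_len(N), pmax(xi, 1L))] - zmax - log(sE))
      nll <- nll - sum(lp[obs])
    }
    if (grad) {
      Pm <- E / sE
      G <- Pm
      G[cbind(which(obs), xi[obs])] <- G[cbind(which(obs), xi[obs])] - 1
      G[!obs, ] <- 0
      gv[i, ] <- gv[i, ] + colSums(G)
      for (j in seq_len(L)) {
        if (j == i) next
        xj <- X[, j]
        ok <- xj > 0L & obs
        if (!any(ok)) next
        A <- rowsum(G[ok, , drop = FALSE], group = xj[ok]) # rows: b values
        bvals <- as.integer(rownames(A))
        D <- matrix(0, q, q) # D[a, b]
        D[, bvals] <- t(A)
        if (i < j) {
          gw[, , pmap[i, j]] <- gw[, , pmap[i, j]] + D
        } else {
          gw[, , pmap[j, i]] <- gw[, , pmap[j, i]] + t(D)
        }
      }
    }
  }
  pen <- lambda_v * sum((v - vstar)^2) +
    if (!is.null(wu)) lambda_w * sum(wu^2) else 0
  val <- nll + pen
  if (!grad) {
    return(val)
  }
  gv <- gv + 2 * lambda_v * (v - vstar)
  gtheta <- c(as.vector(gv), if (!is.null(wu)) as.vector(gw + 2 * lambda_w * wu))
  list(value = val, gradient = gtheta)
}

#' Infer a Potts model by regularized pseudo-likelihood maximization
#'
#' Maximizes the sum over sequences and positions of the log conditional
#' probability of each residue given the rest of its sequence (the standard
#' Potts pseudo-likelihood), minus the prior penalty
#' `lambda_v * ||v - v*||^2 + lambda_w * ||w||^2` where `softmax(v*_i)`
#' equals the (regularized) empirical frequencies of column i. Optimization
#' is deterministic L-BFGS-B from `v = v*`, `w = 0`. Positions holding a gap
#' contribute no conditional term and never condition their neighbours. The
#' returned model is fixed to the zero-sum gauge.
#'
#' @param msa A `potts_msa`.
#' @param config An [inference_config()].
#' @return A `potts_model`; `provenance` records the regularization weights,
#'   MSA dimensions, optimizer convergence code and a `converged` flag (a
#'   non-converged fit warns but still returns).
#' @export
fit_potts <- function(msa, config = inference_config()) {
  L <- msa$L
  q <- msa$q
  X <- msa$matrix
  lambda_v <- config$lambda_v
  lambda_w <- if (is.null(config$lambda_w)) 0.2 * max(L - 1, 1) else config$lambda_w
  freqs <- compute_frequencies(msa)
  vstar <- field_prior(freqs$f_single, epsilon = config$pseudocount_epsilon)

  P <- L * (L - 1) / 2
  theta0 <- c(as.vector(vstar), rep(0, P * q * q))
  fn <- function(th) pl_objective(th, X, q, lambda_v, lambda_w, vstar, grad = FALSE)
  gr <- function(th) pl_objective(th, X, q, lambda_v, lambda_w, vstar, grad = TRUE)$gradient
  fit <- stats::optim(theta0, fn, gr,
    method = "L-BFGS-B",
    control = list(
      maxit = config$max_iterations,
      pgtol = config$gradient_tolerance, factr = 1e4
    )
  )
  if (fit$convergence != 0) {
    warning("pseudo-likelihood optimizer did not converge (code ", fit$convergence, ")")
  }
  up <- pl_unpack(fit$par, L, q)
  w <- array(0, dim = c(L, L, q, q))
  if (P > 0) {
    pairs <- pair_index(L)
    for (k in seq_len(P)) {
      w[pairs[k, 1], pairs[k, 2], , ] <- up$wu[, , k]
    }
    w <- symmetrize_couplings(w)
  }
  model <- potts_model(up$v, w,
    alphabet = msa$alphabet,
    provenance = list(
      method = "pseudo-likelihood", N = msa$N, L = L, q = q,
      lambda_v = lambda_v, lambda_w = lambda_w,
      converged = fit$convergence == 0,
      optim_code = fit$convergence,
      objective = fit$value
    )
  )
  zero_sum_gauge(model)
}

#' Per-position conditional distributions of sequences under a model
#'
#' For each sequence row and each non-gap position i, the conditional
#' distribution over the q states given the rest of the row:
#' `softmax_a(v_i(a) + sum_{j != i, x_j != gap} w_ij(a, x_j))`. Used to test
#' gauge invariance; gauge transforms must leave these untouched.
#'
#' @param model A `potts_model`.
#' @param X N x L integer state matrix (0 = gap).
#' @return N x L x q array of conditional probabilities (NA at gap positions).
#' @export
conditional_probabilities <- function(model, X) {
  N <- nrow(X)
  L <- ncol(X)
  q <- model$q
  out <- array(NA_real_, dim = c(N, L, q))
  for (i in seq_len(L)) {
    Z <- matrix(model$v[i, ], N, q, byrow = TRUE)
    for (j in seq_len(L)) {
      if (j == i) next
      W <- model$w[i, j, , ]
      xj <- X[, j]
      ok <- xj > 0L
      if (any(ok)) Z[ok, ] <- Z[ok, ] + t(W[, xj[ok], drop = FALSE])
    }
    E <- exp(Z - apply(Z, 1, max))
    Pm <- E / rowSums(E)
    obs <- X[, i] > 0L
    out[obs, i, ] <- Pm[obs, ]
  }
  out
}
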