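#' Rescaling configuration
#'
#' Parameters of the two rescaling transforms that make independently
#' inferred models comparable: additive smoothing of the per-position field
#' softmax distributions towards uniform (`tau_v`), and a temperature-skewed
#' smoothing of each coupling block (`tau_w`, softmax base `beta_w`) that
#' damps weakly supported anti-correlations while favoring the large
#' positive couplings the data actually supports.
#'
#' @param tau_v Field smoothing fraction in \[0, 1\] (default 0.4).
#' @param tau_w Coupling smoothing fraction in \[0, 1\] (default 0.4).
#' @param beta_w Positive softmax base for couplings (default 8).
#' @return List of class `rescale_config`.
#' @export
rescale_config <- function(tau_v = 0.4, tau_w = 0.4, beta_w = 8.0) {
  if (tau_v < 0 || tau_v > 1 || tau_w < 0 || tau_w > 1) {
    stop("tau_v and tau_w must lie in [0, 1]", call. = FALSE)
  }
  if (beta_w <= 0) stop("beta_w must be positive", call. = FALSE)
  structure(list(tau_v = tau_v, tau_w = tau_w, beta_w = beta_w),
    class = "rescale_config"
  )
}

# max-subtracted softmax of a vector
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Smooth field vectors towards the uniform distribution
#'
#' Each field row `v_i` is mapped to the probability simplex by softmax,
#' mixed with the uniform distribution (`(1 - tau_v) * p + tau_v / q`), and
#' mapped back by the centered log (zero-sum inverse softmax). The output
#' satisfies `softmax(v~_i) = (1 - tau_v) * softmax(v_i) + tau_v / q`
#' exactly; `tau_v = 0` is the identity on zero-sum rows and `tau_v = 1`
#' sends every row to zero.
#'
#' @param v L x q matrix (rows zero-sum, the inference gauge).
#' @param tau_v Smoothing fraction in \[0, 1\].
#' @return L x q matrix with zero-sum rows.
#' @export
smooth_fields <- function(v, tau_v = 0.4) {
  if (tau_v < 0 || tau_v > 1) stop("tau_v must lie in [0, 1]", call. = FALSE)
  v <- as.matrix(v)
  q <- ncol(v)
  t(apply(v, 1, function(vi) {
    p <- (1 - tau_v) * softmax(vi) + tau_v / q
    lp <- log(p)
    lp - mean(lp)
  }))
}

#' Skew and smooth a coupling block
#'
#' The q x q block is turned into a probability distribution over its q^2
#' entries with softmax base `beta_w` (a base > 1 skews mass towards the
#' largest, positive couplings), mixed with the uniform distribution by
#' `tau_w`, and mapped back through `log / beta_w` centered by the grand
#' mean. Entrywise order is preserved; the zero block maps to the zero block
#' and `tau_w = 1` maps everything to zero. Note the output is centered by a
#' single grand mean over all q^2 entries, not the per-row/per-column
#' zero-sum gauge: rescaled models intentionally leave the strict gauge.
#'
#' @param w_ij q x q numeric matrix.
#' @param tau_w Smoothing fraction in \[0, 1\].
#' @param beta_w Positive softmax base.
#' @return q x q matrix whose entries sum to zero.
#' @export
smooth_couplings <- function(w_ij, tau_w = 0.4, beta_w = 8.0) {
  if (tau_w < 0 || tau_w > 1) stop("tau_w must lie in [0, 1]", call. = FALSE)
  if (beta_w <= 0) stop("beta_w must be positive", call. = FALSE)
  w_ij <- as.matrix(w_ij)
  q2 <- length(w_ij)
  z <- beta_w * as.vector(w_ij)
  p <- (1 - tau_w) * softmax(z) + tau_w / q2
  lp <- log(p)
  matrix((lp - mean(lp)) / beta_w, nrow = nrow(w_ij))
}

#' Rescale a whole Potts model
#'
#' Applies [smooth_fields()] to the field matrix and [smooth_couplings()] to
#' every coupling block (each unordered pair smoothed once, symmetry
#' `w[i,j] = t(w[j,i])` preserved).
#'
#' @param model A `potts_model`.
#' @param config A [rescale_config()].
#' @return Rescaled `potts_model`.
#' @export
rescale_model <- function(model, config = rescale_config()) {
  v <- smooth_fields(model$v, config$tau_v)
  w <- model$w
  L <- model$L
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        blk <- smooth_couplings(model$w[i, j, , ], config$tau_w, config$beta_w)
        w[i, j, , ] <- blk
        w[j, i, , ] <- t(blk)
      }
    }
  }
  prov <- model$provenance
  prov$rescaled <- list(
    tau_v = config$tau_v, tau_w = config$tau_w,
    beta_w = config$beta_w
  )
  potts_model(v, w, alphabet = model$alphabet, provenance = prov)
}
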