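#' Synthetic random Potts model
#'
#' Generates a model with i.i.d. Gaussian fields (rows centered to zero
#' sum) and a chosen number of randomly placed dense coupling blocks
#' (double-centered Gaussian entries); all other blocks are zero.
#' Deterministic given `seed`.
#'
#' @param L Model length (>= 1).
#' @param q Alphabet size (2..20; the alphabet is the first `q` letters of
#'   [AA_ALPHABET]).
#' @param field_scale Standard deviation of field entries before centering
#'   (default 1).
#' @param n_coupled_pairs Number of position pairs with nonzero couplings
#'   (default 0; at most `L(L-1)/2`).
#' @param coupling_scale Standard deviation of coupling entries before
#'   double-centering (default 1).
#' @param seed Integer seed.
#' @return A `potts_model`.
#' @export
random_potts_model <- function(L, q = 20, field_scale = 1.0,
                               n_coupled_pairs = 0, coupling_scale = 1.0,
                               seed = 1) {
  if (L < 1 || q < 2 || q > 20) stop("need L >= 1 and 2 <= q <= 20", call. = FALSE)
  if (n_coupled_pairs < 0 || n_coupled_pairs > L * (L - 1) / 2) {
    stop("n_coupled_pairs out of range", call. = FALSE)
  }
  set.seed(seed)
  v <- matrix(stats::rnorm(L * q, sd = field_scale), L, q)
  v <- v - rowMeans(v)
  w <- array(0, dim = c(L, L, q, q))
  if (n_coupled_pairs > 0 && coupling_scale > 0) {
    pairs <- pair_index(L)
    pick <- sample(nrow(pairs), n_coupled_pairs)
    for (p in pick) {
      blk <- matrix(stats::rnorm(q * q, sd = coupling_scale), q, q)
      blk <- blk - outer(rowMeans(blk), rep(1, q)) -
        outer(rep(1, q), colMeans(blk)) + mean(blk)
      i <- pairs[p, 1]
      j <- pairs[p, 2]
      w[i, j, , ] <- blk
      w[j, i, , ] <- t(blk)
    }
  }
  potts_model(v, w,
    alphabet = substr(AA_ALPHABET, 1, q),
    provenance = list(
      synthetic = TRUE, seed = seed, field_scale = field_scale,
      n_coupled_pairs = n_coupled_pairs, coupling_scale = coupling_scale
    )
  )
}

# linear score (negative energy) of every state combination; states is an
# n x L integer matrix
model_scores <- function(model, states) {
  L <- model$L
  s <- numeric(nrow(states))
  for (i in seq_len(L)) s <- s + model$v[i, ][states[, i]]
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        s <- s + model$w[i, j, , ][cbind(states[, i], states[, j])]
      }
    }
  }
  s
}

#' Sample sequences from a Potts model
#'
#' Draws from the model's Boltzmann distribution, either exactly (full
#' enumeration of the q^L state space, allowed up to 1e6 states) or by
#' single-site Gibbs sampling (default 100*L burn-in sweeps, thinning of L
#' sweeps between samples, recorded in the MSA provenance attribute).
#' Deterministic given `seed`.
#'
#' @param model A `potts_model`.
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @param method `"exact_enumeration"` or `"gibbs"`.
#' @param burn_in,thin Gibbs chain settings (sweeps); defaults `100 * L`
#'   and `L`.
#' @return A `potts_msa` of `n` rows; gap-free.
#' @export
sample_sequences <- function(model, n, seed = 1,
                             method = c("exact_enumeration", "gibbs"),
                             burn_in = NULL, thin = NULL) {
  method <- match.arg(method)
  L <- model$L
  q <- model$q
  set.seed(seed)
  if (method == "exact_enumeration") {
    if (q^L > 1e6) {
      stop("state space larger than 1e6; use method = \"gibbs\"", call. = FALSE)
    }
    states <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
    storage.mode(states) <- "integer"
    s <- model_scores(model, states)
    p <- exp(s - max(s))
    p <- p / sum(p)
    draw <- sample.int(nrow(states), size = n, replace = TRUE, prob = p)
    X <- states[draw, , drop = FALSE]
  } else {
    if (is.null(burn_in)) burn_in <- 100 * L
    if (is.null(thin)) thin <- L
    x <- sample.int(q, L, replace = TRUE)
    X <- matrix(0L, n, L)
    sweep_once <- function(x) {
      for (i in seq_len(L)) {
        z <- model$v[i, ]
        for (j in seq_len(L)) {
          if (j != i) z <- z + model$w[i, j, , x[j]]
        }
        p <- exp(z - max(z))
        x[i] <- sample.int(q, 1, prob = p)
      }
      x
    }
    for (t in seq_len(burn_in)) x <- sweep_once(x)
    for (k in seq_len(n)) {
      for (t in seq_len(thin)) x <- sweep_once(x)
      X[k, ] <- x
    }
  }
  syms <- alphabet_symbols(model$alphabet)
  seqs <- apply(X, 1, function(r) paste(syms[r], collapse = ""))
  msa <- new_msa(seqs,
    ids = paste0("sample", seq_len(n)),
    alphabet = model$alphabet
  )
  attr(msa, "provenance") <- list(
    method = method, seed = seed, n = n,
    burn_in = if (method == "gibbs") burn_in else NA,
    thin = if (method == "gibbs") thin else NA
  )
  msa
}

# add i.i.d. noise to all parameters, re-center to keep the gauge
perturb_model <- function(model, scale) {
  if (scale == 0) {
    return(model)
  }
  L <- model$L
  q <- model$q
  v <- model$v + matrix(stats::rnorm(L * q, sd = scale), L, q)
  v <- v - rowMeans(v)
  w <- model$w
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        blk <- model$w[i, j, , ] + matrix(stats::rnorm(q * q, sd = scale), q, q)
        blk <- blk - outer(rowMeans(blk), rep(1, q)) -
          outer(rep(1, q), colMeans(blk)) + mean(blk)
        w[i, j, , ] <- blk
        w[j, i, , ] <- t(blk)
      }
    }
  }
  potts_model(v, w, alphabet = model$alphabet, provenance = model$provenance)
}

# insert flat background columns (v = 0, w = 0) after the base columns
# listed in `slots` (values in 0..L); returns the model and the new
# positions of the original columns
insert_background_columns <- function(model, slots) {
  L <- model$L
  q <- model$q
  n_ins <- length(slots)
  newL <- L + n_ins
  pos <- integer(L) # new index of each base column
  newv <- matrix(0, newL, q)
  neww <- array(0, dim = c(newL, newL, q, q))
  cur <- 0L
  for (c0 in seq_len(L)) {
    cur <- cur + sum(slots == c0 - 1L)
    cur <- cur + 1L
    pos[c0] <- cur
  }
  newv[pos, ] <- model$v
  neww[pos, pos, , ] <- model$w
  list(
    model = potts_model(newv, neww,
      alphabet = model$alphabet,
      provenance = model$provenance
    ),
    positions = pos
  )
}

#' Plant a homologous pair of Potts models with known correspondence
#'
#' Derives two models from a common base: each copy receives i.i.d.
#' parameter noise of `perturbation_scale` (re-centered to preserve the
#' gauge) and a number of inserted background columns (zero fields, zero
#' couplings). The ground-truth column correspondence of the surviving base
#' columns is recorded. Insertion sites are constrained so that the planted
#' correspondence stays identifiable from the alignment objective: they sit
#' at least three base columns from either end (under free end gaps a
#' near-terminal insertion lets the aligner drop a terminal match and
#' convert a charged internal gap into a free end gap) and all sites --
#' across both copies -- are pairwise separated by at least
#' `min_separation` base columns (two nearby insertions on opposite sides
#' let an ungapped alignment "resync" across the short stretch between
#' them, beating the two gap opens the truth must pay).
#' Deterministic given `seed`.
#'
#' @param base A `potts_model` (long enough to host the requested
#'   insertions under the constraints above).
#' @param perturbation_scale Standard deviation of the parameter noise.
#' @param n_insertions_A,n_insertions_B Background columns inserted into
#'   each copy.
#' @param min_separation Minimum distance (in base columns) between any two
#'   insertion sites across both copies (default 4).
#' @param seed Integer seed.
#' @return List of class `planted_pair`: `model_A`, `model_B`, `truth`
#'   (n x 2 strictly increasing position pairs), `recipe`.
#' @export
plant_homologous_pair <- function(base, perturbation_scale = 0,
                                  n_insertions_A = 0, n_insertions_B = 0,
                                  min_separation = 4, seed = 1) {
  set.seed(seed)
  L <- base$L
  n_tot <- n_insertions_A + n_insertions_B
  interior <- if (L >= 7) seq(3L, L - 3L) else seq_len(max(L - 1, 1))
  A <- perturb_model(base, perturbation_scale)
  B <- perturb_model(base, perturbation_scale)
  slots <- integer(0)
  if (n_tot > 0) {
    # uniform draw of n_tot interior sites with pairwise separation >= g:
    # sample without the constraint in a shrunken range, then re-expand
    g <- as.integer(min_separation)
    m <- length(interior) - (n_tot - 1L) * (g - 1L)
    if (m < n_tot) {
      stop("base too short for the requested insertions at this separation",
        call. = FALSE
      )
    }
    y <- sort(sample.int(m, n_tot))
    slots <- interior[y + (seq_len(n_tot) - 1L) * (g - 1L)]
  }
  which_A <- if (n_tot > 0) sample(n_tot, n_insertions_A) else integer(0)
  slots_A <- sort(slots[which_A])
  slots_B <- sort(slots[setdiff(seq_len(n_tot), which_A)])
  insA <- insert_background_columns(A, slots_A)
  insB <- insert_background_columns(B, slots_B)
  structure(
    list(
      model_A = insA$model, model_B = insB$model,
      truth = cbind(posA = insA$positions, posB = insB$positions),
      recipe = list(
        seed = seed, perturbation_scale = perturbation_scale,
        slots_A = slots_A, slots_B = slots_B, base_L = L
      )
    ),
    class = "planted_pair"
  )
}

#' Planted pair where only couplings disambiguate the alignment
#'
#' Builds a model pair whose field profiles are deliberately ambiguous:
#' model A carries, per block, an anchor column followed by two columns
#' with *identical* field profiles; model B carries the anchor and a single
#' copy. A coupling of the anchor to exactly one of A's two copies (the
#' same block matrix couples B's anchor to its copy) marks which copy is
#' the true correspondent. Field scores and gap costs are symmetric between
#' the two choices, so an independent-site alignment cannot distinguish
#' them while the coupling term strictly prefers the truth.
#'
#' @param n_blocks Number of ambiguous blocks (default 4).
#' @param q Alphabet size (default 20).
#' @param field_scale Scale of the random field profiles (default 2.5;
#'   block rewards must clear the gap-open cost each block pays, so the
#'   profiles emulate well-conserved columns).
#' @param coupling_scale Scale of the disambiguating coupling blocks
#'   (default 3).
#' @param seed Integer seed.
#' @return A `planted_pair` (truth includes anchors and the true copies).
#' @export
coupling_disambiguation_pair <- function(n_blocks = 4, q = 20,
                                         field_scale = 2.5, coupling_scale = 3,
                                         seed = 1) {
  set.seed(seed)
  # Blocks of [anchor, b, b', spacer] in A vs [anchor, b, spacer] in B,
  # closed by a rigid two-column coupled terminal segment.  The spacers
  # (strong profiles shared by both models) keep each block's single
  # unmatched stray column in its own gap segment: without them, a stray
  # adjacent to the next anchor can merge with an anchor skip into one
  # gap segment, which is free under a zero gap-extend penalty.  The
  # coupled terminal segment prevents the last stray from usurping a
  # terminal match.
  LA <- 4L * n_blocks + 2L
  LB <- 3L * n_blocks + 2L
  rand_profile <- function(scale) {
    p <- stats::rnorm(q, sd = scale)
    p - mean(p)
  }
  vA <- matrix(0, LA, q)
  vB <- matrix(0, LB, q)
  wA <- array(0, dim = c(LA, LA, q, q))
  wB <- array(0, dim = c(LB, LB, q, q))
  truth <- matrix(0L, 0, 2)
  coupled_copy <- integer(n_blocks)
  for (t in seq_len(n_blocks)) {
    a0 <- 4L * (t - 1L) + 1L # anchor row in A
    b0 <- 3L * (t - 1L) + 1L # anchor row in B
    anchor <- rand_profile(2 * field_scale)
    bprof <- rand_profile(field_scale)
    spacer <- rand_profile(2 * field_scale)
    vA[a0, ] <- anchor
    vA[a0 + 1L, ] <- bprof
    vA[a0 + 2L, ] <- bprof
    vA[a0 + 3L, ] <- spacer
    vB[b0, ] <- anchor
    vB[b0 + 1L, ] <- bprof
    vB[b0 + 2L, ] <- spacer
    W <- matrix(stats::rnorm(q * q, sd = coupling_scale), q, q)
    W <- W - outer(rowMeans(W), rep(1, q)) - outer(rep(1, q), colMeans(W)) + mean(W)
    copy <- sample(1:2, 1)
    coupled_copy[t] <- copy
    ia <- a0 + copy
    wA[a0, ia, , ] <- W
    wA[ia, a0, , ] <- t(W)
    wB[b0, b0 + 1L, , ] <- W
    wB[b0 + 1L, b0, , ] <- t(W)
    truth <- rbind(
      truth, c(a0, b0), c(ia, b0 + 1L),
      c(a0 + 3L, b0 + 2L)
    )
  }
  for (d in 1:0) {
    term <- rand_profile(2 * field_scale)
    vA[LA - d, ] <- term
    vB[LB - d, ] <- term
  }
  WT <- matrix(stats::rnorm(q * q, sd = coupling_scale), q, q)
  WT <- WT - outer(rowMeans(WT), rep(1, q)) - outer(rep(1, q), colMeans(WT)) + mean(WT)
  wA[LA - 1L, LA, , ] <- WT
  wA[LA, LA - 1L, , ] <- t(WT)
  wB[LB - 1L, LB, , ] <- WT
  wB[LB, LB - 1L, , ] <- t(WT)
  truth <- rbind(truth, c(LA - 1L, LB - 1L), c(LA, LB))
  alphabet <- substr(AA_ALPHABET, 1, q)
  structure(
    list(
      model_A = potts_model(vA, wA, alphabet = alphabet),
      model_B = potts_model(vB, wB, alphabet = alphabet),
      truth = truth,
      recipe = list(
        seed = seed, n_blocks = n_blocks, coupled_copy = coupled_copy,
        field_scale = field_scale, coupling_scale = coupling_scale
      )
    ),
    class = "planted_pair"
  )
}
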