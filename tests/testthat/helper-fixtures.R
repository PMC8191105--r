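# shared fixture builders; everything is generated in code at test time

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# score_tables object built directly from raw tables (bypasses models)
raw_tables <- function(sv, sw = NULL, self_A = NULL, self_B = NULL) {
  LA <- nrow(sv)
  LB <- ncol(sv)
  if (is.null(sw)) sw <- array(0, dim = c(LA, LB, LA, LB))
  if (is.null(self_A)) self_A <- sum(sv^2) + 1
  if (is.null(self_B)) self_B <- sum(sv^2) + 1
  structure(
    list(
      sv = sv, sw = sw, L_A = LA, L_B = LB,
      self_score_A = self_A, self_score_B = self_B,
      offset_applied = 0, w_norm_threshold = 0
    ),
    class = "score_tables"
  )
}

# random instance pair (models + tables) for solver cross-checks
random_instance <- function(seed, q = 3, Lmax = 5, coupled = TRUE) {
  set.seed(seed)
  LA <- sample(2:Lmax, 1)
  LB <- sample(2:Lmax, 1)
  A <- random_potts_model(LA,
    q = q, field_scale = 1,
    n_coupled_pairs = if (coupled) sample.int(choose(LA, 2), 1) else 0,
    coupling_scale = 1.5, seed = seed * 7 + 1
  )
  B <- random_potts_model(LB,
    q = q, field_scale = 1,
    n_coupled_pairs = if (coupled) sample.int(choose(LB, 2), 1) else 0,
    coupling_scale = 1.5, seed = seed * 7 + 2
  )
  cfg <- align_config(
    alpha_w = if (coupled) 1 else 0,
    gap_open = sample(c(0, 0.5, 1.5), 1),
    gap_extend = sample(c(0, 0.2), 1),
    offset_gamma = runif(1, 0, 1), epsilon = 1e-9
  )
  list(A = A, B = B, cfg = cfg, tables = score_tables(A, B, v0 = rep(0, q), config = cfg))
}

# arbitrary gauge transform (per-pair shifts compensated in the fields);
# independent implementation used to test invariance of the conditionals
random_gauge_transform <- function(model, seed) {
  set.seed(seed)
  L <- model$L
  q <- model$q
  v <- model$v
  w <- model$w
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      Kij <- rnorm(q)
      Kji <- rnorm(q)
      w[i, j, , ] <- w[i, j, , ] + outer(Kij, rep(1, q)) + outer(rep(1, q), Kji)
      w[j, i, , ] <- t(w[i, j, , ])
      v[i, ] <- v[i, ] - Kij
      v[j, ] <- v[j, ] - Kji
    }
  }
  v <- v + rnorm(L) # arbitrary per-position constants C_i
  potts_model(v, w, alphabet = model$alphabet)
}
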