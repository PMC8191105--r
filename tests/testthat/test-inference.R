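test_that("independent-site prior fields invert the softmax exactly", {
  # uniform frequencies map to the zero vector
  expect_equal(field_prior(matrix(0.25, 2, 4), epsilon = 0), matrix(0, 2, 4))

  # q = 2 analytic inversion: softmax((x, -x)) = (0.8, 0.2) at x = log(4)/2
  vs <- field_prior(matrix(c(0.8, 0.2), 1, 2), epsilon = 0)
  expect_equal(as.vector(vs), c(log(4) / 2, -log(4) / 2))

  # round trip on random frequency rows
  set.seed(3)
  f <- matrix(rexp(5 * 4), 5, 4)
  f <- f / rowSums(f)
  vs2 <- field_prior(f, epsilon = 0)
  back <- t(apply(vs2, 1, function(v) exp(v) / sum(exp(v))))
  expect_equal(back, f, tolerance = 1e-12)
  expect_equal(rowSums(vs2), rep(0, 5), tolerance = 1e-12)

  expect_error(
    field_prior(matrix(c(1, 0), 1, 2), epsilon = 0),
    "degenerate-frequency"
  )
})

test_that("background fields are centered log-frequencies", {
  expect_equal(background_field(rep(0.25, 4)), rep(0, 4))
  expect_equal(background_field(c(0.8, 0.2)), c(log(4) / 2, -log(4) / 2))
  f0 <- background_frequencies()
  expect_equal(sum(background_field(f0)), 0, tolerance = 1e-12)
  expect_error(background_field(c(1, 0)), "positive")
})

test_that("zero-sum gauge fixing is idempotent and preserves conditionals", {
  set.seed(21)
  m <- random_potts_model(4, q = 3, field_scale = 1, n_coupled_pairs = 3, seed = 9)
  # break the gauge with an arbitrary transform, then fix it
  broken <- random_gauge_transform(m, seed = 10)
  fixed <- zero_sum_gauge(broken)
  for (i in 1:4) {
    expect_equal(sum(fixed$v[i, ]), 0, tolerance = 1e-10)
    for (j in 1:4) {
      if (i == j) next
      expect_equal(max(abs(rowSums(fixed$w[i, j, , ]))), 0, tolerance = 1e-10)
      expect_equal(max(abs(colSums(fixed$w[i, j, , ]))), 0, tolerance = 1e-10)
      expect_equal(fixed$w[i, j, , ], t(fixed$w[j, i, , ]))
    }
  }
  again <- zero_sum_gauge(fixed)
  expect_equal(again$v, fixed$v, tolerance = 1e-12)
  expect_equal(again$w, fixed$w, tolerance = 1e-12)

  # a constant coupling block is annihilated
  mc <- potts_model(matrix(0, 2, 3), alphabet = substr(AA_ALPHABET, 1, 3))
  mc$w[1, 2, , ] <- 5
  mc$w[2, 1, , ] <- 5
  expect_equal(max(abs(zero_sum_gauge(mc)$w)), 0)

  # conditional distributions are invariant under gauge changes (the
  # compensation assumes every neighbour is observed, hence gapless states)
  X <- matrix(sample(1:3, 5 * 4, replace = TRUE), 5, 4)
  p_ref <- conditional_probabilities(m, X)
  expect_equal(conditional_probabilities(zero_sum_gauge(m), X), p_ref,
    tolerance = 1e-9
  )
  for (s in 1:5) {
    p_tr <- conditional_probabilities(random_gauge_transform(m, seed = 30 + s), X)
    expect_equal(p_tr, p_ref, tolerance = 1e-9)
  }
})

test_that("pseudo-likelihood gradient matches numeric differentiation", {
  set.seed(2)
  m <- random_potts_model(3, q = 3, field_scale = 1, n_coupled_pairs = 1, seed = 4)
  msa <- sample_sequences(m, 20, seed = 6)
  X <- msa$matrix
  X[1, 2] <- 0L # include a gap
  vstar <- field_prior(compute_frequencies(msa)$f_single)
  th <- rnorm(3 * 3 + 3 * 9, sd = 0.3)
  an <- pottsalign:::pl_objective(th, X, 3, 2, 1, vstar, grad = TRUE)$gradient
  num <- vapply(seq_along(th), function(i) {
    e <- 1e-6
    tp <- th
    tp[i] <- tp[i] + e
    tm <- th
    tm[i] <- tm[i] - e
    (pottsalign:::pl_objective(tp, X, 3, 2, 1, vstar) -
      pottsalign:::pl_objective(tm, X, 3, 2, 1, vstar)) / (2 * e)
  }, numeric(1))
  expect_equal(an, num, tolerance = 1e-5)
})

test_that("single-column fit matches a brute-force numeric oracle", {
  msa <- new_msa(c("A", "A", "A", "R", "N"), alphabet = substr(AA_ALPHABET, 1, 4))
  cfg <- inference_config(lambda_v = 2, lambda_w = 1)
  fit <- fit_potts(msa, cfg)
  # oracle: gradient-free optimization of the same penalized likelihood
  vstar <- field_prior(compute_frequencies(msa)$f_single)
  counts <- tabulate(msa$matrix[, 1], nbins = 4)
  obj <- function(v) {
    -sum(counts * (v - log(sum(exp(v))))) + 2 * sum((v - vstar)^2)
  }
  opt <- optim(as.vector(vstar), obj, method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-14))
  v_oracle <- opt$par - mean(opt$par)
  expect_equal(as.vector(fit$v), v_oracle, tolerance = 1e-3)
})

test_that("fits are gauge-fixed and couplings vanish for independent sites", {
  set.seed(8)
  indep <- random_potts_model(4, q = 3, field_scale = 1.2, n_coupled_pairs = 0, seed = 13)
  msa <- sample_sequences(indep, 400, seed = 14)
  fit <- fit_potts(msa, inference_config(max_iterations = 300))
  # zero-sum sums vanish after the fit
  expect_lt(max(abs(rowSums(fit$v))), 1e-8)
  expect_lt(max(abs(apply(fit$w, c(1, 2, 4), sum))), 1e-8)
  expect_lt(max(abs(apply(fit$w, c(1, 2, 3), sum))), 1e-8)
  # couplings stay at the noise floor: no larger than 10x the norms
  # obtained after independently permuting each column (which destroys
  # any residual correlation)
  perm <- msa
  for (i in seq_len(perm$L)) perm$matrix[, i] <- sample(perm$matrix[, i])
  fit_perm <- fit_potts(perm, inference_config(max_iterations = 300))
  expect_lt(max(coupling_norms(fit)), 10 * max(coupling_norms(fit_perm)))
})

test_that("a perfectly covarying column pair carries the strongest coupling", {
  set.seed(9)
  other <- replicate(120, paste(sample(c("A", "R", "N"), 3, replace = TRUE), collapse = ""))
  ab <- sample(c("AR", "RA"), 120, replace = TRUE)
  msa <- new_msa(paste0(ab, other), alphabet = substr(AA_ALPHABET, 1, 4))
  fit <- fit_potts(msa, inference_config(max_iterations = 300))
  cn <- coupling_norms(fit)
  cn[lower.tri(cn, diag = TRUE)] <- 0
  expect_equal(unname(which(cn == max(cn), arr.ind = TRUE)[1, ]), c(1, 2))
})

test_that("coupling norms shrink monotonically along a lambda_w ladder", {
  set.seed(10)
  m <- random_potts_model(3, q = 3, field_scale = 1, n_coupled_pairs = 2, coupling_scale = 1.5, seed = 17)
  msa <- sample_sequences(m, 300, seed = 18)
  norms <- sapply(c(0.5, 5, 50, 500), function(lw) {
    f <- fit_potts(msa, inference_config(lambda_w = lw, max_iterations = 200))
    sqrt(sum(f$w^2))
  })
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], norms[1] / 10)
})

test_that("sequence energy matches hand sums and the indicator form", {
  zero <- potts_model(matrix(0, 3, 2), alphabet = "AC")
  expect_equal(sequence_energy(zero, "ACA"), 0)

  m <- potts_model(matrix(c(1, 2, -1, 3), 2, 2), alphabet = "AC")
  m$w[1, 2, , ] <- matrix(c(2, -1, 0, 1), 2, 2)
  m$w[2, 1, , ] <- t(m$w[1, 2, , ])
  # x = (C, A): -(v1(C) + v2(A) + w12(C, A)) = -(-1 + 2 + (-1)) = 0
  expect_equal(sequence_energy(m, "CA"), 0)
  expect_equal(sequence_energy(m, "AC"), -(1 + 3 + 0))
  expect_error(sequence_energy(m, "A-"), "alphabet")

  # indicator-vector form on a random model
  rm <- random_potts_model(4, q = 3, field_scale = 1, n_coupled_pairs = 3, seed = 23)
  set.seed(24)
  x <- sample.int(3, 4, replace = TRUE)
  e <- 0
  for (i in 1:4) {
    ei <- as.numeric(seq_len(3) == x[i])
    e <- e + sum(rm$v[i, ] * ei)
    for (j in seq_len(4)) {
      if (j > i) e <- e + sum(rm$w[i, j, , ] * outer(ei, as.numeric(seq_len(3) == x[j])))
    }
  }
  expect_equal(sequence_energy(rm, x), -e, tolerance = 1e-12)
})

test_that("trimmed columns are re-inserted with background parameters", {
  m <- random_potts_model(4, q = 3, field_scale = 1, n_coupled_pairs = 2, seed = 31)
  v0 <- c(0.5, -0.2, -0.3)
  tr <- trim_record(c(1L, 2L, 4L, 5L), 5L)
  out <- reinsert_columns(m, tr, v0)
  expect_equal(out$L, 5)
  expect_equal(out$v[3, ], v0)
  expect_equal(max(abs(out$w[3, , , ])), 0)
  expect_equal(out$v[c(1, 2, 4, 5), ], m$v)
  expect_equal(out$w[c(1, 2, 4, 5), c(1, 2, 4, 5), , ], m$w)

  # no-op trim record leaves the model unchanged
  idtr <- trim_record(1:4, 4L)
  same <- reinsert_columns(m, idtr, v0)
  expect_equal(same$v, m$v)
  expect_equal(same$w, m$w)
  expect_error(reinsert_columns(m, trim_record(1:3, 5L), v0), "match")
})

test_that("model serialization round-trips exactly", {
  m <- random_potts_model(5, q = 4, field_scale = 1.3, n_coupled_pairs = 3, seed = 41)
  f <- tempfile(fileext = ".potts")
  write_potts(m, f)
  back <- read_potts(f)
  expect_identical(back$v, m$v)
  expect_identical(back$w, m$w)
  expect_identical(back$alphabet, m$alphabet)
})
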