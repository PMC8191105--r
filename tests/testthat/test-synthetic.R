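test_that("random models are deterministic with the requested structure", {
  m1 <- random_potts_model(6, q = 4, field_scale = 1, n_coupled_pairs = 2, seed = 3)
  m2 <- random_potts_model(6, q = 4, field_scale = 1, n_coupled_pairs = 2, seed = 3)
  expect_identical(m1$v, m2$v)
  expect_identical(m1$w, m2$w)

  cn <- coupling_norms(m1)
  cn[lower.tri(cn, diag = TRUE)] <- 0
  expect_equal(sum(cn > 0), 2) # exactly the planted pairs

  m0 <- random_potts_model(6, q = 4, n_coupled_pairs = 2, coupling_scale = 0, seed = 3)
  expect_equal(max(abs(m0$w)), 0)

  # gauge structure: centered fields, double-centered blocks
  expect_equal(rowSums(m1$v), rep(0, 6), tolerance = 1e-12)
  ij <- which(cn > 0, arr.ind = TRUE)[1, ]
  blk <- m1$w[ij[1], ij[2], , ]
  expect_equal(rowSums(blk), rep(0, 4), tolerance = 1e-12)
  expect_equal(colSums(blk), rep(0, 4), tolerance = 1e-12)

  expect_error(random_potts_model(3, q = 4, n_coupled_pairs = 10), "range")
})

test_that("exact enumeration sampling matches the Boltzmann distribution", {
  # zero model: single-site frequencies uniform within 3 sigma binomial bounds
  zero <- potts_model(matrix(0, 2, 4), alphabet = substr(AA_ALPHABET, 1, 4))
  msa <- sample_sequences(zero, 5000, seed = 4)
  f <- compute_frequencies(msa)$f_single
  sigma <- sqrt(0.25 * 0.75 / 5000)
  expect_true(all(abs(f - 0.25) < 3.5 * sigma))

  # a strong positive coupling induces positive direct correlation
  m <- potts_model(matrix(0, 2, 3), alphabet = substr(AA_ALPHABET, 1, 3))
  m$w[1, 2, 1, 1] <- 2
  m$w <- pottsalign:::symmetrize_couplings(m$w)
  msa2 <- sample_sequences(m, 4000, seed = 5)
  fr <- compute_frequencies(msa2)
  expect_gt(fr$f_pair[1, 2, 1, 1], fr$f_single[1, 1] * fr$f_single[2, 1])

  # sample mean energy agrees with the exact expectation
  mm <- random_potts_model(4, q = 3, field_scale = 1, n_coupled_pairs = 2, seed = 6)
  states <- as.matrix(expand.grid(rep(list(1:3), 4)))
  energies <- apply(states, 1, function(x) sequence_energy(mm, x))
  p <- exp(-energies)
  p <- p / sum(p)
  expected <- sum(p * energies)
  sdE <- sqrt(sum(p * (energies - expected)^2))
  msa3 <- sample_sequences(mm, 3000, seed = 7)
  got <- mean(apply(msa3$matrix, 1, function(x) sequence_energy(mm, x)))
  expect_lt(abs(got - expected), 4 * sdE / sqrt(3000))

  big <- potts_model(matrix(0, 20, 4), alphabet = substr(AA_ALPHABET, 1, 4))
  expect_error(sample_sequences(big, 5, method = "exact_enumeration"), "1e6")
})

test_that("Gibbs sampling is deterministic and roughly calibrated", {
  m <- random_potts_model(3, q = 3, field_scale = 1, n_coupled_pairs = 1, seed = 8)
  g1 <- sample_sequences(m, 50, seed = 9, method = "gibbs")
  g2 <- sample_sequences(m, 50, seed = 9, method = "gibbs")
  expect_identical(g1$matrix, g2$matrix)
  expect_equal(attr(g1, "provenance")$burn_in, 300)

  # exact marginals vs Gibbs marginals on a small model
  states <- as.matrix(expand.grid(rep(list(1:3), 3)))
  p <- exp(-apply(states, 1, function(x) sequence_energy(m, x)))
  p <- p / sum(p)
  f_exact <- sapply(1:3, function(a) sum(p[states[, 1] == a]))
  g3 <- sample_sequences(m, 400, seed = 10, method = "gibbs")
  f_gibbs <- compute_frequencies(g3)$f_single[1, ]
  expect_lt(max(abs(f_gibbs - f_exact)), 0.1)
})

test_that("planted pairs record a consistent ground truth", {
  base <- random_potts_model(12, q = 4, field_scale = 1, n_coupled_pairs = 3, seed = 11)
  # no perturbation, no insertions: truth is the identity
  pp0 <- plant_homologous_pair(base, 0, 0, 0, seed = 12)
  expect_equal(pp0$truth, cbind(posA = 1:12, posB = 1:12))
  expect_identical(pp0$model_A$v, base$v)

  # insertions only in A: posB stays contiguous, posA skips inserted columns
  pp1 <- plant_homologous_pair(base, 0, 2, 0, seed = 13)
  expect_equal(pp1$truth[, "posB"], 1:12)
  expect_equal(pp1$model_A$L, 14)
  ins <- setdiff(1:14, pp1$truth[, "posA"])
  expect_equal(length(ins), 2)
  for (i in ins) {
    expect_equal(max(abs(pp1$model_A$v[i, ])), 0)
    expect_equal(max(abs(pp1$model_A$w[i, , , ])), 0)
  }
  expect_true(all(diff(pp1$truth[, "posA"]) > 0))

  pp2 <- plant_homologous_pair(base, 0, 2, 0, seed = 13)
  expect_identical(pp1$truth, pp2$truth)
  expect_identical(pp1$model_A$v, pp2$model_A$v)

  # perturbation-free pair aligns back to the truth at a small offset
  pp3 <- plant_homologous_pair(base, 0, 1, 1, seed = 14)
  cfg <- align_config(
    alpha_w = 1, gap_open = 1, offset_gamma = 0.1,
    epsilon = 1e-6
  )
  aln <- align_potts(pp3$model_A, pp3$model_B, v0 = rep(0, 4), config = cfg)
  expect_equal(precision_recall_f1(aln$pairs, pp3$truth)$f1, 1)
})

test_that("coupling-disambiguation pairs are reproducible and well-formed", {
  d1 <- coupling_disambiguation_pair(seed = 3)
  d2 <- coupling_disambiguation_pair(seed = 3)
  expect_identical(d1$model_A$w, d2$model_A$w)
  expect_identical(d1$truth, d2$truth)
  tr <- d1$truth[order(d1$truth[, 1]), ]
  expect_true(all(diff(tr[, 1]) > 0) && all(diff(tr[, 2]) > 0))
  # the two copies in each block carry identical field profiles
  for (t in seq_len(d1$recipe$n_blocks)) {
    a0 <- 4 * (t - 1) + 1
    expect_identical(d1$model_A$v[a0 + 1, ], d1$model_A$v[a0 + 2, ])
  }
})
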