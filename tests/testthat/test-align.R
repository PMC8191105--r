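test_that("alignment graph has the expected node and edge counts", {
  g1 <- alignment_graph(1, 1)
  expect_equal(g1$n_nodes, 1)
  expect_equal(g1$n_edges, 0)
  g2 <- alignment_graph(2, 2)
  expect_equal(g2$n_edges, 1)
  expect_equal(unname(g2$edges[1, ]), c(1L, 1L, 2L, 2L))
  g3 <- alignment_graph(3, 3)
  expect_equal(g3$n_edges, 9) # choose(3,2)^2
  # every edge strictly increases in both coordinates
  expect_true(all(g3$edges[, "j"] > g3$edges[, "i"]))
  expect_true(all(g3$edges[, "l"] > g3$edges[, "k"]))
})

test_that("row and column sets mutually contradict", {
  rs <- row_set(2, 2, 4, L_B = 5) # heads at row 4 reachable from 2.2
  expect_true(all(rs[, "col"] > 2))
  # no two members lie on a common increasing path (same row, distinct cols)
  expect_true(all(rs[, "row"] == 4))
  expect_equal(anyDuplicated(rs[, "col"]), 0)
  cs <- col_set(3, 2, 4, L_A = 6)
  expect_true(all(cs[, "col"] == 4))
  expect_true(all(cs[, "row"] > 3))
})

test_that("solver handles hand-enumerable instances", {
  cfg <- align_config(
    alpha_w = 1, gap_open = 0, gap_extend = 0,
    offset_gamma = 0, epsilon = 1e-9
  )
  # all positional scores +1: both diagonal pairs, objective 2
  tb <- raw_tables(matrix(1, 2, 2))
  r <- solve_alignment_problem(build_alignment_problem(tb, cfg))
  expect_equal(r$score, 2)
  expect_equal(r$pairs, matrix(c(1L, 2L, 1L, 2L), 2, 2))
  expect_equal(r$status, "optimal")

  # all negative: aligning nothing dominates
  r2 <- solve_alignment_problem(raw_tables(matrix(-1, 2, 2)), cfg)
  expect_equal(r2$score, 0)
  expect_equal(r2$n_aligned, 0)

  # a single strong coupling activates its two endpoints
  sw <- array(0, c(2, 2, 2, 2))
  sw[1, 1, 2, 2] <- 10
  r3 <- solve_alignment_problem(raw_tables(matrix(0, 2, 2), sw), cfg)
  expect_equal(r3$score, 10)
  expect_equal(r3$pairs, matrix(c(1L, 2L, 1L, 2L), 2, 2))

  # 1x1 grid with a negative cell: empty alignment
  r4 <- solve_alignment_problem(raw_tables(matrix(-5, 1, 1)), cfg)
  expect_equal(r4$score, 0)
  expect_equal(r4$n_aligned, 0)
})

test_that("branch and bound matches the brute-force oracle with couplings", {
  for (s in 1:40) {
    inst <- random_instance(s, Lmax = 5, coupled = TRUE)
    r <- solve_alignment_problem(inst$tables, inst$cfg)
    bf <- brute_force_align(inst$tables, inst$cfg)
    expect_equal(r$score, bf$score, tolerance = 1e-8)
    # certificate honesty: rescoring the returned pairs reproduces the score
    expect_equal(alignment_objective(inst$tables, r$pairs, inst$cfg), r$score,
      tolerance = 1e-6
    )
    expect_lte(r$LB, r$UB + 1e-12)
  }
})

test_that("independent-site solver equals the affine-gap DP oracle", {
  set.seed(77)
  for (s in 1:20) {
    LA <- sample(4:8, 1)
    LB <- sample(4:8, 1)
    sv <- matrix(rnorm(LA * LB, sd = 3), LA, LB)
    go <- sample(c(0, 1, 13), 1)
    ge <- sample(c(0, 0.3), 1)
    cfg <- align_config(
      alpha_w = 0, gap_open = go, gap_extend = ge,
      offset_gamma = 0, epsilon = 1e-9
    )
    tb <- raw_tables(sv)
    r <- solve_alignment_problem(tb, cfg)
    d <- dp_align(sv, gap_open = go, gap_extend = ge)
    expect_equal(r$score, d$score, tolerance = 1e-9)
    expect_equal(
      alignment_objective(tb, d$pairs, cfg), d$score,
      tolerance = 1e-9
    )
  }
})

test_that("DP oracle agrees with brute force and handles its edge cases", {
  # identity-favoring diagonal
  sv <- matrix(-1, 4, 4)
  diag(sv) <- 5
  d <- dp_align(sv, gap_open = 2)
  expect_equal(d$pairs, cbind(1:4, 1:4))
  # all negative: empty
  expect_equal(dp_align(matrix(-2, 3, 5), 13)$n_aligned, 0)
  # random 6 x 7 instances against brute force
  set.seed(31)
  for (s in 1:10) {
    sv <- matrix(rnorm(42, sd = 2), 6, 7)
    d <- dp_align(sv, gap_open = 13, gap_extend = 0)
    bf <- brute_force_align(
      raw_tables(sv),
      align_config(alpha_w = 0, gap_open = 13, gap_extend = 0, offset_gamma = 0)
    )
    expect_equal(d$score, bf$score, tolerance = 1e-9)
  }
})

test_that("increasing the offset never aligns more positions", {
  A <- random_potts_model(6, q = 4, field_scale = 1.5, n_coupled_pairs = 3, seed = 91)
  B <- random_potts_model(6, q = 4, field_scale = 1.5, n_coupled_pairs = 3, seed = 92)
  n_prev <- Inf
  for (gamma in c(0, 0.5, 1, 2, 4, 8)) {
    cfg <- align_config(
      alpha_w = 1, gap_open = 1, offset_gamma = gamma,
      epsilon = 1e-9
    )
    r <- align_potts(A, B, v0 = rep(0, 4), config = cfg)
    expect_lte(r$n_aligned, n_prev)
    n_prev <- r$n_aligned
  }
})

test_that("swapping the models mirrors the alignment", {
  for (s in 1:5) {
    A <- random_potts_model(5, q = 3, field_scale = 1.5, n_coupled_pairs = 2, seed = 100 + s)
    B <- random_potts_model(6, q = 3, field_scale = 1.5, n_coupled_pairs = 3, seed = 200 + s)
    cfg <- align_config(alpha_w = 1, gap_open = 1, offset_gamma = 0.5, epsilon = 1e-9)
    rAB <- align_potts(A, B, v0 = rep(0, 3), config = cfg)
    rBA <- align_potts(B, A, v0 = rep(0, 3), config = cfg)
    expect_equal(rAB$score, rBA$score, tolerance = 1e-8)
    expect_equal(rAB$pairs, rBA$pairs[, c(2, 1), drop = FALSE])
  }
})

test_that("aborted searches report a timeout with valid bounds", {
  set.seed(55)
  sv <- matrix(rnorm(64, sd = 2), 8, 8)
  sw <- array(rnorm(8^4, sd = 0.5), c(8, 8, 8, 8))
  tb <- raw_tables(sv, sw, self_A = 100, self_B = 100)
  cfg <- align_config(alpha_w = 1, gap_open = 1, offset_gamma = 0, epsilon = 1e-9)
  r <- solve_alignment_problem(tb, cfg, node_limit = 3)
  expect_equal(r$status, "timeout")
  expect_lte(r$LB, r$UB + 1e-12)
  # the incumbent is still a feasible increasing alignment
  if (r$n_aligned > 1) {
    expect_true(all(diff(r$pairs[, 1]) > 0) && all(diff(r$pairs[, 2]) > 0))
  }
})

test_that("epsilon certificates hold by recomputation from the tables", {
  for (s in 1:10) {
    inst <- random_instance(s + 500, Lmax = 5, coupled = TRUE)
    cfg <- inst$cfg
    cfg$epsilon <- 0.05
    r <- solve_alignment_problem(inst$tables, cfg)
    denom <- inst$tables$self_score_A + inst$tables$self_score_B
    if (r$status %in% c("optimal", "epsilon_optimal") && denom > 0) {
      expect_lte(2 * (r$UB - r$LB) / denom, cfg$epsilon + 1e-9)
    }
  }
})
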