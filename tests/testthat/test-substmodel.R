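test_that("the GTR generator is normalized, scale-invariant and JC-reducing", {
  jc <- substitution_model()
  Q <- rate_matrix(jc)
  expect_equal(unname(Q[row(Q) != col(Q)]), rep(1 / 3, 12))
  expect_equal(unname(rowSums(Q)), rep(0, 4))

  m <- study_gtr_model()
  Qs <- rate_matrix(m)
  expect_equal(-sum(m$base_freqs * diag(Qs)), 1)
  expect_equal(unname(rowSums(Qs)), rep(0, 4), tolerance = 1e-12)

  scaled <- substitution_model(rates = m$rates * 10, base_freqs = m$base_freqs)
  expect_equal(rate_matrix(scaled), rate_matrix(substitution_model(
    rates = m$rates, base_freqs = m$base_freqs)))

  expect_error(substitution_model(rates = c(1, 1, -1, 1, 1, 1)), "positive")
  expect_error(substitution_model(base_freqs = c(0.5, 0.5, 0.2, -0.2)), "positive|sum")
})

test_that("transition probabilities are stochastic, ergodic and reversible", {
  m <- study_gtr_model()
  Q <- rate_matrix(m)
  expect_equal(transition_probs(Q, 0), diag(4), ignore_attr = TRUE)
  Plong <- transition_probs(Q, 500)
  for (i in 1:4) expect_equal(unname(Plong[i, ]), unname(m$base_freqs), tolerance = 1e-9)
  P <- transition_probs(Q, 0.37, r = 1.4)
  expect_equal(unname(rowSums(P)), rep(1, 4))
  # detailed balance pi_i P_ij = pi_j P_ji
  F <- m$base_freqs * P
  expect_equal(F, t(F), tolerance = 1e-12)

  # closed-form Jukes-Cantor oracle
  jc <- rate_matrix(substitution_model())
  Pjc <- transition_probs(jc, 0.1)
  expect_equal(unname(Pjc[1, 2]), 0.25 * (1 - exp(-4 * 0.1 / 3)), tolerance = 1e-12)
})

test_that("discrete gamma category rates are the mean-1 conditional means", {
  for (a in c(0.1, 0.5, 1, 2, 17)) {
    r <- discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1)
    expect_true(all(diff(r) > 0))
    expect_equal(r, oracle_gamma_rates(a, 4), tolerance = 1e-9)
  }
  expect_equal(discrete_gamma_rates(0.5, 1), 1)
  expect_equal(discrete_gamma_rates(Inf, 4), rep(1, 4))
})

test_that("pattern probabilities normalize, degenerate correctly and match the brute-force sum", {
  m <- study_gtr_model(alpha = 0.7, p_inv = 0.3, n_cat = 4)
  tr <- quartet_tree("q1", c(0.3, 0.1, 0.2, 0.4, 0.05))
  p <- pattern_probs(tr, m)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  zero <- quartet_tree("q2", rep(0, 5))
  pz <- pattern_probs(zero, m)
  const_idx <- c(1, 86, 171, 256)
  expect_equal(unname(pz[const_idx]), unname(m$base_freqs), tolerance = 1e-12)
  expect_equal(sum(pz[-const_idx]), 0)

  # JC, one category, no invariants: independent double-sum oracle
  po <- oracle_pattern_probs("q1", rep(0.1, 5), rep(1, 6), rep(0.25, 4),
                             alpha = 1, p_inv = 0, n_cat = 1)
  pp <- pattern_probs(quartet_tree("q1", rep(0.1, 5)),
                      substitution_model(n_cat = 1))
  expect_equal(pp, po, tolerance = 1e-10)
})

test_that("pattern probabilities respect the topology symmetry group", {
  m <- study_gtr_model(alpha = 1.2, p_inv = 0.2, n_cat = 2)
  # swapping the split halves of q1 (A<->C, B<->D with matching branch
  # swaps) must leave each tuple's probability attached to the permuted tuple
  bl <- c(A = 0.4, B = 0.1, C = 0.25, D = 0.6, internal = 0.07)
  p1 <- pattern_probs(quartet_tree("q1", bl), m)
  p2 <- pattern_probs(quartet_tree("q1", bl[c("C", "D", "A", "B", "internal")]), m)
  grid <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  swapped_idx <- grid$c + 4 * (grid$d - 1) + 16 * (grid$a - 1) + 64 * (grid$b - 1)
  expect_equal(p1, p2[swapped_idx], tolerance = 1e-12)
})

test_that("log-likelihood is multinomial over compressed patterns", {
  m <- study_gtr_model(alpha = 1, p_inv = 0, n_cat = 1)
  zero <- quartet_tree("q1", rep(0, 5))
  one_col <- tally_patterns(qa_from_columns(c("C", "C", "C", "C")))
  expect_equal(log_likelihood(one_col, zero, m), log(m$base_freqs[["C"]]))

  # impossible pattern under a zero-length tree
  bad <- tally_patterns(qa_from_columns(c("A", "C", "G", "T")))
  ll <- log_likelihood(bad, zero, m)
  expect_identical(unname(ll[1]), -Inf)
  expect_true(isTRUE(attr(ll, "impossible")))

  tr <- quartet_tree("q1", c(0.2, 0.1, 0.3, 0.15, 0.05))
  qa <- qa_from_columns(c("A", "A", "C", "C"), c("A", "C", "G", "T"), c("T", "T", "T", "T"))
  t1 <- tally_patterns(qa)
  t2 <- tally_patterns(qa_from_columns(c("A", "A", "C", "C"), c("A", "C", "G", "T"),
                                       c("T", "T", "T", "T"), c("A", "A", "C", "C"),
                                       c("A", "C", "G", "T"), c("T", "T", "T", "T")))
  expect_equal(log_likelihood(t2, tr, m), 2 * log_likelihood(t1, tr, m))

  # per-site product from the oracle
  po <- oracle_pattern_probs("q1", c(0.2, 0.1, 0.3, 0.15, 0.05),
                             rep(1, 6), rep(0.25, 4), 1, 0, 1)
  idx <- which(t1$counts256 > 0)
  expect_equal(log_likelihood(t1, tr, substitution_model(n_cat = 1)),
               sum(t1$counts256[idx] * log(po[idx])), tolerance = 1e-9)
})

test_that("likelihood is invariant under consistent taxon relabeling", {
  set.seed(21)
  s <- random_states(300)
  m <- study_gtr_model(alpha = 0.9, p_inv = 0.1, n_cat = 4)
  bl <- c(0.3, 0.12, 0.25, 0.08, 0.04)
  l0 <- log_likelihood(tally_patterns(s), quartet_tree("q1", bl), m)
  # swap within the left pair (A<->B)
  l1 <- log_likelihood(tally_patterns(s[c(2, 1, 3, 4), ]),
                       quartet_tree("q1", bl[c(2, 1, 3, 4, 5)]), m)
  # swap the split halves
  l2 <- log_likelihood(tally_patterns(s[c(3, 4, 1, 2), ]),
                       quartet_tree("q1", bl[c(3, 4, 1, 2, 5)]), m)
  expect_equal(l1, l0, tolerance = 1e-9)
  expect_equal(l2, l0, tolerance = 1e-9)
})

test_that("fitting recovers a simulated tree and is a fixed point at its optimum", {
  cfg <- simulation_config(design = "felsenstein", BL1 = 0.05, BL2 = 0.4,
                           L = 30000, seed = 99,
                           model = study_gtr_model(alpha = 1, p_inv = 0.3, n_cat = 4))
  qa <- simulate_quartet(cfg)
  tl <- tally_patterns(qa)
  fit <- fit_quartet(tl, "q1", mode = "fixed_alpha_inv", alpha = 1, p_inv = 0.3)
  expect_true(fit$converged)
  truth <- sim_branch_lengths(cfg)
  expect_equal(unname(fit$tree$bl), unname(truth$bl), tolerance = 0.2)

  # restarting from the optimum does not move the likelihood
  refit <- fit_quartet(tl, "q1", mode = "fixed_alpha_inv", alpha = 1, p_inv = 0.3)
  expect_lt(abs(refit$logL - fit$logL), 1e-4)

  # all-constant data: divergence collapses to the lower bound
  const <- tally_patterns(qa_rep(list(c("A", "A", "A", "A"), 50),
                                 list(c("T", "T", "T", "T"), 30)))
  fc <- fit_quartet(const, "q1", mode = "fixed_alpha_inv", alpha = 1, p_inv = 0)
  expect_true(all(fc$tree$bl < 1e-4))
})

test_that("expected class counts aggregate the fitted spectrum to length L", {
  fit <- fake_fit("q2", c(sym_q1 = 0.03, asym_q1_CD = 0.02, singleton_A = 0.1))
  ec <- expected_counts(fit, 200)
  expect_equal(sum(ec), 200)
  expect_equal(unname(ec[["sym_q1"]]), 6)
  expect_equal(unname(ec[["asym_q1_CD"]]), 4)
  expect_equal(expected_counts(fit, 0), stats::setNames(rep(0, 15), site_pattern_classes()))

  # zero-length tree puts everything in the constant class
  m <- study_gtr_model(p_inv = 0, n_cat = 1)
  pz <- pattern_probs(quartet_tree("q1", rep(0, 5)), m)
  fz <- structure(list(tree = quartet_tree("q1", rep(0, 5)), pattern_probs = pz),
                  class = "fitted_quartet")
  ecz <- expected_counts(fz, 100)
  expect_equal(unname(ecz[["constant"]]), 100)
  expect_equal(sum(ecz) - ecz[["constant"]], 0)
})
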