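# Independent oracles, deliberately written against different primitives
# than the package: generators are built index-wise, transition matrices
# come from Matrix::expm, gamma category means from numerical
# integration, and pattern probabilities from an explicit per-tuple
# double sum over the two internal node states.

oracle_generator <- function(rates, freqs) {
  # pairs in package order AC, AG, AT, CG, CT, GT over states 1..4
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  Q <- matrix(0, 4, 4)
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- rates[k] * freqs[j]
    Q[j, i] <- rates[k] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

oracle_pmat <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# conditional category means of the mean-1 gamma via numerical
# integration over equal-probability bins
oracle_gamma_rates <- function(alpha, n_cat) {
  if (n_cat == 1) return(1)
  b <- qgamma(seq(0, 1, length.out = n_cat + 1), shape = alpha, rate = alpha)
  b[n_cat + 1] <- max(b[n_cat], qgamma(1 - 1e-12, alpha, alpha)) * 4
  sapply(seq_len(n_cat), function(k) {
    n_cat * integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                      b[k], b[k + 1], rel.tol = 1e-12)$value
  })
}

# explicit 16-term double sum for one tuple, averaged over a supplied
# vector of equally weighted rate multipliers
oracle_pp_rates <- function(topology, bl, rates, freqs, rk, p_inv) {
  Q <- oracle_generator(rates, freqs)
  groups <- list(q1 = c(1, 2, 3, 4), q2 = c(1, 3, 2, 4), q3 = c(1, 4, 2, 3))
  ord <- groups[[topology]]   # roles at (left1, left2, right1, right2)
  p <- numeric(256)
  for (r in rk) {
    P1 <- oracle_pmat(Q, bl[ord[1]] * r)
    P2 <- oracle_pmat(Q, bl[ord[2]] * r)
    P3 <- oracle_pmat(Q, bl[ord[3]] * r)
    P4 <- oracle_pmat(Q, bl[ord[4]] * r)
    PI <- oracle_pmat(Q, bl[5] * r)
    for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4) {
      st <- c(a, b, cc, d)         # states at roles A,B,C,D
      idx <- a + 4 * (b - 1) + 16 * (cc - 1) + 64 * (d - 1)
      s <- 0
      for (x in 1:4) for (y in 1:4)
        s <- s + freqs[x] * P1[x, st[ord[1]]] * P2[x, st[ord[2]]] *
                 PI[x, y] * P3[y, st[ord[3]]] * P4[y, st[ord[4]]]
      p[idx] <- p[idx] + s
    }
  }
  p <- (1 - p_inv) * p / length(rk)
  for (a in 1:4) p[85 * a - 84] <- p[85 * a - 84] + p_inv * freqs[a]
  p
}

oracle_pattern_probs <- function(topology, bl, rates, freqs, alpha, p_inv, n_cat) {
  oracle_pp_rates(topology, bl, rates, freqs, oracle_gamma_rates(alpha, n_cat), p_inv)
}

# midpoint integration of the continuous gamma mixture on the
# probability scale: equally weighted quantile midpoints
oracle_pattern_probs_continuous <- function(topology, bl, rates, freqs,
                                            alpha, p_inv, n_grid = 200) {
  rk <- qgamma((seq_len(n_grid) - 0.5) / n_grid, shape = alpha, rate = alpha)
  oracle_pp_rates(topology, bl, rates, freqs, rk, p_inv)
}

random_model_instance <- function() {
  rates <- exp(rnorm(6, 0, 0.7))
  freqs <- rgamma(4, 5, 1); freqs <- freqs / sum(freqs)
  list(topology = sample(c("q1", "q2", "q3"), 1),
       bl = c(runif(4, 0.01, 1.2), runif(1, 0.005, 0.3)),
       rates = rates, freqs = freqs,
       alpha = runif(1, 0.3, 4), p_inv = runif(1, 0, 0.5),
       n_cat = sample(c(1L, 2L, 4L), 1))
}
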