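# Quartet sequence simulator: GTR + continuous (or discrete) gamma +
# invariant sites on the four branch-length designs of the
# long-branch-attraction study.
#
# Sites are i.i.d.; a site is invariant with probability p_inv (one
# state drawn from the stationary frequencies, shared by all four taxa),
# otherwise its rate multiplier is drawn from the gamma distribution
# (mean 1 among variable sites) and states evolve from a stationary root
# draw at the left internal node along the five branches.  Branch
# lengths are expected substitutions per variable site; they are not
# rescaled for the invariant fraction, matching the +I convention of the
# likelihood core.

#' @include patterns.R substmodel.R
NULL

#' Configure a quartet simulation
#'
#' Branch-length designs: \code{"farris"} (two elongated terminals
#' adjacent, i.e. on the same split half), \code{"felsenstein"} (two
#' elongated terminals non-adjacent), \code{"one_long"} (one terminal at
#' BL2, one at BL3, two short) and \code{"three_long"} (three terminals
#' at BL2, the fourth at BL3).  BL1 is the internal branch, \code{short}
#' the fixed short terminal length (0.1).
#'
#' @param design One of \code{"farris","felsenstein","one_long","three_long"}.
#' @param BL1 Internal branch length.
#' @param BL2 Elongated terminal branch length.
#' @param BL3 Secondary variable terminal length (one_long/three_long).
#' @param short Fixed short terminal length (default 0.1).
#' @param L Number of sites.
#' @param model A \code{subst_model}; default the study GTR with
#'   continuous gamma (alpha 1) and 30\% invariant sites.
#' @param seed Integer RNG seed for the replicate.
#' @param true_topology Generating topology (default \code{"q1"}).
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(design = c("farris", "felsenstein", "one_long", "three_long"),
                              BL1 = 0.01, BL2 = 1.5, BL3 = 0.1, short = 0.1,
                              L = 250000L, model = study_gtr_model(),
                              seed = 1L, true_topology = "q1") {
  design <- match.arg(design)
  true_topology <- match.arg(true_topology, .TOPOLOGIES)
  stopifnot(BL1 >= 0, BL2 >= 0, BL3 >= 0, short >= 0, L >= 1)
  structure(list(design = design, BL1 = BL1, BL2 = BL2, BL3 = BL3,
                 short = short, L = as.integer(L), model = model,
                 seed = as.integer(seed), true_topology = true_topology),
            class = "simulation_config")
}

#' Branch lengths of a simulation design
#'
#' Places the elongated branches on the roles prescribed by the design,
#' relative to the true topology's split: farris puts both BL2 terminals
#' on the same split half, felsenstein on opposite halves; one_long puts
#' BL2 and BL3 on opposite halves (the arrangement in which chance
#' similarity can attract them); three_long elongates all terminals of
#' one configuration except the BL3 one.
#'
#' @param cfg A \code{simulation_config}.
#' @return A \code{quartet_tree} with the design's five branch lengths.
#' @export
sim_branch_lengths <- function(cfg) {
  g <- .TOPO_GROUPS[[cfg$true_topology]]
  bl <- stats::setNames(rep(cfg$short, 4), c("A", "B", "C", "D"))
  switch(cfg$design,
    farris = {
      bl[g$left] <- cfg$BL2
    },
    felsenstein = {
      bl[g$left[1]] <- cfg$BL2
      bl[g$right[1]] <- cfg$BL2
    },
    one_long = {
      bl[g$left[1]] <- cfg$BL2
      bl[g$right[1]] <- cfg$BL3
    },
    three_long = {
      bl[c(g$left, g$right[1])] <- cfg$BL2
      bl[g$right[2]] <- cfg$BL3
    })
  quartet_tree(cfg$true_topology, c(bl, internal = cfg$BL1))
}

# evolve a vector of parent states along one branch; rates is the
# per-site multiplier vector
.evolve <- function(states, t, rates, dec) {
  E <- exp(outer(rates * t, dec$values))          # L x 4
  probs <- (E * dec$A[states, , drop = FALSE]) %*% dec$B
  probs[probs < 0] <- 0
  probs <- probs / rowSums(probs)
  u <- stats::runif(length(states))
  c1 <- probs[, 1]
  c2 <- c1 + probs[, 2]
  c3 <- c2 + probs[, 3]
  1L + (u > c1) + (u > c2) + (u > c3)
}

#' Simulate a quartet alignment
#'
#' @param cfg A \code{simulation_config}.
#' @return A \code{quartet_alignment} (gap-free, all columns used); the
#'   configuration is attached as attribute \code{"config"}.
#' @export
simulate_quartet <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  m <- cfg$model
  tree <- sim_branch_lengths(cfg)
  set.seed(cfg$seed)
  L <- cfg$L
  pi <- m$base_freqs
  inv <- stats::runif(L) < m$p_inv
  nv <- sum(!inv)
  states <- matrix(0L, 4L, L, dimnames = list(c("A", "B", "C", "D"), NULL))
  if (any(inv)) {
    s <- sample.int(4L, sum(inv), replace = TRUE, prob = pi)
    states[, inv] <- rep(s, each = 4L)
  }
  if (nv > 0L) {
    rates <- if (m$n_cat == 0L) {
      if (is.finite(m$alpha)) stats::rgamma(nv, shape = m$alpha, rate = m$alpha) else rep(1, nv)
    } else {
      sample(discrete_gamma_rates(m$alpha, m$n_cat), nv, replace = TRUE)
    }
    dec <- .gtr_eigen(rate_matrix(m), pi)
    g <- .TOPO_GROUPS[[cfg$true_topology]]
    root <- sample.int(4L, nv, replace = TRUE, prob = pi)
    node2 <- .evolve(root, tree$bl["internal"], rates, dec)
    states[g$left[1], !inv] <- .evolve(root, tree$bl[g$left[1]], rates, dec)
    states[g$left[2], !inv] <- .evolve(root, tree$bl[g$left[2]], rates, dec)
    states[g$right[1], !inv] <- .evolve(node2, tree$bl[g$right[1]], rates, dec)
    states[g$right[2], !inv] <- .evolve(node2, tree$bl[g$right[2]], rates, dec)
  }
  qa <- structure(list(roles = c(A = "A", B = "B", C = "C", D = "D"),
                       states = states,
                       original_length = L, used_length = L,
                       excluded = integer(0)),
                  class = "quartet_alignment")
  attr(qa, "config") <- cfg
  qa
}
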