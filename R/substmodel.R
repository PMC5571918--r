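# GTR+Gamma+I machinery on quartet trees.
#
# Likelihoods are computed on the compressed 256-pattern spectrum, so the
# cost of a likelihood evaluation is independent of alignment length.  The
# generator is diagonalized once per evaluation via the standard
# pi-symmetrization of a reversible rate matrix; transition matrices for
# all branch/rate-category combinations are then cheap.

#' @include patterns.R
NULL

.RATE_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Construct a GTR+Gamma+I substitution model
#'
#' @param rates Six positive exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.  Only relative values matter.
#' @param base_freqs Four positive stationary frequencies (A,C,G,T order)
#'   summing to 1.
#' @param alpha Gamma shape parameter for among-site rate variation
#'   (larger = more homogeneous); \code{Inf} means equal rates.
#' @param p_inv Proportion of invariant sites in [0, 1).
#' @param n_cat Number of discrete gamma categories; \code{0} selects the
#'   continuous gamma distribution and is only meaningful for simulation.
#' @return An object of class \code{subst_model}.
#' @export
substitution_model <- function(rates = c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1, GT = 1),
                               base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                               alpha = 1, p_inv = 0, n_cat = 4L) {
  rates <- as.numeric(rates)
  base_freqs <- as.numeric(base_freqs)
  if (length(rates) != 6L || any(!is.finite(rates)) || any(rates <= 0))
    stop("`rates` must be six positive exchangeabilities (AC,AG,AT,CG,CT,GT)")
  if (length(base_freqs) != 4L || any(base_freqs <= 0))
    stop("`base_freqs` must be four positive frequencies (A,C,G,T)")
  if (abs(sum(base_freqs) - 1) > 1e-8)
    stop("`base_freqs` must sum to 1")
  if (!is.finite(alpha) && !identical(alpha, Inf)) stop("`alpha` must be positive")
  if (alpha <= 0) stop("`alpha` must be positive")
  if (p_inv < 0 || p_inv >= 1) stop("`p_inv` must lie in [0, 1)")
  structure(list(rates = stats::setNames(rates, .RATE_NAMES),
                 base_freqs = stats::setNames(base_freqs, .BASES),
                 alpha = alpha, p_inv = p_inv, n_cat = as.integer(n_cat)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model> GTR+G+I\n")
  cat("  exchangeabilities:", paste(sprintf("%s=%.4g", names(x$rates), x$rates), collapse = " "), "\n")
  cat("  base freqs:       ", paste(sprintf("%s=%.4g", names(x$base_freqs), x$base_freqs), collapse = " "), "\n")
  cat(sprintf("  alpha=%.4g  p_inv=%.4g  n_cat=%d\n", x$alpha, x$p_inv, x$n_cat))
  invisible(x)
}

#' GTR parameter set of the simulation study
#'
#' The fixed GTR exchangeabilities and base frequencies under which all
#' built-in long-branch-attraction experiments generate data
#' (C-T 0.3, T-A 0.8, T-G 0.6, C-A 0.5, G-C 0.4, G-A 1.0;
#' frequencies T 0.35, C 0.15, A 0.35, G 0.15), with gamma rate variation
#' and 30% invariant sites.
#'
#' @param alpha Gamma shape parameter (default 1).
#' @param p_inv Invariant-site proportion (default 0.3).
#' @param n_cat Discrete gamma categories; default 0 = continuous, the
#'   generating condition of the study design.
#' @return A \code{subst_model}.
#' @export
study_gtr_model <- function(alpha = 1, p_inv = 0.3, n_cat = 0L) {
  substitution_model(
    rates = c(AC = 0.5, AG = 1.0, AT = 0.8, CG = 0.4, CT = 0.3, GT = 0.6),
    base_freqs = c(A = 0.35, C = 0.15, G = 0.15, T = 0.35),
    alpha = alpha, p_inv = p_inv, n_cat = n_cat)
}

#' Normalized GTR rate matrix
#'
#' Builds the generator Q with off-diagonals s_ij * pi_j, rows summing to
#' zero, scaled so that the expected substitution rate at stationarity is
#' one per unit time (over variable sites).
#'
#' @param m A \code{subst_model}.
#' @return A 4x4 matrix with A,C,G,T dimnames.
#' @export
rate_matrix <- function(m) {
  s <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  s["A", "C"] <- s["C", "A"] <- m$rates["AC"]
  s["A", "G"] <- s["G", "A"] <- m$rates["AG"]
  s["A", "T"] <- s["T", "A"] <- m$rates["AT"]
  s["C", "G"] <- s["G", "C"] <- m$rates["CG"]
  s["C", "T"] <- s["T", "C"] <- m$rates["CT"]
  s["G", "T"] <- s["T", "G"] <- m$rates["GT"]
  pi <- m$base_freqs
  Q <- s * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Spectral decomposition of a reversible generator: P(t) = A exp(Lt) B.
# Symmetrize with sqrt(pi) so a symmetric eigensolver can be used.
.gtr_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  S <- Q * rep(sq, times = 4) / rep(sq, each = 4)  # diag(sq) Q diag(1/sq)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       A = e$vectors / sq,          # diag(1/sq) V
       B = t(e$vectors * sq))       # V' diag(sq)
}

.pmat <- function(dec, t) {
  if (t == 0) return(diag(4))   # exact: keeps impossible patterns at probability 0
  P <- dec$A %*% (exp(dec$values * t) * dec$B)
  P[P < 0] <- 0
  P
}

#' Transition probability matrix
#'
#' exp(r * t * Q) for a branch of length \code{t} and rate multiplier
#' \code{r}.
#'
#' @param Q A generator as returned by \code{\link{rate_matrix}}.
#' @param t Branch length (expected substitutions per site), >= 0.
#' @param r Rate multiplier, >= 0 (default 1).
#' @return A 4x4 row-stochastic matrix.
#' @export
transition_probs <- function(Q, t, r = 1) {
  stopifnot(t >= 0, r >= 0)
  pi <- .stationary_from_Q(Q)
  P <- .pmat(.gtr_eigen(Q, pi), t * r)
  dimnames(P) <- list(.BASES, .BASES)
  P / rowSums(P)
}

# stationary distribution of a reversible generator (left null vector)
.stationary_from_Q <- function(Q) {
  ns <- eigen(t(Q))
  i <- which.min(abs(ns$values))
  v <- Re(ns$vectors[, i])
  v / sum(v)
}

#' Discrete gamma category rates (mean-of-category scheme)
#'
#' Equal-probability categories whose representative rates are the exact
#' conditional means, so the discrete distribution has mean 1 among
#' variable sites.
#'
#' @param alpha Gamma shape parameter.
#' @param n_cat Number of categories (>= 1).
#' @return Numeric vector of length \code{n_cat}.
#' @export
discrete_gamma_rates <- function(alpha, n_cat) {
  n_cat <- as.integer(n_cat)
  stopifnot(n_cat >= 1L)
  if (n_cat == 1L || !is.finite(alpha)) return(rep(1, n_cat))
  b <- stats::qgamma(seq(0, 1, length.out = n_cat + 1L), shape = alpha, rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  r <- n_cat * diff(p)
  # guard against numerical drift in extreme shapes
  r * (1 / mean(r))
}

#' Construct a quartet tree
#'
#' @param topology One of \code{"q1","q2","q3"} (AB|CD, AC|BD, AD|BC).
#' @param bl Five non-negative branch lengths: terminals A,B,C,D then the
#'   internal branch, in expected substitutions per (variable) site.
#' @return An object of class \code{quartet_tree}.
#' @export
quartet_tree <- function(topology, bl) {
  topology <- match.arg(topology, .TOPOLOGIES)
  bl <- as.numeric(bl)
  if (length(bl) != 5L || any(bl < 0) || any(!is.finite(bl)))
    stop("`bl` must be five finite non-negative branch lengths (A,B,C,D,internal)")
  structure(list(topology = topology,
                 bl = stats::setNames(bl, c("A", "B", "C", "D", "internal"))),
            class = "quartet_tree")
}

#' @export
print.quartet_tree <- function(x, ...) {
  cat("<quartet_tree>", x$topology, ":",
      paste(sprintf("%s=%.4g", names(x$bl), x$bl), collapse = " "), "\n")
  invisible(x)
}

# role grouping per topology: left pair evolves from the root-side node,
# right pair from the far node of the internal branch
.TOPO_GROUPS <- list(
  q1 = list(left = c("A", "B"), right = c("C", "D"), perm = c(1L, 2L, 3L, 4L)),
  q2 = list(left = c("A", "C"), right = c("B", "D"), perm = c(1L, 3L, 2L, 4L)),
  q3 = list(left = c("A", "D"), right = c("B", "C"), perm = c(1L, 3L, 4L, 2L))
)

.CONSTANT_IDX <- c(1L, 86L, 171L, 256L)

# reorder a (left1,left2,right1,right2) joint array into canonical
# (A,B,C,D) tuple order
.reorder_joint <- function(joint16, topology) {
  if (topology == "q1") return(as.vector(joint16))
  g <- .TOPO_GROUPS[[topology]]
  arr <- array(joint16, c(4, 4, 4, 4))  # dims: left1, left2, right1, right2
  ord <- match(c("A", "B", "C", "D"), c(g$left, g$right))
  as.vector(aperm(arr, ord))
}

.REP16_I <- rep(1:4, times = 4)
.REP16_J <- rep(1:4, each = 4)

#' Exact site-pattern probabilities on a quartet tree
#'
#' Computes the probability of every ordered 4-tuple (A,B,C,D in A,C,G,T
#' coding) under GTR with discrete gamma rates and a proportion of
#' invariant sites, by summing over the two internal node states.
#'
#' @param tree A \code{quartet_tree}.
#' @param m A \code{subst_model} with \code{n_cat >= 1}.
#' @return Numeric vector of length 256 summing to 1; index of tuple
#'   (a,b,c,d) is \code{a + 4(b-1) + 16(c-1) + 64(d-1)} with states 1..4.
#' @export
pattern_probs <- function(tree, m) {
  if (m$n_cat < 1L) stop("pattern_probs needs a discretized model (n_cat >= 1)")
  pi <- m$base_freqs
  dec <- .gtr_eigen(rate_matrix(m), pi)
  rk <- discrete_gamma_rates(m$alpha, m$n_cat)
  g <- .TOPO_GROUPS[[tree$topology]]
  bl <- tree$bl
  p16 <- matrix(0, 16, 16)
  for (r in rk) {
    P1 <- .pmat(dec, bl[g$left[1]] * r)
    P2 <- .pmat(dec, bl[g$left[2]] * r)
    P3 <- .pmat(dec, bl[g$right[1]] * r)
    P4 <- .pmat(dec, bl[g$right[2]] * r)
    PI <- .pmat(dec, bl["internal"] * r)
    M1 <- P1[, .REP16_I] * P2[, .REP16_J]   # 4 x 16, rows = left node state
    M2 <- P3[, .REP16_I] * P4[, .REP16_J]   # 4 x 16, rows = right node state
    p16 <- p16 + crossprod(M1, (pi * PI) %*% M2)
  }
  p <- .reorder_joint(p16, tree$topology) * ((1 - m$p_inv) / m$n_cat)
  p[.CONSTANT_IDX] <- p[.CONSTANT_IDX] + m$p_inv * pi
  p
}

#' Multinomial log-likelihood of a pattern tally
#'
#' @param tally A \code{pattern_tally}.
#' @param tree A \code{quartet_tree}.
#' @param m A \code{subst_model} (discrete gamma).
#' @return The log-likelihood; \code{-Inf} (with attribute
#'   \code{impossible = TRUE}) if a structurally impossible pattern was
#'   observed.  Positive probabilities are floored at 1e-300 before
#'   logging.
#' @export
log_likelihood <- function(tally, tree, m) {
  p <- pattern_probs(tree, m)
  obs <- which(tally$counts256 > 0L)
  p0 <- p[obs]
  if (any(p0 == 0)) {
    out <- -Inf
    attr(out, "impossible") <- TRUE
    return(out)
  }
  sum(tally$counts256[obs] * log(pmax(p0, 1e-300)))
}
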