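# Maximum-likelihood fitting of a quartet topology.
#
# Box-constrained quasi-Newton optimization (L-BFGS-B) on log-transformed
# branch lengths and exchangeabilities; GT is the reference
# exchangeability fixed at 1 and base frequencies are set to the
# empirical composition of the quartet alignment rather than optimized.
# Starting branch lengths come from Jukes-Cantor pairwise distances via
# the four-point decomposition, which keeps the optimizer fast even in
# extreme long-branch regimes.

#' @include patterns.R substmodel.R
NULL

# per role pair: which of the 256 tuples have differing states
.PAIR_DIFF <- local({
  st <- t(vapply(seq_len(256L), .decode_tuple, integer(4)))
  combs <- list(AB = c(1, 2), AC = c(1, 3), AD = c(1, 4),
                BC = c(2, 3), BD = c(2, 4), CD = c(3, 4))
  lapply(combs, function(ij) st[, ij[1]] != st[, ij[2]])
})

.jc_distances <- function(tally) {
  n <- tally$counts256
  L <- tally$L
  vapply(.PAIR_DIFF, function(d) {
    p <- sum(n[d]) / L
    p <- min(p, 0.70)
    max(-0.75 * log(1 - 4 * p / 3), 1e-6)
  }, numeric(1))
}

.start_branch_lengths <- function(tally, topology) {
  d <- .jc_distances(tally)
  g <- .TOPO_GROUPS[[topology]]
  pn <- function(a, b) paste0(min2 <- sort(c(a, b))[1], sort(c(a, b))[2])
  dd <- function(a, b) d[[pn(a, b)]]
  l1 <- g$left[1]; l2 <- g$left[2]; r1 <- g$right[1]; r2 <- g$right[2]
  ext <- function(x, sib, o1, o2) {
    max((dd(x, sib) + dd(x, o1) - dd(sib, o1)) / 2,
        (dd(x, sib) + dd(x, o2) - dd(sib, o2)) / 2, 1e-4)
  }
  bl <- c(A = 0, B = 0, C = 0, D = 0, internal = 0)
  bl[l1] <- ext(l1, l2, r1, r2)
  bl[l2] <- ext(l2, l1, r1, r2)
  bl[r1] <- ext(r1, r2, l1, l2)
  bl[r2] <- ext(r2, r1, l1, l2)
  bl["internal"] <- max((dd(l1, r1) + dd(l2, r2) + dd(l1, r2) + dd(l2, r1)) / 4 -
                        (dd(l1, l2) + dd(r1, r2)) / 2, 1e-4)
  pmin(pmax(bl, 1e-6), 19)
}

.empirical_base_freqs <- function(tally) {
  counts <- as.vector(crossprod(tally$counts256, .TUPLE_BASE_COUNT))
  f <- counts / sum(counts)
  f <- pmax(f, 1e-6)
  stats::setNames(f / sum(f), .BASES)
}

#' Fit branch lengths and model parameters for one quartet topology
#'
#' Maximizes the multinomial pattern log-likelihood under GTR+Gamma+I for
#' a fixed topology.  Base frequencies are the empirical composition of
#' the data; five branch lengths and five relative exchangeabilities
#' (GT = 1) are always free.  In mode \code{"all_free"} the gamma shape
#' and invariant proportion are estimated too; in
#' \code{"fixed_alpha_inv"} they are held at the supplied values.
#'
#' @param tally A \code{pattern_tally}.
#' @param topology One of \code{"q1","q2","q3"}.
#' @param mode \code{"all_free"} or \code{"fixed_alpha_inv"}.
#' @param alpha,p_inv Values used (and fixed) in \code{"fixed_alpha_inv"}
#'   mode; starting values otherwise.
#' @param n_cat Discrete gamma categories (default 4).
#' @param control List of optimizer settings: \code{bl_bounds} (default
#'   c(1e-8, 20)), \code{alpha_bounds} (c(0.01, 100)), \code{pinv_max}
#'   (0.99), \code{factr} (1e8, L-BFGS-B tolerance scaling), \code{maxit}
#'   (300), \code{restarts} (3 random restarts on non-convergence).
#' @return An object of class \code{fitted_quartet}: list with
#'   \code{tree}, \code{model}, \code{logL}, \code{pattern_probs}
#'   (length-256 vector) and \code{converged}.
#' @export
fit_quartet <- function(tally, topology,
                        mode = c("all_free", "fixed_alpha_inv"),
                        alpha = 1, p_inv = 0.2, n_cat = 4L,
                        control = list()) {
  mode <- match.arg(mode)
  topology <- match.arg(topology, .TOPOLOGIES)
  ctl <- utils::modifyList(list(bl_bounds = c(1e-8, 20),
                                alpha_bounds = c(0.01, 100),
                                pinv_max = 0.99,
                                factr = 1e8, maxit = 300L, restarts = 3L),
                           control)
  freqs <- .empirical_base_freqs(tally)
  obs <- which(tally$counts256 > 0L)
  nobs <- tally$counts256[obs]
  free_ai <- mode == "all_free"

  unpack <- function(par) {
    bl <- exp(par[1:5])
    ex <- c(exp(par[6:10]), 1)
    if (free_ai) {
      a <- exp(par[11]); pi0 <- par[12]
    } else {
      a <- alpha; pi0 <- p_inv
    }
    list(tree = structure(list(topology = topology,
                               bl = stats::setNames(bl, c("A", "B", "C", "D", "internal"))),
                          class = "quartet_tree"),
         model = structure(list(rates = stats::setNames(ex, .RATE_NAMES),
                                base_freqs = freqs, alpha = a, p_inv = pi0,
                                n_cat = as.integer(n_cat)),
                           class = "subst_model"))
  }
  nll <- function(par) {
    u <- unpack(par)
    p <- pattern_probs(u$tree, u$model)[obs]
    v <- -sum(nobs * log(pmax(p, 1e-300)))
    if (!is.finite(v)) v <- 1e12
    v
  }

  bl0 <- .start_branch_lengths(tally, topology)
  start <- c(log(bl0), log(rep(1, 5)))
  lower <- c(rep(log(ctl$bl_bounds[1]), 5), rep(log(1e-5), 5))
  upper <- c(rep(log(ctl$bl_bounds[2]), 5), rep(log(1e5), 5))
  if (free_ai) {
    start <- c(start, log(max(min(alpha, ctl$alpha_bounds[2]), ctl$alpha_bounds[1])),
               min(max(p_inv, 0), ctl$pinv_max))
    lower <- c(lower, log(ctl$alpha_bounds[1]), 0)
    upper <- c(upper, log(ctl$alpha_bounds[2]), ctl$pinv_max)
  }

  run1 <- function(par0) {
    tryCatch(
      stats::optim(par0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = ctl$factr, maxit = ctl$maxit)),
      error = function(e) list(par = par0, value = nll(par0), convergence = 99L))
  }
  best <- run1(start)
  tries <- 0L
  while (best$convergence != 0L && tries < ctl$restarts) {
    tries <- tries + 1L
    jit <- start + stats::rnorm(length(start), 0, 0.3)
    jit <- pmin(pmax(jit, lower), upper)
    cand <- run1(jit)
    if (cand$value < best$value) best <- cand
    if (cand$convergence == 0L) break
  }

  u <- unpack(best$par)
  structure(list(tree = u$tree, model = u$model,
                 logL = -best$value,
                 pattern_probs = pattern_probs(u$tree, u$model),
                 converged = best$convergence == 0L,
                 mode = mode),
            class = "fitted_quartet")
}

#' @export
print.fitted_quartet <- function(x, ...) {
  cat("<fitted_quartet>", x$tree$topology,
      sprintf("logL=%.3f%s\n", x$logL, if (x$converged) "" else " (not converged)"))
  print(x$tree)
  invisible(x)
}

#' Expected site-pattern class counts under a fitted quartet
#'
#' Aggregates the fitted 256-tuple probabilities into the 15 structural
#' classes and scales by an alignment length, giving the expected number
#' of columns of each class.
#'
#' @param fit A \code{fitted_quartet}.
#' @param L Alignment length (number of columns to scale to).
#' @return Named numeric vector over \code{\link{site_pattern_classes}},
#'   summing to \code{L}.
#' @export
expected_counts <- function(fit, L) {
  stopifnot(L >= 0)
  agg <- as.vector(rowsum(fit$pattern_probs, .CLASS256F))
  stats::setNames(agg * L, .CLASS_NAMES)
}
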