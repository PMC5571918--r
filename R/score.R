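# The PhyQuart score: polarized apomorphic support corrected for
# plesiomorphy and ML-expected convergence.
#
# For each of the six polarized quartet trees (three topologies x two
# derived split halves) the observed apomorphic support S_obs is reduced
# by the convergence expectation kappa obtained from ML fits of the two
# competing topologies, with singleton-based omega factors damping
# branch-length asymmetry.  Two published forms of the omega weighting
# exist; both are implemented: "concept_complement" multiplies support
# by 1 - omega (the default: it is the form under which the polarized
# score resists long-branch attraction in the package's own simulations,
# see the methods vignette) and "eq8_direct" multiplies by omega.

#' @include patterns.R substmodel.R fit.R
NULL

.CONVENTIONS <- c("concept_complement", "eq8_direct")

#' Observed singleton correction factor
#'
#' omega_obs = 1 - 4*phi/N where phi is the smallest and N the total of
#' the four observed singleton class counts.  Equal singleton counts give
#' 0 (no asymmetry detected); a missing singleton class gives 1.  With no
#' singletons at all the factor is undefined and the correction is
#' disabled (0 is returned).
#'
#' @param tally A \code{pattern_tally}.
#' @return A value in [0, 1].
#' @export
omega_obs <- function(tally) {
  s <- singleton_stats(tally)
  if (s$N == 0) return(0)
  1 - 4 * s$phi / s$N
}

.omega_single <- function(exp_counts) {
  s <- exp_counts[paste0("singleton_", c("A", "B", "C", "D"))]
  tot <- sum(s)
  if (tot <= 0) return(0)
  1 - 4 * min(s) / tot
}

#' Expected singleton correction factor
#'
#' Mean over the two alternative-topology fits of the singleton factor
#' 1 - 4*min/total computed from their expected singleton class counts.
#' A fit with zero expected singletons contributes 0 (its correction is
#' disabled).
#'
#' @param fit1,fit2 \code{fitted_quartet} objects for the two topologies
#'   other than the one being scored.
#' @param L Alignment length at which expected counts are evaluated.
#' @return A value in [0, 1].
#' @export
omega_exp <- function(fit1, fit2, L) {
  (.omega_single(expected_counts(fit1, L)) +
   .omega_single(expected_counts(fit2, L))) / 2
}

#' ML-expected convergent support for a polarized quartet tree
#'
#' The convergence expectation kappa is the mean, over ML fits of the two
#' competing topologies, of the expected count of the scored topology's
#' symmetric class plus its derived-side asymmetric class: the amount of
#' apomorphy-like support that would arise by chance if one of the other
#' trees were true.
#'
#' @param topology Scored topology (\code{"q1","q2","q3"}).
#' @param derived Derived split half of the polarity (e.g. \code{"CD"}).
#' @param fit1,fit2 \code{fitted_quartet} objects on the other two
#'   topologies.
#' @param L Alignment length for scaling expected frequencies.
#' @return Expected convergent site-pattern count (real, >= 0).
#' @export
kappa_expected <- function(topology, derived, fit1, fit2, L) {
  z <- .check_polarity(topology, derived)
  for (f in list(fit1, fit2)) {
    if (f$tree$topology == z$topology)
      stop("kappa uses fits of the two topologies competing with the scored one")
  }
  one <- function(f) {
    ec <- expected_counts(f, L)
    unname(ec[paste0("sym_", z$topology)] +
           ec[paste0("asym_", z$topology, "_", z$derived)])
  }
  (one(fit1) + one(fit2)) / 2
}

#' Synapomorphy score theta for a polarized quartet tree
#'
#' Combines observed apomorphic support, plesiomorphic count and expected
#' convergence with the omega factors.  Under the default
#' \code{"concept_complement"} the support terms are damped by the
#' complement of the singleton asymmetry:
#' theta = S_obs * (1 - omega_obs) - kappa * (1 - omega_exp).
#' Under \code{"eq8_direct"} they are multiplied by omega itself:
#' theta = S_obs * omega_obs - kappa * omega_exp (the plesiomorphic count
#' is already excluded from S_obs, so tau*w - rho*w = S_obs*w).
#' Negative values are retained; only differences between topologies
#' matter downstream.
#'
#' @param S_obs Observed apomorphic support (integer).
#' @param rho Observed plesiomorphic count (integer; S_obs + rho = tau).
#' @param kappa Expected convergent support.
#' @param omega_obs,omega_exp Correction factors in [0, 1].
#' @param convention \code{"concept_complement"} (default) or
#'   \code{"eq8_direct"}.
#' @return The score theta (real, may be negative).
#' @export
theta_score <- function(S_obs, rho, kappa, omega_obs, omega_exp,
                        convention = c("concept_complement", "eq8_direct")) {
  convention <- match.arg(convention)
  if (convention == "eq8_direct") {
    (S_obs + rho) * omega_obs - rho * omega_obs - kappa * omega_exp
  } else {
    S_obs * (1 - omega_obs) - kappa * (1 - omega_exp)
  }
}

#' Best-polarity score delta for one topology
#'
#' @param theta_right,theta_left Scores of the two polarities of one
#'   topology; ties resolve to the first argument (identical value).
#' @return max of the two.
#' @export
delta_score <- function(theta_right, theta_left) {
  if (theta_right >= theta_left) theta_right else theta_left
}

#' Normalized quartet weights lambda
#'
#' lambda_x = (delta_x - delta_min) / sum_j (delta_j - delta_min).  The
#' weights are non-negative, sum to 1, and the minimizing topology gets
#' weight 0.  If all three deltas are (numerically) equal no topology is
#' preferred and the uniform weights (1/3, 1/3, 1/3) are returned.
#'
#' @param delta Numeric vector of three delta scores (q1, q2, q3).
#' @return Named numeric vector of three weights summing to 1.
#' @export
lambda_weights <- function(delta) {
  stopifnot(length(delta) == 3L)
  ex <- delta - min(delta)
  tot <- sum(ex)
  w <- if (tot <= max(1e-12, 1e-12 * abs(max(delta))))
    rep(1 / 3, 3) else ex / tot
  stats::setNames(w, .TOPOLOGIES)
}

.POLARITIES <- do.call(rbind, lapply(.TOPOLOGIES, function(x)
  data.frame(topology = x, derived = .TOPO_PAIRS[[x]], stringsAsFactors = FALSE)))

#' Score a quartet alignment with the PhyQuart algorithm
#'
#' Runs the full pipeline for one quartet: tally site-patterns, fit all
#' three topologies by ML (each fit is reused as the "alternative" for
#' the other two), score the six polarized quartet trees, and normalize
#' to the lambda weights.  The topology with the largest lambda is the
#' PhyQuart estimate.
#'
#' @param qa A \code{quartet_alignment}.
#' @param convention Omega convention, see \code{\link{theta_score}}.
#' @param n_cat Discrete gamma categories for the internal ML fits.
#' @param fit_mode \code{"all_free"} (default: gamma shape and invariant
#'   proportion estimated from the data) or \code{"fixed_alpha_inv"}.
#' @param alpha,p_inv Fixed values (or starting values) passed to
#'   \code{\link{fit_quartet}}.
#' @param control Optimizer control list, see \code{\link{fit_quartet}}.
#' @return An object of class \code{quartet_scores}: list with
#'   \code{roles}, \code{lambda} (named, sums to 1), \code{delta},
#'   \code{theta} (six polarized trees, named e.g. \code{"q1.CD"} for
#'   topology q1 with derived half CD), \code{omega_obs},
#'   \code{omega_exp} (per topology), \code{winner} (topology with
#'   strictly largest lambda, or \code{"tie"}), \code{used_length},
#'   \code{convention}, \code{fits} and \code{fit_ok}.
#' @examples
#' \donttest{
#' cfg <- simulation_config(design = "felsenstein", BL1 = 0.02, BL2 = 0.5,
#'                          L = 5000, seed = 1)
#' qa <- simulate_quartet(cfg)
#' sc <- evaluate_quartet(qa)
#' sc$lambda
#' }
#' @export
evaluate_quartet <- function(qa, convention = c("concept_complement", "eq8_direct"),
                             n_cat = 4L, fit_mode = "all_free",
                             alpha = 1, p_inv = 0.2, control = list()) {
  convention <- match.arg(convention)
  tally <- tally_patterns(qa)
  L <- if (inherits(qa, "quartet_alignment")) qa$used_length else tally$L
  fits <- lapply(.TOPOLOGIES, function(x)
    fit_quartet(tally, x, mode = fit_mode, alpha = alpha, p_inv = p_inv,
                n_cat = n_cat, control = control))
  names(fits) <- .TOPOLOGIES
  w_obs <- omega_obs(tally)

  w_exp <- vapply(.TOPOLOGIES, function(x) {
    alt <- fits[setdiff(.TOPOLOGIES, x)]
    omega_exp(alt[[1]], alt[[2]], L)
  }, numeric(1))

  theta <- numeric(6)
  names(theta) <- paste(.POLARITIES$topology, .POLARITIES$derived, sep = ".")
  for (i in seq_len(6L)) {
    x <- .POLARITIES$topology[i]
    dv <- .POLARITIES$derived[i]
    oc <- observed_polar_counts(tally, x, dv)
    alt <- fits[setdiff(.TOPOLOGIES, x)]
    k <- kappa_expected(x, dv, alt[[1]], alt[[2]], L)
    theta[i] <- theta_score(oc$S_obs, oc$rho, k, w_obs, w_exp[[x]], convention)
  }
  delta <- vapply(.TOPOLOGIES, function(x) {
    th <- theta[paste(x, .TOPO_PAIRS[[x]], sep = ".")]
    delta_score(th[1], th[2])
  }, numeric(1))
  lambda <- lambda_weights(delta)
  winner <- .strict_argmax(lambda)
  structure(list(roles = if (inherits(qa, "quartet_alignment")) qa$roles else NULL,
                 lambda = lambda, delta = delta, theta = theta,
                 omega_obs = w_obs, omega_exp = w_exp,
                 winner = winner, used_length = L,
                 convention = convention,
                 fits = fits,
                 fit_ok = all(vapply(fits, `[[`, logical(1), "converged"))),
            class = "quartet_scores")
}

# strictly maximal element name, or "tie"
.strict_argmax <- function(x, tol = 1e-9) {
  i <- which.max(x)
  if (sum(x >= x[i] - tol) > 1L) "tie" else names(x)[i]
}

#' @export
print.quartet_scores <- function(x, ...) {
  cat("<quartet_scores>", if (!is.null(x$roles))
    paste(sprintf("%s=%s", names(x$roles), x$roles), collapse = " "), "\n")
  cat(sprintf("  convention=%s  used_length=%d  winner=%s\n",
              x$convention, as.integer(x$used_length), x$winner))
  cat("  lambda:", paste(sprintf("%s=%.4f", names(x$lambda), x$lambda), collapse = "  "), "\n")
  invisible(x)
}
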