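# Simulation-grid runner: generate replicate alignments over a design
# grid, score each with the polarized quartet algorithm and the ML
# baseline, and tabulate reconstruction success.

#' Specify a simulation grid
#'
#' @param designs Character vector of designs (see
#'   \code{\link{simulation_config}}).
#' @param BL1,BL2,BL3 Numeric vectors of internal / elongated /
#'   secondary branch lengths.
#' @param alpha Numeric vector of gamma shape parameters.
#' @param p_inv Invariant-site proportion (single value, default 0.3).
#' @param L Numeric vector of sequence lengths.
#' @param replicates Replicates per configuration (>= 1).
#' @param master_seed Master RNG seed; per-replicate seeds are derived
#'   deterministically from it.
#' @param short Fixed short terminal length (default 0.1).
#' @param model_fun Function \code{(alpha, p_inv) -> subst_model} used to
#'   build each generating model; default the study GTR with continuous
#'   gamma.
#' @param convention Omega convention for the polarized score.
#' @param n_cat Discrete gamma categories used by both inference methods.
#' @return An object of class \code{grid_spec}.
#' @export
grid_spec <- function(designs = "felsenstein", BL1 = 0.01, BL2 = 1.5, BL3 = 0.1,
                      alpha = 1, p_inv = 0.3, L = 250000, replicates = 20L,
                      master_seed = 1L, short = 0.1,
                      model_fun = function(alpha, p_inv) study_gtr_model(alpha, p_inv, n_cat = 0L),
                      convention = "concept_complement", n_cat = 4L) {
  stopifnot(replicates >= 1L, length(designs) > 0L, length(BL1) > 0L,
            length(BL2) > 0L, length(BL3) > 0L, length(alpha) > 0L, length(L) > 0L)
  structure(list(designs = designs, BL1 = BL1, BL2 = BL2, BL3 = BL3,
                 alpha = alpha, p_inv = p_inv, L = L,
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed), short = short,
                 model_fun = model_fun, convention = convention,
                 n_cat = as.integer(n_cat)),
            class = "grid_spec")
}

# deterministic per-replicate seed derived from the master seed; kept
# below 2^31 - 1
.child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 69621) %% 2147483587 + 1)
}

#' Run a simulation grid
#'
#' For every configuration in the grid, simulates the requested
#' replicates and scores both methods against the generating topology.
#' "Correct" requires the true topology to carry a strictly maximal
#' lambda (polarized score) or log-likelihood (ML); ties count as
#' failures.  The run is deterministic given \code{master_seed}.
#'
#' @param spec A \code{grid_spec}.
#' @param methods Subset of \code{c("phyquart", "ml")} to run.
#' @param out_tsv Optional path; if given, results are also streamed to
#'   a tab-separated file.
#' @param verbose Print per-configuration progress.
#' @return A data frame with one row per configuration: the grid
#'   columns, \code{replicates}, \code{phyquart_correct},
#'   \code{ml_correct} and \code{failed} (replicates whose fits did not
#'   all converge are still scored from the best-found optima; only
#'   hard errors are excluded and counted here).  Per-replicate winners
#'   and seeds are in attribute \code{"details"}.
#' @export
run_grid <- function(spec, methods = c("phyquart", "ml"), out_tsv = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  methods <- match.arg(methods, c("phyquart", "ml"), several.ok = TRUE)
  grid <- expand.grid(design = spec$designs, BL1 = spec$BL1, BL2 = spec$BL2,
                      BL3 = spec$BL3, alpha = spec$alpha, L = spec$L,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  details <- vector("list", nrow(grid))
  con <- NULL
  if (!is.null(out_tsv)) {
    con <- file(out_tsv, "w")
    on.exit(close(con))
    writeLines(paste(c(names(grid), "replicates", "phyquart_correct",
                       "ml_correct", "failed"), collapse = "\t"), con)
  }
  rep_counter <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pq_ok <- 0L; ml_ok <- 0L; failed <- 0L
    det <- vector("list", spec$replicates)
    for (r in seq_len(spec$replicates)) {
      rep_counter <- rep_counter + 1L
      seed <- .child_seed(spec$master_seed, rep_counter)
      res <- tryCatch({
        cfg <- simulation_config(design = g$design, BL1 = g$BL1, BL2 = g$BL2,
                                 BL3 = g$BL3, short = spec$short, L = g$L,
                                 model = spec$model_fun(g$alpha, spec$p_inv),
                                 seed = seed, true_topology = "q1")
        qa <- simulate_quartet(cfg)
        pq_win <- ml_win <- NA_character_
        if ("phyquart" %in% methods) {
          sc <- evaluate_quartet(qa, convention = spec$convention, n_cat = spec$n_cat)
          pq_win <- sc$winner
        }
        if ("ml" %in% methods) {
          mlr <- ml_quartet(tally_patterns(qa), mode = "fixed_alpha_inv",
                            alpha = g$alpha, p_inv = spec$p_inv, n_cat = spec$n_cat)
          ml_win <- mlr$winner
        }
        list(seed = seed, phyquart = pq_win, ml = ml_win)
      }, error = function(e) {
        warning("replicate failed (config ", i, ", rep ", r, "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(res)) { failed <- failed + 1L; next }
      if (identical(res$phyquart, cfg_true <- "q1")) pq_ok <- pq_ok + 1L
      if (identical(res$ml, "q1")) ml_ok <- ml_ok + 1L
      det[[r]] <- res
    }
    rows[[i]] <- cbind(g, replicates = spec$replicates - failed,
                       phyquart_correct = if ("phyquart" %in% methods) pq_ok else NA_integer_,
                       ml_correct = if ("ml" %in% methods) ml_ok else NA_integer_,
                       failed = failed)
    details[[i]] <- det
    if (!is.null(con))
      writeLines(paste(unlist(rows[[i]]), collapse = "\t"), con)
    if (verbose) {
      shown <- c(if ("phyquart" %in% methods) sprintf("phyquart %d", pq_ok),
                 if ("ml" %in% methods) sprintf("ml %d", ml_ok))
      message(sprintf("[%d/%d] %s BL1=%g BL2=%g alpha=%g: %s / %d",
                      i, nrow(grid), g$design, g$BL1, g$BL2, g$alpha,
                      paste(shown, collapse = ", "), spec$replicates - failed))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Summarize reconstruction success over a grid
#'
#' Success fractions per design, internal and elongated branch length
#' and method, pooled over gamma shapes (the presentation used for the
#' study's success curves).
#'
#' @param records Data frame returned by \code{\link{run_grid}}.
#' @param pool_alpha Pool replicates over gamma shapes (default TRUE).
#' @return A data frame with columns \code{design}, \code{BL1},
#'   \code{BL2}, (\code{alpha} unless pooled), \code{method},
#'   \code{correct}, \code{replicates} and \code{success}.
#' @export
summarize_success <- function(records, pool_alpha = TRUE) {
  if (is.null(records) || nrow(records) == 0L)
    return(data.frame(design = character(0), BL1 = numeric(0), BL2 = numeric(0),
                      method = character(0), correct = integer(0),
                      replicates = integer(0), success = numeric(0)))
  keys <- c("design", "BL1", "BL2", if (!pool_alpha) "alpha")
  long <- do.call(rbind, lapply(c("phyquart", "ml"), function(mth) {
    col <- paste0(mth, "_correct")
    if (all(is.na(records[[col]]))) return(NULL)
    cbind(records[keys], method = mth,
          correct = records[[col]], replicates = records$replicates)
  }))
  agg <- stats::aggregate(cbind(correct, replicates) ~ .,
                          data = long, FUN = sum)
  agg$success <- agg$correct / agg$replicates
  agg[do.call(order, unname(agg[c(keys, "method")])), , drop = FALSE]
}
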