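# In-code fixtures: tiny alignments and tallies built programmatically.

# quartet alignment from explicit columns (character vectors of length 4)
qa_from_columns <- function(...) {
  cols <- list(...)
  states <- vapply(cols, function(cl) match(toupper(cl), c("A", "C", "G", "T")),
                   integer(4))
  structure(list(roles = c(A = "A", B = "B", C = "C", D = "D"),
                 states = states,
                 original_length = length(cols), used_length = length(cols),
                 excluded = integer(0)),
            class = "quartet_alignment")
}

# repeat columns: qa_rep(list(c("A","A","C","C"), 10), list(...), ...)
qa_rep <- function(...) {
  specs <- list(...)
  cols <- unlist(lapply(specs, function(sp) rep(list(sp[[1]]), sp[[2]])),
                 recursive = FALSE)
  do.call(qa_from_columns, cols)
}

# tally with prescribed singleton counts (plus some constant filler)
tally_with_singletons <- function(nA, nB, nC, nD, extra_cols = list()) {
  cols <- c(rep(list(c("C", "A", "A", "A")), nA),
            rep(list(c("A", "C", "A", "A")), nB),
            rep(list(c("A", "A", "C", "A")), nC),
            rep(list(c("A", "A", "A", "C")), nD),
            rep(list(c("G", "G", "G", "G")), 2),
            extra_cols)
  tally_patterns(do.call(qa_from_columns, cols))
}

# synthetic fitted_quartet whose expected class counts are prescribed:
# mass is placed on one representative tuple per requested class
fake_fit <- function(topology, class_probs) {
  reps <- c(constant = "AAAA",
            singleton_A = "CAAA", singleton_B = "ACAA",
            singleton_C = "AACA", singleton_D = "AAAC",
            sym_q1 = "AACC", sym_q2 = "ACAC", sym_q3 = "ACCA",
            asym_q1_AB = "AACG", asym_q1_CD = "CGAA",
            asym_q2_AC = "ACAG", asym_q2_BD = "CAGA",
            asym_q3_AD = "ACGA", asym_q3_BC = "CAAG",
            all_distinct = "ACGT")
  p <- numeric(256)
  for (cls in names(class_probs)) {
    st <- match(strsplit(reps[[cls]], "")[[1]], c("A", "C", "G", "T"))
    idx <- st[1] + 4 * (st[2] - 1) + 16 * (st[3] - 1) + 64 * (st[4] - 1)
    p[idx] <- p[idx] + class_probs[[cls]]
  }
  leftover <- 1 - sum(p)
  stopifnot(leftover > -1e-12)
  p[1] <- p[1] + max(leftover, 0)   # park remainder on a constant tuple
  structure(list(tree = structure(list(topology = topology,
                                       bl = rep(0, 5)), class = "quartet_tree"),
                 pattern_probs = p, logL = NA_real_, converged = TRUE),
            class = "fitted_quartet")
}

# random 4xL state matrix
random_states <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample.int(4L, 4L * L, replace = TRUE), nrow = 4L)
}
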