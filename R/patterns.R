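# Site-pattern classification for quartets.
#
# Every alignment column over four taxa (roles A,B,C,D) induces a set
# partition of the roles by shared state.  The 256 ordered nucleotide
# 4-tuples fall into 15 structural classes: 1 constant, 4 singleton (one
# deviating role), 3 symmetric (XXYY-type, both split pairs share), 6
# asymmetric (XXYZ-type, exactly one pair shares) and 1 all-distinct.
# Symmetric and asymmetric classes are labelled by the quartet topology
# they support: q1 = AB|CD, q2 = AC|BD, q3 = AD|BC.

.BASES <- c("A", "C", "G", "T")
.TOPOLOGIES <- c("q1", "q2", "q3")

# split halves (pairs of roles) per topology
.TOPO_PAIRS <- list(
  q1 = c("AB", "CD"),
  q2 = c("AC", "BD"),
  q3 = c("AD", "BC")
)

.PAIR_TOPO <- c(AB = "q1", CD = "q1", AC = "q2", BD = "q2", AD = "q3", BC = "q3")

.CLASS_NAMES <- c(
  "constant",
  paste0("singleton_", c("A", "B", "C", "D")),
  paste0("sym_", .TOPOLOGIES),
  "asym_q1_AB", "asym_q1_CD", "asym_q2_AC", "asym_q2_BD",
  "asym_q3_AD", "asym_q3_BC",
  "all_distinct"
)

# canonical tuple index: states s (1..4 for A,C,G,T) at roles (A,B,C,D)
.tuple_index <- function(a, b, c, d) a + 4L * (b - 1L) + 16L * (c - 1L) + 64L * (d - 1L)

.decode_tuple <- function(idx) {
  idx <- idx - 1L
  c(idx %% 4L, (idx %/% 4L) %% 4L, (idx %/% 16L) %% 4L, (idx %/% 64L) %% 4L) + 1L
}

.classify_states <- function(s) {
  roles <- c("A", "B", "C", "D")
  u <- unique(s)
  if (length(u) == 1L) return("constant")
  if (length(u) == 4L) return("all_distinct")
  tab <- tabulate(s, 4L)
  if (length(u) == 2L) {
    if (any(tab == 3L)) {
      deviant <- roles[s == u[tab[u] == 1L]]
      return(paste0("singleton_", deviant))
    }
    # 2+2: the pair containing role A fixes the supported topology
    pair <- paste(roles[s == s[1L]], collapse = "")
    return(paste0("sym_", .PAIR_TOPO[[pair]]))
  }
  # three states: exactly one shared pair
  shared <- u[tab[u] == 2L]
  pair <- paste(roles[s == shared], collapse = "")
  paste0("asym_", .PAIR_TOPO[[pair]], "_", pair)
}

# lookup: class label for each of the 256 canonical tuple indices
.CLASS256 <- vapply(seq_len(256L), function(i) .classify_states(.decode_tuple(i)), character(1))
.CLASS256F <- factor(.CLASS256, levels = .CLASS_NAMES)

# per-tuple base composition (256 x 4), used for empirical frequencies
.TUPLE_BASE_COUNT <- t(vapply(seq_len(256L),
                              function(i) tabulate(.decode_tuple(i), 4L),
                              integer(4)))

#' The 15 structural site-pattern classes
#'
#' @return Character vector of the canonical class labels, in the fixed
#'   order used throughout the package (constant, four singleton classes,
#'   three symmetric, six asymmetric, all-distinct).
#' @export
site_pattern_classes <- function() .CLASS_NAMES

#' Classify a single quartet site-pattern
#'
#' Maps the ordered character states of one alignment column (roles
#' A,B,C,D) to its structural class.  Symmetric (XXYY) and asymmetric
#' (XXYZ) classes carry the quartet topology they support and, for
#' asymmetric patterns, the pair of roles sharing a state.
#'
#' @param states Character vector of length 4 over \code{A,C,G,T} (one state
#'   per role), or an integer vector of length 4 with values in 1..4.
#' @return An object of class \code{pattern_class}: a list with elements
#'   \code{kind} (constant/singleton/symmetric/asymmetric/all_distinct),
#'   \code{label} (canonical class label), and where applicable
#'   \code{topology}, \code{pair} (sharing pair for asymmetric patterns) and
#'   \code{deviant} (deviating role for singletons).
#' @examples
#' classify_site(c("A", "A", "C", "C"))  # symmetric, supports q1 = AB|CD
#' classify_site(c("A", "A", "C", "G"))  # asymmetric q1, sharing pair AB
#' @export
classify_site <- function(states) {
  if (is.character(states)) {
    s <- match(toupper(states), .BASES)
  } else {
    s <- as.integer(states)
    s[s < 1L | s > 4L] <- NA_integer_
  }
  if (length(s) != 4L || anyNA(s))
    stop("`states` must be four symbols from {A,C,G,T}; site exclusion is handled upstream")
  label <- .CLASS256[.tuple_index(s[1], s[2], s[3], s[4])]
  out <- list(label = label)
  if (label == "constant") {
    out$kind <- "constant"
  } else if (label == "all_distinct") {
    out$kind <- "all_distinct"
  } else if (startsWith(label, "singleton_")) {
    out$kind <- "singleton"
    out$deviant <- sub("singleton_", "", label)
  } else if (startsWith(label, "sym_")) {
    out$kind <- "symmetric"
    out$topology <- sub("sym_", "", label)
  } else {
    out$kind <- "asymmetric"
    parts <- strsplit(label, "_", fixed = TRUE)[[1]]
    out$topology <- parts[2]
    out$pair <- parts[3]
  }
  structure(out, class = "pattern_class")
}

#' @export
print.pattern_class <- function(x, ...) {
  cat("<pattern_class>", x$label, "\n")
  invisible(x)
}

#' Tally site-pattern classes of a quartet alignment
#'
#' Counts every column of a quartet alignment into the 15 structural
#' classes and retains the full 256-tuple spectrum, from which the
#' split-support totals (tau), singleton statistics (phi, N) and polarized
#' apomorphy/plesiomorphy counts are derived.
#'
#' @param qa A \code{quartet_alignment} (see \code{\link{extract_quartet}}
#'   or \code{\link{simulate_quartet}}), or a 4 x L integer matrix of
#'   states in 1..4.
#' @return An object of class \code{pattern_tally}: list with
#'   \code{class_counts} (named numeric, the 15 classes),
#'   \code{counts256} (integer spectrum over canonical tuple indices) and
#'   \code{L} (number of columns tallied).
#' @export
tally_patterns <- function(qa) {
  s <- if (inherits(qa, "quartet_alignment")) qa$states else qa
  if (!is.matrix(s) || nrow(s) != 4L || ncol(s) < 1L)
    stop("need a 4 x L matrix with at least one column")
  idx <- s[1, ] + 4L * (s[2, ] - 1L) + 16L * (s[3, ] - 1L) + 64L * (s[4, ] - 1L)
  counts256 <- tabulate(idx, 256L)
  cc <- as.vector(rowsum(counts256, .CLASS256F))
  names(cc) <- .CLASS_NAMES
  structure(list(class_counts = cc, counts256 = counts256, L = ncol(s)),
            class = "pattern_tally")
}

#' @export
print.pattern_tally <- function(x, ...) {
  cat("<pattern_tally>", x$L, "columns\n")
  print(x$class_counts)
  invisible(x)
}

#' Split-support total tau for one topology
#'
#' Number of columns whose pattern supports the given topology, i.e. the
#' symmetric class plus both asymmetric classes of that topology.
#'
#' @param tally A \code{pattern_tally}.
#' @param topology One of \code{"q1","q2","q3"}.
#' @return Integer count.
#' @export
tau_support <- function(tally, topology) {
  topology <- match.arg(topology, .TOPOLOGIES)
  cc <- tally$class_counts
  unname(cc[paste0("sym_", topology)] +
         cc[paste0("asym_", topology, "_", .TOPO_PAIRS[[topology]][1])] +
         cc[paste0("asym_", topology, "_", .TOPO_PAIRS[[topology]][2])])
}

#' Singleton counts and the omega-correction ingredients
#'
#' @param tally A \code{pattern_tally}.
#' @return Named list with \code{counts} (the four singleton classes),
#'   \code{phi} (their minimum) and \code{N} (their sum).
#' @export
singleton_stats <- function(tally) {
  s <- tally$class_counts[paste0("singleton_", c("A", "B", "C", "D"))]
  list(counts = s, phi = unname(min(s)), N = unname(sum(s)))
}

.check_polarity <- function(topology, derived) {
  topology <- match.arg(topology, .TOPOLOGIES)
  pairs <- .TOPO_PAIRS[[topology]]
  derived <- match.arg(derived, pairs)
  list(topology = topology, derived = derived,
       ancestral = setdiff(pairs, derived))
}

#' Apomorphic and plesiomorphic support for a polarized quartet tree
#'
#' A polarized tree is a topology plus a choice of derived split half.
#' Sharing on the derived side is a putative synapomorphy: the symmetric
#' class and the derived-side asymmetric class count as apomorphic support
#' (S_obs), while the ancestral-side asymmetric class is plesiomorphic
#' (rho).  By construction S_obs + rho equals the topology's tau.
#'
#' @param tally A \code{pattern_tally}.
#' @param topology One of \code{"q1","q2","q3"}.
#' @param derived The derived split half, e.g. \code{"CD"} for topology
#'   \code{"q1"} (valid halves: q1 AB/CD, q2 AC/BD, q3 AD/BC).
#' @return List with integer elements \code{S_obs} and \code{rho}.
#' @export
observed_polar_counts <- function(tally, topology, derived) {
  z <- .check_polarity(topology, derived)
  cc <- tally$class_counts
  S_obs <- cc[paste0("sym_", z$topology)] + cc[paste0("asym_", z$topology, "_", z$derived)]
  rho <- cc[paste0("asym_", z$topology, "_", z$ancestral)]
  list(S_obs = unname(S_obs), rho = unname(rho))
}
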