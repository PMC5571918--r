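# Alignment and clan plumbing: reading FASTA/PHYLIP, enumerating
# quartets from clan assignments, per-quartet site exclusion and the
# plain-text report writer.

#' @include patterns.R
NULL

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length sequences (upper
#'   case is enforced).  Names are the taxon labels and must be unique.
#' @return An object of class \code{phy_alignment}: list with
#'   \code{taxa}, \code{seqs} and \code{length}.
#' @export
alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon label(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths (ragged alignment)")
  if (lens[1] < 1L) stop("alignment has zero columns")
  structure(list(taxa = names(seqs), seqs = seqs, length = unname(lens[1])),
            class = "phy_alignment")
}

#' @export
print.phy_alignment <- function(x, ...) {
  cat("<phy_alignment>", length(x$taxa), "taxa x", x$length, "columns\n")
  invisible(x)
}

.sniff_format <- function(path) {
  for (ln in readLines(path, n = 25L, warn = FALSE)) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    return(if (startsWith(ln, ">")) "fasta" else "phylip")
  }
  stop("empty file: ", path)
}

.read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(ch) paste(ch, collapse = ""), character(1))
  names(seqs) <- names(dna)
  alignment(seqs)
}

# Relaxed PHYLIP: "ntax nchar" header, labels up to whitespace,
# sequential or interleaved detected by what parses consistently.
.read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("not a PHYLIP file: missing 'ntax nchar' header")
  ntax <- as.integer(hdr[1]); nchar_ <- as.integer(hdr[2])
  body <- lines[-1]
  strip <- function(x) gsub("\\s+", "", x)

  parse_sequential <- function() {
    seqs <- character(0)
    i <- 1L
    for (k in seq_len(ntax)) {
      if (i > length(body)) return(NULL)
      toks <- strsplit(trimws(body[i]), "\\s+")[[1]]
      name <- toks[1]
      chunk <- strip(paste(toks[-1], collapse = ""))
      i <- i + 1L
      while (nchar(chunk) < nchar_) {
        if (i > length(body)) return(NULL)
        chunk <- paste0(chunk, strip(body[i]))
        i <- i + 1L
      }
      if (nchar(chunk) != nchar_) return(NULL)
      seqs[name] <- chunk
    }
    if (i <= length(body)) return(NULL)
    seqs
  }
  parse_interleaved <- function() {
    if (length(body) %% ntax != 0L) return(NULL)
    first <- body[seq_len(ntax)]
    toks <- strsplit(trimws(first), "\\s+")
    names_ <- vapply(toks, `[[`, character(1), 1L)
    seqs <- vapply(toks, function(tk) strip(paste(tk[-1], collapse = "")), character(1))
    rest <- body[-seq_len(ntax)]
    while (length(rest) > 0L) {
      block <- rest[seq_len(ntax)]
      rest <- rest[-seq_len(ntax)]
      seqs <- paste0(seqs, strip(block))
    }
    if (any(nchar(seqs) != nchar_)) return(NULL)
    stats::setNames(seqs, names_)
  }
  seqs <- parse_sequential()
  if (is.null(seqs)) seqs <- parse_interleaved()
  if (is.null(seqs)) stop("could not parse PHYLIP file (tried sequential and interleaved): ", path)
  if (length(seqs) != ntax) stop("PHYLIP header announces ", ntax, " taxa, found ", length(seqs))
  alignment(seqs)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or PHYLIP (relaxed dialect: labels up to whitespace,
#' sequential or interleaved detected automatically).  Sequences are
#' upper-cased; duplicate taxon labels and ragged lengths are input
#' errors.
#'
#' @param path Path to the alignment file.
#' @param format \code{"auto"} (sniffed from the first non-blank line),
#'   \code{"fasta"} or \code{"phylip"}.
#' @return A \code{phy_alignment}.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .sniff_format(path)
  if (format == "fasta") .read_fasta(path) else .read_phylip(path)
}

#' Write an alignment to FASTA
#'
#' @param aln A \code{phy_alignment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$taxa))
    writeLines(c(paste0(">", aln$taxa[i]), aln$seqs[i]), con)
  invisible(path)
}

#' Read a clan assignment file
#'
#' Plain-text format: four lines of the form
#' \code{clanName: taxon1,taxon2,...}.  Clans must be non-empty and
#' disjoint.
#'
#' @param path Path to the clan file.
#' @return An object of class \code{clan_assignment}: named list of four
#'   character vectors.
#' @export
read_clans <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(lines, function(ln) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed clan line (expected 'name: tax1,tax2,...'): ", ln)
    taxa <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    taxa <- taxa[nzchar(taxa)]
    list(name = trimws(parts[1]), taxa = taxa)
  })
  clans <- stats::setNames(lapply(parsed, `[[`, "taxa"),
                           vapply(parsed, `[[`, character(1), "name"))
  clan_assignment(clans)
}

#' Construct a clan assignment
#'
#' @param clans Named list of exactly four non-empty, disjoint character
#'   vectors of taxon labels.
#' @return An object of class \code{clan_assignment}.
#' @export
clan_assignment <- function(clans) {
  if (length(clans) != 4L) stop("exactly four clans are required, got ", length(clans))
  if (any(lengths(clans) == 0L)) stop("clans must be non-empty")
  all_taxa <- unlist(clans, use.names = FALSE)
  if (anyDuplicated(all_taxa))
    stop("taxon in more than one clan: ",
         paste(unique(all_taxa[duplicated(all_taxa)]), collapse = ", "))
  structure(clans, class = "clan_assignment")
}

#' Enumerate quartets from an alignment and optional clan assignment
#'
#' With a clan assignment, all combinations of one taxon per clan are
#' produced (clan 1 supplies role A, clan 2 role B, and so on), in
#' deterministic lexicographic order with role A varying slowest.  Clan
#' members absent from the alignment are skipped (recorded in the
#' \code{"skipped"} attribute), not fatal.  Without clans the alignment
#' must contain exactly four taxa, yielding one quartet in input order.
#'
#' @param aln A \code{phy_alignment}.
#' @param clans A \code{clan_assignment}, or \code{NULL}.
#' @return List of named character vectors (roles A,B,C,D to taxon
#'   labels), with attribute \code{skipped} listing unmatched labels.
#' @export
enumerate_quartets <- function(aln, clans = NULL) {
  if (is.null(clans)) {
    if (length(aln$taxa) != 4L)
      stop("alignment has ", length(aln$taxa), " taxa; a clan file is required unless there are exactly 4")
    q <- stats::setNames(aln$taxa, c("A", "B", "C", "D"))
    out <- list(q)
    attr(out, "skipped") <- character(0)
    return(out)
  }
  stopifnot(inherits(clans, "clan_assignment"))
  present <- lapply(clans, function(cl) cl[cl %in% aln$taxa])
  skipped <- setdiff(unlist(clans, use.names = FALSE), aln$taxa)
  if (any(lengths(present) == 0L))
    stop("clan(s) with no taxon present in the alignment: ",
         paste(names(clans)[lengths(present) == 0L], collapse = ", "))
  out <- list()
  for (a in present[[1]]) for (b in present[[2]])
    for (cc in present[[3]]) for (d in present[[4]])
      out[[length(out) + 1L]] <- c(A = a, B = b, C = cc, D = d)
  attr(out, "skipped") <- skipped
  out
}

# symbol -> state mapping used everywhere: A,C,G,T -> 1..4 (U counts as
# T); anything else is excluded
.encode_states <- function(string) {
  ch <- strsplit(chartr("U", "T", toupper(string)), "", fixed = TRUE)[[1]]
  match(ch, .BASES)
}

#' Extract a quartet alignment with site exclusion
#'
#' Pulls the four role sequences out of a larger alignment and drops
#' forbidden columns.  Any symbol outside \code{A,C,G,T} (after
#' upper-casing; U maps to T) -- gaps, ambiguity codes, missing data --
#' triggers exclusion.  \code{"per_quartet"} (the default) drops a column
#' only if one of the four chosen sequences is affected;
#' \code{"global"} drops a column if any sequence of the whole alignment
#' is affected there.
#'
#' @param aln A \code{phy_alignment}.
#' @param roles Named character vector mapping roles A,B,C,D to taxon
#'   labels.
#' @param exclusion \code{"per_quartet"} or \code{"global"}.
#' @return An object of class \code{quartet_alignment}: list with
#'   \code{roles}, \code{states} (4 x used_length integer matrix, 1..4 =
#'   A,C,G,T), \code{original_length}, \code{used_length} and
#'   \code{excluded} (1-based indices of dropped columns).
#' @export
extract_quartet <- function(aln, roles, exclusion = c("per_quartet", "global")) {
  exclusion <- match.arg(exclusion)
  roles <- roles[c("A", "B", "C", "D")]
  if (anyNA(roles)) stop("`roles` must name taxa for all of A, B, C, D")
  missing_ <- setdiff(roles, aln$taxa)
  if (length(missing_)) stop("taxa not in alignment: ", paste(missing_, collapse = ", "))
  s <- do.call(rbind, lapply(unname(roles), function(tx) .encode_states(aln$seqs[[tx]])))
  bad <- if (exclusion == "per_quartet") {
    colSums(is.na(s)) > 0L
  } else {
    all_na <- Reduce(`|`, lapply(aln$seqs, function(sq) is.na(.encode_states(sq))))
    all_na
  }
  keep <- which(!bad)
  if (length(keep) == 0L)
    stop("degenerate input: no columns remain after site exclusion")
  structure(list(roles = roles,
                 states = s[, keep, drop = FALSE],
                 original_length = aln$length,
                 used_length = length(keep),
                 excluded = which(bad)),
            class = "quartet_alignment")
}

#' @export
print.quartet_alignment <- function(x, ...) {
  cat("<quartet_alignment>", paste(sprintf("%s=%s", names(x$roles), x$roles), collapse = " "),
      sprintf("| %d of %d columns used\n", x$used_length, x$original_length))
  invisible(x)
}

#' Convert a quartet alignment to a four-taxon alignment object
#'
#' @param qa A \code{quartet_alignment}.
#' @return A \code{phy_alignment} with the role taxa and used columns.
#' @export
quartet_to_alignment <- function(qa) {
  seqs <- apply(qa$states, 1, function(row) paste(.BASES[row], collapse = ""))
  alignment(stats::setNames(seqs, unname(qa$roles)))
}

.REPORT_HEADER <- c("taxon_A", "taxon_B", "taxon_C", "taxon_D",
                    "lambda_q1", "lambda_q2", "lambda_q3",
                    "theta_q1.AB", "theta_q1.CD", "theta_q2.AC", "theta_q2.BD",
                    "theta_q3.AD", "theta_q3.BC",
                    "omega_obs", "used_length")

#' Write a per-quartet split-support report
#'
#' One tab-separated record per quartet: role taxa, the three lambda
#' weights, the six polarized theta scores, omega_obs and the number of
#' used columns.  Reals are printed with six decimals.
#'
#' @param scores A \code{quartet_scores} object or a list of them, in
#'   enumeration order.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(scores, path) {
  if (inherits(scores, "quartet_scores")) scores <- list(scores)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.REPORT_HEADER, collapse = "\t"), con)
  for (sc in scores) {
    roles <- if (is.null(sc$roles)) c(A = "A", B = "B", C = "C", D = "D") else sc$roles
    th <- sc$theta[c("q1.AB", "q1.CD", "q2.AC", "q2.BD", "q3.AD", "q3.BC")]
    fields <- c(unname(roles[c("A", "B", "C", "D")]),
                sprintf("%.6f", sc$lambda[c("q1", "q2", "q3")]),
                sprintf("%.6f", th),
                sprintf("%.6f", sc$omega_obs),
                as.integer(sc$used_length))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}
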