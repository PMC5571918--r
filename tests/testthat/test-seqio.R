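write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("FASTA parsing, case folding and duplicate detection", {
  p <- write_tmp(c(">taxA", "acgtACGT", ">taxB", "ACGTACGT",
                   ">taxC", "AC-TRNG?", ">taxD", "ACGTACGT"), ".fasta")
  aln <- read_alignment(p)
  expect_s3_class(aln, "phy_alignment")
  expect_equal(aln$length, 8)
  expect_equal(aln$taxa, c("taxA", "taxB", "taxC", "taxD"))
  expect_equal(unname(aln$seqs[["taxA"]]), "ACGTACGT")

  dup <- write_tmp(c(">taxA", "ACGT", ">taxA", "ACGT"), ".fasta")
  expect_error(read_alignment(dup), "duplicate")

  ragged <- write_tmp(c(">a", "ACGT", ">b", "ACG"), ".fasta")
  expect_error(read_alignment(ragged), "unequal|ragged")
})

test_that("relaxed PHYLIP is parsed sequentially and interleaved, with auto-detected format", {
  seq_file <- write_tmp(c("4 12",
                          "alpha  ACGTACGTACGT",
                          "beta   ACGTACGTACGA",
                          "gammataxon ACGT ACGT ACGC",
                          "delta  ACGTACGTACGG"), ".phy")
  aln <- read_alignment(seq_file)   # auto: no '>' so PHYLIP
  expect_equal(aln$length, 12)
  expect_equal(aln$taxa, c("alpha", "beta", "gammataxon", "delta"))
  expect_equal(unname(aln$seqs[["gammataxon"]]), "ACGTACGTACGC")

  inter <- write_tmp(c("4 12",
                       "alpha ACGTAC",
                       "beta  ACGTAC",
                       "gamma ACGTAC",
                       "delta ACGTAC",
                       "GTACGT",
                       "GTACGA",
                       "GTACGC",
                       "GTACGG"), ".phy")
  aln2 <- read_alignment(inter, format = "phylip")
  expect_equal(aln2$length, 12)
  expect_equal(unname(aln2$seqs[["delta"]]), "ACGTACGTACGG")

  multi <- write_tmp(c("2 8",
                       "one ACGT",
                       "ACGT",
                       "two ACGT",
                       "ACGA"), ".phy")
  aln3 <- read_alignment(multi, format = "phylip")
  expect_equal(unname(aln3$seqs[["two"]]), "ACGTACGA")

  expect_error(read_alignment(write_tmp(c("notaheader", "x")), format = "phylip"),
               "header")
})

test_that("FASTA round trip preserves taxa and sequences including non-ACGT symbols", {
  aln <- alignment(c(tax1 = "ACGT-RN?", tax2 = "ACGTACGT", tax3 = "NNNNACGT",
                     tax4 = "ACGTACGT"))
  p <- tempfile(fileext = ".fasta")
  write_fasta(aln, p)
  back <- read_alignment(p, format = "fasta")
  expect_equal(back$taxa, aln$taxa)
  expect_equal(back$seqs, aln$seqs)
})

test_that("quartet enumeration follows clans with skipped labels recorded", {
  aln <- alignment(stats::setNames(rep("ACGT", 7), paste0("t", 1:7)))
  clans <- clan_assignment(list(c1 = c("t1", "t2"), c2 = "t3",
                                c3 = "t4", c4 = c("t5", "t6", "t7")))
  q <- enumerate_quartets(aln, clans)
  expect_length(q, 2 * 1 * 1 * 3)
  expect_equal(q[[1]], c(A = "t1", B = "t3", C = "t4", D = "t5"))
  expect_equal(q[[6]], c(A = "t2", B = "t3", C = "t4", D = "t7"))

  # a clan member missing from the alignment is skipped, not fatal
  clans2 <- clan_assignment(list(c1 = c("t1", "missing"), c2 = "t3",
                                 c3 = "t4", c4 = "t5"))
  q2 <- enumerate_quartets(aln, clans2)
  expect_length(q2, 1)
  expect_equal(attr(q2, "skipped"), "missing")

  four <- alignment(c(w = "AC", x = "AC", y = "AC", z = "AC"))
  q3 <- enumerate_quartets(four)
  expect_length(q3, 1)
  expect_equal(unname(q3[[1]]), c("w", "x", "y", "z"))
  expect_error(enumerate_quartets(aln), "clan")
})

test_that("site exclusion drops forbidden columns per quartet or globally", {
  clean <- alignment(c(a = strrep("A", 100), b = strrep("C", 100),
                       c = strrep("G", 100), d = strrep("T", 100)))
  roles <- c(A = "a", B = "b", C = "c", D = "d")
  qa <- extract_quartet(clean, roles)
  expect_equal(qa$used_length, 100)

  gapped <- clean
  seq_a <- gapped$seqs[["a"]]
  substr(seq_a, 7, 7) <- "-"
  gapped <- alignment(c(a = seq_a, gapped$seqs[c("b", "c", "d")]))
  qa2 <- extract_quartet(gapped, roles)
  expect_equal(qa2$used_length, 99)
  expect_equal(qa2$excluded, 7L)

  # gaps only in a 5th taxon: per-quartet extraction unaffected, global drops
  six <- alignment(c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC", d = "ACGTAC",
                     e = "AC--AC", f = "ACGTAC"))
  per <- extract_quartet(six, roles)
  expect_equal(per$used_length, 6)
  glo <- extract_quartet(six, roles, exclusion = "global")
  expect_equal(glo$used_length, 4)
  expect_equal(glo$excluded, c(3L, 4L))

  # U is treated as T, not excluded
  rna <- alignment(c(a = "ACGU", b = "ACGT", c = "ACGT", d = "ACGT"))
  qau <- extract_quartet(rna, roles)
  expect_equal(qau$used_length, 4)
  expect_equal(qau$states[1, 4], 4L)

  allgap <- alignment(c(a = "--", b = "AC", c = "AC", d = "AC"))
  expect_error(extract_quartet(allgap, roles), "degenerate")
})

test_that("per-quartet exclusion never retains fewer columns than global", {
  set.seed(3)
  letters_ <- c("A", "C", "G", "T", "-", "N")
  for (rep in 1:10) {
    mat <- matrix(sample(letters_, 6 * 40, replace = TRUE, prob = c(rep(0.22, 4), 0.06, 0.06)),
                  nrow = 6)
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- paste0("t", 1:6)
    aln <- alignment(seqs)
    roles <- c(A = "t1", B = "t2", C = "t3", D = "t4")
    per <- tryCatch(extract_quartet(aln, roles), error = function(e) NULL)
    glo <- tryCatch(extract_quartet(aln, roles, "global"), error = function(e) NULL)
    if (is.null(per)) expect_null(glo)
    else if (!is.null(glo)) expect_gte(per$used_length, glo$used_length)
  }
})

test_that("reports are tab-separated with fixed columns and six decimals", {
  sc <- structure(list(roles = c(A = "w", B = "x", C = "y", D = "z"),
                       lambda = c(q1 = 1, q2 = 0, q3 = 0),
                       theta = stats::setNames(c(3.5, 1.25, -0.5, 0, 0.125, 2),
                                               c("q1.AB", "q1.CD", "q2.AC",
                                                 "q2.BD", "q3.AD", "q3.BC")),
                       omega_obs = 0.25, used_length = 42),
                  class = "quartet_scores")
  p <- tempfile(fileext = ".tsv")
  write_report(sc, p)
  lines <- readLines(p)
  expect_length(lines, 2)
  expect_match(lines[2], "1\\.000000\t0\\.000000\t0\\.000000")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_length(fields, length(strsplit(lines[1], "\t")[[1]]))
  expect_equal(fields[1:4], c("w", "x", "y", "z"))
  expect_equal(fields[15], "42")

  write_report(list(), p)
  expect_length(readLines(p), 1)

  write_report(list(sc, sc), p)
  expect_length(readLines(p), 3)
})
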