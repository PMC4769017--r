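test_that("read_fasta normalizes case, strips stops, preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "hrdl", ">b desc text", "ACDE", "FGH*"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$residues, c("HRDL", "ACDEFGH"))
})

test_that("read_fasta rejects malformed input with informative errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "HR1DL"), f)
  expect_error(read_fasta(f), "position 3")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "no sequence entries")
  writeLines(c(">dup", "ACD", ">dup", "ACE"), f)
  expect_error(read_fasta(f), "dup")
})

test_that("fasta write/read round-trips ids and residues", {
  set.seed(11)
  rec <- protein_records(
    id = paste0("p", 1:8),
    residues = replicate(8, paste(sample(AA20, sample(5:40, 1),
                                         replace = TRUE), collapse = "")))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  back <- read_fasta(f)
  expect_equal(back$id, rec$id)
  expect_equal(back$residues, rec$residues)
})

test_that("read_fasta attaches taxon metadata by id", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">k1", "ACDE", ">k2", "FGHI"), f)
  meta <- data.frame(id = "k2", genus = "Pichia", species_epithet = "stipitis",
                     division = "Ascomycota")
  rec <- read_fasta(f, metadata = meta)
  expect_true(is.na(rec$genus[1]))
  expect_equal(rec$genus[2], "Pichia")
  expect_equal(rec$division[2], "Ascomycota")
})

test_that("read_alignment enforces alignment invariants", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-", ">b", "A-C"), f)
  aln <- read_alignment(f)
  expect_s3_class(aln, "aa_alignment")
  expect_equal(n_sites(aln), 3L)
  expect_equal(n_seqs(aln), 2L)
  writeLines(c(">a", "ACD", ">b", "ACDE"), f)
  expect_error(read_alignment(f), "ragged")
  writeLines(c(">a", "ACD"), f)
  expect_error(read_alignment(f), "at least 2")
})

test_that("ragged-length error names the offending sequence", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "ACE", ">odd", "ACDE"), f)
  expect_error(read_alignment(f), "odd")
})

test_that("consensus annotation maps column frequencies to symbols", {
  aln <- aa_alignment(c(s1 = "AAAC", s2 = "AACC", s3 = "ATDC", s4 = "AAEC"))
  # columns: AAAA (f=1), AATA (f=.75), ACDE (f=.25), CCCC (f=1)
  ca <- consensus_annotation(aln)
  expect_equal(ca$symbol, c("high", "low", "none", "high"))
  expect_equal(ca$residue[1], "A")
})

test_that("consensus tie-break picks the alphabetically smallest residue", {
  aln <- aa_alignment(c(s1 = "T", s2 = "T", s3 = "A", s4 = "A"))
  ca <- consensus_annotation(aln)
  expect_equal(ca$residue, "A")
  expect_equal(ca$frequency, 0.5)
  expect_equal(ca$symbol, "low")
})

test_that("consensus excludes gaps from the denominator; all-gap is none", {
  aln <- aa_alignment(c(s1 = "A-", s2 = "A-", s3 = "--", s4 = "C-"))
  ca <- consensus_annotation(aln)
  expect_equal(ca$frequency[1], 2 / 3)
  expect_equal(ca$symbol, c("low", "none"))
})

test_that("consensus is invariant under row permutation; identical rows are high", {
  set.seed(3)
  aln <- rand_alignment(6, 25)
  perm <- sample(6)
  seqs <- apply(aln$mat, 1, paste, collapse = "")[perm]
  names(seqs) <- aln$ids[perm]
  expect_equal(consensus_annotation(aln)$symbol,
               consensus_annotation(aa_alignment(seqs))$symbol)
  same <- aa_alignment(c(a = "ACDEF", b = "ACDEF", c = "ACDEF"))
  expect_true(all(consensus_annotation(same, high_level = 1)$symbol == "high"))
})

test_that("write_report emits deterministic TSV that round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(a = character(0), b = integer(0))
  write_report(empty, f)
  expect_equal(length(readLines(f)), 1L)
  rows <- data.frame(a = c("x", "y"), b = c(1L, 2L))
  write_report(rows, f)
  expect_equal(length(readLines(f)), 3L)
  expect_equal(read_report(f), rows)
})
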