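test_that("FASTA reading parses headers and validates sequences", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">X", "ACGT",
               ">EV1|2|maize|KJ000001", "ACGTN",
               ">plain header", "GGGG"), tf)
  p <- read_fasta(tf)
  expect_s3_class(p, "target_panel")
  expect_equal(nrow(p), 3)
  expect_equal(p$sequence[1], "ACGT")
  expect_equal(p$length[1], 4)
  expect_equal(p$event[2], "EV1")
  expect_equal(p$copy_label[2], "2")
  expect_equal(p$crop[2], "maize")
  expect_equal(p$accession[2], "KJ000001")
  expect_true(p$has_ambiguity[2])
  expect_false(p$has_ambiguity[1])
  expect_equal(p$copy_label[3], "1")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">oops", "ACQT"), bad)
  expect_error(read_fasta(bad), "oops")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("FASTA writer round-trips a generated panel byte-identically", {
  ref <- make_reference(2000, 3)
  pp <- make_panel(ref, 12, panel_profile(800, 994), 5)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(pp$panel, f1)
  back <- read_fasta(f1)
  expect_equal(nrow(back), 12)
  expect_equal(back$sequence, pp$panel$sequence)
  expect_equal(back$event, pp$panel$event)
  write_fasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("minimal GenBank reader handles ORIGIN blocks and round-trips", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       TESTREC 60 bp    DNA     linear",
               "DEFINITION  synthetic test record.",
               "ORIGIN",
               "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
               "//"), gb)
  r <- read_genbank_minimal(gb)
  expect_s3_class(r, "reference_genome")
  expect_equal(r$id, "TESTREC")
  expect_equal(r$length, 60)
  expect_equal(r$sequence, paste(rep("ACGT", 15), collapse = ""))

  noorigin <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 4 bp", "acgt", "//"), noorigin)
  expect_error(read_genbank_minimal(noorigin), "ORIGIN")

  malformed <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       Y 8 bp", "ORIGIN", "acgtacgt", "//"), malformed)
  expect_warning(r2 <- read_genbank_minimal(malformed), "numbering")
  expect_equal(r2$sequence, "ACGTACGT")

  ref <- make_reference(730, 11, id = "RT1")
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank_minimal(ref, f)
  back <- read_genbank_minimal(f)
  expect_identical(back$sequence, ref$sequence)
  expect_identical(back$id, ref$id)
})

test_that("the bundled assay table reproduces the 25 published assays", {
  assays <- p35s_assays()
  expect_length(assays, 25)
  expect_named(assays, paste0("M", 1:25))
  m25 <- assays$M25
  expect_equal(m25$kind, "taqman")
  fwd <- m25$oligos[[1]]
  expect_equal(fwd$sequence, "CATCATTGCGATAAAGGAAAGGC")
  expect_equal(c(fwd$reported_start, fwd$reported_end), c(7204L, 7226L))
  expect_equal(m25$reported_amplicon, 125L)

  m24 <- assays$M24
  expect_equal(m24$kind, "nested")
  expect_length(m24$oligos, 3)
  expect_equal(sum(vapply(m24$oligos, `[[`, character(1), "role") ==
                     "reverse"), 2)
  expect_false(m24$size_consistent)
  expect_false(assays$M9$size_consistent)
  expect_false(assays$M10$size_consistent)
  expect_false(assays$M22$size_consistent)
  # every taqman assay carries exactly one probe
  for (a in assays) {
    if (a$kind == "taqman") {
      expect_equal(sum(vapply(a$oligos, `[[`, character(1), "role") ==
                         "probe"), 1)
    }
  }
})

test_that("assay table reading normalises case and validates roles", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay_id\trole\tname\tsequence",
               "A1\tforward\tf1\tacgtacgtacgt",
               "A1\treverse\tr1\tTTTTAAAACCCC"), tf)
  a <- read_assay_table(tf)
  expect_equal(a$A1$oligos[[1]]$sequence, "ACGTACGTACGT")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay_id\trole\tname\tsequence",
               "A2\tforward\tf1\tACGTACGTACGT"), tf2)
  expect_error(read_assay_table(tf2), "A2")
})

test_that("all public report coordinates are 1-based inclusive", {
  assays <- p35s_assays()
  ref <- synth_reference_from_assays(assays, seed = 1)$ref
  spec <- variant_spec(7090, 7347)
  tgt <- derive_variant(ref, spec, event = "T")
  sites <- locate_assay(assays$M2, tgt, scan_policy(max_mismatch = 0))
  for (s in sites) {
    if (nrow(s) > 0) {
      expect_true(all(s$start >= 1))
      expect_true(all(s$end >= s$start))
      expect_true(all(s$end - s$start + 1 ==
                        nchar(assays$M2$oligos[[1]]$sequence) |
                      s$oligo != assays$M2$oligos[[1]]$name))
    }
  }
  rep1 <- map_fragment(tgt, ref)
  expect_true(all(rep1$segments$ref_start >= 1))
  expect_true(all(rep1$segments$frag_start >= 1))
  # interval arithmetic is inclusive: a 23-mer placed at 7204 ends 7226
  o <- assays$M25$oligos[[1]]
  expect_equal(o$reported_end - o$reported_start + 1, nchar(o$sequence))
})
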