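test_that("nearest-neighbor Tm matches a longhand oracle and is
           duplex-symmetric", {
  set.seed(11)
  for (rep in 1:25) {
    s <- random_dna(sample(10:30, 1))
    expect_equal(tm_nearest_neighbor(s), tm_oracle(s), tolerance = 0.5)
    expect_equal(tm_nearest_neighbor(s), tm_nearest_neighbor(revcomp(s)),
                 tolerance = 1e-9)
  }
  # frozen spot check against the oracle at non-default conditions
  s <- "CATCATTGCGATAAAGGAAAGGC"
  expect_equal(tm_nearest_neighbor(s, na_mM = 100, oligo_nM = 400),
               tm_oracle(s, na_mM = 100, oligo_nM = 400),
               tolerance = 0.5)
  expect_error(tm_nearest_neighbor("ACGTNACGTACG"), "ambiguity")
  expect_error(tm_nearest_neighbor("ACGT"), "shorter")
})

test_that("Tm increases with GC content on average", {
  set.seed(22)
  tms <- numeric(0)
  gcs <- integer(0)
  for (rep in 1:300) {
    s <- random_dna(20)
    tms <- c(tms, tm_nearest_neighbor(s))
    gcs <- c(gcs, round(gc_percent(s) / 5))
  }
  m <- tapply(tms, gcs, mean)
  m <- m[as.integer(names(m)) >= 5 & as.integer(names(m)) <= 15]
  expect_true(all(diff(m) > 0))
})

test_that("enumeration respects segment and amplicon constraints", {
  ref <- make_reference(1000, 5)
  # single segment shorter than the minimum primer length
  short <- data.frame(start = 101L, end = 115L)
  out <- enumerate_candidates(short, ref)
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "diagnostics"), "shortest primer")

  # a clean segment yields candidates, all within it
  seg <- data.frame(start = 101L, end = 220L)
  cands <- enumerate_candidates(seg, ref)
  if (nrow(cands) > 0) {
    expect_true(all(cands$forward_start >= 101 & cands$reverse_end <= 220))
    expect_true(all(cands$amplicon >= 60 & cands$amplicon <= 200))
    expect_true(all(cands$probe_start > cands$forward_end &
                      cands$probe_end < cands$reverse_start))
    expect_false(any(startsWith(cands$probe_seq, "G")))
  }

  # an amplicon range no window span can satisfy names the binding
  # constraint
  tight <- enumerate_candidates(
    seg, ref, design_constraints(amplicon_range = c(800L, 900L)))
  expect_equal(nrow(tight), 0)
  expect_match(attr(tight, "diagnostics"), "amplicon")
})

test_that("candidates avoid every profiled SNP position", {
  ref <- make_reference(2500, 8)
  pp <- make_panel(ref, 6, panel_profile(1000, 1109), 17)
  prof <- build_profile(map_panel(pp$panel, ref), ref)
  ci <- find_conserved_intervals(prof)
  segs <- ci$snp_free_segments[[which.max(ci$length)]]
  cands <- enumerate_candidates(segs, ref)
  expect_gt(nrow(cands), 0)
  snp_pos <- unique(prof$variants$ref_pos)
  covers_snp <- function(s, e) any(snp_pos >= s & snp_pos <= e)
  for (i in seq_len(min(nrow(cands), 200))) {
    expect_false(covers_snp(cands$forward_start[i], cands$forward_end[i]))
    expect_false(covers_snp(cands$reverse_start[i], cands$reverse_end[i]))
    expect_false(covers_snp(cands$probe_start[i], cands$probe_end[i]))
  }
})

test_that("verification distinguishes universal from broken sets", {
  ex <- example_panel()
  cand <- data.frame(
    forward_seq = "CATCATTGCGATAAAGGAAAGGC", forward_start = 7204L,
    forward_end = 7226L, reverse_seq = "TGCTTTGAAGACGTGGTTGGA",
    reverse_start = 7308L, reverse_end = 7328L,
    probe_seq = "TCGTGGGTGGGGGTC", probe_start = 7268L,
    probe_end = 7282L, amplicon = 125L, penalty = 0)
  v <- verify_candidate(cand, ex$panel)
  expect_true(v$universal)
  expect_true(all(v$per_target$n_products >= 1))

  # a reverse primer taken outside the shared region breaks
  # universality: siteless on window-confined targets
  bad <- cand
  bad$reverse_seq <- revcomp(ref_subseq(ex$ref, 7365, 7384))
  bad$reverse_start <- 7365L
  bad$reverse_end <- 7384L
  v2 <- verify_candidate(bad, ex$panel)
  expect_false(v2$universal)
  expect_true(anyNA(v2$per_target$reverse_mm))

  expect_error(verify_candidate(cand, ex$panel[0, ]), "empty panel")
})

test_that("ranking puts universal candidates first with stable ties", {
  ex <- example_panel()
  good <- data.frame(
    forward_seq = "CATCATTGCGATAAAGGAAAGGC", forward_start = 7204L,
    forward_end = 7226L, reverse_seq = "TGCTTTGAAGACGTGGTTGGA",
    reverse_start = 7308L, reverse_end = 7328L,
    probe_seq = "TCGTGGGTGGGGGTC", probe_start = 7268L,
    probe_end = 7282L, amplicon = 125L, penalty = 10)
  bad <- good
  bad$reverse_seq <- revcomp(ref_subseq(ex$ref, 7365, 7384))
  bad$reverse_start <- 7365L
  bad$reverse_end <- 7384L
  bad$penalty <- 1  # better score, but not universal
  cands <- rbind(bad, good)
  ranked <- rank_candidates(cands, ex$panel)
  expect_true(ranked$universal[1])
  expect_equal(ranked$forward_start[1], 7204L)

  # permutation invariance and amplicon tie-break
  tie_a <- good; tie_a$amplicon <- 120L
  tie_b <- good; tie_b$amplicon <- 130L
  r1 <- rank_candidates(rbind(tie_a, tie_b), ex$panel)
  r2 <- rank_candidates(rbind(tie_b, tie_a), ex$panel)
  expect_equal(r1$amplicon, r2$amplicon)
  expect_equal(r1$amplicon[1], 120L)

  top <- top_candidate(cands, ex$panel)
  expect_true(top$universal)
  expect_equal(top$forward_start, ranked$forward_start[1])
})
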