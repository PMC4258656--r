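assays <- p35s_assays()
frame <- synth_reference_from_assays(assays, seed = 1)
ref <- frame$ref

test_that("locating an assay is orientation-agnostic and mismatch-capped", {
  # a target spelling the conserved region carries one exact site per
  # conserved-region oligo
  tgt <- derive_variant(ref, variant_spec(7148, 7342), event = "CONS")
  sites <- locate_assay(assays$M25, tgt, scan_policy(max_mismatch = 0))
  expect_true(all(vapply(sites, nrow, integer(1)) == 1))
  expect_true(all(vapply(sites, function(s) s$n_mismatches, integer(1)) == 0))

  # a target confined to 7090-7347 has no site for a reverse primer
  # printed at 7365-7384
  tgt2 <- derive_variant(ref, variant_spec(7090, 7347), event = "M88913")
  s_m1 <- locate_assay(assays$M1, tgt2, scan_policy(max_mismatch = 0))
  expect_equal(nrow(s_m1[["35S-2"]]), 0)
  expect_gte(nrow(s_m1[["35S-1"]]), 1)

  # a reversed-layout assay still pairs: its "forward" primer sits on
  # the minus strand
  s_m18 <- locate_assay(assays$M18, tgt2, scan_policy(max_mismatch = 0))
  expect_equal(s_m18[["SP1 F"]]$strand, "-")
  pred <- predict_amplicons(s_m18, assays$M18)
  expect_equal(pred$products$size, 196L)
})

test_that("amplicon sizes follow inclusive-interval arithmetic", {
  # sizes recomputed from printed coordinates for every assay whose
  # printed size is self-consistent
  expected <- c(M1 = 195L, M2 = 74L, M3 = 101L, M4 = 79L, M5 = 162L,
                M6 = 81L, M7 = 68L, M8 = 205L, M11 = 142L, M12 = 82L,
                M13 = 81L, M14 = 123L, M15 = 195L, M16 = 165L,
                M17 = 158L, M18 = 196L, M19 = 173L, M20 = 220L,
                M21 = 227L, M23 = 111L, M25 = 125L)
  for (id in names(expected)) {
    a <- assays[[id]]
    expect_true(a$size_consistent, info = id)
    pred <- predict_amplicons(sites_from_reported(a), a)
    expect_equal(pred$products$size[pred$products$inner][1],
                 expected[[id]], info = id)
    expect_equal(pred$products$size[pred$products$inner][1],
                 a$reported_amplicon, info = id)
  }
  # the nested assay reports outer and inner products; the inner one
  # is scored
  p24 <- predict_amplicons(sites_from_reported(assays$M24), assays$M24)
  expect_equal(sort(p24$products$size), c(150L, 227L))
  expect_equal(p24$products$size[p24$products$inner], 150L)
})

test_that("duplicated enhancers yield one product per copy", {
  # M2 lies inside 7248-7321; duplicating a head that spans it gives
  # two equal products
  tgt <- derive_variant(ref, variant_spec(7090, 7443, dup_start = 7090,
                                          dup_end = 7344), event = "DE")
  sites <- locate_assay(assays$M2, tgt, scan_policy(max_mismatch = 0))
  # within a qPCR-plausible product window, one product per copy
  pred <- predict_amplicons(sites, assays$M2, max_product = 200L)
  expect_equal(pred$n_products, 2)
  expect_equal(pred$products$size[1], pred$products$size[2])
  # the long cross-copy pairing appears once long products are allowed
  pred_all <- predict_amplicons(sites, assays$M2, max_product = 2000L)
  expect_equal(pred_all$n_products, 3)
})

test_that("coverage classification reproduces the failure modes", {
  pol <- scan_policy()
  # 3'-proximal SNP in the forward primer: covered but inefficient
  o <- assays$M12$oligos[[1]]  # printed 7240-7257; offset 3 base is 7255
  tgt_seq <- ref_subseq(ref, 7090, 7347)
  alt <- setdiff(c("A", "C", "G", "T"), ref_subseq(ref, 7255, 7255))[1]
  spec <- variant_spec(7090, 7347,
                       snps = data.frame(pos = 7255L, alt = alt))
  tc_like <- derive_variant(ref, spec, event = "TC1507like")
  cl <- classify_coverage(assays$M12, tc_like, pol)
  expect_equal(cl$status, "PRIMER_MISMATCH")
  expect_equal(cl$predicted_outcome, "inefficient")
  expect_true(3L %in% cl$detail[[o$name]])

  # probe site disrupted by two SNPs plus a 2-base insertion: probe
  # siteless under an ungapped scan -> inefficient probe call. The
  # primer sites are made to match the assay exactly so the call is
  # driven by the probe.
  ch <- strsplit(ref_subseq(ref, 7090, 7347), "")[[1]]
  at <- function(p) p - 7090L + 1L
  fwd7 <- assays$M7$oligos[[1]]
  ch[at(fwd7$reported_start):at(fwd7$reported_end)] <-
    strsplit(fwd7$sequence, "")[[1]]
  ch[at(7233L)] <- setdiff(c("A", "C", "G", "T"), ch[at(7233L)])[1]
  ch[at(7243L)] <- setdiff(c("A", "C", "G", "T"), ch[at(7243L)])[1]
  pm_seq <- paste0(paste(ch[1:at(7238L)], collapse = ""), "AA",
                   paste(ch[(at(7238L) + 1L):length(ch)], collapse = ""))
  pm_like <- target_panel("pMCG161like", pm_seq)
  cl2 <- classify_coverage(assays$M7, pm_like, pol)
  expect_equal(cl2$status, "PROBE_MISMATCH")
  expect_equal(cl2$predicted_outcome, "inefficient")

  # the conserved-region set is PERFECT on every bundled panel member
  ex <- example_panel()
  for (i in seq_len(nrow(ex$panel))) {
    cl3 <- classify_coverage(assays$M25, ex$panel[i, ], pol)
    expect_equal(cl3$status, "PERFECT", info = ex$panel$target_id[i])
    expect_equal(cl3$predicted_outcome, "amplify")
  }
})

test_that("the coverage matrix composes per-pair calls", {
  ex <- example_panel()
  sub_assays <- assays[c("M1", "M2", "M25")]
  sub_panel <- ex$panel[c(1, 7), ]
  class(sub_panel) <- c("target_panel", "data.frame")
  cm <- coverage_matrix(sub_assays, sub_panel)
  expect_equal(dim(cm$status), c(3L, 2L))
  for (a in names(sub_assays)) {
    for (i in seq_len(nrow(sub_panel))) {
      single <- classify_coverage(sub_assays[[a]], sub_panel[i, ])
      expect_equal(cm$status[a, sub_panel$target_id[i]], single$status)
      expect_equal(cm$outcome[a, sub_panel$target_id[i]],
                   single$predicted_outcome)
    }
  }
  # a target equal to the whole reference fails nothing for assays
  # whose oligos match the reference exactly
  whole <- target_panel("REF", ref$sequence)
  cm2 <- coverage_matrix(assays[c("M19", "M25")], whole,
                         scan_policy(max_mismatch = 0))
  expect_equal(unname(cm2$summary$n_fail), c(0, 0))
})

test_that("auditing the reverse-complemented target mirrors the calls", {
  tgt <- derive_variant(ref, variant_spec(7090, 7347), event = "T")
  rc_tgt <- target_panel("Trc", revcomp(tgt$sequence))
  for (id in c("M1", "M2", "M18", "M25")) {
    c1 <- classify_coverage(assays[[id]], tgt)
    c2 <- classify_coverage(assays[[id]], rc_tgt)
    expect_equal(c1$status, c2$status, info = id)
    expect_equal(c1$n_products, c2$n_products, info = id)
    if (c1$n_products > 0) {
      n <- nchar(tgt$sequence)
      expect_setequal(n - c1$prediction$products$end + 1,
                      c2$prediction$products$start)
    }
  }
})

test_that("raising the mismatch cap never uncovers a covered pair", {
  set.seed(99)
  tgt <- derive_variant(ref, variant_spec(7090, 7400), event = "T")
  for (id in c("M2", "M7", "M12", "M25")) {
    prev_covered <- FALSE
    for (k in 0:3) {
      cl <- classify_coverage(assays[[id]], tgt, scan_policy(max_mismatch = k))
      covered <- cl$status != "NOT_COVERED"
      if (prev_covered) expect_true(covered, info = paste(id, k))
      prev_covered <- covered
    }
  }
})
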