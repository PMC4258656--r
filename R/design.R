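#' Primer/probe design confined to SNP-free conserved segments
#'
#' @name primer_design
#' @keywords internal
NULL

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), for 5'->3' dinucleotide steps.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)
.NN_INIT_GC <- c(dH = 0.1, dS = -2.8)
.NN_INIT_AT <- c(dH = 2.3, dS = 4.1)

#' Nearest-neighbor duplex melting temperature
#'
#' Unified nearest-neighbor enthalpy/entropy sums with terminal
#' initiation terms, an entropic monovalent-salt correction
#' (0.368 * (N-1) * ln\[Na+\] cal/(mol K)) and the two-state formula
#' Tm = dH / (dS + R ln(Ct/x)), with x = 4 for non-self-complementary
#' duplexes (x = 1 plus a symmetry entropy term for self-complementary
#' ones). Conditions default to 50 mM Na+-equivalent and 200 nM total
#' oligo. Note that on this scale PCR oligos read several degrees
#' below the targets quoted for vendor calculators that include
#' divalent-cation corrections.
#'
#' @param sequence DNA string of at least 8 unambiguous bases.
#' @param na_mM Monovalent-salt concentration in mM.
#' @param oligo_nM Total single-strand concentration in nM.
#' @return Melting temperature in degrees Celsius.
#' @export
tm_nearest_neighbor <- function(sequence, na_mM = 50, oligo_nM = 200) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8) stop("sequence shorter than 8 nt", call. = FALSE)
  if (grepl("[^ACGT]", sequence)) {
    stop("ambiguity codes not allowed in Tm calculation", call. = FALSE)
  }
  n <- nchar(sequence)
  steps <- substring(sequence, 1:(n - 1), 2:n)
  dH <- sum(.NN_DH[steps])
  dS <- sum(.NN_DS[steps])
  for (termb in c(substr(sequence, 1, 1), substr(sequence, n, n))) {
    init <- if (termb %in% c("G", "C")) .NN_INIT_GC else .NN_INIT_AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  selfcomp <- identical(sequence, revcomp(sequence))
  if (selfcomp) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  x <- if (selfcomp) 1 else 4
  ct <- oligo_nM * 1e-9
  tm_k <- (dH * 1000) / (dS + 1.9872 * log(ct / x))
  tm_k - 273.15
}

#' GC content in percent
#'
#' @param sequence DNA string.
#' @return Percent of G or C bases.
#' @export
gc_percent <- function(sequence) {
  b <- strsplit(toupper(sequence), "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' Design constraints for primer/probe enumeration
#'
#' Defaults follow common TaqMan practice: primers of 18-27 nt aimed
#' at a nominal 60 degrees C, a probe aimed a nominal 10 degrees
#' higher, no G at the probe 5' end (reporter quenching), and an
#' amplicon of 60-200 bp. Feasibility is checked on the
#' nearest-neighbor scale of [tm_nearest_neighbor()], which reads a
#' few degrees below vendor scales under monovalent-only salt, hence
#' the default primer tolerance of 6 C around the nominal target.
#' Probes are assessed on their effective Tm: probes short enough to
#' be synthesised with a minor-groove binder (at most
#' `probe_mgb_max_len` nt) are credited `probe_mgb_offset` degrees of
#' unmodeled MGB stabilisation; the effective Tm must fall within
#' `probe_tm_tol` of `probe_tm`. This is what lets the short probes
#' that fit between SNPs in fragmented conserved regions compete with
#' conventional 25-30 nt hydrolysis probes.
#'
#' @param primer_len,probe_len Length ranges (nt).
#' @param primer_tm,probe_tm Nominal target melting temperatures (C).
#' @param primer_tm_tol,probe_tm_tol Allowed deviation (C).
#' @param probe_mgb_offset Unmodeled MGB Tm elevation (C) credited to
#'   short probes.
#' @param probe_mgb_max_len Maximum probe length that can carry an MGB
#'   moiety.
#' @param gc_range Allowed GC range in percent.
#' @param amplicon_range Allowed product size range (bp).
#' @param amplicon_opt Amplicon size treated as optimal by the penalty.
#' @param forbid_probe_5prime_g Disallow G as probe 5' base.
#' @param max_complementarity_run Longest allowed perfect
#'   reverse-complement run within or between oligos of a set.
#' @param w_tm,w_gc,w_amplicon Penalty weights (per C deviation, per
#'   percent GC deviation from 50, per bp amplicon deviation).
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(primer_len = c(18L, 27L),
                               probe_len = c(13L, 30L),
                               primer_tm = 60, probe_tm = 70,
                               primer_tm_tol = 6, probe_tm_tol = 5,
                               probe_mgb_offset = 15,
                               probe_mgb_max_len = 18L,
                               gc_range = c(20, 80),
                               amplicon_range = c(60L, 200L),
                               amplicon_opt = 100L,
                               forbid_probe_5prime_g = TRUE,
                               max_complementarity_run = 8L,
                               w_tm = 1, w_gc = 0.5, w_amplicon = 0.05) {
  stopifnot(primer_len[1] <= primer_len[2], probe_len[1] <= probe_len[2],
            probe_tm > primer_tm, amplicon_range[1] <= amplicon_range[2])
  structure(list(primer_len = as.integer(primer_len),
                 probe_len = as.integer(probe_len),
                 primer_tm = primer_tm, probe_tm = probe_tm,
                 primer_tm_tol = primer_tm_tol,
                 probe_tm_tol = probe_tm_tol,
                 probe_mgb_offset = probe_mgb_offset,
                 probe_mgb_max_len = as.integer(probe_mgb_max_len),
                 gc_range = gc_range,
                 amplicon_range = as.integer(amplicon_range),
                 amplicon_opt = as.integer(amplicon_opt),
                 forbid_probe_5prime_g = forbid_probe_5prime_g,
                 max_complementarity_run = as.integer(max_complementarity_run),
                 w_tm = w_tm, w_gc = w_gc, w_amplicon = w_amplicon),
            class = "design_constraints")
}

.kmer_set <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1), k:n))
}

.rc_run_exceeds <- function(kmers_a, rc_kmers_b) {
  # TRUE if a and b share a reverse-complement run longer than the
  # allowed maximum, i.e. a common (max+1)-mer between a and revcomp(b)
  any(kmers_a %in% rc_kmers_b)
}

.windows_in_segments <- function(segments, ref, len_range, tm_window,
                                 gc_range) {
  starts <- integer(0); ends <- integer(0)
  for (k in seq_len(nrow(segments))) {
    s <- segments$start[k]
    e <- segments$end[k]
    for (L in len_range[1]:len_range[2]) {
      if (e - s + 1 < L) next
      st <- s:(e - L + 1L)
      starts <- c(starts, st)
      ends <- c(ends, st + L - 1L)
    }
  }
  if (length(starts) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), seq = character(0),
                      tm = numeric(0), gc = numeric(0)))
  }
  seqs <- substring(ref$sequence, starts, ends)
  gc <- vapply(seqs, gc_percent, numeric(1), USE.NAMES = FALSE)
  keep <- gc >= gc_range[1] & gc <= gc_range[2]
  starts <- starts[keep]; ends <- ends[keep]; seqs <- seqs[keep]
  gc <- gc[keep]
  tm <- vapply(seqs, tm_nearest_neighbor, numeric(1), USE.NAMES = FALSE)
  keep <- tm >= tm_window[1] & tm <= tm_window[2]
  data.frame(start = starts[keep], end = ends[keep],
             length = ends[keep] - starts[keep] + 1L,
             seq = seqs[keep], tm = tm[keep], gc = gc[keep],
             stringsAsFactors = FALSE)
}

#' Enumerate candidate primer/probe sets within SNP-free segments
#'
#' Exhaustively enumerates (forward, probe, reverse) window triples in
#' which each oligo lies wholly inside a SNP-free segment, satisfies
#' the length/Tm/GC constraints of [design_constraints()], the probe
#' lies strictly between and non-overlapping with the primers, the
#' amplicon size is within range, and no pair of oligos shares a
#' reverse-complement run longer than allowed. The forward primer is
#' reported on the plus strand; the reverse primer is the reverse
#' complement of its reference window; the probe is reported on the
#' strand avoiding a 5' G (probes hybridise on either strand).
#' Penalty = w_tm * Tm deviations (probes on their effective Tm) +
#' w_gc * mean GC deviation from 50% + w_amplicon * |size - optimum|.
#'
#' @param segments Data frame of SNP-free segments (`start`, `end`),
#'   e.g. the `snp_free_segments` entry of a conserved interval.
#' @param ref The [reference_genome()].
#' @param constraints A [design_constraints()].
#' @return A `candidate_sets` data frame, one row per candidate, with
#'   oligo sequences, intervals, Tm/GC values (probe Tm reported as
#'   effective Tm), amplicon size and penalty; empty with a
#'   `diagnostics` attribute naming the binding constraint when
#'   enumeration is infeasible.
#' @export
enumerate_candidates <- function(segments, ref,
                                 constraints = design_constraints()) {
  stopifnot(inherits(ref, "reference_genome"))
  cn <- constraints
  if (nrow(segments) == 0 ||
      max(segments$end - segments$start + 1L) < cn$primer_len[1]) {
    return(.empty_candidates("no segment as long as the shortest primer"))
  }
  primers <- .windows_in_segments(
    segments, ref, cn$primer_len,
    cn$primer_tm + c(-1, 1) * cn$primer_tm_tol, cn$gc_range)
  probes <- .windows_in_segments(
    segments, ref, cn$probe_len,
    c(-Inf, Inf), cn$gc_range)
  if (nrow(probes) > 0) {
    # effective probe Tm: short probes are credited MGB stabilisation
    probes$tm <- probes$tm +
      ifelse(probes$length <= cn$probe_mgb_max_len, cn$probe_mgb_offset, 0)
    probes <- probes[abs(probes$tm - cn$probe_tm) <= cn$probe_tm_tol, ,
                     drop = FALSE]
  }
  if (nrow(primers) == 0) {
    return(.empty_candidates("no primer window satisfies length/Tm/GC"))
  }
  if (nrow(probes) == 0) {
    return(.empty_candidates("no probe window satisfies length/Tm/GC"))
  }
  kx <- cn$max_complementarity_run + 1L
  p_fwd_km <- lapply(primers$seq, .kmer_set, kx)
  p_rc_km <- lapply(primers$seq, function(s) .kmer_set(revcomp(s), kx))
  pr_km <- lapply(probes$seq, .kmer_set, kx)
  # self-complementarity of a window rules it out everywhere; the
  # reverse primer of window j is revcomp(seq_j), whose k-mer content
  # mirrors the window's, so the same screens apply
  self_ok <- !vapply(seq_len(nrow(primers)), function(i) {
    .rc_run_exceeds(p_fwd_km[[i]], p_rc_km[[i]])
  }, logical(1))
  probe_self_ok <- !vapply(seq_len(nrow(probes)), function(k) {
    .rc_run_exceeds(pr_km[[k]], .kmer_set(revcomp(probes$seq[k]), kx))
  }, logical(1))

  # probe orientation and 5'-G rule, resolved once per probe window
  probe_seq_out <- probes$seq
  probe_ok <- probe_self_ok
  if (cn$forbid_probe_5prime_g) {
    for (k in seq_len(nrow(probes))) {
      if (startsWith(probes$seq[k], "G")) {
        alt <- revcomp(probes$seq[k])
        if (startsWith(alt, "G")) probe_ok[k] <- FALSE
        else probe_seq_out[k] <- alt
      }
    }
  }

  # probe-vs-primer cross-complementarity, precomputed as a matrix
  compat <- matrix(TRUE, nrow(probes), nrow(primers))
  for (k in seq_len(nrow(probes))) {
    if (!probe_ok[k]) next
    for (i in seq_len(nrow(primers))) {
      if (self_ok[i] && .rc_run_exceeds(pr_km[[k]], p_rc_km[[i]])) {
        compat[k, i] <- FALSE
      }
    }
  }

  # geometric pairing, then vectorized triple assembly
  chunks <- vector("list", 4096)
  nchunk <- 0L
  any_pair <- FALSE
  for (i in seq_len(nrow(primers))) {
    if (!self_ok[i]) next
    fs <- primers$start[i]; fe <- primers$end[i]
    js <- which(primers$end >= fs + cn$amplicon_range[1] - 1L &
                primers$end <= fs + cn$amplicon_range[2] - 1L &
                primers$start > fe & self_ok)
    if (length(js) == 0) next
    any_pair <- TRUE
    ks_all <- which(probes$start > fe & probe_ok & compat[, i])
    if (length(ks_all) == 0) next
    for (j in js) {
      if (.rc_run_exceeds(p_fwd_km[[j]], p_rc_km[[i]])) next
      ks <- ks_all[probes$end[ks_all] < primers$start[j] &
                   compat[ks_all, j]]
      if (length(ks) == 0) next
      nchunk <- nchunk + 1L
      if (nchunk > length(chunks)) {
        chunks <- c(chunks, vector("list", length(chunks)))
      }
      chunks[[nchunk]] <- cbind(i, j, ks)
    }
  }
  if (nchunk > 0L) {
    idx <- do.call(rbind, chunks[seq_len(nchunk)])
    fi <- idx[, 1]; ri <- idx[, 2]; pi <- idx[, 3]
  } else fi <- integer(0)
  if (length(fi) == 0L) {
    return(.empty_candidates(
      if (any_pair) "no probe window fits between any primer pair"
      else "amplicon size range excludes all primer pairings"))
  }
  size <- primers$end[ri] - primers$start[fi] + 1L
  penalty <- cn$w_tm * (abs(primers$tm[fi] - cn$primer_tm) +
                        abs(primers$tm[ri] - cn$primer_tm) +
                        abs(probes$tm[pi] - cn$probe_tm)) +
             cn$w_gc * (abs(primers$gc[fi] - 50) +
                        abs(primers$gc[ri] - 50) +
                        abs(probes$gc[pi] - 50)) / 3 +
             cn$w_amplicon * abs(size - cn$amplicon_opt)
  out <- data.frame(
    forward_seq = primers$seq[fi], forward_start = primers$start[fi],
    forward_end = primers$end[fi], forward_tm = primers$tm[fi],
    forward_gc = primers$gc[fi],
    reverse_seq = vapply(primers$seq, revcomp,
                         character(1), USE.NAMES = FALSE)[ri],
    reverse_start = primers$start[ri], reverse_end = primers$end[ri],
    reverse_tm = primers$tm[ri], reverse_gc = primers$gc[ri],
    probe_seq = probe_seq_out[pi], probe_start = probes$start[pi],
    probe_end = probes$end[pi], probe_tm = probes$tm[pi],
    probe_gc = probes$gc[pi], amplicon = size, penalty = penalty,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("candidate_sets", "data.frame")
  out
}

.empty_candidates <- function(reason) {
  out <- data.frame(forward_seq = character(0), forward_start = integer(0),
                    forward_end = integer(0), forward_tm = numeric(0),
                    forward_gc = numeric(0), reverse_seq = character(0),
                    reverse_start = integer(0), reverse_end = integer(0),
                    reverse_tm = numeric(0), reverse_gc = numeric(0),
                    probe_seq = character(0), probe_start = integer(0),
                    probe_end = integer(0), probe_tm = numeric(0),
                    probe_gc = numeric(0), amplicon = integer(0),
                    penalty = numeric(0))
  class(out) <- c("candidate_sets", "data.frame")
  attr(out, "diagnostics") <- reason
  out
}

.candidate_assay <- function(candidate, id = "candidate") {
  assay(id, list(
    oligo(paste0(id, "_F"), candidate$forward_seq, "forward",
          candidate$forward_start, candidate$forward_end),
    oligo(paste0(id, "_R"), candidate$reverse_seq, "reverse",
          candidate$reverse_start, candidate$reverse_end),
    oligo(paste0(id, "_P"), candidate$probe_seq, "probe",
          candidate$probe_start, candidate$probe_end)),
    kind = "taqman", reported_amplicon = candidate$amplicon)
}

#' Verify a candidate set against a target panel
#'
#' Scans each oligo of the candidate against every panel member and
#' predicts products. A candidate is "universal" when every oligo binds
#' every target with zero mismatches and every target yields at least
#' one product.
#'
#' @param candidate One row of a `candidate_sets` data frame.
#' @param panel A non-empty `target_panel`.
#' @param max_mismatch Mismatch cap used when searching for the best
#'   binding site of each oligo.
#' @return A `candidate_verification`: list with `per_target` (data
#'   frame of per-oligo minimal mismatch counts, NA when no site
#'   within the cap, and product counts) and `universal`.
#' @export
verify_candidate <- function(candidate, panel, max_mismatch = 3L) {
  if (!inherits(panel, "target_panel") || nrow(panel) == 0) {
    stop("verification against an empty panel is undefined", call. = FALSE)
  }
  asy <- .candidate_assay(candidate)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    sites <- locate_assay(asy, panel[i, ],
                          scan_policy(max_mismatch = max_mismatch))
    pred <- predict_amplicons(sites, asy)
    mm <- vapply(sites, function(s) {
      if (nrow(s) == 0) NA_integer_ else min(s$n_mismatches)
    }, integer(1))
    data.frame(target_id = panel$target_id[i],
               forward_mm = mm[[paste0(asy$id, "_F")]],
               reverse_mm = mm[[paste0(asy$id, "_R")]],
               probe_mm = mm[[paste0(asy$id, "_P")]],
               n_products = pred$n_products, stringsAsFactors = FALSE)
  })
  per_target <- do.call(rbind, rows)
  mmcols <- as.matrix(per_target[, c("forward_mm", "reverse_mm",
                                     "probe_mm")])
  universal <- !anyNA(mmcols) && all(mmcols == 0) &&
    all(per_target$n_products >= 1)
  structure(list(per_target = per_target, universal = universal),
            class = "candidate_verification")
}

.candidate_order <- function(candidates) {
  order(candidates$penalty, candidates$amplicon, candidates$forward_start)
}

#' Rank candidate sets against a panel
#'
#' Universal candidates (see [verify_candidate()]) come first, then
#' ascending penalty; ties are broken by smaller amplicon, then by the
#' leftmost forward-primer start. The ranking is invariant under input
#' permutation.
#'
#' @param candidates A `candidate_sets` data frame.
#' @param panel A `target_panel` to verify universality against.
#' @param max_mismatch Passed to [verify_candidate()].
#' @return The candidates with `universal` and `rank` columns added,
#'   sorted by rank.
#' @export
rank_candidates <- function(candidates, panel, max_mismatch = 3L) {
  stopifnot(nrow(candidates) >= 1)
  universal <- vapply(seq_len(nrow(candidates)), function(i) {
    verify_candidate(candidates[i, ], panel, max_mismatch)$universal
  }, logical(1))
  out <- candidates
  out$universal <- universal
  ord <- order(!out$universal, out$penalty, out$amplicon,
               out$forward_start)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("candidate_sets", "data.frame")
  out
}

#' Top-ranked candidate under lazy verification
#'
#' Returns the candidate [rank_candidates()] would place first, but
#' verifies candidates lazily in penalty order, stopping at the first
#' universal one; much faster on large candidate sets.
#'
#' @inheritParams rank_candidates
#' @return One-row `candidate_sets` data frame with a `universal`
#'   column.
#' @export
top_candidate <- function(candidates, panel, max_mismatch = 3L) {
  stopifnot(nrow(candidates) >= 1)
  ord <- .candidate_order(candidates)
  for (i in ord) {
    if (verify_candidate(candidates[i, ], panel, max_mismatch)$universal) {
      out <- candidates[i, , drop = FALSE]
      out$universal <- TRUE
      rownames(out) <- NULL
      return(out)
    }
  }
  out <- candidates[ord[1], , drop = FALSE]
  out$universal <- FALSE
  rownames(out) <- NULL
  out
}
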