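#' Synthetic references, variant panels and truth ledgers
#'
#' Everything downstream of sequence input can be exercised on
#' synthetic data with a known truth ledger: a random reference genome,
#' promoter-fragment variants derived from it by excision, point SNPs,
#' small insertions and tandem duplication of an enhancer-like head
#' ("double enhancer"), and whole panels with a protected SNP-free
#' conserved window.
#'
#' @name synthetic_fixtures
#' @keywords internal
NULL

.local_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a uniform-random reference genome
#'
#' @param length Genome length in bases (>= 500).
#' @param seed Integer seed; generation is reproducible.
#' @param id Identifier for the genome.
#' @return A [reference_genome()].
#' @export
make_reference <- function(length, seed, id = "synthref") {
  if (length < 500) stop("reference length must be >= 500", call. = FALSE)
  seqc <- .local_rng(seed, .random_bases(length))
  reference_genome(id, seqc)
}

#' Specify a synthetic promoter variant
#'
#' @param window_start,window_end Reference interval to excise
#'   (1-based, inclusive), emulating a promoter fragment.
#' @param snps Data frame with columns `pos` (reference position inside
#'   the window) and `alt` (alternate base, must differ from the
#'   reference base).
#' @param insertions Data frame with columns `pos` (reference position;
#'   the string is inserted after it) and `seq` (inserted string,
#'   at most 10 bp).
#' @param dup_start,dup_end Optional sub-interval to tandem-duplicate:
#'   the edited copy of this interval is prepended to the fragment so
#'   that both homologous segments share their reference start, the
#'   layout of a double-enhancer promoter.
#' @return A `variant_spec` object.
#' @export
variant_spec <- function(window_start, window_end, snps = NULL,
                         insertions = NULL, dup_start = NA_integer_,
                         dup_end = NA_integer_) {
  snps <- snps %||% data.frame(pos = integer(0), alt = character(0))
  insertions <- insertions %||% data.frame(pos = integer(0),
                                           seq = character(0))
  if (nrow(snps) > 0 &&
      (any(snps$pos < window_start) || any(snps$pos > window_end))) {
    stop("SNP positions must lie inside the window", call. = FALSE)
  }
  if (anyDuplicated(insertions$pos)) {
    stop("overlapping insertion positions", call. = FALSE)
  }
  if (nrow(insertions) > 0 && any(nchar(insertions$seq) > 10)) {
    stop("insertions are capped at 10 bp", call. = FALSE)
  }
  if (!is.na(dup_start) &&
      (dup_start < window_start || dup_end > window_end ||
       dup_start != window_start)) {
    stop("duplicated interval must start at the window start ",
         "(tandem head duplication)", call. = FALSE)
  }
  structure(list(window_start = as.integer(window_start),
                 window_end = as.integer(window_end),
                 snps = snps, insertions = insertions,
                 dup_start = as.integer(dup_start),
                 dup_end = as.integer(dup_end)),
            class = "variant_spec")
}

#' Derive a synthetic target from a reference and a variant spec
#'
#' Edits are applied right-to-left so planted positions remain valid
#' reference coordinates. SNPs that equal the reference base are
#' rejected. The optional duplicated head is taken from the edited
#' window, so SNPs inside the duplicated interval appear in both
#' copies.
#'
#' @param ref A [reference_genome()].
#' @param spec A [variant_spec()].
#' @param event,copy_label,crop Annotation for the resulting record.
#' @return A one-row `target_panel`.
#' @export
derive_variant <- function(ref, spec, event = "synthetic",
                           copy_label = "1", crop = NA_character_) {
  stopifnot(inherits(ref, "reference_genome"),
            inherits(spec, "variant_spec"))
  if (spec$window_start < 1 || spec$window_end > ref$length) {
    stop("window outside reference bounds", call. = FALSE)
  }
  frag <- strsplit(ref_subseq(ref, spec$window_start, spec$window_end),
                   "")[[1]]
  off <- spec$window_start - 1L
  if (nrow(spec$snps) > 0) {
    for (i in order(spec$snps$pos, decreasing = TRUE)) {
      p <- spec$snps$pos[i] - off
      if (frag[p] == spec$snps$alt[i]) {
        stop("alternate base equals reference base at ", spec$snps$pos[i],
             call. = FALSE)
      }
      frag[p] <- spec$snps$alt[i]
    }
  }
  seqc <- paste(frag, collapse = "")
  if (nrow(spec$insertions) > 0) {
    for (i in order(spec$insertions$pos, decreasing = TRUE)) {
      p <- spec$insertions$pos[i] - off
      seqc <- paste0(substr(seqc, 1, p), spec$insertions$seq[i],
                     substr(seqc, p + 1, nchar(seqc)))
    }
  }
  if (!is.na(spec$dup_start)) {
    head_len <- spec$dup_end - spec$dup_start + 1L
    # the duplicated head carries the same edits (positions relative to
    # the window start, before insertions downstream of it shift)
    head_seq <- paste(frag[seq_len(head_len)], collapse = "")
    ins_in_head <- spec$insertions[spec$insertions$pos <= spec$dup_end, ,
                                   drop = FALSE]
    if (nrow(ins_in_head) > 0) {
      for (i in order(ins_in_head$pos, decreasing = TRUE)) {
        p <- ins_in_head$pos[i] - off
        head_seq <- paste0(substr(head_seq, 1, p), ins_in_head$seq[i],
                           substr(head_seq, p + 1, nchar(head_seq)))
      }
    }
    seqc <- paste0(head_seq, seqc)
  }
  target_panel(event = event, sequence = seqc, copy_label = copy_label,
               crop = crop)
}

#' Default panel generation profile
#'
#' The profile describes the variation structure a synthetic panel
#' emulates: a protected conserved window that no planted SNP touches,
#' per-target SNP counts outside (and, sparsely, inside but never
#' within) that window, occasional small insertions, and at least one
#' double-enhancer target.
#'
#' @param conserved_start,conserved_end Protected window on the
#'   reference (>= 60 bp).
#' @param snps_outside Integer range (min, max) of SNPs planted outside
#'   the protected window per target.
#' @param insertion_prob Probability a target carries one small
#'   insertion (2 bp, outside the protected window).
#' @param edge_margin SNPs and insertions are kept at least this many
#'   bases away from fragment ends (terminal edits are invisible to
#'   local alignment).
#' @return A `panel_profile` list.
#' @export
panel_profile <- function(conserved_start, conserved_end,
                          snps_outside = c(1L, 6L),
                          insertion_prob = 0.25, edge_margin = 12L) {
  if (conserved_end - conserved_start + 1 < 60) {
    stop("conserved window smaller than 60 bp is too small to design into",
         call. = FALSE)
  }
  structure(list(conserved_start = as.integer(conserved_start),
                 conserved_end = as.integer(conserved_end),
                 snps_outside = as.integer(snps_outside),
                 insertion_prob = insertion_prob,
                 edge_margin = as.integer(edge_margin)),
            class = "panel_profile")
}

#' Generate a synthetic target panel with a truth ledger
#'
#' Produces `n` targets derived from `ref`. Every target's window
#' contains the protected conserved window; two anchor targets abut it
#' exactly (one starts at its left bound, one ends at its right bound),
#' so that the intersection of the panel's coverage equals the planted
#' window. At least one target carries a tandem duplication of its
#' window head and at least one target is edit-free.
#'
#' @param ref A [reference_genome()].
#' @param n Number of targets (>= 4).
#' @param profile A [panel_profile()].
#' @param seed Integer seed.
#' @return List with `panel` (a `target_panel`) and `ledger`, a
#'   `truth_ledger` holding, per target, the true window, SNP table and
#'   duplication flag, and the panel-wide true conserved interval.
#' @export
make_panel <- function(ref, n, profile, seed) {
  stopifnot(inherits(ref, "reference_genome"),
            inherits(profile, "panel_profile"), n >= 4)
  a <- profile$conserved_start
  b <- profile$conserved_end
  m <- profile$edge_margin
  if (a - 1 < 80 || ref$length - b < 80) {
    stop("conserved window too close to the reference ends", call. = FALSE)
  }
  .local_rng(seed, {
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      ws <- if (i == 1) a else max(1L, a - sample(40:min(200, a - 1), 1))
      we <- if (i == 2) b else min(ref$length,
                                   b + sample(40:min(200, ref$length - b), 1))
      n_snp <- if (i == 3) 0L else
        sample(profile$snps_outside[1]:profile$snps_outside[2], 1)
      cand <- setdiff(seq(ws + m, we - m), seq(a - 1L, b + 1L))
      snp_pos <- if (n_snp > 0 && length(cand) >= n_snp) {
        sort(sample(cand, n_snp))
      } else integer(0)
      snps <- if (length(snp_pos) > 0) {
        refb <- strsplit(ref_subseq(ref, ws, we), "")[[1]][snp_pos - ws + 1L]
        alt <- vapply(refb, function(rb) sample(setdiff(c("A", "C", "G", "T"),
                                                        rb), 1),
                      character(1))
        data.frame(pos = snp_pos, alt = unname(alt),
                   stringsAsFactors = FALSE)
      } else NULL
      ins <- NULL
      if (i != 3 && stats::runif(1) < profile$insertion_prob &&
          ws + m < a - 2L) {
        # keep insertions clear of planted SNPs: adjacent SNP + indel
        # placements are alignment-degenerate
        ip_cand <- seq(ws + m, a - 2L)
        if (length(snp_pos) > 0) {
          near <- outer(ip_cand, snp_pos, function(x, y) abs(x - y) <= 6)
          ip_cand <- ip_cand[!apply(near, 1, any)]
        }
        if (length(ip_cand) > 0) {
          ip <- if (length(ip_cand) == 1) ip_cand else sample(ip_cand, 1)
          ins <- data.frame(pos = ip, seq = .random_bases(2),
                            stringsAsFactors = FALSE)
        }
      }
      dup <- i == 4  # fixed slot guarantees one double-enhancer target
      dup_end <- if (dup) min(we, b + sample(0:20, 1)) else NA_integer_
      specs[[i]] <- variant_spec(ws, we, snps = snps, insertions = ins,
                                 dup_start = if (dup) ws else NA_integer_,
                                 dup_end = dup_end)
    }
    recs <- lapply(seq_len(n), function(i) {
      derive_variant(ref, specs[[i]], event = sprintf("SYN%02d", i))
    })
    panel <- do.call(rbind, recs)
    class(panel) <- c("target_panel", "data.frame")
    ledger <- structure(list(
      targets = lapply(seq_len(n), function(i) {
        s <- specs[[i]]
        list(target_id = panel$target_id[i],
             window = c(s$window_start, s$window_end),
             snps = s$snps, insertions = s$insertions,
             duplicated = !is.na(s$dup_start),
             dup_interval = if (!is.na(s$dup_start))
               c(s$dup_start, s$dup_end) else NULL)
      }),
      conserved = c(a, b), seed = seed), class = "truth_ledger")
    names(ledger$targets) <- panel$target_id
    list(panel = panel, ledger = ledger)
  })
}

#' Write a truth ledger as JSON
#'
#' @param ledger A `truth_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "truth_ledger"))
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------
# Synthetic stand-in for the assay coordinate frame
# ---------------------------------------------------------------------

.assay_layout_reversed <- function(asy) {
  # Some published tables print "forward" primers that sit downstream
  # on the minus strand; orientation follows from the printed
  # coordinates, not the labels.
  roles <- vapply(asy$oligos, `[[`, character(1), "role")
  fst <- suppressWarnings(
    min(vapply(asy$oligos[roles == "forward"], `[[`, integer(1),
               "reported_start"), na.rm = TRUE))
  rst <- suppressWarnings(
    min(vapply(asy$oligos[roles == "reverse"], `[[`, integer(1),
               "reported_start"), na.rm = TRUE))
  is.finite(fst) && is.finite(rst) && fst > rst
}

.oligo_plus_strand <- function(olig, minus) {
  # Returns (plus-strand sequence, plus-strand mask positions) of the
  # oligo written onto its reported interval.
  if (!minus) {
    list(seq = olig$sequence, mask = olig$mismatch_positions)
  } else {
    L <- olig$length
    list(seq = revcomp(olig$sequence),
         mask = if (length(olig$mismatch_positions)) {
           sort(L - olig$mismatch_positions + 1L)
         } else integer(0))
  }
}

#' Build a synthetic reference consistent with printed assay coordinates
#'
#' Constructs a reference genome on which every bundled oligo spells
#' its printed sequence at its printed interval (reverse-complemented
#' for minus-strand oligos, with strand inferred from each assay's
#' printed layout). Bases flagged in an oligo's mismatch mask are
#' written only where no unflagged oligo covers the position; where
#' several oligos cover a position the unflagged majority wins, with
#' alphabetical tie-breaking. Positions covered by no oligo are filled
#' with seeded random bases. The result is a synthetic stand-in for
#' the real genome, adequate for coordinate and binding-site
#' arithmetic, not a reconstruction of the true sequence.
#'
#' @param assays Named list of [assay()] objects with reported
#'   intervals (e.g. [p35s_assays()]).
#' @param length Total length of the synthetic genome.
#' @param seed Seed for the random fill.
#' @param probe_strand_plus Named logical: for probes whose strand is
#'   ambiguous, TRUE places the printed sequence on the plus strand
#'   (the default for all probes except those that conflict with
#'   primer-derived bases).
#' @return List with `ref` (a [reference_genome()]) and `conflicts`, a
#'   data frame of positions where unflagged oligo bases disagreed
#'   (expected to be empty for the bundled table).
#' @export
synth_reference_from_assays <- function(assays, length = 8024L, seed = 1L,
                                        probe_strand_plus = NULL) {
  votes <- vector("list", length)  # each: data.frame(base, masked)
  add_vote <- function(pos, base, masked) {
    for (k in seq_along(pos)) {
      p <- pos[k]
      votes[[p]] <<- rbind(votes[[p]],
                           data.frame(base = base[k], masked = masked[k],
                                      stringsAsFactors = FALSE))
    }
  }
  place <- function(olig, minus) {
    if (is.na(olig$reported_start)) return(invisible())
    span <- olig$reported_end - olig$reported_start + 1L
    if (span != olig$length) return(invisible())  # inconsistent interval
    ps <- .oligo_plus_strand(olig, minus)
    bases <- strsplit(ps$seq, "")[[1]]
    masked <- rep(FALSE, span)
    masked[ps$mask] <- TRUE
    add_vote(olig$reported_start:olig$reported_end, bases, masked)
  }
  # primers first: their strand follows from the assay layout
  probes <- list()
  for (asy in assays) {
    rev_layout <- .assay_layout_reversed(asy)
    for (olig in asy$oligos) {
      if (olig$role == "probe") {
        probes[[length(probes) + 1L]] <- olig
      } else {
        minus <- if (olig$role == "forward") rev_layout else !rev_layout
        place(olig, minus)
      }
    }
  }
  consensus_at <- function(p) {
    v <- votes[[p]]
    if (is.null(v)) return(NA_character_)
    pool <- if (any(!v$masked)) v$base[!v$masked] else v$base
    tab <- sort(table(pool), decreasing = TRUE)
    names(tab)[1]
  }
  # probes: choose the strand that agrees best with what primers wrote
  for (olig in probes) {
    if (is.na(olig$reported_start) ||
        olig$reported_end - olig$reported_start + 1L != olig$length) next
    forced <- probe_strand_plus[[olig$name]]
    agree <- function(minus) {
      ps <- .oligo_plus_strand(olig, minus)
      bases <- strsplit(ps$seq, "")[[1]]
      ok <- 0L
      for (k in seq_along(bases)) {
        cb <- consensus_at(olig$reported_start + k - 1L)
        if (!is.na(cb) && cb == bases[k]) ok <- ok + 1L
      }
      ok
    }
    minus <- if (!is.null(forced)) !forced else agree(TRUE) > agree(FALSE)
    place(olig, minus)
  }
  out <- character(length)
  conflicts <- list()
  for (p in seq_len(length)) {
    v <- votes[[p]]
    if (is.null(v)) {
      out[p] <- NA_character_
      next
    }
    unmasked <- unique(v$base[!v$masked])
    if (length(unmasked) > 1) {
      conflicts[[length(conflicts) + 1L]] <-
        data.frame(pos = p, bases = paste(sort(unmasked), collapse = "/"),
                   stringsAsFactors = FALSE)
    }
    out[p] <- consensus_at(p)
  }
  fill <- .local_rng(seed, .random_bases(sum(is.na(out))))
  out[is.na(out)] <- strsplit(fill, "")[[1]]
  list(ref = reference_genome("synthetic_assay_frame",
                              paste(out, collapse = "")),
       conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                   else data.frame(pos = integer(0), bases = character(0)))
}

# ---------------------------------------------------------------------
# Bundled synthetic analogue panel
# ---------------------------------------------------------------------

#' Layout table for the bundled synthetic promoter panel
#'
#' Twelve synthetic targets emulating the variation structure observed
#' across published P35S promoter fragments: reference windows of
#' varying extent, double-enhancer tandem duplications sharing their
#' reference start, per-target SNPs inside and outside the conserved
#' region, and exact anchors at the conserved-region bounds (7148 and
#' 7342). The SNP placement is synthetic: counts and positions emulate
#' the published panel's structure, not its exact alignment.
#'
#' @return Data frame with one row per target.
#' @export
example_panel_layout <- function() {
  lay <- function(event, crop, copy, ws, we, ds, de, snps) {
    data.frame(event = event, crop = crop, copy_label = copy,
               window_start = ws, window_end = we,
               dup_start = ds, dup_end = de,
               snp_pos = I(list(snps)), stringsAsFactors = FALSE)
  }
  rbind(
    lay("GTS-40-3-2", "soybean", "1", 7148L, 7468L, NA, NA,
        c(7160L, 7198L, 7290L, 7360L, 7380L, 7400L, 7420L, 7444L)),
    lay("A5547-127", "soybean", "1", 6908L, 7437L, NA, NA, integer(0)),
    lay("NK603", "maize", "1", 7090L, 7381L, 7090L, 7344L, integer(0)),
    lay("TC1507", "maize", "1", 6913L, 7565L, NA, NA,
        c(6950L, 7000L, 7050L, 7255L, 7450L, 7500L)),
    lay("MON810", "maize", "1", 7137L, 7443L, NA, NA, integer(0)),
    lay("T25", "maize", "2", 7027L, 7342L, NA, NA,
        c(7050L, 7070L, 7100L, 7120L, 7140L)),
    lay("MON88913", "cotton", "1", 7090L, 7347L, 7090L, 7344L, integer(0)),
    lay("MON531", "cotton", "1", 7090L, 7443L, 7090L, 7344L, integer(0)),
    lay("KMD", "rice", "1", 7017L, 7478L, NA, NA,
        c(7030L, 7060L, 7300L, 7335L, 7450L, 7470L)),
    lay("Kefeng6", "rice", "1", 7018L, 7478L, 7018L, 7343L,
        c(7300L, 7335L, 7460L)),
    lay("MON89034", "maize", "1", 7148L, 7443L, NA, NA,
        c(7160L, 7198L, 7290L, 7400L, 7420L)),
    lay("LLRice62", "rice", "1", 6908L, 7437L, NA, NA, c(7400L)))
}

#' The bundled synthetic reference and promoter panel
#'
#' Builds the synthetic assay-coordinate reference (see
#' [synth_reference_from_assays()]) and derives the twelve-member
#' synthetic analogue panel of [example_panel_layout()] from it. SNP
#' alternate bases are chosen deterministically (next base in A<C<G<T
#' order), so the bundle is fully reproducible.
#'
#' @param seed Seed for the random fill of the reference.
#' @return List with `ref`, `panel` and `ledger` (as in [make_panel()]).
#' @export
example_panel <- function(seed = 20140101L) {
  sr <- synth_reference_from_assays(p35s_assays(), seed = seed)
  ref <- sr$ref
  lay <- example_panel_layout()
  nxt <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  recs <- vector("list", nrow(lay))
  ledger_targets <- vector("list", nrow(lay))
  for (i in seq_len(nrow(lay))) {
    snp_pos <- lay$snp_pos[[i]]
    snps <- if (length(snp_pos) > 0) {
      refb <- vapply(snp_pos, function(p) ref_subseq(ref, p, p),
                     character(1))
      data.frame(pos = snp_pos, alt = vapply(refb, nxt, character(1)),
                 stringsAsFactors = FALSE)
    } else NULL
    spec <- variant_spec(lay$window_start[i], lay$window_end[i],
                         snps = snps, dup_start = lay$dup_start[i],
                         dup_end = lay$dup_end[i])
    recs[[i]] <- derive_variant(ref, spec, event = lay$event[i],
                                copy_label = lay$copy_label[i],
                                crop = lay$crop[i])
    ledger_targets[[i]] <- list(
      target_id = recs[[i]]$target_id,
      window = c(lay$window_start[i], lay$window_end[i]),
      snps = snps %||% data.frame(pos = integer(0), alt = character(0)),
      insertions = data.frame(pos = integer(0), seq = character(0)),
      duplicated = !is.na(lay$dup_start[i]),
      dup_interval = if (!is.na(lay$dup_start[i]))
        c(lay$dup_start[i], lay$dup_end[i]) else NULL)
  }
  panel <- do.call(rbind, recs)
  class(panel) <- c("target_panel", "data.frame")
  names(ledger_targets) <- panel$target_id
  ledger <- structure(list(targets = ledger_targets,
                           conserved = c(7148L, 7342L), seed = seed),
                      class = "truth_ledger")
  list(ref = ref, panel = panel, ledger = ledger)
}
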