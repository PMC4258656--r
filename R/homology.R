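#' Fragment-to-reference mapping and conservation profiling
#'
#' @name homology_conservation
#' @keywords internal
NULL

#' Parameters for fragment mapping
#'
#' @param score_floor Minimum local-alignment score for a segment to be
#'   reported (default 60, i.e. 30 perfectly matching bases under the
#'   default scoring).
#' @param min_segment Minimum unaligned overhang length (bases) worth
#'   re-aligning as a candidate additional segment; also the minimum
#'   reference overlap between two segments for a duplication call.
#' @param end_anchor Segment ends are trimmed back until they terminate
#'   in at least this many consecutive matching bases; local alignments
#'   otherwise pick up short chance extensions across duplication
#'   junctions and truncation points.
#' @param align Scoring parameters from [align_params()].
#' @return Named list of mapping parameters.
#' @export
map_params <- function(score_floor = 60, min_segment = 50L,
                       end_anchor = 8L, align = align_params()) {
  list(score_floor = score_floor, min_segment = as.integer(min_segment),
       end_anchor = as.integer(end_anchor), align = align)
}

# walk the aligned strings column by column, yielding positions on
# each sequence (NA within gaps) and a match flag
.alignment_columns <- function(aligned_a, aligned_b, a_start, b_start) {
  ac <- strsplit(aligned_a, "")[[1]]
  bc <- strsplit(aligned_b, "")[[1]]
  a_pos <- cumsum(ac != "-")
  a_pos[ac == "-"] <- NA
  a_pos <- a_pos + a_start - 1L
  b_pos <- cumsum(bc != "-")
  b_pos[bc == "-"] <- NA
  b_pos <- b_pos + b_start - 1L
  list(a = ac, b = bc, a_pos = a_pos, b_pos = b_pos,
       match = ac == bc & ac != "-")
}

# columns to keep so that both alignment ends terminate in a run of at
# least `anchor` consecutive matches; NULL when nothing survives
.anchored_range <- function(match, anchor) {
  i1 <- 1L
  i2 <- length(match)
  run_len <- function(from, dir) {
    n <- 0L
    i <- from
    while (i >= i1 && i <= i2 && match[i]) {
      n <- n + 1L
      i <- i + dir
    }
    n
  }
  repeat {
    if (i2 - i1 + 1L < anchor) return(NULL)
    r <- run_len(i2, -1L)
    if (r >= anchor) break
    i2 <- i2 - r
    while (i2 >= i1 && !match[i2]) i2 <- i2 - 1L
  }
  repeat {
    if (i2 - i1 + 1L < anchor) return(NULL)
    r <- run_len(i1, 1L)
    if (r >= anchor) break
    i1 <- i1 + r
    while (i1 <= i2 && !match[i1]) i1 <- i1 + 1L
  }
  c(i1, i2)
}

.segment_stats <- function(cols, keep, score) {
  idx <- keep[1]:keep[2]
  a <- cols$a[idx]; b <- cols$b[idx]
  m <- cols$match[idx]
  n_ins <- sum(b == "-")
  n_del <- sum(a == "-")
  n_match <- sum(m)
  n_mismatch <- length(idx) - n_match - n_ins - n_del
  mm <- which(!m & a != "-" & b != "-")
  list(
    segment = data.frame(
      ref_start = min(cols$b_pos[idx], na.rm = TRUE),
      ref_end = max(cols$b_pos[idx], na.rm = TRUE),
      frag_start = min(cols$a_pos[idx], na.rm = TRUE),
      frag_end = max(cols$a_pos[idx], na.rm = TRUE),
      identity = n_match / length(idx),
      identity_ungapped = n_match / (n_match + n_mismatch),
      n_match = n_match, n_mismatch = n_mismatch,
      n_ins = n_ins, n_del = n_del, score = score,
      stringsAsFactors = FALSE),
    snps = data.frame(
      ref_pos = cols$b_pos[idx][mm], ref_base = b[mm],
      frag_base = a[mm], frag_pos = cols$a_pos[idx][mm],
      stringsAsFactors = FALSE))
}

#' Map a target fragment onto the reference genome
#'
#' Finds one or more local alignments of the fragment against the
#' reference: the best local alignment is taken as a segment, and
#' unaligned fragment overhangs of at least `min_segment` bases are
#' re-aligned recursively. Two segments overlapping by at least
#' `min_segment` bases on the reference are called a duplicated
#' enhancer (the layout of double-enhancer promoters, whose homologous
#' segments share a reference start).
#'
#' @param target One-row `target_panel` (or character sequence).
#' @param ref A [reference_genome()].
#' @param params From [map_params()].
#' @return A `homology_report`: list with `target_id`, `segments` (data
#'   frame sorted by fragment coordinate, with per-segment gapped and
#'   ungapped identity), `snps` (data frame `ref_pos`, `ref_base`,
#'   `frag_base`), `whole_identity` (percent over the whole fragment),
#'   `identity_percent` (whole-percent rounding used in report tables),
#'   `duplicated_enhancer`, `unaligned_overhangs` and `unmapped`.
#' @export
map_fragment <- function(target, ref, params = map_params()) {
  stopifnot(inherits(ref, "reference_genome"))
  target_id <- NA_character_
  if (is.data.frame(target)) {
    target_id <- target$target_id[1]
    target <- target$sequence[1]
  }
  if (nchar(target) < 50) stop("target shorter than 50 bp", call. = FALSE)

  segments <- list()
  snps <- list()
  overhangs <- integer(0)

  recurse <- function(frag, offset) {
    al <- align_affine(frag, ref$sequence, mode = "local",
                       params = params$align)
    if (al$score < params$score_floor) {
      overhangs <<- c(overhangs, nchar(frag))
      return(invisible())
    }
    cols <- .alignment_columns(al$aligned_a, al$aligned_b,
                               al$a_start, al$b_start)
    keep <- .anchored_range(cols$match, params$end_anchor)
    if (is.null(keep)) {
      overhangs <<- c(overhangs, nchar(frag))
      return(invisible())
    }
    st <- .segment_stats(cols, keep, al$score)
    seg <- st$segment
    segments[[length(segments) + 1L]] <<- within(seg, {
      frag_start <- frag_start + offset
      frag_end <- frag_end + offset
    })
    if (nrow(st$snps) > 0) {
      s <- st$snps
      s$frag_pos <- s$frag_pos + offset
      snps[[length(snps) + 1L]] <<- s
    }
    left <- seg$frag_start - 1L
    right <- nchar(frag) - seg$frag_end
    if (left >= params$min_segment) {
      recurse(substr(frag, 1, left), offset)
    } else if (left > 0) overhangs <<- c(overhangs, left)
    if (right >= params$min_segment) {
      recurse(substr(frag, seg$frag_end + 1L, nchar(frag)),
              offset + seg$frag_end)
    } else if (right > 0) overhangs <<- c(overhangs, right)
  }
  recurse(target, 0L)

  if (length(segments) == 0) {
    return(structure(list(target_id = target_id, segments = NULL,
                          snps = NULL, whole_identity = NA_real_,
                          identity_percent = NA_integer_,
                          duplicated_enhancer = FALSE,
                          unaligned_overhangs = overhangs,
                          fragment_length = nchar(target),
                          unmapped = TRUE),
                     class = "homology_report"))
  }
  seg <- do.call(rbind, segments)
  seg <- seg[order(seg$frag_start), , drop = FALSE]
  rownames(seg) <- NULL
  snp_df <- if (length(snps)) {
    s <- do.call(rbind, snps)
    s <- s[order(s$ref_pos), , drop = FALSE]
    rownames(s) <- NULL
    s
  } else data.frame(ref_pos = integer(0), ref_base = character(0),
                    frag_base = character(0), frag_pos = integer(0))
  dup <- FALSE
  if (nrow(seg) > 1) {
    for (i in seq_len(nrow(seg) - 1)) {
      for (j in (i + 1):nrow(seg)) {
        ov <- min(seg$ref_end[i], seg$ref_end[j]) -
              max(seg$ref_start[i], seg$ref_start[j]) + 1L
        if (ov >= params$min_segment) dup <- TRUE
      }
    }
  }
  whole <- 100 * sum(seg$n_match) / nchar(target)
  structure(list(target_id = target_id, segments = seg, snps = snp_df,
                 whole_identity = whole,
                 identity_percent = as.integer(round(whole)),
                 duplicated_enhancer = dup,
                 unaligned_overhangs = overhangs,
                 fragment_length = nchar(target),
                 unmapped = FALSE),
            class = "homology_report")
}

#' @export
print.homology_report <- function(x, ...) {
  if (x$unmapped) {
    cat("<homology_report> ", x$target_id, ": unmapped\n", sep = "")
    return(invisible(x))
  }
  segtxt <- paste(sprintf("%d-%d", x$segments$ref_start,
                          x$segments$ref_end), collapse = ",")
  cat(sprintf("<homology_report> %s: %s  identity %d%%  SNPs %d%s\n",
              x$target_id, segtxt, x$identity_percent, nrow(x$snps),
              if (x$duplicated_enhancer) "  double enhancer" else ""))
  invisible(x)
}

#' Map every panel member onto the reference
#'
#' @param panel A `target_panel`.
#' @param ref A [reference_genome()].
#' @param params From [map_params()].
#' @return Named list of `homology_report` objects.
#' @export
map_panel <- function(panel, ref, params = map_params()) {
  stopifnot(inherits(panel, "target_panel"))
  reps <- lapply(seq_len(nrow(panel)), function(i) {
    map_fragment(panel[i, ], ref, params)
  })
  names(reps) <- panel$target_id
  reps
}

#' Summarise homology reports as a per-target table
#'
#' One row per target with length, homologous region(s), whole-percent
#' identity, SNP count and a double-enhancer note, mirroring the column
#' layout of published panel summaries.
#'
#' @param reports List of `homology_report` objects.
#' @return Data frame.
#' @export
homology_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(
      target_id = r$target_id,
      length = r$fragment_length,
      homologous_region = if (r$unmapped) NA_character_ else
        paste(sprintf("%d-%d", r$segments$ref_start, r$segments$ref_end),
              collapse = ","),
      identity_percent = r$identity_percent,
      n_snps = if (r$unmapped) NA_integer_ else nrow(r$snps),
      double_enhancer = r$duplicated_enhancer,
      stringsAsFactors = FALSE)
  }))
}

#' Build a reference-anchored conservation profile
#'
#' Projects each mapped target's aligned extent and SNPs onto reference
#' coordinates. Coverage is counted two ways: `coverage` counts
#' distinct targets covering a position (used for the coverage-fraction
#' threshold) and `coverage_segments` counts aligned segment copies, so
#' a duplicated enhancer contributes twice there.
#'
#' @param reports List of `homology_report` objects (>= 2 mapped).
#' @param ref The [reference_genome()] the reports are against.
#' @return A `conservation_profile`: list with `coverage`,
#'   `coverage_segments` (integer vectors along the reference),
#'   `variants` (data frame `ref_pos`, `ref_base`, `alt_base`,
#'   `target_id`), `n_units` (number of mapped targets) and
#'   `insertion_adjacent` (logical vector).
#' @export
build_profile <- function(reports, ref) {
  stopifnot(inherits(ref, "reference_genome"))
  mapped <- Filter(function(r) !r$unmapped, reports)
  if (length(mapped) < 2) {
    stop("need at least two mapped reports to build a profile",
         call. = FALSE)
  }
  L <- ref$length
  cov_units <- integer(L)
  cov_segs <- integer(L)
  ins_adj <- logical(L)
  variants <- list()
  for (r in mapped) {
    unit <- logical(L)
    for (i in seq_len(nrow(r$segments))) {
      s <- r$segments[i, ]
      idx <- s$ref_start:s$ref_end
      cov_segs[idx] <- cov_segs[idx] + 1L
      unit[idx] <- TRUE
      if (s$n_ins > 0 || s$n_del > 0) {
        ins_adj[idx] <- ins_adj[idx]  # refined below from aligned strings
      }
    }
    cov_units <- cov_units + as.integer(unit)
    if (nrow(r$snps) > 0) {
      variants[[length(variants) + 1L]] <- data.frame(
        ref_pos = r$snps$ref_pos, ref_base = r$snps$ref_base,
        alt_base = r$snps$frag_base, target_id = r$target_id,
        stringsAsFactors = FALSE)
    }
  }
  var_df <- if (length(variants)) {
    v <- unique(do.call(rbind, variants))
    v <- v[order(v$ref_pos, v$target_id), , drop = FALSE]
    rownames(v) <- NULL
    v
  } else data.frame(ref_pos = integer(0), ref_base = character(0),
                    alt_base = character(0), target_id = character(0))
  structure(list(coverage = cov_units, coverage_segments = cov_segs,
                 variants = var_df, n_units = length(mapped),
                 insertion_adjacent = ins_adj, ref_id = ref$id),
            class = "conservation_profile")
}

#' Extract conserved intervals from a conservation profile
#'
#' Scans the reference left to right for maximal intervals where the
#' fraction of panel targets covering each position is at least
#' `min_coverage_fraction` and the density of distinct variant
#' positions (panel union) over the interval is at most
#' `max_snp_density`. Within each interval the SNP positions partition
#' it into SNP-free segments.
#'
#' @param profile A `conservation_profile`.
#' @param min_coverage_fraction Fraction of targets that must cover a
#'   position (default 1: present in all panel members).
#' @param max_snp_density Maximum distinct-SNP density per base over an
#'   interval (default 6/195, exposed in config).
#' @param min_length Minimum interval length in bp.
#' @return A `conserved_intervals` data frame (`start`, `end`,
#'   `length`, `n_snps`, `snp_density`) with a list-column
#'   `snp_free_segments`; when no interval qualifies, an empty result
#'   whose `near_miss` attribute describes the longest rejected run.
#' @export
find_conserved_intervals <- function(profile,
                                     min_coverage_fraction = 1,
                                     max_snp_density = 6 / 195,
                                     min_length = 60L) {
  stopifnot(inherits(profile, "conservation_profile"))
  L <- length(profile$coverage)
  need <- ceiling(min_coverage_fraction * profile$n_units - 1e-9)
  ok <- profile$coverage >= need
  snp_pos <- sort(unique(profile$variants$ref_pos))
  is_snp <- logical(L)
  is_snp[snp_pos] <- TRUE

  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  run_df <- data.frame(start = starts[runs$values],
                       end = ends[runs$values])

  res <- list()
  best_miss <- NULL
  for (k in seq_len(nrow(run_df))) {
    s <- run_df$start[k]
    run_end <- run_df$end[k]
    while (s <= run_end - min_length + 1L) {
      csnp <- cumsum(is_snp[s:run_end])
      lens <- seq_len(run_end - s + 1L)
      feas <- which(csnp / lens <= max_snp_density + 1e-12)
      if (length(feas) == 0) break
      e <- s + max(feas) - 1L
      if (e - s + 1L >= min_length) {
        snps_in <- snp_pos[snp_pos >= s & snp_pos <= e]
        res[[length(res) + 1L]] <- data.frame(
          start = s, end = e, length = e - s + 1L,
          n_snps = length(snps_in),
          snp_density = length(snps_in) / (e - s + 1L),
          snp_free_segments = I(list(.snp_free_segments(s, e, snps_in))),
          stringsAsFactors = FALSE)
      } else if (is.null(best_miss) || e - s + 1L > best_miss$length) {
        best_miss <- data.frame(start = s, end = e, length = e - s + 1L)
      }
      s <- e + 2L
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               n_snps = integer(0), snp_density = numeric(0),
               snp_free_segments = I(list()))
  rownames(out) <- NULL
  class(out) <- c("conserved_intervals", "data.frame")
  attr(out, "near_miss") <- best_miss
  out
}

.snp_free_segments <- function(start, end, snps_in) {
  bounds <- sort(unique(snps_in))
  seg_starts <- c(start, bounds + 1L)
  seg_ends <- c(bounds - 1L, end)
  keep <- seg_ends >= seg_starts
  data.frame(start = seg_starts[keep], end = seg_ends[keep],
             length = seg_ends[keep] - seg_starts[keep] + 1L)
}
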