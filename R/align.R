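#' Alignment primitives: affine-gap alignment and oligo binding scan
#'
#' @name pairwise_align
#' @keywords internal
NULL

#' Reverse complement of a DNA string
#'
#' @param x Character DNA string (IUPAC letters allowed).
#' @return Reverse-complemented character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Default alignment scoring parameters
#'
#' Match +2, mismatch -3, gap open -5, gap extend -2; a gap of length L
#' costs `|open| + L * |extend|`. These are classic blast2seq-era
#' nucleotide defaults.
#'
#' @param match,mismatch,gap_open,gap_extend Scores (gap penalties are
#'   given as negative numbers).
#' @return Named list of scoring parameters.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = -5,
                         gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Optimal pairwise alignment with affine gap penalties
#'
#' Wraps the dynamic-programming aligner from Biostrings. `mode`
#' "global" is Needleman-Wunsch, "local" Smith-Waterman, and
#' "semiglobal" an overlap alignment (terminal gaps free).
#'
#' @param a,b Character DNA strings (pattern and subject).
#' @param mode One of "global", "local", "semiglobal".
#' @param params Scoring parameters from [align_params()].
#' @return An `alignment_result`: list with `score`, `identity`
#'   (matches / aligned columns), `a_start`, `a_end`, `b_start`,
#'   `b_end` (1-based inclusive), counts `n_match`, `n_mismatch`,
#'   `n_ins`, `n_del`, the aligned strings, and a `mismatches` data
#'   frame with 1-based positions on each sequence.
#' @export
align_affine <- function(a, b, mode = c("global", "local", "semiglobal"),
                         params = align_params()) {
  mode <- match.arg(mode)
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  type <- switch(mode, global = "global", local = "local",
                 semiglobal = "overlap")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = mat, gapOpening = -params$gap_open,
    gapExtension = -params$gap_extend)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  cols <- nchar(ap)
  pa_chars <- strsplit(ap, "")[[1]]
  sb_chars <- strsplit(as_, "")[[1]]
  n_match <- sum(pa_chars == sb_chars & pa_chars != "-")
  n_ins <- sum(sb_chars == "-")   # insertion in pattern relative to subject
  n_del <- sum(pa_chars == "-")
  n_mismatch <- cols - n_match - n_ins - n_del
  mt <- Biostrings::mismatchTable(pa)
  mism <- data.frame(
    a_pos = as.integer(mt$PatternStart),
    b_pos = as.integer(mt$SubjectStart),
    a_base = as.character(mt$PatternSubstring),
    b_base = as.character(mt$SubjectSubstring),
    stringsAsFactors = FALSE)
  mism <- mism[order(mism$b_pos), , drop = FALSE]
  rownames(mism) <- NULL
  structure(
    list(score = Biostrings::score(pa),
         identity = n_match / cols,
         a_start = IRanges::start(pattern(pa)),
         a_end = IRanges::end(pattern(pa)),
         b_start = IRanges::start(subject(pa)),
         b_end = IRanges::end(subject(pa)),
         n_match = n_match, n_mismatch = n_mismatch,
         n_ins = n_ins, n_del = n_del,
         aligned_a = ap, aligned_b = as_,
         mismatches = mism, mode = mode),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s score %.1f identity %.3f a[%d-%d] b[%d-%d]\n",
              x$mode, x$score, x$identity, x$a_start, x$a_end,
              x$b_start, x$b_end))
  invisible(x)
}

.empty_sites <- function() {
  data.frame(target_id = character(0), oligo = character(0),
             role = character(0), start = integer(0), end = integer(0),
             strand = character(0), n_mismatches = integer(0),
             mismatches = I(list()), stringsAsFactors = FALSE)
}

.site_mismatches <- function(oligo_seq, site_seq_plus, start, end, strand) {
  # oligo_seq is 5'->3'; on the minus strand the oligo reads along
  # decreasing reference coordinates.
  L <- nchar(oligo_seq)
  obs <- if (strand == "+") site_seq_plus else revcomp(site_seq_plus)
  oc <- strsplit(oligo_seq, "")[[1]]
  tc <- strsplit(obs, "")[[1]]
  idx <- which(oc != tc)
  if (length(idx) == 0) {
    return(data.frame(target_pos = integer(0), oligo_pos = integer(0),
                      offset3 = integer(0), target_base = character(0),
                      oligo_base = character(0), stringsAsFactors = FALSE))
  }
  tpos <- if (strand == "+") start + idx - 1L else end - idx + 1L
  data.frame(target_pos = as.integer(tpos), oligo_pos = as.integer(idx),
             offset3 = as.integer(L - idx + 1L),
             target_base = tc[idx], oligo_base = oc[idx],
             stringsAsFactors = FALSE)
}

#' Scan a target for ungapped oligo binding sites
#'
#' Every ungapped placement of the oligo on either strand of the target
#' with at most `max_mismatch` mismatching bases is reported. The
#' scanner is deliberately ungapped: a primer that only fits a template
#' with an indel is treated as not binding. IUPAC ambiguity letters in
#' the target match an oligo base only if the letters are identical
#' (conservative audit rule).
#'
#' @param olig An [oligo()] object, or a plain character sequence.
#' @param target Target DNA string (or a single `target_panel` row).
#' @param max_mismatch Maximum number of mismatches per site.
#' @param target_id Identifier copied into the result.
#' @return A `binding_sites` data frame with columns `target_id`,
#'   `oligo`, `role`, `start`, `end` (1-based inclusive on the target
#'   plus strand), `strand`, `n_mismatches` and a `mismatches`
#'   list-column of per-site mismatch tables giving the target
#'   position, the 5'-based oligo position, and the offset from the
#'   oligo 3' end (offset 1 = terminal base).
#' @export
scan_oligo <- function(olig, target, max_mismatch = 3, target_id = NA_character_) {
  stopifnot(max_mismatch >= 0)
  if (is.character(olig)) olig <- oligo("oligo", olig, "forward")
  stopifnot(inherits(olig, "oligo"))
  if (is.data.frame(target)) {
    if (is.na(target_id) && "target_id" %in% names(target)) {
      target_id <- target$target_id[1]
    }
    target <- target$sequence[1]
  }
  L <- olig$length
  if (L > nchar(target)) {
    warning("oligo '", olig$name, "' longer than target; no sites",
            call. = FALSE)
    return(.empty_sites())
  }
  subj <- Biostrings::DNAString(target)
  one_strand <- function(query, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(query), subj,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
    if (length(hits) == 0) return(.empty_sites())
    st <- IRanges::start(hits)
    en <- IRanges::end(hits)
    keep <- st >= 1 & en <= nchar(target)
    st <- st[keep]; en <- en[keep]
    if (length(st) == 0) return(.empty_sites())
    mm <- lapply(seq_along(st), function(i) {
      .site_mismatches(olig$sequence, substr(target, st[i], en[i]),
                       st[i], en[i], strand)
    })
    data.frame(target_id = target_id, oligo = olig$name, role = olig$role,
               start = as.integer(st), end = as.integer(en),
               strand = strand,
               n_mismatches = vapply(mm, nrow, integer(1)),
               mismatches = I(mm), stringsAsFactors = FALSE)
  }
  res <- rbind(one_strand(olig$sequence, "+"),
               one_strand(revcomp(olig$sequence), "-"))
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("binding_sites", "data.frame")
  res
}

#' Mismatch offsets from the oligo 3' end
#'
#' @param site A single-row `binding_sites` entry (or a data frame from
#'   which the first row is taken).
#' @return Sorted integer vector of offsets from the 3' end; offset 1
#'   means the 3'-terminal base mismatches; empty for a perfect site.
#' @export
mismatch_offsets <- function(site) {
  stopifnot(is.data.frame(site), nrow(site) >= 1)
  mm <- site$mismatches[[1]]
  sort(as.integer(mm$offset3))
}
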