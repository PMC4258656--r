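#' Domain constructors and readers for sequences and assay tables
#'
#' @name seq_io
#' @keywords internal
NULL

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

.check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), IUPAC_LETTERS)
  if (length(bad) > 0) {
    stop("non-nucleotide characters in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

.has_ambiguity <- function(x) {
  grepl("[^ACGT]", x)
}

#' Create a reference genome object
#'
#' The reference genome is the coordinate frame all positions in
#' reports are expressed against (1-based, inclusive).
#'
#' @param id Character identifier.
#' @param sequence DNA string (A/C/G/T; IUPAC ambiguity letters are
#'   accepted and flagged).
#' @return An object of class `reference_genome` with fields `id`,
#'   `sequence`, `length` and `has_ambiguity`.
#' @export
reference_genome <- function(id, sequence) {
  sequence <- .check_dna(sequence, paste0("reference '", id, "'"))
  structure(
    list(id = as.character(id), sequence = sequence,
         length = nchar(sequence),
         has_ambiguity = .has_ambiguity(sequence)),
    class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome> ", x$id, ": ", x$length, " bp",
      if (x$has_ambiguity) " (contains ambiguity codes)", "\n", sep = "")
  invisible(x)
}

#' Extract a 1-based inclusive sub-interval of a reference genome
#'
#' @param ref A `reference_genome`.
#' @param start,end 1-based inclusive bounds.
#' @return Character sequence of the sub-interval.
#' @export
ref_subseq <- function(ref, start, end) {
  stopifnot(inherits(ref, "reference_genome"))
  if (start < 1 || end > ref$length || start > end) {
    stop("interval [", start, ", ", end, "] outside reference bounds",
         call. = FALSE)
  }
  substr(ref$sequence, start, end)
}

#' Create a panel of target records
#'
#' A target record is one promoter variant: the sequence carried by a
#' transgenic event (or vector), possibly one of several copies within
#' the event.
#'
#' @param event Character vector of event names (e.g. "MON88913").
#' @param sequence Character vector of DNA sequences.
#' @param copy_label Label distinguishing multiple copies of the
#'   element within one event; defaults to "1".
#' @param crop,accession Optional annotation columns.
#' @return A `target_panel` data frame with one row per record and a
#'   `has_ambiguity` flag.
#' @export
target_panel <- function(event, sequence, copy_label = "1",
                         crop = NA_character_, accession = NA_character_) {
  sequence <- vapply(seq_along(sequence), function(i) {
    s <- .check_dna(sequence[i], paste0("record '", event[i], "'"))
    if (nchar(s) == 0) {
      stop("empty sequence for record '", event[i], "'", call. = FALSE)
    }
    s
  }, character(1))
  df <- data.frame(
    event = as.character(event),
    copy_label = rep_len(as.character(copy_label), length(event)),
    crop = rep_len(as.character(crop), length(event)),
    accession = rep_len(as.character(accession), length(event)),
    sequence = sequence,
    length = nchar(sequence),
    has_ambiguity = .has_ambiguity(sequence),
    stringsAsFactors = FALSE)
  key <- paste(df$event, df$copy_label, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicated (event, copy_label): ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  df$target_id <- key
  class(df) <- c("target_panel", "data.frame")
  df
}

#' Read a target panel from a FASTA file
#'
#' Headers of the form `event|copy_label|crop|accession` are split into
#' the corresponding fields; headers without `|` become the event name
#' with copy label "1".
#'
#' @param path Path to a FASTA file.
#' @return A `target_panel` data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("not readable as FASTA: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  pick <- function(i) vapply(fields, function(f) {
    if (length(f) >= i && nzchar(f[i])) f[i] else NA_character_
  }, character(1))
  event <- pick(1)
  copy_label <- pick(2)
  copy_label[is.na(copy_label)] <- "1"
  target_panel(event = event, sequence = as.character(set),
               copy_label = copy_label, crop = pick(3),
               accession = pick(4))
}

#' Write a target panel to FASTA
#'
#' Headers are emitted as `event|copy_label|crop|accession` (trailing
#' missing fields dropped) so that [read_fasta()] round-trips.
#'
#' @param panel A `target_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "target_panel"))
  hdr <- vapply(seq_len(nrow(panel)), function(i) {
    f <- c(panel$event[i], panel$copy_label[i], panel$crop[i],
           panel$accession[i])
    while (length(f) > 1 && is.na(f[length(f)])) f <- f[-length(f)]
    f[is.na(f)] <- ""
    paste(f, collapse = "|")
  }, character(1))
  set <- Biostrings::BStringSet(panel$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a reference genome from a minimal GenBank flat file
#'
#' Only the LOCUS name and the ORIGIN sequence block are used; features
#' and qualifiers are ignored. Lines in the ORIGIN block are expected to
#' start with a base index; if the numbering is malformed but the bases
#' parse, the sequence is still returned with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @return A `reference_genome`.
#' @export
read_genbank_minimal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus) > 0) strsplit(trimws(locus[1]), "[[:space:]]+")[[1]][2]
        else sub("\\.[^.]*$", "", basename(path))
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("no ORIGIN block in ", path, call. = FALSE)
  block <- lines[(ori[1] + 1):length(lines)]
  stop_at <- grep("^//", block)
  if (length(stop_at) > 0) block <- block[seq_len(stop_at[1] - 1)]
  if (!all(grepl("^[[:space:]]*[0-9]+[[:space:]]", block))) {
    warning("malformed ORIGIN numbering in ", path,
            "; bases parsed anyway", call. = FALSE)
  }
  seq <- toupper(gsub("[0-9[:space:]/]", "", paste(block, collapse = "")))
  if (nchar(seq) == 0) stop("empty ORIGIN block in ", path, call. = FALSE)
  reference_genome(id, seq)
}

#' Write a reference genome as a minimal GenBank flat file
#'
#' @param ref A `reference_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank_minimal <- function(ref, path) {
  stopifnot(inherits(ref, "reference_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear", ref$id,
                     ref$length), con)
  writeLines(sprintf("DEFINITION  %s.", ref$id), con)
  writeLines("ORIGIN", con)
  s <- tolower(ref$sequence)
  starts <- seq(1, nchar(s), by = 60)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Create an oligo (primer or probe)
#'
#' @param name Oligo name.
#' @param sequence DNA sequence, written 5' to 3'.
#' @param role One of "forward", "reverse", "probe".
#' @param reported_start,reported_end Optional 1-based inclusive
#'   interval on the reference, as printed in the source assay table.
#' @param mismatch_positions Optional integer vector of 5'-based
#'   positions within `sequence` flagged as differing from the
#'   reference (or from some templates) in the source table.
#' @return An `oligo` object.
#' @export
oligo <- function(name, sequence, role = c("forward", "reverse", "probe"),
                  reported_start = NA_integer_, reported_end = NA_integer_,
                  mismatch_positions = integer(0)) {
  role <- match.arg(role)
  sequence <- .check_dna(sequence, paste0("oligo '", name, "'"))
  if (nchar(sequence) < 10) {
    stop("oligo '", name, "' shorter than 10 nt", call. = FALSE)
  }
  structure(
    list(name = as.character(name), sequence = sequence, role = role,
         length = nchar(sequence),
         reported_start = as.integer(reported_start),
         reported_end = as.integer(reported_end),
         mismatch_positions = as.integer(mismatch_positions)),
    class = "oligo")
}

#' Create an assay (primer pair or primer/probe set)
#'
#' @param id Assay identifier (e.g. "M25").
#' @param oligos List of [oligo()] objects; at least one forward and one
#'   reverse primer.
#' @param kind One of "conventional", "taqman", "nested", "microarray".
#' @param reported_amplicon Optional printed amplicon size in bp.
#' @param size_consistent Whether the printed amplicon size agrees with
#'   the printed primer coordinates (some published tables are
#'   internally inconsistent).
#' @return An `assay` object.
#' @export
assay <- function(id, oligos,
                  kind = c("conventional", "taqman", "nested", "microarray"),
                  reported_amplicon = NA_integer_, size_consistent = TRUE) {
  kind <- match.arg(kind)
  stopifnot(all(vapply(oligos, inherits, logical(1), "oligo")))
  roles <- vapply(oligos, `[[`, character(1), "role")
  if (!any(roles == "forward") || !any(roles == "reverse")) {
    stop("assay '", id, "' lacks a forward or reverse primer",
         call. = FALSE)
  }
  if (kind == "taqman" && sum(roles == "probe") != 1) {
    stop("taqman assay '", id, "' must contain exactly one probe",
         call. = FALSE)
  }
  structure(
    list(id = as.character(id), oligos = oligos, kind = kind,
         reported_amplicon = as.integer(reported_amplicon),
         size_consistent = isTRUE(size_consistent)),
    class = "assay")
}

#' @export
print.assay <- function(x, ...) {
  cat("<assay> ", x$id, " (", x$kind, "), ", length(x$oligos),
      " oligos", sep = "")
  if (!is.na(x$reported_amplicon)) {
    cat(", reported amplicon ", x$reported_amplicon, " bp", sep = "")
  }
  cat("\n")
  for (o in x$oligos) {
    cat(sprintf("  %-8s %-22s %s", o$role, o$name, o$sequence))
    if (!is.na(o$reported_start)) {
      cat(sprintf("  [%d-%d]", o$reported_start, o$reported_end))
    }
    cat("\n")
  }
  invisible(x)
}

#' Read an assay table (TSV or JSON)
#'
#' The table has one row per oligo with columns `assay_id`, `role`,
#' `name`, `sequence` and optionally `reported_start`, `reported_end`,
#' `reported_amplicon`, `kind`, `mismatch_mask` (comma-separated
#' 5'-based positions flagged as mismatching the reference) and
#' `size_consistent`. Sequences are uppercased on read.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @return Named list of [assay()] objects, in table order.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  needed <- c("assay_id", "role", "name", "sequence")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("assay table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  opt_int <- function(col, i) {
    if (!col %in% names(df)) return(NA_integer_)
    v <- df[[col]][i]
    if (is.na(v) || v == "") NA_integer_ else as.integer(v)
  }
  ids <- unique(df$assay_id)
  res <- lapply(ids, function(id) {
    rows <- which(df$assay_id == id)
    oligos <- lapply(rows, function(i) {
      mask <- integer(0)
      if ("mismatch_mask" %in% names(df)) {
        m <- df$mismatch_mask[i]
        if (!is.na(m) && nzchar(m)) {
          mask <- as.integer(strsplit(m, ",", fixed = TRUE)[[1]])
        }
      }
      oligo(name = df$name[i], sequence = toupper(df$sequence[i]),
            role = df$role[i],
            reported_start = opt_int("reported_start", i),
            reported_end = opt_int("reported_end", i),
            mismatch_positions = mask)
    })
    kind <- if ("kind" %in% names(df)) df$kind[rows[1]] else "conventional"
    amp <- opt_int("reported_amplicon", rows[1])
    sc <- TRUE
    if ("size_consistent" %in% names(df)) {
      sc <- !identical(toupper(df$size_consistent[rows[1]]), "FALSE")
    }
    assay(id = id, oligos = oligos, kind = kind, reported_amplicon = amp,
          size_consistent = sc)
  })
  names(res) <- ids
  res
}

#' The bundled P35S screening assay table
#'
#' The 25 published P35S screening assays (24 collected methods M1-M24
#' plus the conserved-region TaqMan set M25), with printed binding
#' coordinates on the CaMV genome (GenBank NC_001497.1), printed
#' amplicon sizes, and per-oligo flags for bases printed as mismatching
#' the reference. Four assays (M9, M10, M22, M24) have printed amplicon
#' sizes inconsistent with their own printed coordinates and are
#' flagged `size_consistent = FALSE`.
#'
#' @return Named list of 25 [assay()] objects.
#' @export
p35s_assays <- function() {
  path <- system.file("extdata", "p35s_assays.tsv", package = "ampliscreen",
                      mustWork = TRUE)
  read_assay_table(path)
}
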