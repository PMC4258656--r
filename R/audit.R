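#' Assay auditing: binding sites, amplicons, coverage calls
#'
#' @name assay_audit
#' @keywords internal
NULL

#' Scan policy for assay auditing
#'
#' @param max_mismatch Maximum mismatches for a placement to count as a
#'   binding site. No mismatch threshold for "binding" is standard;
#'   the default of 3 is always reported alongside results, never
#'   silently applied.
#' @param critical_3prime A primer mismatch within this many bases of
#'   the 3' end (offset 1 = terminal base) predicts inefficient
#'   amplification.
#' @param max_product Maximum plausible PCR product size in bp.
#' @param probe_mismatch_fail Number of probe mismatches at or above
#'   which hybridisation is predicted inefficient.
#' @return A `scan_policy` list.
#' @export
scan_policy <- function(max_mismatch = 3L, critical_3prime = 4L,
                        max_product = 2000L, probe_mismatch_fail = 2L) {
  structure(list(max_mismatch = as.integer(max_mismatch),
                 critical_3prime = as.integer(critical_3prime),
                 max_product = as.integer(max_product),
                 probe_mismatch_fail = as.integer(probe_mismatch_fail)),
            class = "scan_policy")
}

#' Locate every oligo of an assay on a target
#'
#' Each oligo is scanned on both strands (orientation-agnostic: some
#' published "forward" primers sit downstream on the minus strand).
#' Sites exceeding the policy's mismatch cap are excluded. Absence of a
#' site is data, not an error.
#'
#' @param asy An [assay()].
#' @param target One-row `target_panel` or character sequence.
#' @param policy A [scan_policy()].
#' @return Named list (by oligo name) of `binding_sites` data frames.
#' @export
locate_assay <- function(asy, target, policy = scan_policy()) {
  stopifnot(inherits(asy, "assay"))
  sites <- lapply(asy$oligos, function(o) {
    scan_oligo(o, target, max_mismatch = policy$max_mismatch)
  })
  names(sites) <- vapply(asy$oligos, `[[`, character(1), "name")
  sites
}

#' Predict amplicons from located binding sites
#'
#' Enumerates all inward-facing forward/reverse site pairings with a
#' product no longer than `max_product`: a plus-strand site paired with
#' a minus-strand site downstream of it (either role may provide either
#' strand). The product spans from the leftmost site start to the
#' rightmost site end; size = rightmost end - leftmost start + 1.
#' Targets carrying a duplicated enhancer can yield several products.
#' For nested assays every forward/reverse combination is enumerated
#' and the smallest product is flagged as the scored (inner) one.
#'
#' @param sites Named list from [locate_assay()].
#' @param asy The [assay()] the sites belong to.
#' @param max_product Maximum product size in bp.
#' @return An `amplicon_prediction`: list with `assay_id`, `products`
#'   (data frame `start`, `end`, `size`, oligo names, strands, total
#'   mismatches, `inner` flag) and `n_products`.
#' @export
predict_amplicons <- function(sites, asy, max_product = 2000L) {
  roles <- vapply(asy$oligos, `[[`, character(1), "role")
  onames <- vapply(asy$oligos, `[[`, character(1), "name")
  fwd_names <- onames[roles == "forward"]
  rev_names <- onames[roles == "reverse"]
  prods <- list()
  for (fn in fwd_names) {
    for (rn in rev_names) {
      fs <- sites[[fn]]
      rs <- sites[[rn]]
      if (is.null(fs) || is.null(rs) || nrow(fs) == 0 || nrow(rs) == 0) next
      for (i in seq_len(nrow(fs))) {
        for (j in seq_len(nrow(rs))) {
          a <- fs[i, ]; b <- rs[j, ]
          if (a$strand == b$strand) next
          plus <- if (a$strand == "+") a else b
          minus <- if (a$strand == "+") b else a
          if (minus$start <= plus$end) next  # must face inward
          size <- minus$end - plus$start + 1L
          if (size > max_product) next
          prods[[length(prods) + 1L]] <- data.frame(
            forward = fn, reverse = rn,
            start = plus$start, end = minus$end, size = size,
            forward_strand = a$strand, reverse_strand = b$strand,
            n_mismatches = a$n_mismatches + b$n_mismatches,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  products <- if (length(prods)) do.call(rbind, prods) else
    data.frame(forward = character(0), reverse = character(0),
               start = integer(0), end = integer(0), size = integer(0),
               forward_strand = character(0), reverse_strand = character(0),
               n_mismatches = integer(0))
  products <- products[order(products$start, products$size), , drop = FALSE]
  rownames(products) <- NULL
  products$inner <- logical(nrow(products))
  if (nrow(products) > 0) {
    if (asy$kind == "nested") {
      products$inner[which.min(products$size)] <- TRUE
    } else {
      products$inner <- TRUE
    }
  }
  structure(list(assay_id = asy$id, products = products,
                 n_products = nrow(products)),
            class = "amplicon_prediction")
}

#' Build binding sites from the printed coordinates of an assay
#'
#' Places each oligo at its reported interval with the strand implied
#' by the assay's printed layout (reversed-layout assays print their
#' "forward" primer downstream on the minus strand). Useful for
#' coordinate arithmetic such as verifying printed amplicon sizes.
#'
#' @param asy An [assay()] with reported intervals.
#' @return Named list of one-row `binding_sites` data frames.
#' @export
sites_from_reported <- function(asy) {
  stopifnot(inherits(asy, "assay"))
  rev_layout <- .assay_layout_reversed(asy)
  sites <- lapply(asy$oligos, function(o) {
    if (is.na(o$reported_start)) return(.empty_sites())
    minus <- switch(o$role,
                    forward = rev_layout,
                    reverse = !rev_layout,
                    probe = FALSE)
    df <- data.frame(target_id = "reported", oligo = o$name,
                     role = o$role, start = o$reported_start,
                     end = o$reported_end,
                     strand = if (minus) "-" else "+",
                     n_mismatches = 0L,
                     mismatches = I(list(data.frame())),
                     stringsAsFactors = FALSE)
    class(df) <- c("binding_sites", "data.frame")
    df
  })
  names(sites) <- vapply(asy$oligos, `[[`, character(1), "name")
  sites
}

#' Classify the coverage of a target by an assay
#'
#' Status is NOT_COVERED when some primer has no binding site under the
#' policy or no inward-facing pair forms; PERFECT when every oligo
#' binds with zero mismatches (and, for probe assays, the probe lies
#' inside a product); otherwise PRIMER_MISMATCH or PROBE_MISMATCH
#' according to where the mismatches sit. The predicted outcome is
#' "fail" for NOT_COVERED; "inefficient" when a primer mismatch falls
#' within the critical 3' window, the probe carries at least
#' `probe_mismatch_fail` mismatches, or the probe has no ungapped site
#' at all (e.g. an indel in its binding site); otherwise "amplify".
#'
#' @param asy An [assay()].
#' @param target One-row `target_panel` or character sequence.
#' @param policy A [scan_policy()].
#' @return A `coverage_call`: list with `assay_id`, `target_id`,
#'   `status`, `predicted_outcome`, `detail` (per-oligo mismatch
#'   offsets), `n_products` and the `amplicon_prediction`.
#' @export
classify_coverage <- function(asy, target, policy = scan_policy()) {
  target_id <- if (is.data.frame(target)) target$target_id[1] else
    NA_character_
  sites <- locate_assay(asy, target, policy)
  pred <- predict_amplicons(sites, asy, policy$max_product)
  roles <- vapply(asy$oligos, `[[`, character(1), "role")
  onames <- vapply(asy$oligos, `[[`, character(1), "name")
  primer_names <- onames[roles != "probe"]
  probe_names <- onames[roles == "probe"]

  primer_missing <- any(vapply(primer_names, function(nm) {
    nrow(sites[[nm]]) == 0
  }, logical(1)))
  if (primer_missing || pred$n_products == 0) {
    call <- list(assay_id = asy$id, target_id = target_id,
                 status = "NOT_COVERED", predicted_outcome = "fail",
                 detail = list(), n_products = 0L, prediction = pred)
    class(call) <- "coverage_call"
    return(call)
  }

  # per-oligo detail from the best (fewest-mismatch) site that is
  # consistent with a predicted product
  prods <- pred$products
  in_product <- function(st, en) {
    any(st >= prods$start & en <= prods$end)
  }
  detail <- list()
  primer_offsets <- integer(0)
  primer_mm <- 0L
  for (nm in primer_names) {
    s <- sites[[nm]]
    s <- s[vapply(seq_len(nrow(s)),
                  function(i) in_product(s$start[i], s$end[i]),
                  logical(1)), , drop = FALSE]
    if (nrow(s) == 0) s <- sites[[nm]]
    best <- s[which.min(s$n_mismatches), , drop = FALSE]
    off <- mismatch_offsets(best)
    detail[[nm]] <- off
    primer_offsets <- c(primer_offsets, off)
    primer_mm <- primer_mm + best$n_mismatches
  }
  probe_mm <- 0L
  probe_siteless <- FALSE
  for (nm in probe_names) {
    s <- sites[[nm]]
    if (nrow(s) == 0) {
      probe_siteless <- TRUE
      detail[[nm]] <- NA_integer_
      next
    }
    sp <- s[vapply(seq_len(nrow(s)),
                   function(i) in_product(s$start[i], s$end[i]),
                   logical(1)), , drop = FALSE]
    if (nrow(sp) == 0) sp <- s
    best <- sp[which.min(sp$n_mismatches), , drop = FALSE]
    detail[[nm]] <- mismatch_offsets(best)
    probe_mm <- probe_mm + best$n_mismatches
  }

  status <- if (primer_mm == 0 && probe_mm == 0 && !probe_siteless) {
    "PERFECT"
  } else if (primer_mm > 0) {
    "PRIMER_MISMATCH"
  } else {
    "PROBE_MISMATCH"
  }
  outcome <- if (any(primer_offsets <= policy$critical_3prime) ||
                 probe_mm >= policy$probe_mismatch_fail || probe_siteless) {
    "inefficient"
  } else {
    "amplify"
  }
  if (status == "PERFECT") outcome <- "amplify"
  call <- list(assay_id = asy$id, target_id = target_id, status = status,
               predicted_outcome = outcome, detail = detail,
               n_products = pred$n_products, prediction = pred)
  class(call) <- "coverage_call"
  call
}

#' @export
print.coverage_call <- function(x, ...) {
  cat(sprintf("<coverage_call> %s vs %s: %s (%s), %d product(s)\n",
              x$assay_id, x$target_id, x$status, x$predicted_outcome,
              x$n_products))
  invisible(x)
}

#' Audit a collection of assays against a collection of targets
#'
#' @param assays Named list of [assay()] objects.
#' @param panel A `target_panel`.
#' @param policy A [scan_policy()].
#' @return A `coverage_matrix`: list with `calls` (long data frame of
#'   assay x target status/outcome/product count), `status` and
#'   `outcome` matrices (assays x targets), and `summary`, a per-assay
#'   data frame with the number of targets predicted to fail and a
#'   flag for targets yielding multiple products (quantification-bias
#'   warning for double-enhancer promoters).
#' @export
coverage_matrix <- function(assays, panel, policy = scan_policy()) {
  stopifnot(length(assays) >= 1, inherits(panel, "target_panel"),
            nrow(panel) >= 1)
  calls <- list()
  for (a in assays) {
    for (i in seq_len(nrow(panel))) {
      cl <- classify_coverage(a, panel[i, ], policy)
      calls[[length(calls) + 1L]] <- data.frame(
        assay_id = cl$assay_id, target_id = cl$target_id,
        status = cl$status, predicted_outcome = cl$predicted_outcome,
        n_products = cl$n_products, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, calls)
  ids <- vapply(assays, `[[`, character(1), "id")
  tids <- panel$target_id
  status <- matrix(long$status, nrow = length(ids), byrow = TRUE,
                   dimnames = list(ids, tids))
  outcome <- matrix(long$predicted_outcome, nrow = length(ids),
                    byrow = TRUE, dimnames = list(ids, tids))
  nprod <- matrix(long$n_products, nrow = length(ids), byrow = TRUE,
                  dimnames = list(ids, tids))
  summary <- data.frame(
    assay_id = ids,
    n_fail = rowSums(outcome == "fail"),
    n_inefficient = rowSums(outcome == "inefficient"),
    n_amplify = rowSums(outcome == "amplify"),
    n_multiproduct = rowSums(nprod > 1),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(calls = long, status = status, outcome = outcome,
                 n_products = nprod, summary = summary,
                 policy = policy),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat("<coverage_matrix> ", nrow(x$status), " assays x ", ncol(x$status),
      " targets; per-assay failures:\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write a coverage matrix as TSV
#'
#' @param cm A `coverage_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "coverage_matrix"))
  df <- data.frame(assay_id = rownames(cm$status), cm$status,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
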