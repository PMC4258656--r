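#' qPCR standard curves, efficiency, ENGL checks, replicate statistics
#'
#' @name qpcr_stats
#' @keywords internal
NULL

#' Read a qPCR replicate table
#'
#' TSV with columns `copies` and `ct` (empty `ct` cell = no
#' amplification), optionally `event`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with numeric `copies` and `ct` (NA for negative
#'   reactions).
#' @export
read_qpcr_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("copies", "ct") %in% names(df))) {
    stop("qPCR table needs columns 'copies' and 'ct'", call. = FALSE)
  }
  df$copies <- as.numeric(df$copies)
  df$ct <- suppressWarnings(as.numeric(df$ct))
  df
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(copies). By default all
#' replicate points enter the regression; `use_level_means` fits the
#' per-level mean Ct instead.
#'
#' @param levels Data frame with columns `copies` and `ct` (NA = no
#'   amplification; negatives are dropped from the fit).
#' @param use_level_means Fit level means rather than all replicates.
#' @return A `standard_curve`: list with `slope` (Ct per log10 copies),
#'   `intercept`, `r_squared`, `efficiency` (percent), `n_levels`,
#'   `n_points` and the input data.
#' @export
fit_standard_curve <- function(levels, use_level_means = FALSE) {
  stopifnot(is.data.frame(levels),
            all(c("copies", "ct") %in% names(levels)))
  d <- levels[!is.na(levels$ct), , drop = FALSE]
  lv <- unique(d$copies)
  if (length(lv) < 3) {
    stop("need at least 3 dilution levels with a positive Ct",
         call. = FALSE)
  }
  if (use_level_means) {
    d <- do.call(rbind, lapply(split(d, d$copies), function(g) {
      data.frame(copies = g$copies[1], ct = mean(g$ct))
    }))
  }
  x <- log10(d$copies)
  if (stats::var(x) == 0) stop("zero variance in log10(copies)",
                               call. = FALSE)
  fit <- stats::lm(ct ~ x, data = data.frame(ct = d$ct, x = x))
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  eff <- if (slope < 0) efficiency_from_slope(slope) else NA_real_
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, efficiency = eff,
                 n_levels = length(lv), n_points = nrow(d),
                 data = d, use_level_means = use_level_means),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(paste0("<standard_curve> slope %.3f, intercept %.2f, ",
                     "R^2 %.4f, efficiency %.2f%% (%d levels, %d points)\n"),
              x$slope, x$intercept, x$r_squared, x$efficiency,
              x$n_levels, x$n_points))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' E = (10^(-1/slope) - 1) * 100, reported to 0.01 percent. A slope of
#' -3.3219 (perfect doubling per cycle) gives 100%.
#'
#' @param slope Standard-curve slope in Ct per log10(copies); must be
#'   negative.
#' @return Efficiency in percent, rounded to two decimals.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.finite(slope) || slope >= 0) {
    stop("efficiency is defined only for negative slopes", call. = FALSE)
  }
  round((10^(-1 / slope) - 1) * 100, 2)
}

#' ENGL method-performance verdict
#'
#' Minimum performance requirements for quantitative GMO methods:
#' slope between -3.6 and -3.1 (inclusive) and R^2 at least 0.98.
#'
#' @param slope Standard-curve slope.
#' @param r_squared Regression R^2.
#' @return An `engl_verdict` list with `slope_ok`, `r2_ok`, `overall`.
#' @export
engl_verdict <- function(slope, r_squared) {
  slope_ok <- slope >= -3.6 && slope <= -3.1
  r2_ok <- r_squared >= 0.98
  structure(list(slope_ok = slope_ok, r2_ok = r2_ok,
                 overall = slope_ok && r2_ok),
            class = "engl_verdict")
}

#' Replicate-level statistics for one dilution level
#'
#' Mean Ct, sample standard deviation (n-1 denominator) and relative
#' standard deviation (SD/mean * 100, to two decimals) of the positive
#' replicates. Mirroring published LOD tables, the statistics are
#' reported only when every replicate was positive.
#'
#' @param cts Numeric vector of Ct values of the positive replicates
#'   (use NA for negative reactions if included).
#' @param n_total Total number of replicates attempted.
#' @param copies Template copy number of the level (annotation).
#' @return A `replicate_level`: list with `copies`, `n_positive`,
#'   `n_total`, `mean_ct`, `sd_ct`, `rsd_percent` (NA unless all
#'   replicates positive; SD/RSD NA for a single replicate).
#' @export
replicate_stats <- function(cts, n_total = length(cts),
                            copies = NA_real_) {
  stopifnot(n_total >= 1)
  pos <- cts[!is.na(cts)]
  n_pos <- length(pos)
  if (n_pos > n_total) stop("more positives than replicates", call. = FALSE)
  all_pos <- n_pos == n_total
  mean_ct <- if (n_pos > 0 && all_pos) mean(pos) else NA_real_
  sd_ct <- if (all_pos && n_pos > 1) stats::sd(pos) else NA_real_
  rsd <- if (all_pos && n_pos > 1) round(100 * sd_ct / mean_ct, 2) else
    NA_real_
  structure(list(copies = copies, n_positive = n_pos, n_total = n_total,
                 mean_ct = mean_ct, sd_ct = sd_ct, rsd_percent = rsd,
                 single_replicate = n_pos == 1),
            class = "replicate_level")
}

.level_df <- function(levels) {
  if (is.data.frame(levels)) return(levels)
  do.call(rbind, lapply(levels, function(l) {
    data.frame(copies = l$copies, n_positive = l$n_positive,
               n_total = l$n_total,
               rsd_percent = l$rsd_percent %||% NA_real_)
  }))
}

#' Call the limit of detection from a dilution series
#'
#' The LOD is the lowest copy number at which every replicate was
#' positive, provided every higher level is also all-positive. A
#' monotonicity violation (an intermediate level not all-positive)
#' pushes the LOD above the violating level, with a warning.
#'
#' @param levels Data frame with columns `copies`, `n_positive`,
#'   `n_total` (or a list of [replicate_stats()] results).
#' @return LOD in copies, or NA (with a message in the `reason`
#'   attribute) when no level qualifies.
#' @export
call_lod <- function(levels) {
  d <- .level_df(levels)
  d <- d[order(-d$copies), , drop = FALSE]
  all_pos <- d$n_positive == d$n_total
  if (!any(all_pos)) {
    out <- NA_real_
    attr(out, "reason") <- "no all-positive level"
    return(out)
  }
  # longest all-positive prefix going down the dilution series
  run <- cumprod(as.integer(all_pos))
  lod <- min(d$copies[run == 1])
  if (any(all_pos[run == 0])) {
    warning("non-monotone hit pattern: all-positive level below a ",
            "failing one ignored", call. = FALSE)
  }
  lod
}

#' Call the limit of quantification
#'
#' Two selectable rules: "rsd" (default) takes the lowest all-positive
#' level at or above the LOD whose replicate RSD does not exceed the
#' threshold; "factor" takes `factor_over_lod` times the LOD, the
#' LOD-LOQ relationship used in measurement guidance documents.
#'
#' @param levels As in [call_lod()]; the "rsd" rule additionally needs
#'   an `rsd_percent` column.
#' @param rule "rsd" or "factor".
#' @param rsd_threshold Maximum RSD in percent (default 25).
#' @param factor_over_lod Multiplier for the "factor" rule (default 5).
#' @return LOQ in copies, or NA with a `reason` attribute when the
#'   rule is unreachable.
#' @export
call_loq <- function(levels, rule = c("rsd", "factor"),
                     rsd_threshold = 25, factor_over_lod = 5) {
  rule <- match.arg(rule)
  lod <- suppressWarnings(call_lod(levels))
  if (is.na(lod)) {
    out <- NA_real_
    attr(out, "reason") <- "LOD undefined"
    return(out)
  }
  if (rule == "factor") return(factor_over_lod * lod)
  d <- .level_df(levels)
  ok <- d$n_positive == d$n_total & d$copies >= lod &
    !is.na(d$rsd_percent) & d$rsd_percent <= rsd_threshold
  if (!any(ok)) {
    out <- NA_real_
    attr(out, "reason") <- "no all-positive level meets the RSD threshold"
    return(out)
  }
  min(d$copies[ok])
}

#' The bundled qPCR sensitivity table
#'
#' Published replicate summaries (hit ratio, mean Ct, SD, RSD) for five
#' transgenic events assayed with the conserved-region quantitative
#' method over a 1-80 copy dilution series, as shipped in
#' `extdata/qpcr_sensitivity.tsv`.
#'
#' @return Data frame with columns `event`, `copies`, `n_positive`,
#'   `n_total`, `mean_ct`, `sd_ct`, `rsd_percent`.
#' @export
qpcr_sensitivity_table <- function() {
  path <- system.file("extdata", "qpcr_sensitivity.tsv",
                      package = "ampliscreen", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df
}

#' The bundled standard-curve parameter table
#'
#' Published standard-curve parameters (R^2 and slope) for five
#' transgenic events assayed with the conserved-region quantitative
#' method.
#'
#' @return Data frame with columns `event`, `r_squared`, `slope`.
#' @export
qpcr_curve_table <- function() {
  path <- system.file("extdata", "qpcr_curves.tsv",
                      package = "ampliscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Simulate a qPCR dilution series with known efficiency
#'
#' Generates replicate Ct values from the single-hit model
#' Ct = intercept + slope * log10(copies) with Gaussian noise, where
#' slope = -1 / log10(1 + E/100). Used for parameter-recovery checks.
#'
#' @param efficiency True amplification efficiency in percent.
#' @param copies Vector of dilution levels.
#' @param n_replicates Replicates per level.
#' @param intercept Ct at 1 copy.
#' @param noise_sd Gaussian Ct noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame with columns `copies` and `ct`.
#' @export
simulate_dilution_series <- function(efficiency = 100,
                                     copies = 10^(1:5),
                                     n_replicates = 3,
                                     intercept = 40, noise_sd = 0.1,
                                     seed = 1L) {
  slope <- -1 / log10(1 + efficiency / 100)
  .local_rng(seed, {
    d <- expand.grid(rep = seq_len(n_replicates), copies = copies)
    data.frame(copies = d$copies,
               ct = intercept + slope * log10(d$copies) +
                 stats::rnorm(nrow(d), 0, noise_sd))
  })
}
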