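# Independent oracles used across the suite. These deliberately share
# no code with the package: the scanner oracle is a positionwise
# Hamming scan, the aligner oracle a three-matrix affine DP written
# from the recurrences, and the Tm oracle a longhand nearest-neighbor
# sum typed in from the unified parameter table.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# every ungapped placement of `olig` (5'->3') on either strand of
# `target` with at most k mismatches
scan_oracle <- function(olig, target, k) {
  L <- nchar(olig)
  n <- nchar(target)
  hits <- list()
  if (L > n) return(data.frame(start = integer(0), end = integer(0),
                               strand = character(0), mm = integer(0)))
  oc <- strsplit(olig, "")[[1]]
  rcc <- strsplit(rc_oracle(olig), "")[[1]]
  tc <- strsplit(target, "")[[1]]
  for (s in 1:(n - L + 1)) {
    win <- tc[s:(s + L - 1)]
    mm_p <- sum(win != oc)
    if (mm_p <= k) {
      hits[[length(hits) + 1]] <- data.frame(start = s, end = s + L - 1,
                                             strand = "+", mm = mm_p)
    }
    mm_m <- sum(win != rcc)
    if (mm_m <= k) {
      hits[[length(hits) + 1]] <- data.frame(start = s, end = s + L - 1,
                                             strand = "-", mm = mm_m)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mm = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), ]
}

# affine-gap DP oracle; a gap of length L costs |go| + L * |ge|
dp_align_oracle <- function(a, b, mode = c("global", "local"),
                            match = 2, mismatch = -3, go = -5, ge = -2) {
  mode <- match.arg(mode)
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (mode == "global") {
    for (i in 2:(n + 1)) Ix[i, 1] <- go + ge * (i - 1)
    for (j in 2:(m + 1)) Iy[1, j] <- go + ge * (j - 1)
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  best_local <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      if (mode == "local") M[i, j] <- max(M[i, j], s, 0)
      Ix[i, j] <- max(M[i - 1, j] + go + ge, Iy[i - 1, j] + go + ge,
                      Ix[i - 1, j] + ge)
      Iy[i, j] <- max(M[i, j - 1] + go + ge, Ix[i, j - 1] + go + ge,
                      Iy[i, j - 1] + ge)
      if (mode == "local" && M[i, j] > best_local) best_local <- M[i, j]
    }
  }
  if (mode == "global") max(M[n + 1, m + 1], Ix[n + 1, m + 1],
                            Iy[n + 1, m + 1])
  else best_local
}

# longhand nearest-neighbor Tm (unified parameters, 1 M -> salt-
# corrected), independent of the package implementation
tm_oracle <- function(seq, na_mM = 50, oligo_nM = 200) {
  dh_tab <- list(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
                 CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
                 CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
                 CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds_tab <- list(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
                 CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
                 CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
                 CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dh <- 0; ds <- 0
  for (i in 1:(n - 1)) {
    st <- paste0(ch[i], ch[i + 1])
    dh <- dh + dh_tab[[st]]
    ds <- ds + ds_tab[[st]]
  }
  for (endb in c(ch[1], ch[n])) {
    if (endb %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  selfc <- identical(seq, rc_oracle(seq))
  if (selfc) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1) * log(na_mM / 1000)
  ct <- oligo_nM * 1e-9
  dh * 1000 / (ds + 1.9872 * log(ct / ifelse(selfc, 1, 4))) - 273.15
}

# closed-form simple linear regression (for the standard-curve oracle)
ols_oracle <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  slope <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  intercept <- ym - slope * xm
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - ym)^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# rescale a sample to an exact mean and sample SD
rescale_exact <- function(x, mean_target, sd_target) {
  z <- (x - mean(x)) / stats::sd(x)
  z * sd_target + mean_target
}
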