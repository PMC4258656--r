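test_that("efficiency follows the slope formula", {
  expect_equal(efficiency_from_slope(-1 / log10(2)), 100)
  expect_equal(efficiency_from_slope(-3.411), 96.41, tolerance = 0.011)
  expect_equal(efficiency_from_slope(-3.226), 104.17, tolerance = 0.011)
  expect_error(efficiency_from_slope(3.3), "negative")
  expect_error(efficiency_from_slope(0), "negative")
})

test_that("standard-curve fitting matches a closed-form OLS oracle", {
  # perfect doubling: Ct drops one cycle per doubling of template
  lv <- rep(10^(1:5), each = 3)
  d <- data.frame(copies = lv, ct = 38 - log2(lv))
  sc <- fit_standard_curve(d)
  expect_equal(sc$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(sc$r_squared, 1)
  expect_equal(sc$efficiency, 100)

  set.seed(33)
  for (rep in 1:25) {
    d2 <- simulate_dilution_series(runif(1, 85, 110), seed = rep,
                                   noise_sd = 0.3)
    sc2 <- fit_standard_curve(d2)
    o <- ols_oracle(log10(d2$copies), d2$ct)
    expect_equal(sc2$slope, o$slope, tolerance = 1e-9)
    expect_equal(sc2$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(sc2$r_squared, o$r2, tolerance = 1e-9)
  }

  # noise-free replicates on a line give R^2 = 1 whatever the slope
  lv3 <- rep(c(10, 100, 1000, 10000, 100000), each = 3)
  d3 <- data.frame(copies = lv3, ct = 41 - 2.9 * log10(lv3))
  sc3 <- fit_standard_curve(d3)
  expect_equal(sc3$r_squared, 1)
  expect_equal(sc3$slope, -2.9, tolerance = 1e-9)

  expect_error(fit_standard_curve(data.frame(copies = c(10, 100),
                                             ct = c(35, 31))),
               "3 dilution levels")
  expect_error(fit_standard_curve(data.frame(copies = rep(10, 4),
                                             ct = c(35, 35.1, 34.9, 35))),
               "3 dilution levels")
})

test_that("level-mean fitting is available and distinct", {
  set.seed(44)
  d <- simulate_dilution_series(100, noise_sd = 0.4, seed = 9)
  all_points <- fit_standard_curve(d)
  means <- fit_standard_curve(d, use_level_means = TRUE)
  expect_equal(means$n_points, 5)
  expect_equal(all_points$slope, means$slope, tolerance = 0.05)
})

test_that("replicate statistics mirror published table conventions", {
  # reconstruct the TC1507 50-copy row: mean 33.31, SD 0.36 -> RSD 1.08
  set.seed(55)
  cts <- rescale_exact(rnorm(10), 33.31, 0.36)
  rl <- replicate_stats(cts, n_total = 10, copies = 50)
  expect_equal(rl$n_positive, 10)
  expect_equal(rl$mean_ct, 33.31, tolerance = 1e-9)
  expect_equal(rl$sd_ct, 0.36, tolerance = 1e-9)
  expect_equal(rl$rsd_percent, 1.08)

  one <- replicate_stats(35.2, n_total = 1)
  expect_true(one$single_replicate)
  expect_true(is.na(one$sd_ct))

  const <- replicate_stats(rep(34, 5), n_total = 5)
  expect_equal(const$sd_ct, 0)
  expect_equal(const$rsd_percent, 0)

  # statistics withheld unless every replicate is positive
  partial <- replicate_stats(c(36.1, 36.8, NA), n_total = 3)
  expect_equal(partial$n_positive, 2)
  expect_true(is.na(partial$mean_ct))
  expect_true(is.na(partial$rsd_percent))

  # RSD is invariant under rescaling of the Ct values
  x <- c(33.1, 33.5, 33.9, 34.2)
  r1 <- replicate_stats(x, 4)$rsd_percent
  r2 <- replicate_stats(3 * x, 4)$rsd_percent
  expect_equal(r1, r2)
})

test_that("LOD follows the all-positive rule down the series", {
  d <- data.frame(copies = c(80, 50, 40, 20, 10, 5, 1),
                  n_positive = c(10, 10, 10, 10, 10, 8, 4),
                  n_total = c(10, 10, 10, 10, 10, 10, 12))
  expect_equal(call_lod(d), 10)

  expect_equal(call_lod(data.frame(copies = c(100, 10, 1),
                                   n_positive = c(5, 5, 5),
                                   n_total = c(5, 5, 5))), 1)

  # non-monotone table: the all-positive level below a failure is
  # ignored, with a warning
  nm <- data.frame(copies = c(100, 50, 10),
                   n_positive = c(5, 4, 5), n_total = c(5, 5, 5))
  expect_warning(lod <- call_lod(nm), "non-monotone")
  expect_equal(lod, 100)

  none <- data.frame(copies = c(10, 1), n_positive = c(3, 1),
                     n_total = c(5, 5))
  expect_true(is.na(call_lod(none)))
})

test_that("LOQ supports the RSD rule and the LOD-multiple rule", {
  tab <- qpcr_sensitivity_table()
  for (ev in unique(tab$event)) {
    d <- tab[tab$event == ev, ]
    expect_equal(call_lod(d), 10, info = ev)
    # every all-positive level passes a 25% RSD threshold, so the RSD
    # rule bottoms out at the LOD
    expect_equal(call_loq(d, "rsd", rsd_threshold = 25), 10, info = ev)
    # the LOD-multiple relationship gives the published-style call
    expect_equal(call_loq(d, "factor", factor_over_lod = 5), 50, info = ev)
    # an unreachable RSD threshold is reported, not invented
    expect_true(is.na(call_loq(d, "rsd", rsd_threshold = 0)), info = ev)
  }
})

test_that("ENGL verdict boundaries are inclusive", {
  expect_true(engl_verdict(-3.6, 0.99)$overall)
  expect_true(engl_verdict(-3.1, 0.99)$overall)
  expect_true(engl_verdict(-3.3, 0.98)$overall)
  expect_false(engl_verdict(-3.61, 0.99)$overall)
  expect_false(engl_verdict(-3.09, 0.99)$overall)
  expect_false(engl_verdict(-3.3, 0.979)$overall)
  v <- engl_verdict(-2.0, 0.99)
  expect_false(v$slope_ok)
  expect_true(v$r2_ok)
  expect_equal(v$overall, v$slope_ok && v$r2_ok)
})

test_that("qPCR tables read empty cells as negative reactions", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("copies\tct", "100\t35.1", "100\t35.3", "10\t38.0",
               "10\t", "1\t"), tf)
  d <- read_qpcr_table(tf)
  expect_equal(sum(is.na(d$ct)), 2)
  expect_equal(nrow(d), 5)
})
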