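test_that("bipolar derivation cancels common-mode components", {
  a <- rnorm(100)
  expect_equal(bipolar_derive(a, a), rep(0, 100))
  expect_equal(bipolar_derive(a, rep(0, 100)), a)
  # common-mode 50 Hz line on both electrodes cancels below -60 dB:
  # differential 8 and 12 Hz signals survive, the shared line does not
  t <- (0:9999) / 1000
  line <- sin(2 * pi * 50 * t)
  a <- 0.5 * sin(2 * pi * 8 * t) + line
  b <- 0.5 * sin(2 * pi * 12 * t) + line
  d <- bipolar_derive(a, b)
  p <- welch_psd(d, 1000)
  line_bin <- which.min(abs(p$freq - 50))
  pure <- welch_psd(line, 1000)
  atten_db <- 10 * log10(p$psd[line_bin] / pure$psd[line_bin])
  expect_lt(atten_db, -60)
  expect_error(bipolar_derive(a, b[1:10]), "equal length")
})

test_that("the 50 Hz notch removes line noise and spares the passband", {
  t <- (0:9999) / 1000
  s50 <- sin(2 * pi * 50 * t)
  atten <- 20 * log10(sd(notch_50(s50, 1000)) / sd(s50))
  expect_lt(atten, -30)
  s10 <- sin(2 * pi * 10 * t)
  ripple <- abs(20 * log10(sd(notch_50(s10, 1000)) / sd(s10)))
  expect_lt(ripple, 1)
  s55 <- sin(2 * pi * 55 * t)
  ripple55 <- abs(20 * log10(sd(notch_50(s55, 1000)) / sd(s55)))
  expect_lt(ripple55, 1)
  dc <- rep(2, 3000)
  expect_lt(max(abs(notch_50(dc, 1000) - 2)), 0.01)
  expect_error(notch_50(s50, 90), "twice")
})

test_that("Welch PSD conserves variance and localizes sinusoids", {
  set.seed(6)
  x <- rnorm(60000)                          # 60 s at 1 kHz
  p <- welch_psd(x, 1000)
  df <- p$freq[2] - p$freq[1]
  expect_equal(df, 0.5)
  expect_equal(sum(p$psd) * df / var(x), 1, tolerance = 0.05)
  # pure 32 Hz sinusoid peaks at the 32 Hz bin
  t <- (0:19999) / 1000
  s <- sin(2 * pi * 32 * t)
  p <- welch_psd(s, 1000)
  expect_equal(p$freq[which.max(p$psd)], 32)
  # doubling the amplitude quadruples the power
  p2 <- welch_psd(2 * s, 1000)
  expect_equal(max(p2$psd) / max(p$psd), 4, tolerance = 1e-9)
  expect_error(welch_psd(rnorm(100), 1000), "two Welch segments")
})

test_that("PSD normalization makes the 1-80 Hz window sum to one", {
  set.seed(12)
  p <- welch_psd(rnorm(30000), 1000)
  np <- normalize_psd(p)
  inb <- np$freq >= 1 & np$freq <= 80
  expect_equal(sum(np$norm_psd[inb]), 1, tolerance = 1e-9)
  # flat spectrum: equal bins; two equal lines: 0.5 each
  flat <- list(freq = seq(0, 100, by = 0.5), psd = rep(2, 201))
  nf <- normalize_psd(flat)
  expect_equal(length(unique(round(nf$norm_psd, 12))), 1)
  two <- list(freq = seq(0, 100, by = 0.5), psd = rep(0, 201))
  two$psd[two$freq == 10] <- 5
  two$psd[two$freq == 40] <- 5
  nt <- normalize_psd(two)
  expect_equal(nt$norm_psd[nt$freq == 10], 0.5)
  expect_equal(nt$norm_psd[nt$freq == 40], 0.5)
})

test_that("band powers follow the seven-band scheme with the 50 Hz bin excluded", {
  scheme <- band_scheme()
  expect_equal(nrow(scheme), 7)
  expect_true(all(scheme$lo[-1] > head(scheme$hi, -1)))    # non-overlapping
  expect_true(scheme$hi[6] < 50 && scheme$lo[7] > 50)
  freq <- seq(0, 100, by = 0.5)
  line <- list(freq = freq, psd = as.numeric(freq == 32))
  bp <- band_relative_power(normalize_psd(line))
  expect_equal(unname(bp["high_beta"]), 1)
  # flat normalized spectrum: band power proportional to bin count
  flat <- normalize_psd(list(freq = freq, psd = rep(1, length(freq))))
  bp <- band_relative_power(flat)
  widths <- 2 * (scheme$hi - scheme$lo) + 1
  widths[7] <- widths[7]                                   # 50 Hz outside band
  expect_equal(unname(bp / bp[1]), widths / widths[1], tolerance = 1e-9)
  # 50 Hz line contributes to no band
  l50 <- normalize_psd(list(freq = freq, psd = as.numeric(freq == 50) + 0.001))
  expect_lt(sum(band_relative_power(l50)), 0.5)
})

test_that("frequency weighting flattens a 1/f spectrum and ramps white noise", {
  freq <- seq(1, 80, by = 0.5)
  spec <- matrix(1 / freq, ncol = 3, nrow = length(freq))
  w <- frequency_weighted_tf(spec, freq)
  expect_equal(max(w) - min(w), 0, tolerance = 1e-12)
  expect_equal(colSums(w), rep(1, 3))
  white <- matrix(1, length(freq), 2)
  ww <- frequency_weighted_tf(white, freq)
  expect_equal(ww[, 1], freq / sum(freq), tolerance = 1e-12)
  z <- cbind(1 / freq, 0)
  wz <- frequency_weighted_tf(z, freq)
  expect_equal(attr(wz, "zero_columns"), 2L)
  expect_equal(sum(wz[, 2]), 0)
})

test_that("1/f generator recovers its exponent and is seed-stable", {
  st <- signal_truth(osc_amp = 0, line_amp = 0, one_over_f_exponent = 1,
                     duration_s = 60, seed = 8)
  g <- gen_field_potentials(st)
  p <- welch_psd(g$signals[, 1], st$fs, segment_s = 4)
  sel <- p$freq >= 2 & p$freq <= 80
  fit <- lm(log(p$psd[sel]) ~ log(p$freq[sel]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
  g2 <- gen_field_potentials(st)
  expect_identical(g$signals, g2$signals)
  # pure oscillation, no noise: Welch peak at the planted frequency
  st2 <- signal_truth(osc_amp = 1, line_amp = 0, noise_scale = 0, seed = 2)
  g3 <- gen_field_potentials(st2)
  p3 <- welch_psd(g3$signals[, 1], st2$fs)
  expect_equal(p3$freq[which.max(p3$psd)], 32)
  expect_error(signal_truth(osc_amp = -1), "non-negative")
})

test_that("the planted high-beta oscillation lands in the high-beta band", {
  for (seed in 1:5) {
    st <- signal_truth(osc_amp = 1, duration_s = 20, seed = seed)
    g <- gen_field_potentials(st)
    np <- normalize_psd(welch_psd(notch_50(g$signals[, 1], st$fs), st$fs))
    sel <- np$freq >= 1 & np$freq <= 80
    pk <- np$freq[sel][which.max(np$norm_psd[sel])]
    expect_gte(pk, 25)
    expect_lte(pk, 35)
    bp <- band_relative_power(np)
    expect_equal(names(which.max(bp)), "high_beta")
  }
})

test_that("band powers are invariant to overall signal amplitude", {
  st <- signal_truth(osc_amp = 1, seed = 3, duration_s = 20)
  g <- gen_field_potentials(st)
  x <- g$signals[, 1]
  b1 <- band_relative_power(normalize_psd(welch_psd(x, st$fs)))
  b2 <- band_relative_power(normalize_psd(welch_psd(7.5 * x, st$fs)))
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("band-wise group comparison flags planted differences only", {
  # identical groups: all p = 1
  m <- matrix(runif(42), 6, 7, dimnames = list(NULL, band_scheme()$band))
  res <- compare_band_power(m, m)
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
  # complete separation in one band, 6 vs 6: exact p = 2/924 < 0.007
  a <- m; b <- m
  a[, "high_beta"] <- a[, "high_beta"] + 1
  res <- compare_band_power(a, b)
  expect_equal(res$p[res$band == "high_beta"], 2 / 924, tolerance = 1e-12)
  expect_true(res$significant[res$band == "high_beta"])
})

test_that("the spectral screen is selective for the planted band across seeds", {
  band_mat <- function(amps, expo, seed) {
    st <- signal_truth(osc_amp = amps, one_over_f_exponent = expo,
                       duration_s = 30, line_amp = 0, seed = seed)
    sig <- gen_field_potentials(st, n_channels = 6)
    t(apply(sig$signals, 2, function(ch)
      band_relative_power(normalize_psd(welch_psd(ch, st$fs)))))
  }
  n_seeds <- 20
  flags <- matrix(FALSE, n_seeds, 7)
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    expo <- runif(6, 0.5, 1.5)           # electrode-to-electrode variability
    pd <- band_mat(runif(6, 0.25, 0.55), expo, seed)
    ctrl <- band_mat(0, expo, seed + 1000)
    flags[seed, ] <- compare_band_power(pd, ctrl)$significant
  }
  colnames(flags) <- band_scheme()$band
  expect_true(all(flags[, "high_beta"]))
  expect_true(all(colMeans(flags[, colnames(flags) != "high_beta"]) <= 0.2))
})

test_that("signal tables round-trip through the headered CSV format", {
  st <- signal_truth(duration_s = 1, seed = 5)
  g <- gen_field_potentials(st, n_channels = 2)
  tmp <- tempfile(fileext = ".csv")
  write_signal_csv(g$signals, st$fs, tmp)
  back <- read_signal_csv(tmp)
  expect_equal(back$fs, 1000)
  expect_equal(unname(back$signals), unname(g$signals), tolerance = 1e-12)
  unlink(tmp)
})
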