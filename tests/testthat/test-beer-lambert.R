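test_that("DPF equation reproduces neonatal reference values", {
  expect_equal(round(compute_dpf(695, 0), 2), 5.31)
  expect_equal(round(compute_dpf(830, 0), 2), 4.67)
})

test_that("DPF matches independent polynomial evaluation at another point", {
  # hand evaluation of the wavelength/age polynomial, frozen
  expect_equal(compute_dpf(830, 25), 5.5373969375, tolerance = 1e-10)
})

test_that("DPF rejects out-of-range wavelengths and ages", {
  expect_error(compute_dpf(600, 0), "wavelength")
  expect_error(compute_dpf(950, 0), "wavelength")
  expect_error(compute_dpf(695, -1), "age")
})

test_that("intensity-to-OD conversion is definitional", {
  layout <- probe_layout(n_channels = 2)
  n <- 100
  I <- array(1, c(n, 2, 2))
  rec <- structure(list(intensity = I, fs = 10, layout = layout,
                        subject_id = "t"), class = "raw_recording")
  od <- intensity_to_od(rec)
  expect_true(all(od$dod == 0))        # constant intensity -> zero dOD

  # I = mean * 10^(-x) at one sample -> dOD = x there (approximately:
  # the sample itself shifts the mean, so use a long series)
  n <- 10000
  I <- array(1, c(n, 2, 2))
  I[500, 1, 1] <- 10^(-0.3)
  rec$intensity <- I
  od <- intensity_to_od(rec)
  expect_equal(od$dod[500, 1, 1], 0.3, tolerance = 1e-3)

  # seeded random series vs elementwise log oracle
  set.seed(11)
  I <- array(exp(rnorm(n * 4, 0, 0.1)), c(n, 2, 2))
  rec$intensity <- I
  od <- intensity_to_od(rec)
  for (ch in 1:2) for (w in 1:2) {
    expected <- -log10(I[, ch, w] / mean(I[, ch, w]))
    expect_equal(od$dod[, ch, w], expected, tolerance = 1e-12)
  }

  rec$intensity[3, 2, 1] <- -1
  expect_error(intensity_to_od(rec), "channel")
})

test_that("modified Beer-Lambert inversion round-trips seeded concentrations", {
  layout <- probe_layout(n_channels = 4)
  set.seed(21)
  n <- 200
  hbo <- matrix(rnorm(n * 4, 0, 0.5), n, 4)
  hbr <- matrix(rnorm(n * 4, 0, 0.2), n, 4)
  dod <- neonirs:::conc_to_od(hbo, hbr, layout)
  od <- structure(list(dod = dod, fs = 10, layout = layout,
                       channel_id = layout$channel_id), class = "od_series")
  conc <- od_to_conc(od, layout)
  expect_equal(conc$hbo, hbo, tolerance = 1e-6)
  expect_equal(conc$hbr, hbr, tolerance = 1e-6)

  # zero OD -> zero concentrations
  od0 <- od; od0$dod[] <- 0
  conc0 <- od_to_conc(od0, layout)
  expect_true(all(conc0$hbo == 0) && all(conc0$hbr == 0))

  # doubling the source-detector distance halves recovered concentrations
  layout2 <- probe_layout(n_channels = 4, distance_cm = 6)
  conc2 <- od_to_conc(od, layout2)
  expect_equal(conc2$hbo, hbo / 2, tolerance = 1e-6)
})

test_that("singular extinction matrices are rejected", {
  layout <- probe_layout(n_channels = 2)
  bad <- matrix(c(1, 1, 2, 2), 2, 2)
  od <- make_od(array(0, c(10, 2, 2)))
  expect_error(od_to_conc(od, layout, extinction = bad), "singular")
})

test_that("SNR pruning applies the discard rule at every wavelength", {
  set.seed(31)
  n <- 500
  layout <- probe_layout(n_channels = 6)
  I <- array(0, c(n, 6, 2))
  # channels 1-3 constructed at SNR 20, channels 4-6 at SNR 1.5 exactly:
  # intensities bounded in (0, 2] via a scaled sine so mean/sd is controlled
  for (ch in 1:6) for (w in 1:2) {
    snr <- if (ch <= 3) 20 else 1.5
    e <- sin(2 * pi * seq_len(n) / 50)          # zero-mean, bounded
    e <- (e - mean(e)) / sd(e)
    I[, ch, w] <- 1 + e / snr                   # mean 1, sd 1/snr, positive
  }
  rec <- structure(list(intensity = I, fs = 10, layout = layout,
                        subject_id = "t"), class = "raw_recording")
  keep <- prune_channels(rec, snr_thresh = 2)
  expect_equal(as.vector(keep), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

  # channel with sd close to mean (SNR ~1) is discarded
  snr1 <- rec
  snr1$intensity[, 1, 1] <- qexp(ppoints(n))   # positive, mean ~ sd
  expect_false(prune_channels(snr1, 2)[1])

  # noise-free constant channel: infinite SNR, retained and logged
  cz <- rec
  cz$intensity[, 2, ] <- 1
  kz <- prune_channels(cz, 2)
  expect_true(kz[2])
  expect_true(attr(kz, "zero_variance")[2])
})
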