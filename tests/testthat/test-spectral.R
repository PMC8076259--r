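eps_from <- function(x, fs = 125) epoch_signal(x, fs = fs, epoch_len = 4)

test_that("per-epoch high-pass removes DC and keeps in-band amplitude", {
  fs <- 125
  t <- (0:(20 * 4 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  ep <- eps_from(x)
  ep_dc <- eps_from(x + 5)
  hp <- highpass_epochs(ep)
  hp_dc <- highpass_epochs(ep_dc)
  # the 5.0 offset is removed: epoch means return to within 1% of the offset
  expect_lt(max(abs(rowMeans(hp_dc) - rowMeans(hp))), 0.01 * 5)
  expect_lt(max(abs(rowMeans(hp_dc))), 0.01 * 5)
  # 10 Hz amplitude preserved within 5% (centre of an epoch, away from edges)
  expect_lt(abs(max(abs(hp[3, 100:400])) - 1), 0.05)

  z <- highpass_epochs(eps_from(rep(0, 4000)))
  expect_true(all(z == 0))
  expect_error(highpass_epochs(ep, cutoff = 70), "Nyquist")
})

test_that("epoch PSD peaks at the right bins and is Parseval-consistent", {
  fs <- 125
  t <- (0:(4 * fs - 1)) / fs
  ep <- eps_from(sin(2 * pi * 10 * t))
  psd <- epoch_psd(ep)
  freqs <- attr(psd, "freqs")
  expect_equal(freqs[2] - freqs[1], 0.25)
  expect_equal(freqs[1], 0)
  expect_equal(freqs[length(freqs)], 62.5)
  expect_equal(freqs[which.max(psd[1, ])], 10)

  # Parseval: integrated PSD equals windowed mean-square power
  w <- 0.54 - 0.46 * cos(2 * pi * (0:499) / 499)
  x <- rnorm(500)
  psd_x <- epoch_psd(eps_from(x))
  expect_equal(sum(psd_x[1, ]) * 0.25, sum((x * w)^2) / sum(w^2),
               tolerance = 0.01)

  two <- eps_from(sin(2 * pi * 3 * t) + sin(2 * pi * 8 * t))
  p2 <- epoch_psd(two)
  top2 <- sort(freqs[order(p2[1, ], decreasing = TRUE)[1:2]])
  expect_equal(top2, c(3, 8))

  ep5 <- epoch_signal(rnorm(125 * 5), fs = 125, epoch_len = 5)
  expect_error(epoch_psd(ep5), "0.25 Hz grid")
})

test_that("normalization yields unit-sum, scale-invariant spectra", {
  flat <- structure(matrix(2.5, 3, 251), freqs = seq(0, 62.5, 0.25))
  norm <- normalize_psd(flat)
  expect_equal(as.numeric(norm[1, ]), rep(1 / 251, 251))

  set.seed(2)
  raw <- structure(matrix(rexp(5 * 251), 5, 251), freqs = seq(0, 62.5, 0.25))
  n1 <- normalize_psd(raw)
  expect_equal(rowSums(n1), rep(1, 5), tolerance = 1e-12)
  n2 <- normalize_psd(raw * 7.3)
  expect_equal(as.numeric(n2), as.numeric(n1), tolerance = 1e-12)

  raw0 <- raw; raw0[2, ] <- 0
  n0 <- normalize_psd(raw0)
  expect_true(all(is.na(n0[2, ])))
  expect_identical(attr(n0, "excluded"), c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("state PSD summaries aggregate per state and ignore epoch order", {
  freqs <- seq(0, 62.5, 0.25)
  base <- rexp(251); base <- base / sum(base)
  spec <- structure(matrix(base, 20, 251, byrow = TRUE), freqs = freqs)
  h <- hypnogram(rep(c("WAKE", "NREMS"), 10), epoch_len = 4)
  # REMS is absent throughout this fixture: its empty-summary warning is
  # exercised explicitly at the end
  s <- suppressWarnings(state_psd_summary(spec, h, "light"))
  expect_true(all(s$q75 - s$q25 == 0))
  w <- s[s$state == "WAKE", ]
  sel <- freqs >= 1 & freqs <= 22.75
  expect_equal(w$median, base[sel])

  set.seed(4)
  spec2 <- structure(matrix(rexp(20 * 251), 20, 251), freqs = freqs)
  spec2 <- normalize_psd(spec2)
  perm <- sample(20)
  h_perm <- hypnogram(h$states[perm], epoch_len = 4)
  s_orig <- suppressWarnings(state_psd_summary(spec2, h, "light"))
  s_perm <- suppressWarnings(
    state_psd_summary(structure(spec2[perm, ], freqs = freqs), h_perm, "light")
  )
  expect_equal(s_perm$median, s_orig$median)

  # every state is absent in the (empty) dark phase here
  w <- testthat::capture_warnings(out <- state_psd_summary(spec, h, "dark"))
  expect_match(w, "absent", all = TRUE)
  expect_equal(nrow(out), 0L)
})

test_that("band powers sum bins inclusively and are subadditive", {
  freqs <- seq(0, 62.5, 0.25)
  flat <- structure(matrix(1 / 251, 1, 251), freqs = freqs)
  expect_equal(band_power(flat, "delta"), 17 / 251) # 1.0-5.0 Hz = 17 bins
  expect_equal(band_power(flat, "theta"), 13 / 251)
  expect_equal(band_power(flat, "eta"), 28 / 251)

  conc <- structure(matrix(0, 1, 251), freqs = freqs)
  conc[1, which(freqs == 8)] <- 1
  expect_equal(band_power(conc, "theta"), 1)
  expect_equal(band_power(conc, "delta"), 0)
  expect_equal(band_power(conc, "alpha"), 0)

  set.seed(5)
  sp <- normalize_psd(structure(matrix(rexp(251), 1), freqs = freqs))
  total <- sum(vapply(names(band_scheme()), function(b) band_power(sp, b), 0))
  expect_lte(total, 1)
  expect_error(band_power(sp, c(60, 70)), "outside")
})

test_that("eta QC flags only clearly attenuated animals", {
  eta <- stats::setNames(rep(0.04, 8), paste0("m", 1:8))
  expect_true(all(!eta_qc(eta)))
  eta["m3"] <- 0.004
  flags <- eta_qc(eta)
  expect_true(flags[["m3"]])
  expect_equal(sum(flags), 1L)
  expect_warning(eta_qc(eta[1:2]), "skipped")
})

test_that("white-noise PSD is flat and strain NREMS spectra differ as published", {
  # delta down / theta up in S1-like vs BL6-like NREMS relative spectra
  get_nrems_bands <- function(preset, seed) {
    prof <- strain_preset(preset)
    hyp <- hypnogram(rep("NREMS", 75), epoch_len = 4)
    gr <- generate_recording(hyp, prof, fs = 250, seed = seed)
    rec <- downsample(gr$recording, 125)
    sp <- normalize_psd(epoch_psd(highpass_epochs(epoch_signal(rec, epoch_len = 4))))
    c(delta = mean(band_power(sp, "delta")), theta = mean(band_power(sp, "theta")))
  }
  ok_delta <- 0; ok_theta <- 0
  for (s in 1:5) {
    s1 <- get_nrems_bands("S1-like", 100 + s)
    bl6 <- get_nrems_bands("BL6-like", 200 + s)
    ok_delta <- ok_delta + (s1["delta"] < bl6["delta"])
    ok_theta <- ok_theta + (s1["theta"] > bl6["theta"])
  }
  expect_gte(ok_delta, 4)
  expect_gte(ok_theta, 4)
})
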