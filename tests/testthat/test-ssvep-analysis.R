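make_rec <- function(signal_fun, fs = 512, dur = 30, labels = c("M1", "M2", "Oz"),
                     events = tibble::tibble()) {
  n <- round(fs * dur)
  t <- (seq_len(n) - 1) / fs
  d <- matrix(0, length(labels), n)
  rownames(d) <- NULL
  d[which(labels == "Oz"), ] <- signal_fun(t)
  eeg_recording(d, fs, labels, events)
}

test_that("preprocessing removes common mode, stop-band tones, and resamples exactly", {
  # identical signal on every channel vanishes under mastoid referencing
  n <- 512 * 10
  t <- (seq_len(n) - 1) / 512
  common <- sin(2 * pi * 7 * t)
  d <- rbind(common, common, common, common)
  rec <- eeg_recording(d, 512, c("M1", "M2", "Oz", "POz"))
  pp <- preprocess(rec)
  expect_lt(max(abs(pp$data)), 1e-9)
  # resampling arithmetic: 10 s at 512 Hz in, exactly 2560 samples out
  expect_identical(ncol(pp$data), 2560L)
  expect_equal(pp$fs, 256)

  # 50 Hz line-noise tone attenuated far beyond 20 dB
  rec50 <- make_rec(function(t) 10 * sin(2 * pi * 50 * t), dur = 10)
  pp50 <- preprocess(rec50)
  oz <- pp50$data[3, ]
  # ignore filter edge transients
  core <- oz[200:(length(oz) - 200)]
  expect_lt(max(abs(core)) / 10, 10^(-20 / 20))

  # an in-band 5 Hz tone passes with unit gain
  rec5 <- make_rec(function(t) 2 * sin(2 * pi * 5 * t), dur = 10)
  core5 <- preprocess(rec5)$data[3, 200:2300]
  expect_equal(max(abs(core5)), 2, tolerance = 0.02)

  expect_error(preprocess(eeg_recording(matrix(0, 2, 100), 512, c("A", "B"))),
               "Available")
})

test_that("epoching keeps nine clean sub-epochs and rejects exactly the injected ones", {
  truth <- synthetic_ground_truth(ssvep_amplitude_map = c(A = 2),
                                  noise_sd_uv = 0.5, seed = 11)
  rec <- generate_synthetic_eeg("A", truth, n_channels = 11, fs_hz = 256,
                                n_trials = 1)
  ep <- epoch_and_reject(preprocess(rec))
  expect_identical(nrow(ep), 9L)          # ten 2-s sub-epochs, first dropped
  expect_identical(sum(ep$kept), 9L)
  expect_setequal(ep$sub_epoch, 2:10)

  # inject a +/-600 uV transient into chosen sub-epochs of chosen trials
  art <- tibble::tibble(condition = c("A", "B"), trial = c(1L, 2L),
                        sub_epoch = c(4L, 7L))
  rec2 <- generate_synthetic_eeg(c("A", "B"), truth, n_channels = 11,
                                 fs_hz = 256, n_trials = 2,
                                 artifact_epochs = art, artifact_uv = 600)
  ep2 <- epoch_and_reject(preprocess(rec2))
  rejected <- ep2[!ep2$kept, ]
  expect_identical(nrow(ep2), 36L)
  expect_equal(nrow(rejected), 2L)
  expect_equal(rejected$condition, art$condition)
  expect_equal(rejected$trial, art$trial)
  expect_equal(rejected$sub_epoch, art$sub_epoch)
})

test_that("baseline subtraction centers constant-offset trials", {
  fs <- 256
  n <- fs * 25
  d <- matrix(7.5, 2, n)                  # constant offset, no dynamics
  rec <- eeg_recording(d, fs, c("Oz", "POz"),
                       tibble::tibble(sample = 2 * fs, condition = "A"))
  ep <- epoch_and_reject(rec)
  expect_true(all(vapply(ep$data, function(m) max(abs(m)), numeric(1)) < 1e-12))
})

test_that("trials that overrun the recording are skipped with a log entry", {
  fs <- 256
  rec <- eeg_recording(matrix(0, 1, fs * 30), fs, "Oz",
                       tibble::tibble(sample = c(2 * fs, 25 * fs),
                                      condition = c("A", "B")))
  expect_message(ep <- epoch_and_reject(rec), "skipped")
  expect_setequal(unique(ep$condition), "A")
})

test_that("Welch spectra have 0.5 Hz bins and conserve tone power", {
  fs <- 256; nseg <- 8
  t <- (seq_len(2 * fs) - 1) / fs
  a <- 3
  segs <- replicate(nseg, matrix(a * sin(2 * pi * 5 * t), 1), simplify = FALSE)
  psd <- welch_psd(segs, fs = fs, labels = "Oz")
  expect_equal(psd$df, 0.5)
  expect_equal(diff(psd$freq)[1], 0.5)
  peak_bin <- which(psd$freq == 5)
  expect_equal(which.max(psd$psd[1, ]), peak_bin)
  # integrated power around the peak equals a^2 / 2 within 1%
  band <- abs(psd$freq - 5) <= 1
  expect_equal(sum(psd$psd[1, band]) * psd$df, a^2 / 2, tolerance = 0.01)

  # white noise is flat across the band
  wsegs <- withr::with_seed(5, replicate(
    200, matrix(rnorm(2 * fs), 1), simplify = FALSE))
  wp <- welch_psd(wsegs, fs = fs, labels = "Oz")
  lo <- mean(wp$psd[1, wp$freq >= 1 & wp$freq <= 20])
  hi <- mean(wp$psd[1, wp$freq >= 21 & wp$freq <= 40])
  expect_equal(lo / hi, 1, tolerance = 0.05)

  expect_error(welch_psd(list(), fs = fs), "No sub-epochs")
})

test_that("SSVEP extraction reads the exact bins over the nine posterior channels", {
  truth <- synthetic_ground_truth(ssvep_amplitude_map = c(A = 2),
                                  harmonic_ratio = 0.25, noise_sd_uv = 0,
                                  seed = 13)
  rec <- generate_synthetic_eeg("A", truth, n_channels = 13, fs_hz = 512,
                                n_trials = 1)
  res <- analyze_ssvep(rec)
  # amplitude a -> PSD a^2/(2 df) = a^2 at the 5 Hz bin (df = 0.5)
  expect_equal(res$power_fundamental, 4, tolerance = 0.05 * 4)
  expect_equal(res$power_harmonic, 0.25, tolerance = 0.05)
  expect_identical(res$n_epochs_kept, 9L)

  # a pure 10 Hz component lands in the harmonic, not the fundamental
  fs <- 256
  t <- (seq_len(2 * fs) - 1) / fs
  seg <- matrix(rep(2 * sin(2 * pi * 10 * t), each = 9), 9, byrow = FALSE)
  psd <- welch_psd(list(seg), fs = fs, labels = posterior_channels())
  out <- extract_ssvep(psd)
  expect_identical(out$n_channels, 9L)
  expect_lt(out$power_fundamental, 1e-12)
  expect_equal(out$power_harmonic, 4, tolerance = 1e-6)

  expect_error(extract_ssvep(psd, channels_of_interest = c("Oz", "XX")),
               "not present")
  expect_error(extract_ssvep(psd, f0 = 5.25), "grid")
})

test_that("estimated fundamental power grows with injected amplitude under 1/f noise", {
  amps <- c(0.5, 1, 2, 4)
  got <- sapply(seq_along(amps), function(i) {
    truth <- synthetic_ground_truth(ssvep_amplitude_map = c(A = amps[i]),
                                    noise_sd_uv = 1, seed = 40 + i)
    rec <- generate_synthetic_eeg("A", truth, n_channels = 11, fs_hz = 256,
                                  n_trials = 1)
    analyze_ssvep(rec)$power_fundamental
  })
  expect_true(all(diff(got) > 0))
})
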