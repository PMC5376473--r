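test_that("CSV recordings round-trip exactly and carry shape metadata", {
  rec <- noise_rec(512, c("Fp1", "F3", "P3"), fs = 256)
  expect_equal(duration(rec), 2.0)
  path <- withr_local_file("rec.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$channels, rec$channels)
  expect_equal(back$fs, 256)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
})

test_that("EDF round-trip preserves channel order and data to 16-bit quantization", {
  chs <- c("Fp1", "Fp2", "F3", "F4", "P3", "P4", "Cz")
  rec <- noise_rec(256 * 3, chs, fs = 256, seed = 4)
  path <- withr_local_file("rec.edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$channels, chs)
  expect_equal(back$fs, 256)
  # one digital step per channel range
  qstep <- apply(rec$data, 2, function(v) diff(range(v))) / 65535
  for (j in seq_along(chs))
    expect_lt(max(abs(back$data[, j] - rec$data[, j])), qstep[j])
})

test_that("non-finite samples are rejected unless a fill policy is given", {
  path <- withr_local_file("nan.csv")
  write.csv(data.frame(a = c(1, NaN, 3), b = c(1, 2, 3)), path,
            row.names = FALSE)
  expect_error(read_recording(path, fs = 10), "non-finite")
  rec <- read_recording(path, fs = 10, na_action = "zero")
  expect_equal(unname(rec$data[2, "a"]), 0)
})

test_that("recording validation rejects malformed inputs", {
  expect_error(eeg_recording(matrix(0, 4, 2), c("a", "a"), 10), "unique")
  expect_error(eeg_recording(matrix(0, 4, 2), c("a", "b"), -1), "positive")
  expect_error(eeg_recording(matrix(0, 4, 2), c("a", "b"), 10,
                             annotations = data.frame(time_s = 99,
                                                      label = "LOC")),
               "within")
})

test_that("Butterworth low-pass passes the passband and attenuates per its own response", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(cbind(sin(2 * pi * 10 * t)), "c1", fs)
  filt <- lowpass_filter(rec)
  mid <- 257:(length(t) - 256)           # avoid edge transients
  amp10 <- max(abs(filt$data[mid, 1]))
  expect_equal(amp10, 1, tolerance = 0.01)

  rec100 <- eeg_recording(cbind(sin(2 * pi * 100 * t)), "c1", fs)
  f100 <- lowpass_filter(rec100)
  amp100 <- sqrt(mean(f100$data[mid, 1]^2)) * sqrt(2)
  att_db <- -20 * log10(amp100)
  expect_gt(att_db, 40)
  # measured attenuation matches the designed (squared, zero-phase)
  # magnitude response within 1 dB
  bf <- signal::butter(9, 50 / 128, type = "low")
  H <- signal::freqz(bf$b, bf$a, Fs = fs, n = 2048)
  hmag <- abs(H$h[which.min(abs(H$f - 100))])^2   # filtfilt squares |H|
  expect_equal(att_db, -20 * log10(hmag), tolerance = 1)
})

test_that("filtering is linear and rejects cutoffs at or above Nyquist", {
  fs <- 128
  set.seed(7)
  x <- rnorm(512); y <- rnorm(512)
  rx <- eeg_recording(cbind(x), "c", fs)
  ry <- eeg_recording(cbind(y), "c", fs)
  rxy <- eeg_recording(cbind(2 * x - 3 * y), "c", fs)
  lhs <- lowpass_filter(rxy, 30)$data
  rhs <- 2 * lowpass_filter(rx, 30)$data - 3 * lowpass_filter(ry, 30)$data
  expect_equal(lhs, rhs, tolerance = 1e-8)
  expect_error(lowpass_filter(rx, 200), "Nyquist")
})

test_that("windowing yields fully contained windows on the study grid", {
  rec <- eeg_recording(matrix(0, 140 * 60 * 4, 1), "c", fs = 4)
  w <- make_windows(rec, 60, 30)
  expect_equal(nrow(w), floor((140 * 60 - 60) / 30) + 1)  # 279
  expect_equal(w$start_s[1:3], c(0, 30, 60))
  expect_true(all(w$end_idx - w$start_idx == 60 * 4))
  expect_true(all(w$end_idx <= nrow(rec$data) + 1))

  one <- make_windows(eeg_recording(matrix(0, 240, 1), "c", 4), 60, 30)
  expect_equal(nrow(one), 1L)
  expect_error(make_windows(eeg_recording(matrix(0, 236, 1), "c", 4), 60),
               "duration")
  expect_error(make_windows(rec, -1, 30), "positive")
})

test_that("interior samples are covered length/step times when step divides length", {
  rec <- eeg_recording(matrix(0, 1000, 1), "c", fs = 10)
  w <- make_windows(rec, 20, 10)
  cover <- integer(1000)
  for (i in seq_len(nrow(w)))
    cover[w$start_idx[i]:(w$end_idx[i] - 1)] <-
      cover[w$start_idx[i]:(w$end_idx[i] - 1)] + 1L
  interior <- 201:(1000 - 200)
  expect_true(all(cover[interior] == 2L))
})

test_that("selection schedule matches an independent enumeration of both clauses", {
  dur <- 140 * 60
  t0 <- 300; t1 <- t0 + 3600
  got <- selection_schedule(t0, t1, dur)
  # brute-force enumeration, clause by clause
  cl <- c(t0 + seq(0, 600, 30), t0 + 600 + seq(0, 3600, 60),
          t1 + seq(0, 1200, 30), t1 + 1200 + seq(0, 1200, 60),
          t1 + 2400 + seq(0, 1200, 120))
  want <- sort(unique(cl[cl <= dur]))
  expect_equal(got, want)
  expect_equal(diff(got[1:2]), 30)
  # short record clips
  short <- selection_schedule(0, 200, 300)
  expect_true(all(short <= 300))
  expect_error(selection_schedule(100, 50, 300))
})
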