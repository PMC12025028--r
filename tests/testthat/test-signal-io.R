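test_that("sessions round-trip through paired CSV files", {
  withr::with_seed(31, {
    sess <- recording_session(matrix(rnorm(4 * 200), 4, 200), 100,
                              data.frame(label = c(1, 7), start_s = c(0, 1),
                                         end_s = c(0.8, 1.9)))
  })
  sig <- withr::local_tempfile(fileext = ".csv")
  ann <- withr::local_tempfile(fileext = ".csv")
  write_session(sess, sig, ann)
  back <- read_session(sig, ann)
  expect_equal(back$sampling_rate, 100)
  expect_equal(back$signal, sess$signal, tolerance = 1e-6)
  expect_equal(back$annotations$label, sess$annotations$label)
})

test_that("sampling rate is inferred from the time column", {
  sig <- withr::local_tempfile(fileext = ".csv")
  ann <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,ch1,ch2,ch3,ch4", "0,0,0,0,0", "0.1,1,1,1,1"), sig)
  writeLines("label,start_s,end_s", ann)
  expect_equal(read_session(sig, ann)$sampling_rate, 10)
})

test_that("malformed inputs raise errors naming the problem", {
  sig <- withr::local_tempfile(fileext = ".csv")
  ann <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,ch1", "0,0", "0.1,1", "0.05,2"), sig)  # non-monotone
  writeLines("label,start_s,end_s", ann)
  expect_error(read_session(sig, ann), "not strictly increasing")
  writeLines(c("time_s,ch1", "0,0", "0.1,1"), sig)
  writeLines(c("label,start_s,end_s", "1,0,5"), ann)  # beyond duration
  expect_error(read_session(sig, ann), "duration")
  expect_error(read_session("nope.csv", ann), "not found")
  expect_error(recording_session(matrix(0, 2, 10), -5), "sampling_rate")
  expect_error(recording_session(matrix(0, 2, 100), 10,
                                 data.frame(label = c(1, 2),
                                            start_s = c(0, 1),
                                            end_s = c(2, 3))),
               "overlap")
})

test_that("notch filter suppresses its target frequency and passes others", {
  on_target <- notch_filter(sine_session(50), filter_spec())
  expect_lte(emg_rms(on_target$signal[1, ]), 0.1 * emg_rms(sine_session(50)$signal[1, ]))
  off_target <- notch_filter(sine_session(100), filter_spec())
  expect_gte(emg_rms(off_target$signal[1, ]), 0.7 * emg_rms(sine_session(100)$signal[1, ]))
  zero <- recording_session(matrix(0, 4, 1000), 1000)
  expect_equal(notch_filter(zero, filter_spec())$signal, zero$signal)
  slow <- recording_session(matrix(0, 4, 100), 60)
  expect_error(notch_filter(slow, filter_spec(notch_freq = 50)), "Nyquist")
})

test_that("band-pass removes DC and out-of-band tones, passes the band", {
  dc <- recording_session(matrix(2.5, 4, 4000), 2000)
  filtered <- bandpass_filter(dc, filter_spec())
  expect_lte(max(abs(filtered$signal)), 1e-6)
  inband <- bandpass_filter(sine_session(150), filter_spec())
  atten_db <- 20 * log10(emg_rms(sine_session(150)$signal[1, ]) /
                           emg_rms(inband$signal[1, ]))
  expect_lte(atten_db, 3)
  low <- bandpass_filter(sine_session(5), filter_spec())
  atten_low <- 20 * log10(emg_rms(sine_session(5)$signal[1, ]) /
                            emg_rms(low$signal[1, ]))
  expect_gte(atten_low, 20)
  expect_error(bandpass_filter(recording_session(matrix(0, 4, 100), 500),
                               filter_spec()), "Nyquist")
})

test_that("filters are linear", {
  withr::with_seed(33, {
    x <- matrix(rnorm(4 * 2000), 4, 2000)
    y <- matrix(rnorm(4 * 2000), 4, 2000)
  })
  fs <- 2000
  a <- 2.3; b <- -0.7
  for (f in list(notch_filter, bandpass_filter)) {
    fx <- f(recording_session(x, fs), filter_spec())$signal
    fy <- f(recording_session(y, fs), filter_spec())$signal
    fxy <- f(recording_session(a * x + b * y, fs), filter_spec())$signal
    expect_equal(fxy, a * fx + b * fy, tolerance = 1e-9)
  }
})

test_that("window geometry matches the recording setup", {
  fs <- 1925.9259
  sess <- toy_labelled_session(fs, data.frame(label = 1, start_s = 0, end_s = 5))
  w <- segment_windows(sess)
  expect_equal(dim(w$samples)[2], 481L)  # floor(1925.9259 * 0.25)
  expect_equal(dim(w$samples)[3], 96L)   # floor((L - 481) / 96) + 1
  expect_true(all(w$info$label == 1))
})

test_that("window counts follow the closed form for random interval lengths", {
  fs <- 1000
  n_win <- floor(fs * 0.25)
  step <- floor(fs * 0.05)
  withr::with_seed(34, {
    for (r in 1:20) {
      L_s <- runif(1, 0.25, 3)
      sess <- toy_labelled_session(fs, data.frame(label = 3, start_s = 0,
                                                  end_s = L_s), seed = r)
      w <- segment_windows(sess)
      L <- ceiling(L_s * fs - 1e-9)  # samples in the half-open interval
      expect_equal(dim(w$samples)[3], (L - n_win) %/% step + 1L)
    }
  })
})

test_that("consecutive windows overlap by 80% and never straddle intervals", {
  fs <- 1000
  sess <- toy_labelled_session(fs, data.frame(label = c(1, 6),
                                              start_s = c(0, 1),
                                              end_s = c(1, 2.5)))
  w <- segment_windows(sess)
  n_win <- dim(w$samples)[2]
  starts <- round(w$info$start_s * fs)
  within <- split(starts, w$info$interval)
  for (s in within) {
    if (length(s) > 1) {
      expect_true(all(diff(s) == floor(fs * 0.05)))
      expect_equal((n_win - diff(s)[1]) / n_win, 0.8)
    }
  }
  # no window crosses the 1 s boundary between the two intervals
  ends <- starts + n_win / fs * fs
  first <- w$info$interval == 1
  expect_true(all(starts[first] + n_win <= 1 * fs + 1))
  expect_true(all(starts[!first] >= 1 * fs - 1))
})

test_that("short intervals yield no windows, with a warning; exact fit yields one", {
  fs <- 1000
  sess <- toy_labelled_session(fs, data.frame(label = 2, start_s = 0,
                                              end_s = 0.1))
  expect_warning(w <- segment_windows(sess), "shorter than one window")
  expect_equal(dim(w$samples)[3], 0L)
  exact <- toy_labelled_session(fs, data.frame(label = 2, start_s = 0,
                                               end_s = 0.25))
  expect_equal(dim(segment_windows(exact)$samples)[3], 1L)
  expect_error(segment_windows(exact, window_ms = 50, step_ms = 50),
               "window_ms > step_ms")
})

test_that("window sets persist through the CSV container", {
  fs <- 200
  sess <- toy_labelled_session(fs, data.frame(label = c(1, 6),
                                              start_s = c(0, 1),
                                              end_s = c(1, 2)))
  w <- segment_windows(sess)
  prefix <- withr::local_tempfile()
  write_windows(w, prefix)
  back <- read_windows(prefix)
  expect_equal(back$samples, w$samples, tolerance = 1e-6)
  expect_equal(back$info$label, w$info$label)
  expect_equal(back$sampling_rate, fs)
})
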