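make_sine_recording <- function(freq, fs = 600, dur = 20, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  ev <- data.frame(sample = integer(0), stimulus_id = character(0),
                   category = character(0), task = character(0))
  new_recording(matrix(amp * sin(2 * pi * freq * t), 1), fs, ev)
}

mid_span <- function(rec) {
  n <- ncol(rec$data)
  round(n * 0.25):round(n * 0.75)
}

test_that("filter chain attenuates and passes the right bands", {
  r60 <- make_sine_recording(60)
  f60 <- apply_filter_chain(r60, bandstop_hz = 60)
  i <- mid_span(r60)
  expect_lt(sd(f60$data[1, i]) / sd(r60$data[1, i]), 0.05)
  r10 <- make_sine_recording(10)
  f10 <- apply_filter_chain(r10, bandstop_hz = 60)
  expect_equal(sd(f10$data[1, i]) / sd(r10$data[1, i]), 1, tolerance = 0.02)
  # high-pass removes a DC offset (long record: the 0.1 Hz edge response
  # must have decayed in the analysed middle span)
  rdc <- make_sine_recording(10, dur = 120)
  rdc$data <- rdc$data + 5
  fdc <- apply_filter_chain(rdc)
  expect_lt(abs(mean(fdc$data[1, mid_span(rdc)])), 0.05)
  expect_error(apply_filter_chain(make_sine_recording(10, fs = 80)),
               "Nyquist")
})

test_that("filter chain is linear and zero-phase", {
  set.seed(5)
  fs <- 600
  ev <- data.frame(sample = integer(0), stimulus_id = character(0),
                   category = character(0), task = character(0))
  x <- matrix(rnorm(2 * fs * 10), 2)
  y <- matrix(rnorm(2 * fs * 10), 2)
  ch <- function(m) apply_filter_chain(new_recording(m, fs, ev))$data
  expect_equal(ch(2 * x + 3 * y), 2 * ch(x) + 3 * ch(y), tolerance = 1e-9)
  # a band-limited bump keeps its peak latency (group delay ~ 0)
  t <- seq(0, 10, by = 1 / fs)
  bump <- exp(-(t - 5)^2 / (2 * 0.05^2))
  fb <- ch(matrix(bump, 1))
  expect_lte(abs(which.max(fb[1, ]) - which.max(bump)), 1)
})

test_that("resampling halves the length and preserves slow signals", {
  r <- make_sine_recording(5, fs = 600, dur = 1)
  r$events <- data.frame(sample = 600L, stimulus_id = "x", category = "A",
                         task = "body")
  r2 <- resample_recording(r, 300)
  expect_equal(ncol(r2$data), ceiling(ncol(r$data) / 2))
  expect_equal(r2$sample_rate, 300)
  expect_equal(r2$events$sample, 300L)
  orig <- r$data[1, seq(1, ncol(r$data), by = 2)]
  i <- 50:250
  expect_gt(cor(orig[i], r2$data[1, i]), 0.999)
  expect_error(resample_recording(r2, 600), "upsampling")
  expect_error(resample_recording(r, 250), "divide")
})

test_that("epoching extracts the stimulus-locked windows", {
  fs <- 300
  set.seed(6)
  n <- fs * 60
  dat <- matrix(rnorm(2 * n), 2)
  onsets <- seq(2 * fs, 55 * fs, length.out = 20)
  ev <- data.frame(sample = as.integer(onsets),
                   stimulus_id = sprintf("s%02d", 1:20),
                   category = rep(LETTERS[1:4], 5), task = "body")
  rec <- new_recording(dat, fs, ev)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$epochs), c(20, 2, 240))
  expect_equal(sum(ep$time_ms == 0), 1)
  # an event too close to the start is dropped
  ev2 <- rbind(data.frame(sample = 10L, stimulus_id = "early", category = "A",
                          task = "body"), ev)
  ep2 <- epoch_recording(new_recording(dat, fs, ev2))
  expect_equal(dim(ep2$epochs)[1], 20)
  expect_equal(attr(ep2, "dropped"), 1L)
  # epoch content equals the raw slice
  k <- ev$sample[3]
  expect_equal(ep$epochs[3, , ], dat[, (k - 60 + 1):(k + 180)])
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  fs <- 300
  set.seed(7)
  ev <- data.frame(sample = as.integer(seq(2 * fs, 28 * fs, length.out = 8)),
                   stimulus_id = letters[1:8], category = "A", task = "body")
  rec <- new_recording(matrix(rnorm(2 * fs * 30) + 3, 2), fs, ev)
  ep <- baseline_correct(epoch_recording(rec))
  sel <- ep$time_ms >= -150 & ep$time_ms < 0
  bl <- apply(ep$epochs[, , sel], c(1, 2), mean)
  expect_equal(max(abs(bl)), 0, tolerance = 1e-12)
  ep2 <- baseline_correct(ep)
  expect_equal(ep2$epochs, ep$epochs, tolerance = 1e-12)
  # constant epochs become all zero
  rc <- new_recording(matrix(1, 1, fs * 30), fs, ev)
  epc <- baseline_correct(epoch_recording(rc))
  expect_equal(max(abs(epc$epochs)), 0)
})

test_that("artifact screening flags constructed outliers and spares clean data", {
  fs <- 300
  set.seed(8)
  ev <- data.frame(sample = as.integer(seq(2 * fs, 115 * fs, length.out = 60)),
                   stimulus_id = sprintf("s%02d", 1:60), category = "A",
                   task = "body")
  rec <- new_recording(matrix(rnorm(4 * fs * 120), 4), fs, ev)
  ep <- epoch_recording(rec)
  clean <- screen_artifacts(ep, 4)
  expect_lt(mean(clean$rejected), 0.05)
  # inject a huge spike into trial 7
  ep$epochs[7, 2, 100] <- 100 * max(abs(ep$epochs))
  flagged <- screen_artifacts(ep, 4)
  expect_true(flagged$rejected[7])
  none <- screen_artifacts(ep, Inf)
  expect_false(any(none$rejected))
  expect_error(screen_artifacts(epoch_recording(
    new_recording(matrix(rnorm(fs * 10), 1), fs, ev[1:2, ])), 4), ">= 5")
})

test_that("condition averages equal the naive loop means", {
  fs <- 300
  set.seed(9)
  ev <- data.frame(sample = as.integer(seq(2 * fs, 55 * fs, length.out = 24)),
                   stimulus_id = sprintf("s%02d", 1:24),
                   category = rep(LETTERS[1:4], 6), task = "body")
  rec <- new_recording(matrix(rnorm(3 * fs * 60), 3), fs, ev)
  ep <- epoch_recording(rec)
  ep$rejected[c(2, 11)] <- TRUE
  evk <- average_by_condition(ep)
  expect_equal(sum(evk$cells$n_trials), 24 - 2)
  for (ci in seq_len(nrow(evk$cells))) {
    sel <- which(ep$labels$category == evk$cells$category[ci] & !ep$rejected)
    ref <- 0
    for (s in sel) ref <- ref + ep$epochs[s, , ]
    expect_equal(evk$evoked[ci, , ], ref / length(sel), tolerance = 1e-12)
  }
  # three identical epochs average to themselves
  ep3 <- ep
  ep3$epochs <- ep$epochs[c(1, 1, 1), , , drop = FALSE]
  ep3$labels <- ep$labels[c(1, 1, 1), ]
  ep3$rejected <- rep(FALSE, 3)
  ev3 <- average_by_condition(ep3)
  expect_equal(ev3$evoked[1, , ], ep$epochs[1, , ], tolerance = 1e-12)
})

test_that("filter and resample stages approximately commute on band-limited data", {
  set.seed(10)
  fs <- 600
  ev <- data.frame(sample = integer(0), stimulus_id = character(0),
                   category = character(0), task = character(0))
  t <- seq(0, 20, by = 1 / fs)
  x <- matrix(sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 23 * t), 1)
  rec <- new_recording(x, fs, ev)
  a <- resample_recording(apply_filter_chain(rec), 300)
  b <- apply_filter_chain(resample_recording(rec, 300))
  i <- mid_span(a)
  expect_lt(sqrt(mean((a$data[1, i] - b$data[1, i])^2)) /
              sqrt(mean(b$data[1, i]^2)), 0.01)
})

test_that("bad channels are replaced by their spatial neighbours", {
  fs <- 300
  set.seed(11)
  lay <- make_sensor_layout(8, modality = "MEG")
  ev <- data.frame(sample = as.integer(seq(2 * fs, 28 * fs, length.out = 6)),
                   stimulus_id = letters[1:6], category = "A", task = "body")
  rec <- new_recording(matrix(rnorm(8 * fs * 30), 8), fs, ev)
  ep <- epoch_recording(rec)
  ep2 <- interpolate_bad_channels(ep, lay$positions, bad = 3L, k = 4)
  d2 <- as.matrix(dist(lay$positions))^2
  nb <- setdiff(order(d2[3, ]), 3)[1:4]
  ref <- apply(ep$epochs[, nb, ], c(1, 3), mean)
  expect_equal(ep2$epochs[, 3, ], ref, tolerance = 1e-12)
  # untouched channels stay identical; empty bad set is a no-op
  expect_equal(ep2$epochs[, 1, ], ep$epochs[, 1, ])
  expect_identical(interpolate_bad_channels(ep, lay$positions,
                                            bad = integer(0)), ep)
  # rejection log covers every trial
  ep$rejected[2] <- TRUE
  log <- rejection_log(ep)
  expect_equal(nrow(log), 6)
  expect_equal(sum(log$rejected), 1)
})
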