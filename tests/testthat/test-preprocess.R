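make_rec <- function(x, fs = 128) eeg_recording(x, fs = fs)

test_that("common average reference zeroes the channel mean and is idempotent", {
  set.seed(1)
  x <- matrix(rnorm(8 * 256), 8)
  rec <- preprocess_recording(make_rec(x), band = c(1, 45), notch = 50)
  expect_lt(max(abs(colMeans(rec$data))), 1e-9)
  car1 <- common_average_reference(x)
  expect_equal(common_average_reference(car1), car1, tolerance = 1e-12)
})

test_that("the notch suppresses 50 Hz and the passband preserves 10 Hz", {
  fs <- 256
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  mk <- function(f) rbind(sin(2 * pi * f * t), cos(2 * pi * f * t),
                          sin(2 * pi * f * t + 1))
  mid <- 500:2000 # steady-state portion, away from edge transients
  p50 <- preprocess_recording(make_rec(mk(50), fs), target_fs = 256)
  expect_lt(sd(p50$data[1, mid]) / sd(mk(50)[1, mid]), 0.05)
  p10 <- preprocess_recording(make_rec(mk(10), fs), target_fs = 256)
  # CAR of the three phase-shifted sinusoids keeps channel 1 sinusoidal
  ratio <- sd(p10$data[1, mid]) / sd(common_average_reference(mk(10))[1, mid])
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("resampling halves the rate and preserves a passband tone", {
  fs <- 256
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- rbind(sin(2 * pi * 10 * t), -sin(2 * pi * 10 * t))
  out <- preprocess_recording(make_rec(x, fs), target_fs = 128)
  expect_equal(out$fs, 128)
  expect_equal(ncol(out$data), length(t) / 2)
  expect_equal(sd(out$data[1, 300:700]), sd(x[1, 600:1400]) / 1, # CAR keeps antiphase pair
               tolerance = 0.06)
})

test_that("sampling below the band Nyquist is rejected", {
  expect_error(preprocess_recording(make_rec(matrix(0, 2, 100), fs = 64)),
               "Nyquist")
})

test_that("epoch counts follow the overlap formula and windows tile correctly", {
  rec <- make_rec(matrix(rnorm(2 * 128 * 10), 2))
  es <- epoch_recording(rec, window = 2, overlap = 0.5)
  expect_equal(dim(es$epochs)[1], 9) # (10 - 2)/1 + 1
  expect_equal(dim(es$epochs)[3], 256)
  expect_equal(es$starts, seq(0L, by = 128L, length.out = 9))
  # consecutive epochs share exactly one second
  expect_equal(es$epochs[2, , 1:128], es$epochs[1, , 129:256])
  es1 <- epoch_recording(make_rec(matrix(0, 2, 256)), 2, 0.5)
  expect_equal(dim(es1$epochs)[1], 1)
  expect_equal(dim(epoch_recording(make_rec(matrix(0, 2, 150 * 128)))$epochs)[1],
               149)
  expect_error(epoch_recording(make_rec(matrix(0, 2, 100))), "shorter")
})

test_that("epoch rejection flags amplitude spikes and variance outliers only", {
  set.seed(2)
  es <- epoch_recording(make_rec(matrix(0, 3, 128 * 6)))
  expect_equal(sum(reject_epochs(es)$rejected), 0)
  x <- matrix(rnorm(3 * 128 * 6, sd = 10), 3)
  x[2, 400] <- 500 # lives in epochs 2-4 (overlapping)
  es2 <- reject_epochs(epoch_recording(make_rec(x)), amp_limit = 100,
                       var_z_limit = Inf)
  expect_true(all(which(es2$rejected) %in% 2:4))
  expect_gte(sum(es2$rejected), 1)
  # i.i.d. Gaussian epochs: few rejections at default thresholds
  y <- matrix(rnorm(4 * 128 * 201, sd = 10), 4)
  es3 <- reject_epochs(epoch_recording(make_rec(y)))
  expect_lt(mean(es3$rejected), 0.10)
  # everything rejected is an explicit error
  z <- matrix(500, 2, 128 * 4)
  expect_error(reject_epochs(epoch_recording(make_rec(z))), "rejected")
})

test_that("channel standardization conforms subjects to the modal layout", {
  mk <- function(names, seed) {
    set.seed(seed)
    eeg_recording(matrix(rnorm(length(names) * 64), length(names)),
                  fs = 128, ch_names = names)
  }
  same <- list(mk(c("A", "B", "C"), 1), mk(c("A", "B", "C"), 2),
               mk(c("A", "B", "C"), 3))
  out <- standardize_channels(same)
  expect_equal(out$layout, c("A", "B", "C"))
  expect_identical(out$recordings[[2]]$data, same[[2]]$data)
  mixed <- list(mk(c("A", "B", "C"), 1), mk(c("A", "B", "C"), 2),
                mk(c("A", "B", "D"), 3))
  out2 <- standardize_channels(mixed)
  expect_equal(out2$layout, c("A", "B", "C"))
  third <- out2$recordings[[3]]
  expect_equal(third$ch_names, c("A", "B", "C"))
  expect_true(all(third$data["C", ] == 0)) # zero-filled missing channel
  expect_equal(third$data["A", ], mixed[[3]]$data["A", ]) # D dropped, A kept
  expect_equal(unique(vapply(out2$recordings,
                             function(r) nrow(r$data), numeric(1))), 3)
  expect_error(standardize_channels(list()), "empty")
})
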