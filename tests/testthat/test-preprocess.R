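test_that("baseline correction zeroes the baseline mean", {
  e <- noise_epochs(seed = 1)
  e$data[1, 1, ] <- 5  # constant channel
  out <- baseline_correct(e, c(-400, -200))
  expect_equal(max(abs(out$data[1, 1, ])), 0)
  idx <- which(out$times >= -400 & out$times <= -200)
  bl <- apply(out$data[, , idx], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # an added offset is removed, the signal shape kept
  e2 <- e
  e2$data <- e$data + 10
  out2 <- baseline_correct(e2, c(-400, -200))
  expect_equal(out$data, out2$data)
  expect_equal(length(out$log), 1L)
})

test_that("bad-channel detection flags planted channels, spares protected", {
  e <- noise_epochs(seed = 2)
  j <- which(!(e$channels %in% dlpfc_electrodes()))[1]
  e$data[, j, ] <- e$data[, j, ] * 50
  expect_identical(detect_bad_channels(e), e$channels[j])
  # the same corruption on a protected DLPFC electrode is never flagged
  e2 <- noise_epochs(seed = 2)
  j2 <- match("F3", e2$channels)
  e2$data[, j2, ] <- e2$data[, j2, ] * 50
  expect_identical(detect_bad_channels(e2), character(0))
  # the pooled score also catches the clear case (it may add occasional
  # false positives, which is why it is not the default)
  expect_true(e$channels[j] %in% detect_bad_channels(e, method = "pooled"))
})

test_that("homogeneous recordings yield an empty bad-channel list", {
  hits <- vapply(1:100, function(s)
    length(detect_bad_channels(noise_epochs(seed = 100 + s))), 0L)
  expect_gte(mean(hits == 0), 0.99)
})

test_that("epoch rejection removes exactly the high-amplitude trials", {
  e <- noise_epochs(seed = 3)
  e$data[4, 2, 100] <- 1200
  out <- reject_epochs(e, 1000, ignore_window = NULL)
  expect_equal(attr(out, "rejected_trials"), 4L)
  expect_equal(dim(out$data)[1], 9)
  # all-quiet data are untouched
  e2 <- noise_epochs(seed = 4)
  e2$data <- pmin(pmax(e2$data, -900), 900)
  out2 <- reject_epochs(e2, 1000, ignore_window = NULL)
  expect_equal(dim(out2$data)[1], 10)
  expect_length(attr(out2, "rejected_trials"), 0)
  # spikes on already-flagged channels do not reject trials
  e3 <- noise_epochs(seed = 5)
  e3$data[2, 1, 50] <- 5000
  e3$bad_channels <- e3$channels[1]
  out3 <- reject_epochs(e3, 1000, ignore_window = NULL)
  expect_length(attr(out3, "rejected_trials"), 0)
})

test_that("pulse-window excision reconstructs cubic signals exactly", {
  tt <- seq(-100, 200, by = 1)
  cub <- 2 + 0.03 * tt - 1e-4 * tt^2 + 5e-7 * tt^3
  dat <- array(NA_real_, c(2, 1, length(tt)))
  dat[1, 1, ] <- cub
  dat[2, 1, ] <- -3 * cub + 1
  e <- epoch_set(dat, "Cz", 1000, tt)
  out <- excise_and_interpolate(e, c(-5, 30), context = 20)
  expect_lt(max(abs(out$data[1, 1, ] - cub)), 1e-6)
  expect_lt(max(abs(out$data[2, 1, ] - (-3 * cub + 1))), 1e-6)
  # samples outside the window are bit-identical
  keep <- tt < -5 | tt > 30
  expect_identical(out$data[, , keep], e$data[, , keep])
})

test_that("planted pulse transients are removed by excision", {
  cfg <- tiny_eeg_config(seed = 6, tms_transient = TRUE)
  ds <- generate_tep_dataset(cfg)
  e <- ds$epochs[[1]]$single
  win <- which(e$times >= -5 & e$times <= 30)
  expect_gt(max(abs(e$data[, , win])), 1500)
  out <- excise_and_interpolate(e, c(-5, 30))
  expect_lt(max(abs(out$data[, , win])), 500)
})

test_that("filtering resamples, suppresses 50 Hz, preserves 10 Hz", {
  tms <- seq(-2000, 2000, by = 1000 / 3000)
  mk <- function(f) {
    dat <- array(100 * sin(2 * pi * f * tms / 1000), c(1, 1, length(tms)))
    epoch_set(dat, "Cz", 3000, tms)
  }
  f50 <- filter_and_resample(mk(50))
  expect_equal(f50$sfreq, 1000)
  expect_equal(dim(f50$data)[3], 4001)
  cen <- function(e) {
    i <- which(e$times >= -500 & e$times <= 500)
    max(abs(e$data[1, 1, i]))
  }
  expect_lt(cen(f50), 10)          # >= 20 dB attenuation
  f10 <- filter_and_resample(mk(10))
  expect_lt(abs(cen(f10) - 100) / 100, 0.05)
  expect_error(filter_and_resample(mk(10), target_rate = 999), "divide")
  expect_error(filter_and_resample(mk(10), bandpass = c(0.5, 600)),
               "Nyquist")
})

test_that("spherical interpolation rebuilds smooth scalp fields", {
  mon <- standard_montage(64)
  field <- 3 * mon$x + 2 * mon$y - mon$z + 1.5 * mon$x * mon$y
  tt <- seq(-50, 50, by = 2)
  dat <- array(NA_real_, c(1, 64, length(tt)))
  dat[1, , ] <- outer(field, sin(2 * pi * 5 * tt / 1000) + 1)
  e <- epoch_set(dat, mon$name, 500, tt, positions = mon)
  j <- match("C3", mon$name)
  truth <- e$data[1, j, ]
  e$data[1, j, ] <- 999
  e$bad_channels <- "C3"
  out <- interpolate_bad_channels(e)
  expect_gt(cor(out$data[1, j, ], truth), 0.9)
  # the corrupted values leave no residual
  expect_lt(max(abs(out$data[1, j, ])), 100)
  expect_length(out$bad_channels, 0)
  # no flagged channels: identity on the data
  e2 <- noise_epochs(seed = 7)
  out2 <- interpolate_bad_channels(e2)
  expect_identical(out2$data, e2$data)
})

test_that("average re-reference zeroes the cross-channel mean", {
  e <- noise_epochs(seed = 8)
  out <- rereference_average(e)
  expect_lt(max(abs(apply(out$data, c(1, 3), mean))), 1e-9)
  expect_equal(out$reference, "average")
  # idempotent
  out2 <- rereference_average(out)
  expect_equal(out2$data, out$data)
  # channel differences (bipolar quantities) are reference-invariant
  expect_equal(out$data[, 1, ] - out$data[, 2, ],
               e$data[, 1, ] - e$data[, 2, ])
})

test_that("the full chain logs every step and matches planted truth", {
  cfg <- tiny_eeg_config(seed = 9, n_bad_channels = 1, n_bad_epochs = 3)
  ds <- generate_tep_dataset(cfg)
  sub <- names(ds$epochs)[1]
  out <- run_preprocessing(ds$epochs[[sub]]$single, tiny_params())
  rep <- attr(out, "report")
  expect_identical(sort(rep$bad_channels),
                   sort(ds$ground_truth$bad_channels[[sub]]))
  expect_identical(rep$rejected_trials,
                   ds$ground_truth$bad_epochs[[sub]]$single)
  steps <- vapply(out$log, `[[`, "", "step")
  expect_equal(steps, c("baseline_correct", "detect_bad_channels",
                        "reject_epochs", "excise_and_interpolate",
                        "filter_and_resample", "interpolate_bad_channels",
                        "rereference_average"))
  expect_equal(out$sfreq, 250)
  expect_lt(max(abs(apply(out$data, c(1, 3), mean))), 1e-9)
  # clean data: nothing removed
  cfg2 <- tiny_eeg_config(seed = 10)
  ds2 <- generate_tep_dataset(cfg2)
  out2 <- run_preprocessing(ds2$epochs[[1]]$single, tiny_params())
  rep2 <- attr(out2, "report")
  expect_length(rep2$bad_channels, 0)
  expect_length(rep2$rejected_trials, 0)
})
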