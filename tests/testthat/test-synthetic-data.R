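test_that("generated epoch dimensions follow the configuration", {
  cfg <- synth_config(n_trd = 2, n_hc = 1, n_trials_per_condition = 5,
                      n_channels = 12, sampling_rate = 500,
                      epoch_window = c(-400, 400), seed = 1)
  ds <- generate_tep_dataset(cfg)
  expect_length(ds$epochs, 3)
  for (sub in ds$epochs) {
    expect_named(sub, c("single", "paired"))
    expect_equal(dim(sub$single$data), c(5, 12, 401))
    expect_equal(sub$paired$sfreq, 500)
  }
  expect_equal(nrow(ds$source_model$leadfield), 12)
  expect_equal(length(ds$source_model$source_region),
               34 * cfg$n_sources_per_region)
})

test_that("the default configuration encodes the full study design", {
  cfg <- synth_config()
  expect_equal(cfg$n_trd, 60)
  expect_equal(cfg$n_hc, 30)
  expect_equal(cfg$n_trials_per_condition, 80)
  expect_equal(cfg$n_channels, 64)
  expect_equal(cfg$sampling_rate, 3000)
  expect_equal(cfg$epoch_window, c(-2000, 2000))
  expect_equal(cfg$n_regions, 34)
  expect_equal(cfg$planted_effect_d, 0.52)
  # implied samples per epoch at 3 kHz over -2000..2000 ms
  expect_equal(diff(cfg$epoch_window) / 1000 * cfg$sampling_rate + 1, 12001)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_trd = 0), "positive")
  expect_error(synth_config(propagation_profile = rep(1, 10)), "length")
  expect_error(synth_config(propagation_profile = c(rep(1, 33), -1)), ">= 0")
  expect_error(expression_config(planted_r = 1.4), "outside")
})

test_that("identical seed and config reproduce the dataset exactly", {
  cfg <- tiny_eeg_config(seed = 5, n_bad_channels = 1, n_bad_epochs = 1)
  a <- generate_tep_dataset(cfg)
  b <- generate_tep_dataset(cfg)
  expect_identical(a$epochs[[1]]$paired$data, b$epochs[[1]]$paired$data)
  expect_identical(a$source_model$leadfield, b$source_model$leadfield)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$clinical, b$clinical)
})

test_that("every planted artifact is enumerated in the ground truth", {
  cfg <- tiny_eeg_config(seed = 3, n_bad_channels = 2, n_bad_epochs = 3)
  ds <- generate_tep_dataset(cfg)
  gt <- ds$ground_truth
  for (sub in names(ds$epochs)) {
    expect_length(gt$bad_channels[[sub]], 2)
    expect_false(any(gt$bad_channels[[sub]] %in% dlpfc_electrodes()))
    expect_length(gt$bad_epochs[[sub]]$single, 3)
    expect_length(gt$bad_epochs[[sub]]$paired, 3)
  }
  expect_true(gt$tms_transient)
  expect_equal(gt$planted_effect_d, cfg$planted_effect_d)
})

test_that("the evoked waveform peaks near 100 ms and starts at onset", {
  tt <- seq(-500, 500, by = 1)
  u <- evoked_waveform(tt)
  expect_equal(max(abs(u)), 1)
  expect_true(all(u[tt < 20] == 0))
  peak <- tt[which.max(u)]
  expect_gt(peak, 70)
  expect_lt(peak, 130)
})

test_that("the null configuration plants no group difference", {
  # window-mean facilitation gains have equal group means when d = 0
  cfg <- synth_config(n_trd = 20, n_hc = 10, n_trials_per_condition = 2,
                      n_channels = 8, sampling_rate = 250,
                      epoch_window = c(-300, 300), planted_effect_d = 0,
                      seed = 7)
  ds <- generate_tep_dataset(cfg)
  facil <- t(vapply(ds$ground_truth$subject_effects,
                    function(x) x$facilitation, numeric(34)))
  grp <- ds$clinical$group
  expect_equal(unname(facil[grp == "TRD", 1]) -
                 ds$ground_truth$facilitation_gain[grp == "TRD"],
               rep(0, 20))
  # and the recovered group difference of measured indices is unbiased
  diffs <- vapply(1:40, function(s) {
    cfg <- desk_config(seed = s, planted_effect_d = 0, n_trd = 10, n_hc = 6)
    ds <- generate_tep_dataset(cfg)
    idx <- cohort_icf_indices(ds, baseline = c(-350, -20))
    stim <- ds$source_model$stim_region
    mean(idx$icf_dspm[idx$group == "HC", stim]) -
      mean(idx$icf_dspm[idx$group == "TRD", stim])
  }, 0)
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("expression fixture ground truth is exact and reproducible", {
  cfg <- small_expr_config(seed = 11)
  a <- generate_expression_fixture(cfg)
  b <- generate_expression_fixture(cfg)
  expect_identical(a$probes, b$probes)
  expect_identical(a$ground_truth, b$ground_truth)
  gt <- a$ground_truth
  # planted background failures are exactly the probes below 50%
  frac <- tapply(a$probes$above_background, a$probes$probe_id, mean)
  expect_setequal(names(frac)[frac >= 0.5], gt$surviving_probes)
  # at least one probe on each side of every filter
  expect_gt(length(setdiff(names(frac), gt$surviving_probes)), 0)
  expect_gt(length(gt$dropped_far), 0)
  expect_gt(length(gt$dropped_right), 0)
  expect_gt(length(setdiff(unique(a$probes$gene), gt$surviving_genes)), 0)
})

test_that("differential stability is 1 for donor-identical profiles", {
  profile <- c(1, 3, 2, 5, 4)
  probes <- data.frame(
    probe_id = "P1", gene = "G1",
    sample_id = sprintf("s%d", 1:10),
    intensity = rep(profile, 2),
    above_background = TRUE)
  assignments <- data.frame(
    sample_id = sprintf("s%d", 1:10),
    donor = rep(c("d1", "d2"), each = 5),
    region = rep(sprintf("R%d", 1:5), 2))
  ds <- differential_stability_select(probes, assignments, keep_fraction = 1)
  expect_equal(ds$selection$ds, 1)
})

test_that("a zero planted correlation yields a null mean correlation", {
  rbar <- vapply(1:30, function(s) {
    fx <- generate_expression_fixture(small_expr_config(seed = s,
                                                        planted_r = 0))
    pipe <- process_expression_fixture(fx)
    planted <- intersect(fx$ground_truth$planted_genes, rownames(pipe$matrix))
    set_mean_correlation(planted, pipe$matrix, fx$ground_truth$target_map)
  }, 0)
  expect_lt(abs(mean(rbar)), 2 * sd(rbar) / sqrt(length(rbar)))
})

test_that("cohort bundles are reproducible and complete", {
  dir1 <- file.path(tempdir(), "bundleA")
  dir2 <- file.path(tempdir(), "bundleB")
  cfg <- tiny_eeg_config(seed = 2, n_trials = 4, n_channels = 10)
  ecfg <- small_expr_config(seed = 3)
  generate_cohort_bundle(dir1, cfg, ecfg)
  generate_cohort_bundle(dir2, cfg, ecfg)
  expect_identical(readBin(file.path(dir1, "manifest.json"), "raw", 1e6),
                   readBin(file.path(dir2, "manifest.json"), "raw", 1e6))
  expect_identical(readBin(file.path(dir1, "ground_truth.json"), "raw", 1e7),
                   readBin(file.path(dir2, "ground_truth.json"), "raw", 1e7))
  bundle <- read_cohort_bundle(dir1)
  expect_length(bundle$dataset$source_model$regions, 34)
  expect_equal(sort(bundle$manifest$files),
               sort(list.files(dir1)[list.files(dir1) != "manifest.json"]))
  expect_false(bundle$manifest$null_configuration)
  # null configuration is recorded as such
  dir3 <- file.path(tempdir(), "bundleC")
  generate_cohort_bundle(dir3, tiny_eeg_config(seed = 2, n_trials = 4,
                                               n_channels = 10) |>
                           (\(x) { x$planted_effect_d <- 0; x })(), ecfg)
  m3 <- jsonlite::read_json(file.path(dir3, "manifest.json"))
  expect_true(m3$null_configuration)
  expect_equal(m3$planted_effect_d, 0)
  unlink(c(dir1, dir2, dir3), recursive = TRUE)
})
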