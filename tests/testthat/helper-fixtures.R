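# Shared fixture builders. All tests generate their data in code; sizes are
# kept small so the whole suite runs quickly.

# one- or two-subject EEG fixture with optional planted artifacts
tiny_eeg_config <- function(seed, n_bad_channels = 0, n_bad_epochs = 0,
                            n_trials = 10, n_channels = 16,
                            tms_transient = TRUE, noise_sd = 20) {
  synth_config(n_trd = 1, n_hc = 1, n_trials_per_condition = n_trials,
               n_channels = n_channels, sampling_rate = 500,
               epoch_window = c(-400, 400), noise_sd = noise_sd,
               artifact_spec = list(n_bad_channels = n_bad_channels,
                                    n_bad_epochs = n_bad_epochs,
                                    tms_transient = tms_transient),
               seed = seed)
}

tiny_params <- function() {
  preprocess_params(epoch_window = c(-400, 400),
                    baseline_window = c(-350, -150),
                    target_rate = 250)
}

# small expression fixture (fast to generate in Monte Carlo loops)
small_expr_config <- function(seed, planted_r = 0.6, n_genes = 60,
                              n_donors = 3) {
  expression_config(n_genes = n_genes, n_donors = n_donors,
                    genes_per_type = 3, n_bg_fail = 4, n_noisy_probes = 4,
                    n_far_samples = 2, n_right_samples = 2,
                    planted_r = planted_r, seed = seed)
}

# plain epoch_set of spatially uncorrelated noise
noise_epochs <- function(seed, n_trials = 10, n_channels = 16,
                         n_times = 300, sd = 20, sfreq = 500) {
  set.seed(seed)
  mon <- standard_montage(n_channels)
  epoch_set(array(rnorm(n_trials * n_channels * n_times, sd = sd),
                  c(n_trials, n_channels, n_times)),
            mon$name, sfreq,
            seq(-n_times + 1, 0) * 1000 / sfreq, positions = mon)
}
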