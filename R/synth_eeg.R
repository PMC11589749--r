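# Synthetic TMS-EEG cohort generator. The generator plants a known evoked
# waveform at the source level, projects it through a random well-conditioned
# leadfield, adds spatially correlated sensor noise and optional artifacts,
# and records everything it planted in a ground-truth object so downstream
# modules can be tested against exact truth.

#' Source model: leadfield plus region labels
#'
#' @param leadfield channels x sources gain matrix.
#' @param source_region integer vector, region index (1..n_regions) of each
#'   source column.
#' @param regions character vector of region names in canonical order.
#' @param stim_region integer index of the stimulated region.
#' @param channels channel names matching the leadfield rows.
#' @return object of class `source_model`.
#' @export
source_model <- function(leadfield, source_region, regions = dk_regions(),
                         stim_region = dk_stim_index(), channels = NULL) {
  stopifnot(is.matrix(leadfield), all(is.finite(leadfield)))
  if (length(source_region) != ncol(leadfield))
    stop("one region label per source required")
  if (any(source_region < 1L | source_region > length(regions)))
    stop("region labels out of range")
  structure(list(leadfield = leadfield,
                 source_region = as.integer(source_region),
                 regions = regions, stim_region = as.integer(stim_region),
                 channels = channels),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %d channels x %d sources, %d regions (stim: %s)\n",
              nrow(x$leadfield), ncol(x$leadfield), length(x$regions),
              x$regions[x$stim_region]))
  invisible(x)
}

# random leadfield with bounded spectral condition number (default 3) and
# unit mean column norm; fixed by the RNG state at call time. When the
# system is overdetermined (sources <= channels) the columns are drawn
# orthogonal with graded gains, so distinct regions project to
# distinguishable sensor patterns and source crosstalk stays a small
# perturbation; otherwise a graded-spectrum random matrix is used.
make_leadfield <- function(n_channels, n_sources, cond = 3) {
  m <- matrix(stats::rnorm(n_channels * n_sources), n_channels, n_sources)
  if (n_sources <= n_channels) {
    q <- qr.Q(qr(m))
    g <- q %*% diag(seq(cond, 1, length.out = n_sources), n_sources)
  } else {
    sv <- svd(m)
    k <- length(sv$d)
    g <- sv$u %*% (seq(cond, 1, length.out = k) * t(sv$v))
  }
  g / mean(sqrt(colSums(g^2)))
}

# random sensor correlation matrix (unit diagonal, positive definite)
make_sensor_correlation <- function(n_channels) {
  a <- matrix(stats::rnorm(n_channels * 2L * n_channels), n_channels)
  s <- tcrossprod(a) / (2L * n_channels)
  d <- 1 / sqrt(diag(s))
  s * tcrossprod(d)
}

# clinical covariates emulating the study demographics: age ~ mid-forties in
# both groups, 40% female, MADRS 32.1 (7.1) and illness duration 10.9 (9.2)
# years in the TRD group only
make_clinical <- function(n_trd, n_hc) {
  n <- n_trd + n_hc
  group <- c(rep("TRD", n_trd), rep("HC", n_hc))
  age <- c(stats::rnorm(n_trd, 45.37, 11.85), stats::rnorm(n_hc, 45.63, 13.16))
  sex <- ifelse(stats::runif(n) < 0.4, "F", "M")
  madrs <- ifelse(group == "TRD", stats::rnorm(n, 32.1, 7.1), NA_real_)
  dur <- ifelse(group == "TRD", pmax(0.5, stats::rnorm(n, 10.9, 9.2)), NA_real_)
  data.frame(subject = sprintf("sub-%03d", seq_len(n)), group = group,
             age = round(age, 1), sex = sex, madrs = round(madrs, 1),
             duration_illness = round(dur, 1), stringsAsFactors = FALSE)
}

#' Generate a synthetic ICF TMS-EEG cohort
#'
#' Simulates a full two-group paired-pulse facilitation study with known
#' ground truth. Per subject and condition the generator builds an evoked
#' source time course (damped sinusoids peaking near 100 ms), projects it
#' through a fixed random leadfield, and adds spatially correlated Gaussian
#' sensor noise per trial. The paired-pulse condition carries an extra
#' facilitation response whose subject-level gain is reduced in the TRD
#' group by `planted_effect_d` between-subject SDs at the stimulated region,
#' scaled by `propagation_profile` elsewhere; `planted_effect_d = 0` is the
#' exact null. Optional artifacts (bad channels, high-amplitude epochs,
#' pulse-window transients) are planted and reported in the ground truth.
#'
#' @param config a [synth_config()].
#' @return list with elements `epochs` (per subject: list of `single` and
#'   `paired` [epoch_set]s), `source_model`, `clinical` (data.frame),
#'   `ground_truth` and `config`.
#' @export
#' @examples
#' cfg <- synth_config(n_trd = 2, n_hc = 1, n_trials_per_condition = 4,
#'                     n_channels = 8, sampling_rate = 250,
#'                     epoch_window = c(-400, 400), seed = 1)
#' ds <- generate_tep_dataset(cfg)
#' dim(ds$epochs[[1]]$paired$data)
generate_tep_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n_sub <- config$n_trd + config$n_hc
  nch <- config$n_channels
  nspr <- config$n_sources_per_region
  nsrc <- config$n_regions * nspr
  sfreq <- config$sampling_rate
  times <- seq(config$epoch_window[1], config$epoch_window[2],
               by = 1000 / sfreq)
  nt <- length(times)
  ntr <- config$n_trials_per_condition

  montage <- standard_montage(nch)
  gain <- make_leadfield(nch, nsrc)
  src_region <- rep(seq_len(config$n_regions), each = nspr)
  model <- source_model(gain, src_region, regions = dk_regions()[seq_len(config$n_regions)],
                        stim_region = min(dk_stim_index(), config$n_regions),
                        channels = montage$name)
  sigma <- make_sensor_correlation(nch)
  noise_chol <- chol(sigma)

  clinical <- make_clinical(config$n_trd, config$n_hc)
  u <- evoked_waveform(times, config$waveform)
  prof <- config$propagation_profile
  # propagation weights: how strongly each region responds at all
  wreg <- 0.3 + 0.7 * prof

  # subject-level gains
  gain_sub <- stats::rnorm(n_sub, 1, config$subject_gain_sd)
  facil_sub <- stats::rnorm(n_sub, config$icf_gain_mean, config$icf_gain_sd)
  is_trd <- clinical$group == "TRD"

  art <- config$artifact_spec
  protected <- dlpfc_electrodes()
  trans_idx <- which(times >= art$transient_window[1] &
                       times <= art$transient_window[2])

  epochs <- vector("list", n_sub)
  names(epochs) <- clinical$subject
  gt_bad_ch <- list(); gt_bad_ep <- list()
  true_means <- list()

  for (s in seq_len(n_sub)) {
    # per-region facilitation gain for this subject (group reduction scaled
    # by the propagation profile of the planted difference)
    reduce <- if (is_trd[s]) config$planted_effect_d * config$icf_gain_sd * prof
              else 0 * prof
    facil_r <- facil_sub[s] - reduce

    # source amplitude per source x condition component
    amp_single <- config$source_amp * gain_sub[s] * wreg[src_region]
    amp_extra <- config$source_amp * gain_sub[s] *
      wreg[src_region] * facil_r[src_region]

    ev_single <- gain %*% (amp_single %o% u)          # channels x time
    ev_paired <- ev_single + gain %*% (amp_extra %o% u)

    bad_ch_names <- character()
    if (art$n_bad_channels > 0) {
      cand <- setdiff(montage$name, protected)
      bad_ch_names <- sample(cand, art$n_bad_channels)
    }
    sets <- list()
    bad_ep <- list(single = integer(), paired = integer())
    for (cond in c("single", "paired")) {
      ev <- if (cond == "single") ev_single else ev_paired
      z <- matrix(stats::rnorm(ntr * nch * nt), nch)
      noise <- config$noise_sd * crossprod(noise_chol, z)  # nch x (ntr*nt)
      dat <- array(0, c(ntr, nch, nt))
      for (tr in seq_len(ntr)) {
        cols <- ((tr - 1) * nt + 1):(tr * nt)
        dat[tr, , ] <- ev + noise[, cols]
      }
      if (length(bad_ch_names)) {
        j <- match(bad_ch_names, montage$name)
        dat[, j, ] <- dat[, j, ] * art$bad_channel_scale
      }
      if (art$n_bad_epochs > 0) {
        eps <- sample(seq_len(ntr), art$n_bad_epochs)
        good_ch <- setdiff(seq_len(nch), match(bad_ch_names, montage$name))
        ok_t <- which(times > art$transient_window[2] + 35 | times < -50)
        for (e in eps) {
          ch <- sample(good_ch, 1)
          t0 <- sample(ok_t, 1)
          dat[e, ch, t0] <- dat[e, ch, t0] +
            sign(stats::rnorm(1)) * art$bad_epoch_amp
        }
        bad_ep[[cond]] <- sort(eps)
      }
      if (isTRUE(art$tms_transient) && length(trans_idx)) {
        decay <- exp(-(seq_along(trans_idx) - 1) / (length(trans_idx) / 3))
        dat[, , trans_idx] <- sweep(dat[, , trans_idx, drop = FALSE], 3,
                                    art$transient_amp * decay, `+`)
      }
      sets[[cond]] <- epoch_set(dat, montage$name, sfreq, times,
                                condition = cond, positions = montage)
    }
    epochs[[s]] <- sets
    gt_bad_ch[[clinical$subject[s]]] <- bad_ch_names
    gt_bad_ep[[clinical$subject[s]]] <- bad_ep
    true_means[[clinical$subject[s]]] <- list(
      single_amp = amp_single, facilitation = facil_r)
  }

  ground_truth <- list(
    planted_effect_d = config$planted_effect_d,
    effect_profile = prof,
    stim_region = model$stim_region,
    bad_channels = gt_bad_ch,
    bad_epochs = gt_bad_ep,
    tms_transient = isTRUE(art$tms_transient),
    transient_window = art$transient_window,
    subject_gain = gain_sub,
    facilitation_gain = facil_sub,
    waveform = u,
    subject_effects = true_means
  )

  list(epochs = epochs, source_model = model, clinical = clinical,
       ground_truth = ground_truth, config = config)
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
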