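# Deterministic EEG cleaning chain for TMS-evoked epochs: baseline
# correction, robust bad-channel detection (DLPFC electrodes protected),
# amplitude-based epoch rejection, pulse-window excision with local cubic
# interpolation, anti-aliased downsampling, zero-phase band-pass and notch
# filtering, spherical-spline interpolation of removed channels, and average
# re-referencing. Independent component analysis is deliberately absent:
# the artifacts the generator plants are handled by these deterministic
# steps.

#' Preprocessing parameters
#'
#' @param epoch_window epoch limits in ms.
#' @param baseline_window window whose mean is subtracted per trial/channel.
#' @param channel_z_threshold robust z threshold for bad-channel detection.
#' @param protected_channels channels never auto-flagged (stimulation site).
#' @param epoch_amplitude_threshold absolute voltage threshold (uV) for
#'   epoch rejection.
#' @param excision_window window around the pulse replaced by cubic
#'   interpolation (ms).
#' @param excision_context ms of data on each side used to fit the cubic.
#' @param target_rate sampling rate after decimation (Hz).
#' @param bandpass band-pass edges (Hz).
#' @param notch band-stop edges (Hz).
#' @param channel_score `"per_trial_median"` (median across trials of
#'   within-trial robust z of the channel SD) or `"pooled"` (robust z of the
#'   SD pooled over all trials and samples).
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(epoch_window = c(-2000, 2000),
                              baseline_window = c(-500, -150),
                              channel_z_threshold = 3,
                              protected_channels = dlpfc_electrodes(),
                              epoch_amplitude_threshold = 1000,
                              excision_window = c(-5, 30),
                              excision_context = 20,
                              target_rate = 1000,
                              bandpass = c(0.5, 100),
                              notch = c(48, 52),
                              channel_score = c("per_trial_median", "pooled")) {
  stopifnot(channel_z_threshold > 0, epoch_amplitude_threshold > 0,
            baseline_window[1] >= epoch_window[1],
            baseline_window[2] <= epoch_window[2],
            excision_window[1] >= epoch_window[1],
            excision_window[2] <= epoch_window[2])
  structure(list(
    epoch_window = epoch_window, baseline_window = baseline_window,
    channel_z_threshold = channel_z_threshold,
    protected_channels = protected_channels,
    epoch_amplitude_threshold = epoch_amplitude_threshold,
    excision_window = excision_window, excision_context = excision_context,
    target_rate = target_rate, bandpass = bandpass, notch = notch,
    channel_score = match.arg(channel_score)), class = "preprocess_params")
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window, so the post-hoc baseline mean is zero to float precision.
#'
#' @param epochs an [epoch_set()].
#' @param baseline_window c(from, to) in ms.
#' @return corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_window = c(-500, -150)) {
  check_window(epochs$times, baseline_window, "baseline window")
  idx <- time_mask(epochs$times, baseline_window[1], baseline_window[2])
  if (!length(idx)) stop("empty baseline window")
  bl <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - as.vector(bl) # recycles over the time margin
  log_step(epochs, "baseline_correct", from = baseline_window[1],
           to = baseline_window[2])
}

#' Detect channels with abnormal variability
#'
#' Scores each channel's variability robustly against the other channels and
#' returns the names whose score exceeds the threshold. Variability is
#' computed on the trial residuals after removing the cross-trial mean, so a
#' strong stimulus-locked response does not masquerade as noise. With the
#' default `"per_trial_median"` score, the per-trial channel SDs are
#' z-scored across channels within each trial using median/MAD, and a
#' channel's score is the median of its per-trial z values; the `"pooled"`
#' alternative z-scores the single SD computed over all trials and samples.
#' Channels over the stimulation site (`protected`) are never flagged.
#' Detection only: the data are not modified.
#'
#' @param epochs an [epoch_set()].
#' @param z_threshold robust z threshold (default 3).
#' @param protected channel names exempt from exclusion.
#' @param method scoring method, see above.
#' @return character vector of flagged channel names (possibly empty).
#' @export
detect_bad_channels <- function(epochs, z_threshold = 3,
                                protected = dlpfc_electrodes(),
                                method = c("per_trial_median", "pooled")) {
  method <- match.arg(method)
  d <- dim(epochs$data)
  if (d[2] < 4) stop("need at least 4 channels")
  robust_z <- function(x) {
    s <- stats::mad(x)
    if (s == 0) return(rep(0, length(x)))
    (x - stats::median(x)) / s
  }
  # robust evoked estimate (cross-trial median) so sparse high-amplitude
  # trials do not leak into every trial's residual
  evoked <- apply(epochs$data, c(2, 3), stats::median)   # channels x time
  resid <- epochs$data -
    aperm(array(evoked, c(d[2], d[3], d[1])), c(3, 1, 2))
  if (method == "pooled") {
    sds <- apply(resid, 2, stats::sd)
    score <- robust_z(sds)
  } else {
    sds <- sqrt(rowMeans(sweep(resid, c(1, 2),
                               rowMeans(resid, dims = 2))^2, dims = 2))
    z <- t(apply(sds, 1, robust_z))                      # trials x channels
    score <- apply(z, 2, stats::median)
  }
  flag <- epochs$channels[score > z_threshold]
  flag <- setdiff(flag, protected)
  if (length(flag) == d[2]) stop("all channels flagged: corrupt recording")
  flag
}

#' Reject epochs with excessive amplitude
#'
#' Removes trials whose absolute voltage exceeds the threshold on any
#' channel not already flagged bad, evaluated outside the pulse excision
#' window (where the hardware transient lives and is later excised rather
#' than used to reject data). Removed trial indices are logged.
#'
#' @param epochs an [epoch_set()]; amplitude is evaluated on the data as
#'   given (normally after baseline correction).
#' @param amplitude_threshold in microvolts (default 1000).
#' @param ignore_window window in ms excluded from the amplitude scan
#'   (default the pulse excision window); `NULL` scans everything.
#' @return `epoch_set` with offending trials removed; attribute
#'   `rejected_trials` holds their original indices.
#' @export
reject_epochs <- function(epochs, amplitude_threshold = 1000,
                          ignore_window = c(-5, 30)) {
  stopifnot(amplitude_threshold > 0)
  keep_ch <- !(epochs$channels %in% epochs$bad_channels)
  keep_t <- rep(TRUE, length(epochs$times))
  if (!is.null(ignore_window))
    keep_t[time_mask(epochs$times, ignore_window[1], ignore_window[2])] <- FALSE
  sub <- epochs$data[, keep_ch, keep_t, drop = FALSE]
  peak <- apply(abs(sub), 1, max)
  bad <- which(peak > amplitude_threshold)
  if (length(bad) == dim(epochs$data)[1])
    stop("all epochs exceed the amplitude threshold")
  if (length(bad)) epochs$data <- epochs$data[-bad, , , drop = FALSE]
  epochs <- log_step(epochs, "reject_epochs",
                     threshold = amplitude_threshold,
                     n_rejected = length(bad),
                     rejected = paste(bad, collapse = ","))
  attr(epochs, "rejected_trials") <- bad
  epochs
}

#' Excise the pulse window and bridge it with a cubic fit
#'
#' Replaces all samples inside the excision window by the prediction of a
#' cubic polynomial fitted to `context` ms of data flanking the window on
#' each side, per trial and channel. A cubic underlying signal is therefore
#' reconstructed exactly, and the bridged segment joins the flanks smoothly.
#' Data outside the window are untouched.
#'
#' @param epochs an [epoch_set()].
#' @param excision_window c(from, to) in ms (default c(-5, 30)).
#' @param context ms of flanking data per side used for the fit.
#' @return `epoch_set` with the window bridged.
#' @export
excise_and_interpolate <- function(epochs, excision_window = c(-5, 30),
                                   context = 20) {
  times <- epochs$times
  check_window(times, excision_window, "excision window")
  inside <- time_mask(times, excision_window[1], excision_window[2])
  if (!length(inside)) return(log_step(epochs, "excise", skipped = TRUE))
  left <- which(times < excision_window[1] &
                  times >= excision_window[1] - context)
  right <- which(times > excision_window[2] &
                   times <= excision_window[2] + context)
  if (length(left) < 2 || length(right) < 2)
    stop("excision window too close to the epoch edge")
  flank <- c(left, right)
  # scaled time basis keeps the Vandermonde system well conditioned
  t0 <- mean(times[inside]); sc <- diff(range(times[flank])) / 2
  basis <- function(t) cbind(1, (t - t0) / sc, ((t - t0) / sc)^2,
                             ((t - t0) / sc)^3)
  xf <- basis(times[flank]); xi <- basis(times[inside])
  proj <- xi %*% solve(crossprod(xf), t(xf))   # inside x flank
  d <- dim(epochs$data)
  y <- matrix(epochs$data[, , flank], d[1] * d[2])   # (tr*ch) x flank
  fill <- y %*% t(proj)
  epochs$data[, , inside] <- array(fill, c(d[1], d[2], length(inside)))
  log_step(epochs, "excise_and_interpolate", from = excision_window[1],
           to = excision_window[2], context = context)
}

#' Zero-phase filtering and decimation
#'
#' Applies an anti-aliasing low-pass, decimates to `target_rate` (which must
#' divide the current rate), then applies the band-pass and band-stop
#' filters. All filters are Butterworth, applied forward-backward
#' (`signal::filtfilt`) for zero phase; the band-pass is realized as a
#' high-pass/low-pass cascade for numerical stability at the low edge.
#'
#' @param epochs an [epoch_set()].
#' @param bandpass c(low, high) Hz.
#' @param notch c(low, high) Hz band-stop, `NULL` to skip.
#' @param target_rate Hz; must divide `epochs$sfreq`.
#' @param order Butterworth order per section.
#' @return filtered, resampled `epoch_set`.
#' @export
filter_and_resample <- function(epochs, bandpass = c(0.5, 100),
                                notch = c(48, 52), target_rate = 1000,
                                order = 4) {
  sf <- epochs$sfreq
  if (target_rate > sf) stop("target rate above current rate")
  ratio <- sf / target_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("target rate must divide the sampling rate")
  ratio <- round(ratio)
  nyq_t <- target_rate / 2
  if (bandpass[2] >= nyq_t)
    stop("band-pass upper edge must be below the target Nyquist rate")

  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), d[3])  # time x (tr*ch)
  apply_filt <- function(filt, x) {
    apply(x, 2, function(col) signal::filtfilt(filt, col))
  }
  if (ratio > 1) {
    aa <- signal::butter(order, (0.8 * nyq_t) / (sf / 2), type = "low")
    flat <- apply_filt(aa, flat)
    keep <- seq(1, d[3], by = ratio)
    flat <- flat[keep, , drop = FALSE]
    epochs$times <- epochs$times[keep]
    epochs$sfreq <- target_rate
  }
  nyq <- epochs$sfreq / 2
  hp <- signal::butter(order, bandpass[1] / nyq, type = "high")
  lp <- signal::butter(order, bandpass[2] / nyq, type = "low")
  flat <- apply_filt(lp, apply_filt(hp, flat))
  if (!is.null(notch)) {
    bs <- signal::butter(order, notch / nyq, type = "stop")
    flat <- apply_filt(bs, flat)
  }
  epochs$data <- aperm(array(flat, c(length(epochs$times), d[1], d[2])),
                       c(2, 3, 1))
  log_step(epochs, "filter_and_resample", low = bandpass[1],
           high = bandpass[2],
           notch = if (is.null(notch)) "none" else paste(notch, collapse = "-"),
           rate = epochs$sfreq, idempotent = FALSE)
}

#' Interpolate flagged channels by spherical splines
#'
#' Replaces the data of flagged channels with spherical-spline estimates
#' (Perrin et al. interpolation on the unit sphere) computed from the
#' remaining channels. With no flagged channels this is the identity.
#'
#' @param epochs an [epoch_set()] with electrode `positions`.
#' @param bad channel names to rebuild (default the recorded bad channels).
#' @param m spline order (default 4).
#' @param nterms number of Legendre terms (default 50).
#' @param lambda ridge regularization of the spline system.
#' @return `epoch_set` with channels rebuilt and the bad list cleared.
#' @export
interpolate_bad_channels <- function(epochs, bad = epochs$bad_channels,
                                     m = 4, nterms = 50, lambda = 1e-5) {
  if (!length(bad)) return(log_step(epochs, "interpolate_bad_channels",
                                    n = 0))
  if (is.null(epochs$positions)) stop("electrode positions required")
  if (length(bad) > length(epochs$channels) / 2)
    stop("more than half of the channels flagged")
  good <- setdiff(epochs$channels, bad)
  pos <- epochs$positions
  pg <- as.matrix(pos[match(good, pos$name), c("x", "y", "z")])
  pb <- as.matrix(pos[match(bad, pos$name), c("x", "y", "z")])
  tr <- spline_transfer(pg, pb, m = m, nterms = nterms, lambda = lambda)
  d <- dim(epochs$data)
  gi <- match(good, epochs$channels); bi <- match(bad, epochs$channels)
  for (trial in seq_len(d[1])) {
    epochs$data[trial, bi, ] <- tr %*% epochs$data[trial, gi, ]
  }
  epochs$bad_channels <- character()
  log_step(epochs, "interpolate_bad_channels", n = length(bad),
           channels = paste(bad, collapse = ","))
}

#' Re-reference to the average of all electrodes
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the cross-channel mean is zero at every trial and time point. Idempotent,
#' and channel differences are unchanged.
#'
#' @param epochs an [epoch_set()].
#' @return re-referenced `epoch_set`.
#' @export
rereference_average <- function(epochs) {
  if (dim(epochs$data)[2] < 2) stop("need at least 2 channels")
  mu <- apply(epochs$data, c(1, 3), mean)   # trials x time
  d <- dim(epochs$data)
  epochs$data <- epochs$data -
    aperm(array(mu, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs$reference <- "average"
  log_step(epochs, "rereference_average")
}

#' Run the full preprocessing chain
#'
#' Applies, in order: baseline correction, bad-channel detection, epoch
#' rejection, pulse-window excision with cubic bridging, anti-aliased
#' decimation with band-pass/notch filtering, spherical-spline interpolation
#' of the flagged channels, and average re-referencing. The returned object
#' logs every step with its parameters; `attr(, "report")` summarizes the
#' flagged channels and rejected trials.
#'
#' @param epochs raw [epoch_set()].
#' @param params a [preprocess_params()].
#' @return cleaned `epoch_set`.
#' @export
run_preprocessing <- function(epochs, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  out <- baseline_correct(epochs, params$baseline_window)
  bad <- detect_bad_channels(out, params$channel_z_threshold,
                             params$protected_channels,
                             method = params$channel_score)
  out$bad_channels <- bad
  out <- log_step(out, "detect_bad_channels", n = length(bad),
                  channels = paste(bad, collapse = ","))
  out <- reject_epochs(out, params$epoch_amplitude_threshold,
                       ignore_window = params$excision_window)
  rejected <- attr(out, "rejected_trials")
  out <- excise_and_interpolate(out, params$excision_window,
                                params$excision_context)
  out <- filter_and_resample(out, params$bandpass, params$notch,
                             params$target_rate)
  out <- interpolate_bad_channels(out, bad)
  out <- rereference_average(out)
  attr(out, "report") <- list(bad_channels = bad,
                              rejected_trials = rejected,
                              n_trials = dim(out$data)[1])
  out
}
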