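# Sensor-level evoked summaries: trial averaging, DLPFC electrode cluster
# series, paired-minus-single facilitation contrasts, local mean field
# power, and time-window means.

#' Time window of interest
#'
#' Default 50-120 ms after the pulse, the interval over which the evoked
#' facilitation response peaks; both endpoints are inclusive.
#'
#' @param start,end window limits in ms.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(start = 50, end = 120) {
  stopifnot(start < end)
  structure(list(start = start, end = end), class = "window_spec")
}

#' Average trials into an evoked response
#'
#' @param epochs an [epoch_set()] with at least one trial.
#' @return object of class `evoked`: list with `data` (channels x time
#'   matrix, uV), `channels`, `times`, `sfreq`, `n_trials`, `condition`.
#' @export
average_tep <- function(epochs) {
  if (n_trials(epochs) < 1) stop("no trials to average")
  avg <- colMeans(epochs$data, dims = 1)   # channels x time
  structure(list(data = avg, channels = epochs$channels,
                 times = epochs$times, sfreq = epochs$sfreq,
                 n_trials = n_trials(epochs), condition = epochs$condition),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %s: %d channels x %d samples (%d trials)\n",
              x$condition, nrow(x$data), ncol(x$data), x$n_trials))
  invisible(x)
}

#' Electrode-cluster time series
#'
#' Unweighted mean waveform across the named electrodes, by default the
#' three electrodes over the stimulated DLPFC.
#'
#' @param evoked an [average_tep()] result.
#' @param electrodes channel names to average.
#' @return numeric time series (uV), with the time axis as `attr(,"times")`.
#' @export
roi_series <- function(evoked, electrodes = dlpfc_roi()) {
  idx <- match(electrodes, evoked$channels)
  if (anyNA(idx))
    stop("missing electrode(s): ",
         paste(electrodes[is.na(idx)], collapse = ", "))
  out <- colMeans(evoked$data[idx, , drop = FALSE])
  attr(out, "times") <- evoked$times
  out
}

#' Facilitation contrast between two time series
#'
#' Point-wise paired-pulse minus single-pulse difference. Both series must
#' share the same time axis.
#'
#' @param series_paired,series_single numeric series with matching
#'   `attr(,"times")` (or equal length if no time axis is attached).
#' @return difference series, paired minus single.
#' @export
icf_contrast <- function(series_paired, series_single) {
  tp <- attr(series_paired, "times"); ts <- attr(series_single, "times")
  if (!is.null(tp) && !is.null(ts) &&
      (length(tp) != length(ts) || any(tp != ts)))
    stop("time axes do not match")
  if (length(series_paired) != length(series_single))
    stop("series lengths do not match")
  out <- series_paired - series_single
  attr(out, "times") <- tp %||% ts
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local mean field power over an electrode cluster
#'
#' Field strength of the evoked response across a local electrode set at
#' each time point. `"rms"` (default) is the root mean square across the
#' electrodes, the conventional LMFP; `"abs"` averages absolute voltages
#' instead. The facilitation LMFP contrast is `icf_contrast(lmfp(paired),
#' lmfp(single))`.
#'
#' @param evoked an [average_tep()] result.
#' @param electrodes channel names of the local cluster.
#' @param method `"rms"` or `"abs"`.
#' @return non-negative time series with `attr(,"times")`.
#' @export
lmfp <- function(evoked, electrodes = dlpfc_roi(),
                 method = c("rms", "abs")) {
  method <- match.arg(method)
  idx <- match(electrodes, evoked$channels)
  if (anyNA(idx))
    stop("missing electrode(s): ",
         paste(electrodes[is.na(idx)], collapse = ", "))
  sub <- evoked$data[idx, , drop = FALSE]
  out <- if (method == "rms") sqrt(colMeans(sub^2)) else colMeans(abs(sub))
  attr(out, "times") <- evoked$times
  out
}

#' Mean of a time series over the window of interest
#'
#' Arithmetic mean over the samples with `start <= t <= end` (inclusive).
#'
#' @param series numeric series with `attr(,"times")` in ms.
#' @param window a [window_spec()].
#' @param times time axis, taken from the series attribute by default.
#' @return scalar mean.
#' @export
window_mean <- function(series, window = window_spec(),
                        times = attr(series, "times")) {
  if (is.null(times)) stop("no time axis available")
  idx <- time_mask(times, window$start, window$end)
  if (!length(idx)) stop("window contains no samples")
  mean(series[idx])
}
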