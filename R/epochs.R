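#' Construct an epoch set
#'
#' Container for epoched multi-channel EEG: a trials x channels x time array
#' in microvolts with channel metadata, a time axis in milliseconds relative
#' to the TMS pulse, and an ordered processing log. Every preprocessing step
#' returns a new `epoch_set` with one log record appended, so the full chain
#' applied to a dataset can be reconstructed from the object itself.
#'
#' @param data numeric array, trials x channels x time (microvolts).
#' @param channels character vector of channel names (10-20 labels),
#'   length `dim(data)[2]`.
#' @param sfreq sampling rate in Hz.
#' @param times numeric time axis in ms, length `dim(data)[3]`, strictly
#'   increasing, 0 = TMS pulse.
#' @param condition condition tag, e.g. `"single"` or `"paired"`.
#' @param reference reference state tag (`"linked"` at acquisition,
#'   `"average"` after re-referencing).
#' @param positions optional data.frame of unit-sphere electrode positions
#'   (columns `name, x, y, z`); required for spherical interpolation.
#' @param bad_channels character vector of channels flagged bad.
#' @param log list of step records.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, channels, sfreq, times,
                      condition = "single", reference = "linked",
                      positions = NULL, bad_channels = character(),
                      log = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(channels) != dim(data)[2])
    stop("channel count does not match names")
  if (length(times) != dim(data)[3])
    stop("time axis length does not match data")
  if (any(diff(times) <= 0)) stop("time axis must be strictly increasing")
  structure(
    list(data = data, channels = as.character(channels), sfreq = sfreq,
         times = as.numeric(times), condition = condition,
         reference = reference, positions = positions,
         bad_channels = bad_channels, log = log),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz [%g, %g] ms\n",
    d[1], d[2], d[3], x$sfreq, min(x$times), max(x$times)))
  cat(sprintf("  condition: %s | reference: %s | bad channels: %s\n",
              x$condition, x$reference,
              if (length(x$bad_channels)) paste(x$bad_channels, collapse = ",")
              else "none"))
  if (length(x$log))
    cat("  log:", paste(vapply(x$log, `[[`, "", "step"), collapse = " -> "),
        "\n")
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

# append one processing record; params must be a named list of scalars
log_step <- function(epochs, step, ...) {
  rec <- list(step = step, params = list(...))
  epochs$log <- c(epochs$log, list(rec))
  epochs
}

# indices of samples with from <= t <= to (ms, inclusive ends)
time_mask <- function(times, from, to) {
  if (from > to) stop("empty time window")
  which(times >= from & times <= to)
}

# sample indices strictly inside an open window (from, to)
time_mask_open <- function(times, from, to) {
  which(times > from & times < to)
}

check_window <- function(times, window, what = "window") {
  if (window[1] < min(times) || window[2] > max(times))
    stop(what, " [", window[1], ", ", window[2], "] ms outside the epoch [",
         min(times), ", ", max(times), "] ms")
  invisible(TRUE)
}
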