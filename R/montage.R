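# Nominal spherical 10-10 montage. Positions are built from two nominal
# angles per electrode: an anterior-posterior rotation away from the vertex
# along the midline and a lateral rotation along the coronal arc (odd digits
# left, even digits right, 18 degrees per 10% step). This is the usual
# idealized spherical layout, adequate for spherical-spline interpolation;
# it makes no claim to subject-specific geometry.

.montage_rows <- function() {
  # row label -> anterior(+)/posterior(-) angle in degrees from the vertex
  c(
    Fp = 72, AF = 54, F = 36, FT = 18, FC = 18, C = 0, T = 0,
    TP = -18, CP = -18, P = -36, PO = -54, O = -72, I = -90
  )
}

.montage_labels <- function() {
  c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2",
    "Iz"
  )
}

.parse_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3L) stop("unrecognized electrode label: ", label)
  list(row = m[2], pos = m[3])
}

.label_angles <- function(label) {
  p <- .parse_label(label)
  rows <- .montage_rows()
  if (!p$row %in% names(rows)) stop("unknown electrode row: ", p$row)
  ap <- rows[[p$row]]
  if (identical(p$pos, "z")) {
    lat <- 0
  } else {
    d <- as.integer(p$pos)
    # odd digits on the left (positive lateral angle), even on the right
    step <- ceiling(d / 2)
    lat <- 18 * step * if (d %% 2 == 1) 1 else -1
  }
  c(ap = ap, lat = lat)
}

#' Standard spherical electrode montage
#'
#' Returns a nominal spherical 10-10 montage of up to 64 electrodes as unit
#' 3D positions (head radius 1, x toward the nose, y toward the left ear,
#' z toward the vertex). For `n < 64` a deterministic subset is returned that
#' always contains the DLPFC electrodes (`F7, F5, F3, F1, AF3, FC3, FC5`) and
#' spreads the remaining channels over the scalp.
#'
#' @param n Number of electrodes (4..64).
#' @return data.frame with columns `name`, `x`, `y`, `z`.
#' @export
#' @examples
#' head(standard_montage(16))
standard_montage <- function(n = 64) {
  labels <- .montage_labels()
  stopifnot(n >= 4, n <= length(labels))
  if (n < length(labels)) {
    keep <- dlpfc_electrodes()
    rest <- setdiff(labels, keep)
    idx <- round(seq(1, length(rest), length.out = n - length(keep)))
    labels <- c(keep, rest[idx])
    labels <- labels[order(match(labels, .montage_labels()))]
  }
  ang <- t(vapply(labels, .label_angles, numeric(2)))
  ap <- ang[, "ap"] * pi / 180
  lat <- ang[, "lat"] * pi / 180
  # vertex (0,0,1) rotated forward by ap about the y-axis, then laterally
  # about the resulting anterior axis; equivalent closed form:
  x <- sin(ap) * cos(lat)
  y <- sin(lat)
  z <- cos(ap) * cos(lat)
  r <- sqrt(x^2 + y^2 + z^2)
  data.frame(name = labels, x = x / r, y = y / r, z = z / r,
             stringsAsFactors = FALSE)
}

#' Electrodes over the left DLPFC stimulation site
#'
#' The seven frontal electrodes covering the stimulated left DLPFC. These are
#' protected from automatic bad-channel exclusion during preprocessing.
#'
#' @return Character vector of electrode names.
#' @export
dlpfc_electrodes <- function() c("F5", "F3", "F1", "F7", "AF3", "FC3", "FC5")

#' Sensor region of interest for the DLPFC evoked response
#'
#' The electrode cluster averaged for sensor-level DLPFC summaries.
#' @return Character vector of electrode names.
#' @export
dlpfc_roi <- function() c("F3", "F5", "AF3")
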