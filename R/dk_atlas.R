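#' Canonical left-hemisphere Desikan-Killiany region list
#'
#' The 34 cortical regions of the Desikan-Killiany parcellation for one
#' hemisphere, in the conventional FreeSurfer `aparc` order. All region-indexed
#' objects in the package (source models, region time series, t-maps,
#' expression matrices) use this order, so vectors from different modules can
#' be aligned by position as well as by name.
#'
#' @return Character vector of length 34.
#' @export
#' @examples
#' length(dk_regions())
#' dk_stim_region() %in% dk_regions()
dk_regions <- function() {
  c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula"
  )
}

#' Stimulated region of the left DLPFC target
#'
#' The Desikan-Killiany region containing the stimulation target at MNI
#' coordinates (-38, 44, 26), i.e. the rostral middle frontal gyrus, which is
#' the standard DK label for the left dorsolateral prefrontal cortex.
#'
#' @return Single region name (character).
#' @export
dk_stim_region <- function() "rostralmiddlefrontal"

#' Index of the stimulated region in the canonical order
#' @return Integer index into [dk_regions()].
#' @export
dk_stim_index <- function() match(dk_stim_region(), dk_regions())
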