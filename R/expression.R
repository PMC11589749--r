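# AHBA-style expression preprocessing: background filtering at the probe
# level, sample-to-region assignment with a 2 mm threshold and
# left-hemisphere restriction, probe selection and gene filtering by
# differential stability across donors, and construction of the final
# genes x regions expression matrix with within-donor normalization.

#' Filter probes by the above-background rule
#'
#' Keeps probes whose fraction of above-background samples is at least
#' `min_fraction` (inclusive, so exactly 50% survives the default rule).
#'
#' @param probes long probe table with columns `probe_id`, `gene`,
#'   `sample_id`, `intensity`, `above_background`.
#' @param min_fraction minimum above-background fraction (default 0.5).
#' @return filtered probe table; attribute `removed_probes` lists the
#'   excluded probe ids.
#' @export
filter_background <- function(probes, min_fraction = 0.5) {
  stopifnot(is.logical(probes$above_background))
  frac <- tapply(probes$above_background, probes$probe_id, mean)
  keep <- names(frac)[frac >= min_fraction]
  if (!length(keep)) stop("no probe survives the background filter")
  out <- probes[probes$probe_id %in% keep, , drop = FALSE]
  attr(out, "removed_probes") <- sort(setdiff(names(frac), keep))
  out
}

#' Assign samples to regions by proximity
#'
#' Drops right-hemisphere samples, then assigns each remaining sample to its
#' nearest region centroid if the Euclidean distance is at most
#' `max_distance` mm; farther samples are dropped with a warning count.
#'
#' @param samples table with `sample_id`, `donor`, `hemisphere`, `x`, `y`,
#'   `z` (mm).
#' @param centroids region geometry: `region`, `x`, `y`, `z` (left
#'   hemisphere).
#' @param max_distance assignment threshold in mm (default 2).
#' @return data.frame `sample_id`, `donor`, `region`, `distance` for the
#'   assigned samples; attributes `dropped_far` and `dropped_right`.
#' @export
assign_samples <- function(samples, centroids, max_distance = 2) {
  stopifnot(all(is.finite(as.matrix(samples[, c("x", "y", "z")]))))
  right <- samples$hemisphere != "left"
  left <- samples[!right, , drop = FALSE]
  cm <- as.matrix(centroids[, c("x", "y", "z")])
  sm <- as.matrix(left[, c("x", "y", "z")])
  # squared distances samples x centroids
  d2 <- outer(rowSums(sm^2), rowSums(cm^2), `+`) - 2 * sm %*% t(cm)
  d2[d2 < 0] <- 0
  nearest <- max.col(-d2)
  dist <- sqrt(d2[cbind(seq_len(nrow(sm)), nearest)])
  ok <- dist <= max_distance
  if (!any(ok)) warning("no sample could be assigned to a region")
  out <- data.frame(sample_id = left$sample_id[ok], donor = left$donor[ok],
                    region = centroids$region[nearest[ok]],
                    distance = dist[ok], stringsAsFactors = FALSE)
  attr(out, "dropped_far") <- left$sample_id[!ok]
  attr(out, "dropped_right") <- samples$sample_id[right]
  out
}

# per-donor probe x region mean-intensity profiles for the assigned samples
probe_region_profiles <- function(probes, assignments) {
  pr <- merge(probes, assignments, by = "sample_id")
  donors <- sort(unique(pr$donor))
  probe_ids <- sort(unique(pr$probe_id))
  regions <- sort(unique(pr$region))
  lapply(stats::setNames(donors, donors), function(d) {
    sub <- pr[pr$donor == d, ]
    m <- tapply(sub$intensity, list(factor(sub$probe_id, probe_ids),
                                    factor(sub$region, regions)), mean)
    m
  })
}

#' Differential stability: probe selection and gene filter
#'
#' Differential stability (DS) of a probe is the mean over donor pairs of
#' the Pearson correlation between the probe's regional expression profiles
#' in the two donors (computed over the regions both donors cover). Per
#' gene, the probe with the highest DS is selected; genes are then ranked by
#' the DS of their selected probe and the top `keep_fraction` retained.
#'
#' @param probes (background-filtered) long probe table.
#' @param assignments sample-to-region assignment from [assign_samples()].
#' @param keep_fraction fraction of genes kept by the DS filter
#'   (default 0.5).
#' @return list with `selection` (data.frame gene, probe_id, ds),
#'   `kept_genes`, `ds_threshold`.
#' @export
differential_stability_select <- function(probes, assignments,
                                          keep_fraction = 0.5) {
  profiles <- probe_region_profiles(probes, assignments)
  if (length(profiles) < 2) stop("need at least 2 donors")
  if (ncol(profiles[[1]]) < 3) stop("need at least 3 common regions")
  pairs <- utils::combn(length(profiles), 2)
  ds_mat <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- profiles[[pairs[1, k]]]; b <- profiles[[pairs[2, k]]]
    vapply(seq_len(nrow(a)), function(i) {
      ok <- is.finite(a[i, ]) & is.finite(b[i, ])
      if (sum(ok) < 3) return(NA_real_)
      stats::cor(a[i, ok], b[i, ok])
    }, 0)
  }, numeric(nrow(profiles[[1]])))
  ds_mat <- matrix(ds_mat, nrow = nrow(profiles[[1]]))
  ds <- rowMeans(ds_mat, na.rm = TRUE)
  names(ds) <- rownames(profiles[[1]])

  gene_of <- probes$gene[match(names(ds), probes$probe_id)]
  sel <- do.call(rbind, lapply(split(seq_along(ds), gene_of), function(ii) {
    best <- ii[which.max(ds[ii])]
    data.frame(gene = gene_of[best], probe_id = names(ds)[best],
               ds = ds[best], stringsAsFactors = FALSE)
  }))
  rownames(sel) <- NULL
  n_keep <- ceiling(keep_fraction * nrow(sel))
  thr <- sort(sel$ds, decreasing = TRUE)[n_keep]
  kept <- sel$gene[sel$ds >= thr]
  list(selection = sel, kept_genes = sort(kept), ds_threshold = thr)
}

# scaled robust sigmoid normalization of one vector (median/IQR sigmoid,
# then min-max to the unit interval)
srs_normalize <- function(x) {
  med <- stats::median(x)
  sc <- stats::IQR(x) / 1.35
  if (sc == 0) return(rep(0.5, length(x)))
  s <- 1 / (1 + exp(-(x - med) / sc))
  rng <- range(s)
  if (diff(rng) == 0) rep(0.5, length(x)) else (s - rng[1]) / diff(rng)
}

#' Build the genes x regions expression matrix
#'
#' For each donor, the selected probe's intensities are normalized per gene
#' across that donor's assigned samples (scaled robust sigmoid by default),
#' averaged within region, and the donor region-vectors are then averaged
#' into the final matrix. Regions with no sample in any donor are an error.
#'
#' @param probes background-filtered long probe table.
#' @param assignments from [assign_samples()].
#' @param selection `selection` data.frame from
#'   [differential_stability_select()] (one probe per gene); genes outside
#'   `kept_genes` should already be excluded by the caller if desired.
#' @param regions region names defining the column order.
#' @param normalization `"srs"`, `"zscore"` or `"none"`.
#' @return matrix genes x regions with attribute `provenance` (selection
#'   table) and `normalization`.
#' @export
build_matrix <- function(probes, assignments, selection,
                         regions = dk_regions(),
                         normalization = c("srs", "zscore", "none")) {
  normalization <- match.arg(normalization)
  probes <- probes[probes$probe_id %in% selection$probe_id, , drop = FALSE]
  pr <- merge(probes, assignments, by = "sample_id")
  pr$gene <- selection$gene[match(pr$probe_id, selection$probe_id)]
  donors <- sort(unique(pr$donor))
  genes <- sort(unique(selection$gene))
  norm_fun <- switch(normalization,
                     srs = srs_normalize,
                     zscore = function(x) as.numeric(scale(x)),
                     none = identity)
  donor_mats <- lapply(donors, function(d) {
    sub <- pr[pr$donor == d, ]
    m <- matrix(NA_real_, length(genes), length(regions),
                dimnames = list(genes, regions))
    for (g in split(seq_len(nrow(sub)), sub$gene)) {
      x <- norm_fun(sub$intensity[g])
      mm <- tapply(x, factor(sub$region[g], regions), mean)
      m[sub$gene[g[1]], ] <- mm
    }
    m
  })
  covered <- Reduce(`+`, lapply(donor_mats, function(m) !is.na(m)))
  if (any(covered == 0))
    stop("region without samples in any donor: ",
         paste(unique(regions[colSums(covered == 0) > 0]), collapse = ", "))
  total <- Reduce(`+`, lapply(donor_mats, function(m) {
    m[is.na(m)] <- 0; m
  }))
  out <- total / covered
  attr(out, "provenance") <- selection
  attr(out, "normalization") <- normalization
  out
}

#' Load and validate cell-type gene sets
#'
#' @param annotation data.frame with columns `gene`, `cell_type` (labels
#'   within the nine canonical classes, each gene at most once).
#' @param matrix_genes genes present in the expression matrix; sets are
#'   restricted to these.
#' @return named list of gene vectors, one per requested class.
#' @export
load_cell_sets <- function(annotation, matrix_genes) {
  unknown <- setdiff(unique(annotation$cell_type), cell_types())
  if (length(unknown))
    stop("unknown cell class: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(annotation$gene))
    stop("gene annotated to more than one class: ",
         paste(unique(annotation$gene[duplicated(annotation$gene)]),
               collapse = ", "))
  present <- annotation[annotation$gene %in% matrix_genes, , drop = FALSE]
  sets <- split(present$gene, factor(present$cell_type,
                                     levels = unique(annotation$cell_type)))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    stop("no matrix genes for class: ", paste(empty, collapse = ", "))
  sets
}

#' Run the full expression pipeline on a fixture
#'
#' Chains the filters in their canonical order — background filter, sample
#' assignment (2 mm, left hemisphere), differential-stability probe
#' selection and gene filter, matrix construction, cell-set loading — and
#' records what each stage removed.
#'
#' @param fixture result of [generate_expression_fixture()] (or an
#'   equivalently shaped list of tables).
#' @param min_fraction background threshold.
#' @param max_distance assignment threshold (mm).
#' @param keep_fraction DS gene-filter fraction.
#' @param normalization passed to [build_matrix()].
#' @return list with `matrix`, `cell_sets`, `assignments`, `selection`,
#'   `log`.
#' @export
process_expression_fixture <- function(fixture, min_fraction = 0.5,
                                       max_distance = 2,
                                       keep_fraction = 0.5,
                                       normalization = "srs") {
  pb <- filter_background(fixture$probes, min_fraction)
  asg <- assign_samples(fixture$samples, fixture$centroids, max_distance)
  dsel <- differential_stability_select(pb, asg, keep_fraction)
  sel <- dsel$selection[dsel$selection$gene %in% dsel$kept_genes, ,
                        drop = FALSE]
  mat <- build_matrix(pb, asg, sel, regions = fixture$centroids$region,
                      normalization = normalization)
  sets <- load_cell_sets(fixture$cell_annotation, rownames(mat))
  list(matrix = mat, cell_sets = sets, assignments = asg, selection = dsel,
       log = list(
         removed_probes = attr(pb, "removed_probes"),
         dropped_far = attr(asg, "dropped_far"),
         dropped_right = attr(asg, "dropped_right"),
         kept_genes = dsel$kept_genes,
         normalization = normalization))
}
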