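# Synthetic donor-level expression fixture in the style of the Allen Human
# Brain Atlas: probe-level intensity tables with above-background flags over
# multiple donors, sample coordinates around region centroids, and a
# gene-to-cell-type annotation over nine classes. Every filter of the
# expression pipeline has planted items on both sides, enumerated in the
# ground truth.

#' Canonical cell-type classes
#'
#' The nine cortical cell classes used for virtual histology.
#' @return character vector of length 9.
#' @export
cell_types <- function() {
  c("ependymal", "oligodendrocyte", "microglia", "CA1_pyramidal",
    "interneuron", "endothelial", "S1_pyramidal", "astrocyte", "mural")
}

#' Configuration for the expression fixture generator
#'
#' @param n_genes total genes (even; half are planted as donor-stable, half
#'   as donor-inconsistent so the differential-stability filter separates
#'   them cleanly).
#' @param n_donors donors (default 6).
#' @param n_regions cortical regions (default 34).
#' @param planted_celltype cell class whose genes carry the planted map
#'   correlation.
#' @param planted_r target correlation in `[-1, 1]` between the planted
#'   class's regional expression and `target_map`.
#' @param target_map length-`n_regions` vector the correlation is planted
#'   against; `NULL` uses the default propagation-difference profile.
#' @param genes_per_type marker genes per cell class.
#' @param n_bg_fail probes planted to fail the 50% above-background rule.
#' @param n_noisy_probes genes given a second, donor-inconsistent probe (the
#'   probe-selection step must prefer the stable one).
#' @param n_far_samples,n_right_samples per donor: samples planted beyond
#'   the 2 mm assignment threshold / in the right hemisphere.
#' @param seed RNG seed.
#' @return list of class `expression_config`.
#' @export
expression_config <- function(n_genes = 120, n_donors = 6, n_regions = 34,
                              planted_celltype = "astrocyte",
                              planted_r = 0.6, target_map = NULL,
                              genes_per_type = 5,
                              n_bg_fail = 8, n_noisy_probes = 10,
                              n_far_samples = 3, n_right_samples = 4,
                              seed = 1L) {
  if (n_donors < 2) stop("need at least 2 donors")
  if (abs(planted_r) > 1) stop("planted correlation outside [-1, 1]")
  if (n_genes %% 2 != 0) stop("n_genes must be even")
  if (!planted_celltype %in% cell_types()) stop("unknown cell type")
  if (9 * genes_per_type > n_genes / 2)
    stop("not enough stable genes for the cell-type sets")
  if (is.null(target_map)) {
    idx <- seq_len(n_regions)
    target_map <- exp(-abs(idx - min(dk_stim_index(), n_regions)) / 10)
  }
  if (length(target_map) != n_regions) stop("target_map length mismatch")
  structure(list(n_genes = n_genes, n_donors = n_donors,
                 n_regions = n_regions,
                 planted_celltype = planted_celltype,
                 planted_r = planted_r, target_map = target_map,
                 genes_per_type = genes_per_type, n_bg_fail = n_bg_fail,
                 n_noisy_probes = n_noisy_probes,
                 n_far_samples = n_far_samples,
                 n_right_samples = n_right_samples, seed = as.integer(seed)),
            class = "expression_config")
}

# well-separated left-hemisphere region centroids (mm): jittered lattice
# with x < 0, minimum spacing ~10 mm
make_centroids <- function(n_regions) {
  side <- ceiling(n_regions^(1 / 3))
  grid <- expand.grid(ix = seq_len(side), iy = seq_len(side),
                      iz = seq_len(side))[seq_len(n_regions), ]
  data.frame(region = dk_regions()[seq_len(n_regions)],
             hemisphere = "left",
             x = -20 - 12 * grid$ix + stats::runif(n_regions, -1, 1),
             y = 12 * grid$iy + stats::runif(n_regions, -1, 1),
             z = 12 * grid$iz + stats::runif(n_regions, -1, 1),
             stringsAsFactors = FALSE)
}

#' Generate an AHBA-like expression fixture with known truth
#'
#' Builds probe, sample and annotation tables for a multi-donor expression
#' dataset in which every downstream filter has planted pass and fail items:
#' probes below the 50% above-background rule, duplicate donor-inconsistent
#' probes that differential stability must reject, samples farther than 2 mm
#' from any region centroid, right-hemisphere samples, and one cell class
#' whose genes' regional expression correlates `planted_r` with
#' `target_map`. The ground truth lists every planted item exactly.
#'
#' @param config an [expression_config()].
#' @return list with `probes` (long table: probe_id, gene, sample_id,
#'   intensity, above_background), `samples`, `centroids`, `cell_annotation`
#'   (gene, cell_type), `ground_truth`, `config`.
#' @export
generate_expression_fixture <- function(config) {
  stopifnot(inherits(config, "expression_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  ng <- config$n_genes; nd <- config$n_donors; nr <- config$n_regions
  genes <- sprintf("GENE%04d", seq_len(ng))
  stable <- genes[seq_len(ng / 2)]
  unstable <- setdiff(genes, stable)

  # cell-type annotation over the stable genes, planted class first
  ann_genes <- stable[seq_len(9 * config$genes_per_type)]
  ann <- data.frame(
    gene = ann_genes,
    cell_type = rep(c(config$planted_celltype,
                      setdiff(cell_types(), config$planted_celltype)),
                    each = config$genes_per_type),
    stringsAsFactors = FALSE)
  planted_genes <- ann$gene[ann$cell_type == config$planted_celltype]

  # target map direction (unit-variance standardized) and an orthogonal
  # residual direction for the planted correlation
  y <- as.numeric(scale(config$target_map))
  zr <- stats::rnorm(nr)
  zr <- stats::residuals(stats::lm(zr ~ y))
  zr <- as.numeric(scale(zr))
  r0 <- config$planted_r

  # base regional profiles (log2-intensity scale, mean 7)
  base <- matrix(stats::rnorm(ng * nr, 0, 1), ng, nr,
                 dimnames = list(genes, NULL))
  base[match(planted_genes, genes), ] <-
    matrix(rep(r0 * y + sqrt(max(0, 1 - r0^2)) * zr, each = length(planted_genes)),
           length(planted_genes)) +
    0.15 * matrix(stats::rnorm(length(planted_genes) * nr),
                  length(planted_genes))
  base <- 7 + base

  centroids <- make_centroids(nr)

  # samples: per donor one sample inside each region (<= 1.5 mm from its
  # centroid), plus planted far (> 2 mm from every centroid) and
  # right-hemisphere samples
  samples <- list(); sid <- 0L
  for (d in seq_len(nd)) {
    donor <- sprintf("donor%02d", d)
    off <- function(rmin, rmax, n) {
      v <- matrix(stats::rnorm(3 * n), n)
      v <- v / sqrt(rowSums(v^2)) * stats::runif(n, rmin, rmax)
      v
    }
    o1 <- off(0.2, 1.5, nr)
    reg <- data.frame(sample_id = sprintf("s%04d", sid + seq_len(nr)),
                      donor = donor, hemisphere = "left",
                      x = centroids$x + o1[, 1], y = centroids$y + o1[, 2],
                      z = centroids$z + o1[, 3],
                      true_region = centroids$region,
                      planted = "assigned", stringsAsFactors = FALSE)
    sid <- sid + nr
    far_idx <- sample(nr, config$n_far_samples)
    o2 <- off(2.5, 3.5, config$n_far_samples)
    far <- data.frame(sample_id = sprintf("s%04d", sid + seq_len(config$n_far_samples)),
                      donor = donor, hemisphere = "left",
                      x = centroids$x[far_idx] + o2[, 1],
                      y = centroids$y[far_idx] + o2[, 2],
                      z = centroids$z[far_idx] + o2[, 3],
                      true_region = NA_character_,
                      planted = "far", stringsAsFactors = FALSE)
    sid <- sid + config$n_far_samples
    right_idx <- sample(nr, config$n_right_samples)
    o3 <- off(0.2, 1.5, config$n_right_samples)
    right <- data.frame(sample_id = sprintf("s%04d", sid + seq_len(config$n_right_samples)),
                        donor = donor, hemisphere = "right",
                        x = -(centroids$x[right_idx]) + o3[, 1],
                        y = centroids$y[right_idx] + o3[, 2],
                        z = centroids$z[right_idx] + o3[, 3],
                        true_region = NA_character_,
                        planted = "right_hemisphere", stringsAsFactors = FALSE)
    sid <- sid + config$n_right_samples
    samples[[d]] <- rbind(reg, far, right)
  }
  samples <- do.call(rbind, samples)
  ns <- nrow(samples)

  # probes: one good probe per gene; noisy duplicate probes for some stable
  # genes; background-failing probes for some genes
  probe_defs <- data.frame(probe_id = sprintf("P%05d", seq_len(ng)),
                           gene = genes, kind = "good",
                           stringsAsFactors = FALSE)
  noisy_genes <- sample(stable, config$n_noisy_probes)
  probe_defs <- rbind(probe_defs, data.frame(
    probe_id = sprintf("P%05d", ng + seq_len(config$n_noisy_probes)),
    gene = noisy_genes, kind = "noisy", stringsAsFactors = FALSE))
  bg_genes <- sample(genes, config$n_bg_fail)
  probe_defs <- rbind(probe_defs, data.frame(
    probe_id = sprintf("P%05d", ng + config$n_noisy_probes +
                         seq_len(config$n_bg_fail)),
    gene = bg_genes, kind = "bg_fail", stringsAsFactors = FALSE))

  # donor-specific profiles: stable genes share `base` (plus donor noise),
  # unstable genes get independent profiles per donor
  donor_ids <- unique(samples$donor)
  donor_profiles <- lapply(donor_ids, function(d) {
    p <- base + 0.25 * matrix(stats::rnorm(ng * nr), ng, nr)
    ui <- match(unstable, genes)
    p[ui, ] <- 7 + matrix(stats::rnorm(length(ui) * nr), length(ui))
    p
  })
  names(donor_profiles) <- donor_ids

  region_of <- match(samples$true_region, centroids$region)  # NA for far/right
  donor_of <- match(samples$donor, donor_ids)

  n_probe <- nrow(probe_defs)
  intens <- matrix(NA_real_, n_probe, ns,
                   dimnames = list(probe_defs$probe_id, samples$sample_id))
  for (p in seq_len(n_probe)) {
    gi <- match(probe_defs$gene[p], genes)
    if (probe_defs$kind[p] == "noisy") {
      vals <- 7 + stats::rnorm(ns)          # no regional structure
    } else {
      mu <- vapply(seq_len(ns), function(s) {
        r <- region_of[s]
        if (is.na(r)) 7 else donor_profiles[[donor_of[s]]][gi, r]
      }, 0)
      vals <- mu + 0.1 * stats::rnorm(ns)
    }
    intens[p, ] <- vals
  }

  # above-background flags with deterministic counts per probe: good/noisy
  # probes above in 90% of samples, planted failures in 30%
  flags <- matrix(FALSE, n_probe, ns,
                  dimnames = dimnames(intens))
  for (p in seq_len(n_probe)) {
    k <- if (probe_defs$kind[p] == "bg_fail") floor(0.3 * ns)
         else ceiling(0.9 * ns)
    flags[p, sample(ns, k)] <- TRUE
  }

  probes <- data.frame(
    probe_id = rep(probe_defs$probe_id, each = ns),
    gene = rep(probe_defs$gene, each = ns),
    sample_id = rep(samples$sample_id, n_probe),
    intensity = round(as.vector(t(intens)), 4),
    above_background = as.vector(t(flags)),
    stringsAsFactors = FALSE)

  surviving_probes <- probe_defs$probe_id[probe_defs$kind != "bg_fail"]
  selected_probe <- stats::setNames(
    probe_defs$probe_id[probe_defs$kind == "good"],
    probe_defs$gene[probe_defs$kind == "good"])
  planted_r_by_type <- stats::setNames(rep(0, 9), cell_types())
  planted_r_by_type[config$planted_celltype] <- r0

  ground_truth <- list(
    surviving_probes = sort(surviving_probes),
    selected_probe = selected_probe[order(names(selected_probe))],
    surviving_genes = sort(stable),
    assigned_samples = samples$sample_id[samples$planted == "assigned"],
    dropped_far = samples$sample_id[samples$planted == "far"],
    dropped_right = samples$sample_id[samples$planted == "right_hemisphere"],
    planted_r = planted_r_by_type,
    planted_genes = planted_genes,
    cell_set_sizes = stats::setNames(
      as.integer(table(factor(ann$cell_type, levels = cell_types()))),
      cell_types()),
    target_map = config$target_map)

  list(probes = probes,
       samples = samples[, c("sample_id", "donor", "hemisphere",
                             "x", "y", "z")],
       centroids = centroids, cell_annotation = ann,
       ground_truth = ground_truth, config = config)
}
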