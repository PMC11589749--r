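# Cohort bundles: a directory holding one generated study (EEG epochs,
# source model, clinical table, expression fixture, ground truth, manifest)
# so every downstream stage can run from files. Tables are TSV, ground
# truth and manifest JSON, the generator config YAML; the large numeric
# arrays (epochs, source model) are RDS-serialized.

#' Write a complete synthetic cohort to disk
#'
#' Generates an EEG cohort and an expression fixture from the two configs
#' and writes them under `path`. The manifest records the seeds, the configs
#' and the file list; regenerating with the same configs reproduces the
#' bundle byte for byte.
#'
#' @param path output directory (created if needed).
#' @param config a [synth_config()].
#' @param expr_config an [expression_config()]; by default its target map is
#'   tied to the EEG config's planted propagation-difference profile so the
#'   planted cell class tracks the planted group difference.
#' @return `path`, invisibly; side effect: files written.
#' @export
generate_cohort_bundle <- function(path, config = synth_config(),
                                   expr_config = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  if (is.null(expr_config))
    expr_config <- expression_config(
      n_regions = config$n_regions,
      target_map = config$propagation_profile,
      seed = config$seed + 1L)

  dataset <- generate_tep_dataset(config)
  fixture <- generate_expression_fixture(expr_config)

  saveRDS(dataset$epochs, file.path(path, "epochs.rds"), version = 2)
  saveRDS(dataset$source_model, file.path(path, "source_model.rds"),
          version = 2)
  write_tsv <- function(df, name)
    utils::write.table(df, file.path(path, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_tsv(dataset$clinical, "clinical.tsv")
  write_tsv(fixture$probes, "probes.tsv")
  write_tsv(fixture$samples, "samples.tsv")
  write_tsv(fixture$centroids, "centroids.tsv")
  write_tsv(fixture$cell_annotation, "celltypes.tsv")

  gt <- list(eeg = dataset$ground_truth,
             expression = fixture$ground_truth)
  jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(list(eeg = unclass(config),
                        expression = unclass(expr_config)),
                   file.path(path, "config.yaml"))
  manifest <- list(
    format = "icfmap-bundle-1",
    seed_eeg = config$seed, seed_expression = expr_config$seed,
    n_trd = config$n_trd, n_hc = config$n_hc,
    planted_effect_d = config$planted_effect_d,
    null_configuration = config$planted_effect_d == 0,
    files = c("epochs.rds", "source_model.rds", "clinical.tsv",
              "probes.tsv", "samples.tsv", "centroids.tsv",
              "celltypes.tsv", "ground_truth.json", "config.yaml"))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort bundle
#'
#' @param path bundle directory written by [generate_cohort_bundle()].
#' @return list with `dataset` (as from [generate_tep_dataset()], plus the
#'   clinical table read back from TSV), `expression` (as from
#'   [generate_expression_fixture()]), `ground_truth` and `manifest`.
#' @export
read_cohort_bundle <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  missing <- manifest$files[!file.exists(file.path(path, manifest$files))]
  if (length(missing))
    stop("bundle incomplete, missing: ", paste(missing, collapse = ", "))
  cfg <- yaml::read_yaml(file.path(path, "config.yaml"))
  read_tsv <- function(name)
    utils::read.table(file.path(path, name), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                            simplifyVector = TRUE)
  dataset <- list(
    epochs = readRDS(file.path(path, "epochs.rds")),
    source_model = readRDS(file.path(path, "source_model.rds")),
    clinical = read_tsv("clinical.tsv"),
    ground_truth = gt$eeg,
    config = structure(cfg$eeg, class = "synth_config"))
  expression <- list(
    probes = read_tsv("probes.tsv"),
    samples = read_tsv("samples.tsv"),
    centroids = read_tsv("centroids.tsv"),
    cell_annotation = read_tsv("celltypes.tsv"),
    ground_truth = gt$expression,
    config = structure(cfg$expression, class = "expression_config"))
  list(dataset = dataset, expression = expression, ground_truth = gt,
       manifest = manifest)
}
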