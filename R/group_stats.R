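# Group-level statistics: pooled two-sample t-tests (raw data or printed
# summaries), the 2x2 chi-square, the 34-region HC-minus-TRD t-map that
# feeds virtual histology, clinical correlations, and the end-to-end study
# driver.

#' Pooled-variance two-sample t-test
#'
#' Student's t with the pooled SD (df = n1 + n2 - 2), two-sided p from the t
#' distribution, and Cohen's d with the pooled-SD denominator. The sign of t
#' follows `mean(a) - mean(b)`.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list of class `t_test_result`: `t`, `df`, `p`, `d`, `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`.
#' @export
two_sample_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  t_from_summary(mean(a), stats::sd(a), length(a),
                 mean(b), stats::sd(b), length(b))
}

#' Pooled t-test from summary statistics
#'
#' The same pooled-variance test as [two_sample_t()], computed from group
#' means, SDs and sizes only, as needed to check statistics against printed
#' demographic tables.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @return a `t_test_result` list.
#' @export
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 <= 0) stop("zero pooled variance")
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- (mean_a - mean_b) / se
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 d = (mean_a - mean_b) / sqrt(sp2),
                 mean_a = mean_a, mean_b = mean_b, sd_a = sd_a, sd_b = sd_b,
                 n_a = n_a, n_b = n_b),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, Cohen's d = %.3f\n",
              x$df, x$t, x$p, x$d))
  invisible(x)
}

#' Pearson chi-square for a 2x2 table
#'
#' Pearson's chi-square without continuity correction (so a table with
#' proportional rows gives exactly 0).
#'
#' @param tab 2x2 matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_contingency <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the contingency table")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Region-wise group comparison t-map
#'
#' Per-region pooled t-test of the ICF-dSPM index with the HC group first,
#' so positive t means the index is reduced in the TRD group. All regions
#' are retained regardless of significance; the map is a descriptive input
#' to virtual histology, not an inferential endpoint.
#'
#' @param icf_hc,icf_trd subjects x regions matrices of per-subject ICF
#'   index values (same region columns, canonical order).
#' @return list of class `tmap`: `t` (named vector), `p`, `d`, `direction`.
#' @export
regional_tmap <- function(icf_hc, icf_trd) {
  icf_hc <- as.matrix(icf_hc); icf_trd <- as.matrix(icf_trd)
  if (ncol(icf_hc) != ncol(icf_trd)) stop("region counts differ")
  if (nrow(icf_hc) < 2 || nrow(icf_trd) < 2)
    stop("need at least 2 subjects per group")
  tests <- lapply(seq_len(ncol(icf_hc)), function(j)
    two_sample_t(icf_hc[, j], icf_trd[, j]))
  tv <- vapply(tests, `[[`, 0, "t")
  names(tv) <- colnames(icf_hc)
  structure(list(t = tv,
                 p = vapply(tests, `[[`, 0, "p"),
                 d = vapply(tests, `[[`, 0, "d"),
                 direction = "HC-TRD"),
            class = "tmap")
}

#' Correlation between an index and a clinical score
#'
#' Pearson (default) or Spearman correlation with its two-sided p-value.
#'
#' @param index numeric vector (e.g. per-subject ICF-dSPM index).
#' @param scores clinical scores, same length.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n`, `method`.
#' @export
clinical_correlation <- function(index, scores,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(index, scores)
  if (sum(ok) < 3) stop("need at least 3 paired observations")
  ct <- suppressWarnings(
    stats::cor.test(index[ok], scores[ok], method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), method = method)
}

#' Per-subject ICF indices for a synthetic cohort
#'
#' Runs the subject-level analysis over a generated dataset: optional
#' preprocessing, trial averaging per condition, shrinkage noise covariance
#' pooled over both conditions' baselines, dSPM inverse, region extraction,
#' and the windowed facilitation contrast. Also returns the sensor-level
#' DLPFC indices (ICF-TEP and ICF-LMFP window means).
#'
#' @param dataset result of [generate_tep_dataset()].
#' @param lambda2 inverse regularization.
#' @param window a [window_spec()].
#' @param baseline noise-covariance baseline (clipped to the epoch).
#' @param preprocess either `FALSE` (use the raw clean epochs), `TRUE`
#'   (default parameters) or a [preprocess_params()] object.
#' @param roi electrode cluster for sensor-level indices.
#' @return list with `icf_dspm` (subjects x regions matrix), `icf_tep`,
#'   `icf_lmfp` (per-subject sensor indices), `group` (factor), `clinical`.
#' @export
cohort_icf_indices <- function(dataset, lambda2 = 1/9,
                               window = window_spec(),
                               baseline = c(-500, -15),
                               preprocess = FALSE,
                               roi = dlpfc_roi()) {
  model <- dataset$source_model
  subjects <- names(dataset$epochs)
  nreg <- length(model$regions)
  icf <- matrix(NA_real_, length(subjects), nreg,
                dimnames = list(subjects, model$regions))
  tep <- lmf <- stats::setNames(numeric(length(subjects)), subjects)
  params <- if (isTRUE(preprocess)) preprocess_params() else preprocess
  for (s in seq_along(subjects)) {
    pair <- dataset$epochs[[s]]
    if (!isFALSE(preprocess) && !is.null(params))
      pair <- lapply(pair, run_preprocessing, params = params)
    ev <- lapply(pair, average_tep)
    ncov_s <- estimate_noise_cov(pair$single, baseline)
    ncov_p <- estimate_noise_cov(pair$paired, baseline)
    ncov <- ncov_s
    ncov$cov <- (ncov_s$cov + ncov_p$cov) / 2
    inv <- compute_inverse(model, ncov, lambda2)
    reg <- lapply(ev, function(e) extract_region_series(apply_dspm(inv, e),
                                                        model))
    icf[s, ] <- icf_dspm(reg$paired, reg$single, window)
    tep[s] <- window_mean(icf_contrast(roi_series(ev$paired, roi),
                                       roi_series(ev$single, roi)), window)
    lmf[s] <- window_mean(icf_contrast(lmfp(ev$paired, roi),
                                       lmfp(ev$single, roi)), window)
  }
  list(icf_dspm = icf, icf_tep = tep, icf_lmfp = lmf,
       group = factor(dataset$clinical$group, levels = c("HC", "TRD")),
       clinical = dataset$clinical)
}

#' Run the full synthetic study
#'
#' End-to-end driver: subject-level ICF indices (sensor and source), group
#' comparisons at the DLPFC, the 34-region t-map, clinical correlations in
#' the TRD group, demographic summaries, and (when an expression fixture is
#' supplied) the virtual-histology analysis against the t-map.
#'
#' @param dataset result of [generate_tep_dataset()] or a bundle read by
#'   [read_cohort_bundle()].
#' @param expression optional result of [generate_expression_fixture()].
#' @param vh_config a [vh_config()] for the virtual-histology stage.
#' @param exclude character vector of subject ids dropped before analysis
#'   (mirrors exclusions for incomplete data).
#' @param ... passed to [cohort_icf_indices()].
#' @return list of class `study_report`.
#' @export
run_study <- function(dataset, expression = NULL, vh_config = NULL,
                      exclude = character(), ...) {
  idx <- cohort_icf_indices(dataset, ...)
  keep <- !(rownames(idx$icf_dspm) %in% exclude)
  icf <- idx$icf_dspm[keep, , drop = FALSE]
  grp <- idx$group[keep]
  clin <- idx$clinical[keep, , drop = FALSE]
  stim <- dataset$source_model$stim_region

  hc <- grp == "HC"; trd <- grp == "TRD"
  dlpfc <- two_sample_t(icf[hc, stim], icf[trd, stim])
  sensor_tep <- two_sample_t(idx$icf_tep[keep][hc], idx$icf_tep[keep][trd])
  sensor_lmfp <- two_sample_t(idx$icf_lmfp[keep][hc], idx$icf_lmfp[keep][trd])
  tmap <- regional_tmap(icf[hc, , drop = FALSE], icf[trd, , drop = FALSE])

  cors <- list(
    madrs = clinical_correlation(icf[trd, stim], clin$madrs[trd]),
    duration_illness = clinical_correlation(icf[trd, stim],
                                            clin$duration_illness[trd]))

  demo <- list(
    age = two_sample_t(clin$age[trd], clin$age[hc]),
    sex = chi2_contingency(table(clin$sex, clin$group)[, c("TRD", "HC")]))

  vh <- NULL
  if (!is.null(expression)) {
    if (is.null(vh_config)) vh_config <- vh_config()
    pipe <- process_expression_fixture(expression)
    vh <- run_virtual_histology(pipe$matrix, pipe$cell_sets, tmap$t,
                                vh_config)
  }
  structure(list(dlpfc = dlpfc, sensor_tep = sensor_tep,
                 sensor_lmfp = sensor_lmfp, tmap = tmap,
                 clinical_correlations = cors, demographics = demo,
                 virtual_histology = vh, excluded = exclude,
                 n_hc = sum(hc), n_trd = sum(trd),
                 seed = dataset$config$seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d TRD vs %d HC (seed %s)\n",
              x$n_trd, x$n_hc, x$seed))
  cat("  DLPFC ICF-dSPM: "); print(x$dlpfc)
  cat("  sensor ICF-TEP: "); print(x$sensor_tep)
  cat("  sensor ICF-LMFP:"); print(x$sensor_lmfp)
  if (!is.null(x$virtual_histology)) {
    cat("  virtual histology:\n")
    print(x$virtual_histology)
  }
  invisible(x)
}
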