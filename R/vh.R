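# Virtual histology: does the regional expression of a cell class's genes
# track the regional group-difference map more strongly than matched-size
# random gene sets? Observed statistic: mean over the set's genes of the
# correlation between the gene's regional expression and the t-map. Null:
# the same statistic for random same-size gene draws from the full
# surviving-gene pool; empirical two-sided p with the add-one rule;
# Bonferroni across the nine classes.

#' Virtual-histology configuration
#'
#' @param n_resamples random gene-set draws for the null (desk default
#'   1e5; the emulated study design uses 1e6).
#' @param correlation `"pearson"` (default) or `"spearman"`.
#' @param seed RNG seed for the draws.
#' @param alpha_family family-wise alpha (default 0.05).
#' @param n_tests number of cell classes tested (default 9).
#' @param exclude_target if `TRUE`, null draws exclude the target set's own
#'   genes from the pool (default `FALSE`: draws come from the full pool).
#' @return list of class `vh_config`.
#' @export
vh_config <- function(n_resamples = 1e5,
                      correlation = c("pearson", "spearman"),
                      seed = 1L, alpha_family = 0.05, n_tests = 9,
                      exclude_target = FALSE) {
  stopifnot(n_resamples >= 1, alpha_family > 0, alpha_family < 1)
  structure(list(n_resamples = as.integer(n_resamples),
                 correlation = match.arg(correlation),
                 seed = as.integer(seed), alpha_family = alpha_family,
                 n_tests = n_tests, exclude_target = exclude_target),
            class = "vh_config")
}

# per-gene correlation of each expression row with the map
gene_map_correlations <- function(expression_matrix, tmap,
                                  method = "pearson") {
  if (ncol(expression_matrix) != length(tmap))
    stop("map length does not match the number of regions")
  if (stats::sd(tmap) == 0) stop("zero-variance map")
  apply(expression_matrix, 1, function(x) {
    if (stats::sd(x) == 0) stop("zero-variance gene row")
    stats::cor(x, tmap, method = method)
  })
}

#' Mean gene-set correlation with a regional map
#'
#' Mean over the set's genes of the correlation between the gene's regional
#' expression profile and the map.
#'
#' @param gene_set character vector of genes, all present in the matrix.
#' @param expression_matrix genes x regions matrix.
#' @param tmap regional map (length = number of regions).
#' @param method correlation type.
#' @return scalar mean correlation.
#' @export
set_mean_correlation <- function(gene_set, expression_matrix, tmap,
                                 method = "pearson") {
  if (!length(gene_set)) stop("empty gene set")
  miss <- setdiff(gene_set, rownames(expression_matrix))
  if (length(miss))
    stop("genes not in the matrix: ", paste(miss, collapse = ", "))
  gc <- gene_map_correlations(
    expression_matrix[gene_set, , drop = FALSE], tmap, method)
  mean(gc)
}

#' Random-gene-set null distribution
#'
#' Draws `n_resamples` uniform samples of `set_size` genes without
#' replacement from the pool (all matrix rows, minus the target set when
#' `exclude_target` is set) and records the mean set correlation of each
#' draw. Per-gene correlations are computed once, so a draw reduces to
#' averaging `set_size` stored values.
#'
#' @param set_size genes per draw.
#' @param expression_matrix genes x regions matrix.
#' @param tmap regional map.
#' @param config a [vh_config()].
#' @param target_genes the target set (needed when `exclude_target`).
#' @return list of class `null_distribution`: `samples`, `set_size`,
#'   `pool_size`, `seed`, `ci95`.
#' @export
resample_null <- function(set_size, expression_matrix, tmap,
                          config = vh_config(), target_genes = NULL) {
  pool <- rownames(expression_matrix)
  if (isTRUE(config$exclude_target) && length(target_genes))
    pool <- setdiff(pool, target_genes)
  if (set_size > length(pool)) stop("set size exceeds the gene pool")
  gc <- gene_map_correlations(expression_matrix[pool, , drop = FALSE],
                              tmap, config$correlation)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- length(gc)
  draws <- vapply(seq_len(config$n_resamples),
                  function(i) mean(gc[sample.int(n, set_size)]), 0)
  structure(list(samples = draws, set_size = set_size, pool_size = n,
                 seed = config$seed,
                 ci95 = unname(stats::quantile(draws, c(0.025, 0.975)))),
            class = "null_distribution")
}

#' Two-sided empirical p-value with the add-one rule
#'
#' `p = min(1, 2 * min((#{null >= obs} + 1) / (n + 1),
#' (#{null <= obs} + 1) / (n + 1)))`: the doubled smaller add-one tail,
#' capped at 1, so p is never exactly 0.
#'
#' @param observed observed statistic.
#' @param null a [resample_null()] result or a numeric vector of null
#'   samples.
#' @return p-value in (0, 1].
#' @export
empirical_p_two_sided <- function(observed, null) {
  s <- if (inherits(null, "null_distribution")) null$samples else null
  if (!length(s)) stop("empty null distribution")
  n <- length(s)
  up <- (sum(s >= observed) + 1) / (n + 1)
  lo <- (sum(s <= observed) + 1) / (n + 1)
  min(1, 2 * min(up, lo))
}

#' Exhaustive small-pool null distribution
#'
#' Enumerates the mean set correlation for every size-`set_size` gene
#' combination of the pool; the exact reference the resampling null is
#' checked against. Guarded by `choose(pool, set_size) <= 1e6`.
#'
#' @param set_size genes per combination.
#' @param expression_matrix genes x regions matrix (small pool).
#' @param tmap regional map.
#' @param method correlation type.
#' @return numeric vector of all `choose(pool, set_size)` values.
#' @export
enumerate_null_exact <- function(set_size, expression_matrix, tmap,
                                 method = "pearson") {
  n <- nrow(expression_matrix)
  if (choose(n, set_size) > 1e6)
    stop("enumeration bound exceeded: choose(", n, ", ", set_size, ") > 1e6")
  gc <- gene_map_correlations(expression_matrix, tmap, method)
  as.numeric(utils::combn(n, set_size, function(ii) mean(gc[ii])))
}

#' Run the virtual-histology analysis
#'
#' For each of the nine cell classes: observed mean set correlation with the
#' map, matched-size resampling null, add-one two-sided empirical p, null
#' 95% interval, and the Bonferroni decision at
#' `alpha_family / n_tests`.
#'
#' @param expression_matrix genes x regions matrix.
#' @param cell_sets named list of gene sets (from [load_cell_sets()]).
#' @param tmap regional map (the HC-minus-TRD t-vector).
#' @param config a [vh_config()].
#' @param keep_null if `TRUE`, attach the full null sample vectors as
#'   attribute `nulls`.
#' @return data.frame of class `vh_result`, one row per cell class:
#'   `cell_type`, `set_size`, `mean_r`, `p`, `null_lo`, `null_hi`,
#'   `significant`.
#' @export
run_virtual_histology <- function(expression_matrix, cell_sets, tmap,
                                  config = vh_config(), keep_null = FALSE) {
  if (any(lengths(cell_sets) == 0)) stop("empty cell-type set")
  alpha <- config$alpha_family / config$n_tests
  nulls <- list()
  rows <- lapply(names(cell_sets), function(ct) {
    genes <- cell_sets[[ct]]
    obs <- set_mean_correlation(genes, expression_matrix, tmap,
                                config$correlation)
    nd <- resample_null(length(genes), expression_matrix, tmap, config,
                        target_genes = genes)
    if (keep_null) nulls[[ct]] <<- nd$samples
    p <- empirical_p_two_sided(obs, nd)
    data.frame(cell_type = ct, set_size = length(genes), mean_r = obs,
               p = p, null_lo = nd$ci95[1], null_hi = nd$ci95[2],
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "config") <- config
  if (keep_null) attr(out, "nulls") <- nulls
  class(out) <- c("vh_result", class(out))
  out
}

#' @export
print.vh_result <- function(x, ...) {
  cat(sprintf("virtual histology (alpha = %.4f per test):\n",
              attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
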