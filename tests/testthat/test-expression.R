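toy_probes <- function(fracs) {
  # one probe per entry, 10 samples, `fracs` above-background fractions
  do.call(rbind, lapply(seq_along(fracs), function(i) {
    data.frame(probe_id = sprintf("P%d", i), gene = sprintf("G%d", i),
               sample_id = sprintf("s%d", 1:10),
               intensity = rnorm(10, 7),
               above_background = rep(c(TRUE, FALSE),
                                      c(round(10 * fracs[i]),
                                        10 - round(10 * fracs[i]))))
  }))
}

test_that("the background filter is inclusive at exactly 50%", {
  pr <- toy_probes(c(0.4, 0.5, 0.9))
  out <- filter_background(pr)
  expect_setequal(unique(out$probe_id), c("P2", "P3"))
  expect_identical(attr(out, "removed_probes"), "P1")
  expect_error(filter_background(toy_probes(c(0.1, 0.2))), "no probe")
})

test_that("sample assignment honours the 2 mm rule and hemisphere", {
  centroids <- data.frame(region = c("A", "B"), hemisphere = "left",
                          x = c(-30, -60), y = c(0, 0), z = c(0, 0))
  samples <- data.frame(
    sample_id = c("near", "far", "right"),
    donor = "d1",
    hemisphere = c("left", "left", "right"),
    x = c(-31.5, -32.5, -30), y = 0, z = 0)
  asg <- assign_samples(samples, centroids)
  expect_equal(asg$sample_id, "near")
  expect_equal(asg$region, "A")
  expect_equal(asg$distance, 1.5)
  expect_identical(attr(asg, "dropped_far"), "far")
  expect_identical(attr(asg, "dropped_right"), "right")
})

test_that("differential stability equals the mean pairwise correlation", {
  prof <- list(d1 = c(1, 2, 3, 4, 5), d2 = c(1, 2, 3, 4, 5),
               d3 = c(5, 4, 3, 2, 1))
  probes <- do.call(rbind, lapply(names(prof), function(d) {
    data.frame(probe_id = "P1", gene = "G1",
               sample_id = paste0(d, "_", 1:5),
               intensity = prof[[d]], above_background = TRUE)
  }))
  assignments <- do.call(rbind, lapply(names(prof), function(d) {
    data.frame(sample_id = paste0(d, "_", 1:5), donor = d,
               region = sprintf("R%d", 1:5))
  }))
  ds <- differential_stability_select(probes, assignments, keep_fraction = 1)
  # pairwise correlations: +1, -1, -1 -> mean -1/3
  expect_equal(ds$selection$ds, mean(c(1, -1, -1)))
  # two identical donors only: DS = 1; exactly opposite: DS = -1
  ds2 <- differential_stability_select(
    probes[probes$sample_id %in% c(paste0("d1_", 1:5), paste0("d2_", 1:5)), ],
    assignments[assignments$donor %in% c("d1", "d2"), ], keep_fraction = 1)
  expect_equal(ds2$selection$ds, 1)
  ds3 <- differential_stability_select(
    probes[probes$sample_id %in% c(paste0("d1_", 1:5), paste0("d3_", 1:5)), ],
    assignments[assignments$donor %in% c("d1", "d3"), ], keep_fraction = 1)
  expect_equal(ds3$selection$ds, -1)
})

test_that("matrix construction matches a brute-force group-by mean", {
  fx <- generate_expression_fixture(small_expr_config(seed = 21))
  pb <- filter_background(fx$probes)
  asg <- assign_samples(fx$samples, fx$centroids)
  dsel <- differential_stability_select(pb, asg)
  sel <- dsel$selection[dsel$selection$gene %in% dsel$kept_genes, ]
  mat <- build_matrix(pb, asg, sel, regions = fx$centroids$region,
                      normalization = "none")
  # brute-force oracle: per donor group-by mean, then cross-donor mean
  merged <- merge(pb[pb$probe_id %in% sel$probe_id, ], asg, by = "sample_id")
  for (g in sample(rownames(mat), 5)) {
    p <- sel$probe_id[sel$gene == g]
    sub <- merged[merged$probe_id == p, ]
    donor_means <- tapply(sub$intensity, list(sub$donor, sub$region), mean)
    oracle <- colMeans(donor_means, na.rm = TRUE)
    expect_equal(mat[g, names(oracle)], oracle, tolerance = 1e-10)
  }
  # invariance to sample and donor order
  perm <- sample(nrow(pb))
  mat2 <- build_matrix(pb[perm, ], asg[sample(nrow(asg)), ], sel,
                       regions = fx$centroids$region, normalization = "none")
  expect_equal(mat2, mat, ignore_attr = TRUE)
})

test_that("identical donors collapse to a single donor's matrix", {
  prof <- c(3, 1, 4, 1, 5)
  mk <- function(d) data.frame(
    probe_id = "P1", gene = "G1", sample_id = paste0(d, "_", 1:5),
    intensity = prof, above_background = TRUE)
  probes <- rbind(mk("d1"), mk("d2"))
  asg <- do.call(rbind, lapply(c("d1", "d2"), function(d)
    data.frame(sample_id = paste0(d, "_", 1:5), donor = d,
               region = sprintf("R%d", 1:5))))
  sel <- data.frame(gene = "G1", probe_id = "P1", ds = 1)
  both <- build_matrix(probes, asg, sel, regions = sprintf("R%d", 1:5),
                       normalization = "none")
  one <- build_matrix(mk("d1"), asg[asg$donor == "d1", ], sel,
                      regions = sprintf("R%d", 1:5), normalization = "none")
  expect_equal(both, one, ignore_attr = TRUE)
  expect_equal(unname(one["G1", ]), prof)
})

test_that("cell sets are validated and restricted to matrix genes", {
  ann <- data.frame(gene = c("G1", "G2", "G3"), cell_type = "astrocyte")
  sets <- load_cell_sets(ann, c("G1", "G3", "G9"))
  expect_equal(sets$astrocyte, c("G1", "G3"))
  expect_error(load_cell_sets(data.frame(gene = "G1", cell_type = "glia"),
                              "G1"), "unknown cell class")
  expect_error(load_cell_sets(data.frame(gene = c("G1", "G1"),
                                         cell_type = c("mural", "astrocyte")),
                              "G1"), "more than one")
  expect_error(load_cell_sets(ann, c("X1", "X2")), "no matrix genes")
})

test_that("pipeline survivors equal the generator truth exactly", {
  for (s in c(5, 6)) {
    fx <- generate_expression_fixture(small_expr_config(seed = s))
    pipe <- process_expression_fixture(fx)
    gt <- fx$ground_truth
    expect_setequal(setdiff(unique(fx$probes$probe_id),
                            pipe$log$removed_probes), gt$surviving_probes)
    expect_setequal(rownames(pipe$matrix), gt$surviving_genes)
    expect_setequal(pipe$assignments$sample_id, gt$assigned_samples)
    expect_setequal(pipe$log$dropped_far, gt$dropped_far)
    expect_setequal(pipe$log$dropped_right, gt$dropped_right)
    sel <- pipe$selection$selection
    expect_true(all(gt$selected_probe[sel$gene] == sel$probe_id))
    expect_equal(vapply(pipe$cell_sets, length, 0L)[cell_types()],
                 gt$cell_set_sizes)
    # assigned samples land in their true region
    m <- merge(pipe$assignments,
               data.frame(sample_id = fx$samples$sample_id),
               by = "sample_id")
    expect_equal(nrow(pipe$assignments),
                 length(gt$assigned_samples))
  }
})
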