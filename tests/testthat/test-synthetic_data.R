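# Synthetic-data generator: determinism, ground-truth recovery,
# co-localization structure.

small_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, chrom_length = 2e6, n_genes = 150,
             kap1_background = list(n_tes = 25, n_body = 50,
                                    n_intergenic = 100), ...)
}

test_that("the generator is fully deterministic under a seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(small_cfg(seed = 9), d1)
  simulate_dataset(small_cfg(seed = 9), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 9)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(small_cfg(seed = 10), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genes.gtf"))),
                         unname(tools::md5sum(file.path(d3, "genes.gtf")))))
})

test_that("genes are placed without overlap and strands are ~50/50", {
  cfg <- sim_config(seed = 3, chrom_length = 8e6, n_genes = 1000,
                    gene_length_meanlog = log(2500))
  g <- simulate_genome(cfg)
  expect_equal(nrow(g), 1000L)
  for (chr in unique(g$chrom)) {
    s <- g[g$chrom == chr, ]
    expect_true(all(s$start[-1] - s$end[-nrow(s)] >= cfg$gene_spacing))
  }
  frac_plus <- mean(g$strand == "+")
  expect_gt(frac_plus, 0.45)
  expect_lt(frac_plus, 0.55)
})

test_that("infeasible packing raises an informative error", {
  cfg <- sim_config(seed = 1, chrom_length = 5e4, n_genes = 100)
  expect_error(simulate_genome(cfg), "increase chrom_length")
})

test_that("coverage recovers the planted pausing ratio", {
  cfg <- small_cfg(seed = 6,
                   pausing_mixture = data.frame(fraction = 1, rho = 6))
  g <- simulate_genome(cfg)
  cov <- simulate_polii_coverage(g, cfg, "WT")
  tab <- pi_table(cov$track, g, pi_config())
  expect_equal(median(tab$pi[tab$eligible]), 6, tolerance = 0.05)
  # knockdown coverage uses the planted rho_kd (0.8 * 6 here)
  cov_kd <- simulate_polii_coverage(g, cfg, "KD")
  tab_kd <- pi_table(cov_kd$track, g, pi_config())
  expect_equal(median(tab_kd$pi[tab_kd$eligible]), 0.8 * 6,
               tolerance = 0.05)
})

test_that("zero depth with zero background yields an all-zero track and PI 1", {
  cfg <- small_cfg(seed = 6, depth = 0, background = 0)
  g <- simulate_genome(cfg)
  cov <- simulate_polii_coverage(g, cfg, "WT")
  expect_true(all(unlist(cov$track$signal) == 0))
  tab <- pi_table(cov$track, g, pi_config())
  expect_true(all(tab$pi[tab$eligible] == 1))
})

test_that("promoter-binding labels are recovered exactly from planted peaks", {
  cfg <- small_cfg(seed = 8)
  g <- simulate_genome(cfg)
  pk <- simulate_peaks(g, cfg)
  called <- promoter_binding(g, pk$peaks$KAP1, flank = cfg$flank)
  expect_identical(unname(called[g$gene_id]), unname(pk$binding[g$gene_id]))
  expect_gt(sum(called), 0)
  expect_lt(sum(called), nrow(g))
})

test_that("planted peak categories are recovered exactly by annotation", {
  cfg <- small_cfg(seed = 12)
  g <- simulate_genome(cfg)
  pk <- simulate_peaks(g, cfg)
  ann <- annotate_peaks(pk$peaks$KAP1, g, flank = cfg$flank,
                        tes_flank = cfg$flank)
  expect_identical(ann$assignment, pk$kap1_categories)
  planted <- table(pk$kap1_categories)
  for (cat in names(planted)) {
    expect_equal(ann$table$count[ann$table$category == cat],
                 as.integer(planted[[cat]]))
  }
})

test_that("co-placed marks with no jitter put the correlation spike at offset 0", {
  cfg <- small_cfg(seed = 14,
                   marks = list(PolII = list(p_given_kap1 = 1,
                                             jitter_sd = 0, width = 300,
                                             n_independent = 0)))
  g <- simulate_genome(cfg)
  pk <- simulate_peaks(g, cfg)
  prof <- positional_correlation(pk$peaks$KAP1, pk$peaks$PolII)
  center <- which(prof$offsets == 0)
  expect_equal(which.max(prof$counts), center)
  # every factor peak contributes its own co-placed mark at offset 0
  expect_gte(prof$counts[center], nrow(pk$peaks$KAP1))
})

test_that("a mark with zero conditional probability never overlaps the factor", {
  cfg <- small_cfg(seed = 15)
  g <- simulate_genome(cfg)
  pk <- simulate_peaks(g, cfg)
  expect_equal(overlap_fraction(pk$peaks$KAP1, pk$peaks$H3K9me3), 0)
})

test_that("zero-noise knockdown expression recovers planted DE labels exactly", {
  cfg <- small_cfg(seed = 16, kd = list(
    frac_up = 0.1, frac_down = 0.1, effect_up = 4, effect_down = 0.25,
    noise_sdlog = 0, pi_effect = 0.8, pi_effect_threshold = 4))
  g <- simulate_genome(cfg)
  ex <- simulate_expression_and_kd(g, cfg)
  fc <- fold_change_labels(ex$expression[, "WT"], ex$expression[, "KD"],
                           gene_ids = rownames(ex$expression))
  expect_identical(fc$de_status, ex$truth$de_status)
  expect_equal(sum(fc$de_status == "up"), 15L)
  expect_equal(sum(fc$de_status == "down"), 15L)

  # all-unit effects leave every gene unchanged
  cfg0 <- small_cfg(seed = 16, kd = list(
    frac_up = 0, frac_down = 0, effect_up = 4, effect_down = 0.25,
    noise_sdlog = 0, pi_effect = 1, pi_effect_threshold = 4))
  ex0 <- simulate_expression_and_kd(simulate_genome(cfg0), cfg0)
  fc0 <- fold_change_labels(ex0$expression[, "WT"], ex0$expression[, "KD"])
  expect_true(all(fc0$de_status == "unchanged"))
})

test_that("graded binding makes bound genes more expressed and more paused", {
  cfg <- sim_config(seed = 17, chrom_length = 4e6, n_genes = 400)
  g <- simulate_genome(cfg)
  expect_gt(median(g$expr_wt[g$bound]), median(g$expr_wt[!g$bound]))
  expect_gt(mean(g$rho[g$bound] >= 4), mean(g$rho[!g$bound] >= 4))
})
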