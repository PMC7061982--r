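# Positional correlation, feature annotation, promoter binding,
# overlap fractions.

test_that("positional correlation of a peak with itself is a unit spike at 0", {
  p <- peak_set("chr1", 1000, 1400, name = "a")
  prof <- positional_correlation(p, p, window = 10000, bin = 100)
  expect_equal(sum(prof$counts), 1L)
  expect_equal(prof$values[prof$offsets == 0], 1)
  expect_equal(length(prof$values), 2 * 10000 / 100 + 1)
})

test_that("a single anchor-target pair lands in the bin nearest its offset", {
  a <- peak_set("chr1", 900, 1100, name = "a")     # midpoint 1000
  b <- peak_set("chr1", 1500, 1700, name = "b")    # midpoint 1600
  prof <- positional_correlation(a, b, window = 10000, bin = 100)
  expect_equal(sum(prof$counts), 1L)
  expect_equal(prof$offsets[prof$counts == 1], 600)
  expect_equal(prof$values[prof$counts == 1], 1)
})

test_that("profiles match the all-pairs enumeration oracle exactly", {
  set.seed(11)
  for (i in 1:10) {
    a <- random_peaks(sample.int(30, 1) + 5, chrom_len = 30000,
                      chroms = c("chr1", "chr2"))
    b <- random_peaks(sample.int(30, 1) + 5, chrom_len = 30000,
                      chroms = c("chr1", "chr2"))
    prof <- positional_correlation(a, b, window = 5000, bin = 100)
    expect_identical(prof$counts, oracle_xcorr_counts(a, b, 5000, 100))
    expect_equal(prof$values,
                 prof$counts / (nrow(a) * nrow(b)))
  }
})

test_that("profile counts conserve the number of in-window pairs", {
  set.seed(12)
  a <- random_peaks(40, chrom_len = 20000)
  b <- random_peaks(25, chrom_len = 20000)
  prof <- positional_correlation(a, b, window = 4000, bin = 200)
  a_mid <- floor((a$start + a$end) / 2)
  b_mid <- floor((b$start + b$end) / 2)
  n_pairs <- sum(abs(outer(b_mid, a_mid, "-")) <= 4000)
  expect_equal(sum(prof$counts), n_pairs)
  expect_equal(sum(prof$values) * nrow(a) * nrow(b), n_pairs)
})

test_that("swapping anchors and targets mirrors the profile exactly", {
  set.seed(13)
  for (i in 1:10) {
    a <- random_peaks(30, chrom_len = 15000)
    b <- random_peaks(20, chrom_len = 15000)
    ab <- positional_correlation(a, b, window = 3000, bin = 100)
    ba <- positional_correlation(b, a, window = 3000, bin = 100)
    expect_identical(ab$counts, rev(ba$counts))
  }
})

test_that("positional correlation validates its inputs", {
  a <- peak_set("chr1", 1, 10)
  empty <- peak_set(character(), numeric(), numeric())
  expect_error(positional_correlation(empty, a), "empty")
  expect_error(positional_correlation(a, empty), "empty")
  expect_error(positional_correlation(a, a, window = 1000, bin = 300),
               "multiple")
})

test_that("peaks are annotated by midpoint with configurable precedence", {
  g <- gene_models(c("g1", "g2"), c("chr1", "chr1"), c(5000, 50000),
                   c(15000, 60000), c("+", "-"))
  pk <- peak_set("chr1",
                 c(5000, 10000, 14800, 100000, 70000),
                 c(5100, 10200, 15100, 100400, 70100),
                 name = "KAP1")
  ann <- annotate_peaks(pk, g)
  expect_equal(ann$assignment,
               c("promoter", "gene_body", "tes_proximal", "intergenic",
                 "intergenic"))
  expect_equal(sum(ann$table$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(ann$table$count), nrow(pk))

  # a peak whose midpoint is both in a promoter window and in the gene
  # body follows the precedence order
  ann2 <- annotate_peaks(pk, g,
                         precedence = c("gene_body", "promoter",
                                        "tes_proximal", "intergenic"))
  expect_equal(ann2$assignment[1], "gene_body")
  # single-category peaks are unaffected by precedence permutation
  expect_equal(ann2$assignment[4:5], ann$assignment[4:5])
})

test_that("peaks on a gene-free chromosome are intergenic", {
  g <- gene_models("g1", "chr1", 5000, 15000, "+")
  pk <- peak_set("chr9", 100, 300, name = "x")
  expect_equal(annotate_peaks(pk, g)$assignment, "intergenic")
})

test_that("annotate_peaks accepts user-supplied feature sets", {
  g <- gene_models("g1", "chr1", 5000, 15000, "+")
  exons <- data.frame(chrom = "chr1", start = 9000, end = 9500)
  pk <- peak_set("chr1", c(9100, 12000), c(9300, 12200), name = "x")
  ann <- annotate_peaks(pk, g, features = list(exon = exons),
                        precedence = c("promoter", "exon", "gene_body",
                                       "intergenic"))
  expect_equal(ann$assignment, c("exon", "gene_body"))
  expect_error(annotate_peaks(pk, g, features = list(exon = exons)),
               "precedence does not cover")
})

test_that("promoter binding is any >= 1 bp overlap with the half-open window", {
  g <- gene_models("g1", "chr1", 1000, 9000, "+")  # window [750, 1251)
  expect_true(promoter_binding(g, peak_set("chr1", 900, 1100))[["g1"]])
  # 1-bp touch at the window edge counts
  expect_true(promoter_binding(g, peak_set("chr1", 1250, 1300))[["g1"]])
  # half-open boundary: peak starting at the window end does not
  expect_false(promoter_binding(g, peak_set("chr1", 1251, 1300))[["g1"]])
  expect_false(promoter_binding(g, peak_set("chr1", 1260, 1300))[["g1"]])
  expect_false(promoter_binding(g, peak_set("chr2", 900, 1100))[["g1"]])
})

test_that("overlap_fraction matches the all-pairs oracle", {
  a <- peak_set("chr1", c(0, 100), c(50, 150))
  expect_equal(overlap_fraction(a, a), 1.0)
  b <- peak_set("chr2", c(0, 100), c(50, 150))
  expect_equal(overlap_fraction(a, b), 0.0)
  expect_error(overlap_fraction(a, peak_set(character(), numeric(),
                                            numeric())), "empty")
  set.seed(21)
  for (i in 1:10) {
    x <- random_peaks(35, chrom_len = 8000, chroms = c("chr1", "chr2"))
    y <- random_peaks(20, chrom_len = 8000, chroms = c("chr1", "chr2"))
    expect_equal(overlap_fraction(x, y), oracle_overlap_fraction(x, y))
  }
})

test_that("subtract_overlapping splits a set by co-occurrence with another", {
  a <- peak_set("chr1", c(0, 1000, 2000), c(100, 1100, 2100), name = "A")
  b <- peak_set("chr1", 1050, 1200, name = "B")
  kept <- subtract_overlapping(a, b)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$start, c(0, 2000))
  dropped <- subtract_overlapping(a, b, keep = "overlapping")
  expect_equal(dropped$start, 1000)
  expect_equal(nrow(kept) + nrow(dropped), nrow(a))
})
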