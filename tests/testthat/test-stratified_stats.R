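# Mann-Whitney machinery, fold-change labelling, stratified dataset,
# high-PI analysis, BH adjustment.

test_that("U statistic and exact p match hand enumeration for {1,2} vs {3,4}", {
  res <- mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(res$statistic, 0)
  oracle <- oracle_mwu_exact(c(1, 2), c(3, 4))
  # all 6 labelings, one as extreme in each direction
  expect_equal(oracle$p_lower, 1 / 6)
  expect_equal(res$p_value, oracle$p_two_sided)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$effect_direction, "down")
})

test_that("exact p equals the full-enumeration oracle for all n1, n2 <= 7", {
  set.seed(31)
  for (n1 in c(2, 4, 7)) {
    for (n2 in c(2, 5, 7)) {
      for (rep in 1:3) {
        x <- rnorm(n1)
        y <- rnorm(n2, mean = runif(1, -1, 1))
        res <- mann_whitney_u(x, y, mode = "exact")
        oracle <- oracle_mwu_exact(x, y)
        expect_equal(res$statistic, oracle$u)
        expect_equal(res$p_value, oracle$p_two_sided, tolerance = 1e-12)
      }
    }
  }
})

test_that("identical samples give U = n^2/2 and p ~ 1", {
  x <- c(1.5, 2.5, 3.5, 7, 9, 12, 15)
  res <- mann_whitney_u(x, x, mode = "normal")
  expect_equal(res$statistic, length(x)^2 / 2)
  expect_gt(res$p_value, 0.9)
  expect_equal(res$effect_direction, "none")
})

test_that("exact mode falls back with a warning on ties or large samples", {
  expect_warning(res <- mann_whitney_u(c(1, 2, 2), c(2, 3), mode = "exact"),
                 "falling back")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_warning(mann_whitney_u(rnorm(15), rnorm(15), mode = "exact"),
                 "falling back")
  expect_error(mann_whitney_u(numeric(), 1:3), "empty sample")
})

test_that("fold-change labels follow the threshold rule and are antisymmetric", {
  fc <- fold_change_labels(c(10, 10, 10), c(10, 40, 2),
                           fc_threshold = 2, pseudocount = 0)
  expect_equal(fc$de_status, c("unchanged", "up", "down"))
  expect_equal(fc$abs_log2_fc, c(0, 2, abs(log2(0.2))))

  set.seed(32)
  wt <- rlnorm(200, 2, 1)
  kd <- wt * sample(c(0.2, 0.5, 1, 2.5, 6), 200, replace = TRUE)
  f1 <- fold_change_labels(wt, kd)
  f2 <- fold_change_labels(kd, wt)
  expect_equal(f1$de_status == "up", f2$de_status == "down")
  expect_equal(f1$de_status == "down", f2$de_status == "up")
  expect_equal(f1$abs_log2_fc, f2$abs_log2_fc)
  expect_error(fold_change_labels(c(-1, 2), c(1, 2)), "negative")
})

make_dataset <- function(n = 200, bound_shift = 0, kd_pi_factor = 1,
                         seed = 33, high_frac = 0.3) {
  set.seed(seed)
  bound <- runif(n) < 0.5
  pi_wt_val <- exp(rnorm(n, log(2), 0.5))
  hi <- seq_len(n) <= round(high_frac * n)
  pi_wt_val[hi] <- exp(rnorm(sum(hi), log(8), 0.3))
  expr_wt <- rlnorm(n, 2, 1) * exp(bound_shift * bound)
  pi_wt_tab <- data.frame(gene_id = sprintf("g%03d", 1:n),
                          pi = pi_wt_val, eligible = TRUE)
  kd_val <- ifelse(pi_wt_val >= 4, pi_wt_val * kd_pi_factor, pi_wt_val)
  pi_kd_tab <- data.frame(gene_id = pi_wt_tab$gene_id, pi = kd_val,
                          eligible = TRUE)
  expr <- cbind(WT = expr_wt, KD = expr_wt)
  rownames(expr) <- pi_wt_tab$gene_id
  build_stratified_dataset(pi_wt_tab, pi_kd_tab,
                           setNames(bound, pi_wt_tab$gene_id), expr)
}

test_that("compare_strata detects a planted expression shift between bound and unbound", {
  ds <- make_dataset(n = 400, bound_shift = 0.5)
  res <- compare_strata(ds, "expression", function(d) d$bound,
                        function(d) !d$bound)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$effect_direction, "up")
  expect_equal(res$n_group1 + res$n_group2, 400)
})

test_that("compare_strata is null on identical strata and errors on empty ones", {
  ds <- make_dataset(n = 150)
  same <- compare_strata(ds, "pi", function(d) rep(TRUE, nrow(d)),
                         function(d) rep(TRUE, nrow(d)))
  expect_gt(same$p_value, 0.9)
  # WT vs KD with a null knockdown
  null_kd <- compare_strata(make_dataset(kd_pi_factor = 1), "pi",
                            function(d) rep(TRUE, nrow(d)),
                            function(d) rep(TRUE, nrow(d)),
                            condition_a = "WT", condition_b = "KD")
  expect_gt(null_kd$p_value, 0.9)
  expect_error(
    compare_strata(ds, "pi", function(d) d$pi_WT > 1e9,
                   function(d) rep(TRUE, nrow(d))),
    "empty stratum")
})

test_that("high-PI analysis: null knockdown gives unit correlations and p ~ 1", {
  ds <- make_dataset(n = 300, kd_pi_factor = 1)
  hp <- high_pi_comparison(ds, threshold = 4)
  expect_gt(hp$n, 0)
  expect_equal(hp$subsets$pearson, c(1, 1))
  expect_equal(hp$subsets$spearman, c(1, 1))
  expect_gt(hp$overall$p_value, 0.9)
  expect_error(high_pi_comparison(ds, threshold = 1e6), "no genes with")
})

test_that("a uniform KD effect on high-PI genes shifts both binding subsets alike", {
  ds <- make_dataset(n = 600, kd_pi_factor = 0.8, seed = 34)
  hp <- high_pi_comparison(ds, threshold = 4)
  # the shift is detected overall
  expect_lt(hp$overall$p_value, 0.01)
  expect_equal(hp$overall$effect_direction, "up")  # WT > KD
  # but does not differ between bound and unbound subsets
  expect_gt(hp$shift_by_binding$p_value, 0.05)
  expect_equal(hp$subsets$n[1] + hp$subsets$n[2], hp$n)
})

test_that("external de_status labels override the fold-change rule", {
  ds <- make_dataset(n = 50)
  labels <- setNames(rep("up", 50), ds$gene_id)
  pi_wt_tab <- data.frame(gene_id = ds$gene_id, pi = ds$pi_WT,
                          eligible = TRUE)
  pi_kd_tab <- data.frame(gene_id = ds$gene_id, pi = ds$pi_KD,
                          eligible = TRUE)
  expr <- cbind(WT = ds$expr_WT, KD = ds$expr_KD)
  rownames(expr) <- ds$gene_id
  ds2 <- build_stratified_dataset(pi_wt_tab, pi_kd_tab,
                                  setNames(ds$bound, ds$gene_id), expr,
                                  de_status = labels)
  expect_true(all(ds2$de_status == "up"))
  expect_error(
    build_stratified_dataset(pi_wt_tab, pi_kd_tab,
                             setNames(ds$bound, ds$gene_id), expr,
                             de_status = setNames("sideways", ds$gene_id[1])),
    "invalid de_status")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  # monotone non-decreasing after sorting
  set.seed(35)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "within")
  expect_error(bh_adjust(c(0.5, NA)), "finite")
})

test_that("a 0.5 SD location shift at n = 200/group is detected reliably", {
  set.seed(36)
  hits <- 0L
  for (i in 1:200) {
    x <- rnorm(200)
    y <- rnorm(200, mean = 0.5)
    if (mann_whitney_u(x, y, mode = "normal")$p_value < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 200, 0.95)
})
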