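# Stratified comparisons: Mann-Whitney-Wilcoxon tests on gene groups,
# fold-change labelling, high-PI subset analysis, BH adjustment.

new_comparison_result <- function(label, x, y, statistic, p_value,
                                  paired = FALSE) {
  mx <- stats::median(x)
  my <- stats::median(y)
  direction <- if (mx > my) "up" else if (mx < my) "down" else "none"
  structure(list(label = label, n_group1 = length(x), n_group2 = length(y),
                 statistic = unname(statistic), p_value = unname(p_value),
                 medians = c(group1 = mx, group2 = my),
                 effect_direction = direction, paired = paired),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              if (x$paired) " [paired]" else ""))
  cat(sprintf("  n = %d vs %d; medians %.4g vs %.4g (group1 %s)\n",
              x$n_group1, x$n_group2, x$medians[1], x$medians[2],
              x$effect_direction))
  cat(sprintf("  statistic = %.6g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Mann-Whitney-Wilcoxon two-sample test
#'
#' Rank-based two-sided location test between two samples, reporting
#' the U statistic (number of (x, y) pairs with x > y, counting ties
#' as 1/2). Exact mode computes the exact null distribution of U
#' (equivalent to enumerating all `choose(n1 + n2, n1)` group
#' labelings) and requires `n1 + n2 <= 20` with no ties; otherwise it
#' falls back, with a warning, to the normal approximation with tie
#' and continuity corrections. `mode = "auto"` picks exact whenever it
#' is available.
#'
#' @param x,y numeric samples (non-empty, finite).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param label label stored in the result.
#' @param paired paired (signed-rank) variant on `x - y`; requires
#'   equal lengths.
#'
#' @return A `comparison_result`: group sizes, `statistic` (U, or the
#'   signed-rank V when paired), two-sided `p_value`, group medians and
#'   effect direction (`group1` relative to `group2`).
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal"),
                           label = "", paired = FALSE) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in sample")
  }
  if (paired && length(x) != length(y)) {
    stop("paired test requires equal-length samples")
  }
  ties <- if (paired) {
    d <- x - y
    any(d == 0) || anyDuplicated(abs(d[d != 0])) > 0
  } else {
    anyDuplicated(c(x, y)) > 0
  }
  exact_ok <- (length(x) + length(y) <= 20L) && !ties
  use_exact <- switch(mode,
    auto = exact_ok,
    exact = {
      if (!exact_ok) {
        warning("exact mode unavailable (ties or n1 + n2 > 20); ",
                "falling back to normal approximation")
      }
      exact_ok
    },
    normal = FALSE)
  # degenerate case: a single shared value (or no nonzero paired
  # differences) carries no rank information; the tie-corrected
  # normal variance is 0 there, so report p = 1 directly
  degenerate <- if (paired) all(x == y) else
    length(unique(c(x, y))) == 1L
  if (degenerate) {
    stat <- if (paired) 0 else length(x) * length(y) / 2
    return(new_comparison_result(label, x, y, stat, 1, paired = paired))
  }
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", paired = paired,
    exact = use_exact, correct = TRUE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  new_comparison_result(label, x, y, ht$statistic, min(p, 1),
                        paired = paired)
}

#' Label genes by expression fold change between conditions
#'
#' Transparent fold-change rule standing in for a full differential
#' expression model: with ratio
#' `r = (kd + pseudocount) / (wt + pseudocount)`, a gene is `"up"`
#' when `r >= fc_threshold`, `"down"` when `r <= 1 / fc_threshold`,
#' else `"unchanged"`. Swapping the two conditions swaps the up and
#' down labels exactly. Externally computed labels (any DE caller) can
#' be substituted downstream via the `de_status` argument of
#' [build_stratified_dataset()].
#'
#' @param expr_wt,expr_kd non-negative expression vectors, paired by
#'   gene.
#' @param fc_threshold fold-change threshold (> 1; default 2).
#' @param pseudocount added to both values before the ratio
#'   (default 0.01).
#' @param gene_ids optional gene identifiers.
#'
#' @return data.frame: `gene_id`, `de_status` (`up`/`down`/
#'   `unchanged`), `log2_fc`, `abs_log2_fc`.
#' @export
fold_change_labels <- function(expr_wt, expr_kd, fc_threshold = 2,
                               pseudocount = 0.01, gene_ids = NULL) {
  stopifnot(length(expr_wt) == length(expr_kd), fc_threshold > 1,
            pseudocount >= 0)
  if (any(expr_wt < 0) || any(expr_kd < 0)) {
    stop("negative expression values")
  }
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(expr_wt))
  r <- (expr_kd + pseudocount) / (expr_wt + pseudocount)
  status <- ifelse(r >= fc_threshold, "up",
                   ifelse(r <= 1 / fc_threshold, "down", "unchanged"))
  data.frame(gene_id = gene_ids, de_status = status, log2_fc = log2(r),
             abs_log2_fc = abs(log2(r)), stringsAsFactors = FALSE)
}

#' Assemble the per-gene stratified dataset
#'
#' Joins WT and KD pausing tables, expression, promoter-binding calls
#' and differential-expression labels into one row per gene eligible in
#' both conditions — the substrate of all stratified comparisons.
#'
#' @param pi_wt,pi_kd [pi_table()] outputs for the two conditions.
#' @param binding named logical vector from [promoter_binding()].
#' @param expression expression matrix with columns `condition_wt` and
#'   `condition_kd`.
#' @param condition_wt,condition_kd column names in `expression`
#'   (defaults `"WT"`, `"KD"`).
#' @param fc_threshold,pseudocount passed to [fold_change_labels()].
#' @param de_status optional externally supplied labels: named
#'   character vector (gene id -> `up`/`down`/`unchanged`) replacing
#'   the built-in fold-change rule.
#' @param pi_threshold WT PI at or above which `high_pi_WT` is set
#'   (default 4).
#'
#' @return data.frame of class `stratified_dataset`: `gene_id`,
#'   `pi_WT`, `pi_KD`, `expr_WT`, `expr_KD`, `bound`, `high_pi_WT`,
#'   `de_status`, `log2_fc`, `abs_log2_fc`.
#' @export
build_stratified_dataset <- function(pi_wt, pi_kd, binding, expression,
                                     condition_wt = "WT",
                                     condition_kd = "KD",
                                     fc_threshold = 2, pseudocount = 0.01,
                                     de_status = NULL, pi_threshold = 4) {
  stopifnot(is.data.frame(pi_wt), is.data.frame(pi_kd))
  for (cond in c(condition_wt, condition_kd)) {
    if (!cond %in% colnames(expression)) {
      stop("condition '", cond, "' not found in expression table")
    }
  }
  keep <- intersect(pi_wt$gene_id[pi_wt$eligible],
                    pi_kd$gene_id[pi_kd$eligible])
  keep <- intersect(keep, rownames(expression))
  keep <- intersect(keep, names(binding))
  if (length(keep) == 0L) stop("no genes shared by all inputs")
  keep <- sort(keep)
  wt <- pi_wt[match(keep, pi_wt$gene_id), ]
  kd <- pi_kd[match(keep, pi_kd$gene_id), ]
  ewt <- expression[keep, condition_wt]
  ekd <- expression[keep, condition_kd]
  fc <- fold_change_labels(ewt, ekd, fc_threshold = fc_threshold,
                           pseudocount = pseudocount, gene_ids = keep)
  status <- fc$de_status
  if (!is.null(de_status)) {
    if (is.null(names(de_status))) stop("de_status must be named by gene id")
    hit <- match(keep, names(de_status))
    status <- ifelse(is.na(hit), "unchanged", de_status[hit])
    bad <- !status %in% c("up", "down", "unchanged")
    if (any(bad)) stop("invalid de_status value(s): ",
                       paste(unique(status[bad]), collapse = ", "))
  }
  out <- data.frame(gene_id = keep, pi_WT = wt$pi, pi_KD = kd$pi,
                    expr_WT = ewt, expr_KD = ekd,
                    bound = unname(binding[keep]),
                    high_pi_WT = wt$pi >= pi_threshold,
                    de_status = status, log2_fc = fc$log2_fc,
                    abs_log2_fc = fc$abs_log2_fc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("stratified_dataset", "data.frame")
  out
}

resolve_stratum <- function(data, stratum, label) {
  sel <- if (is.function(stratum)) stratum(data) else stratum
  if (!is.logical(sel) || length(sel) != nrow(data)) {
    stop("stratum predicate '", label,
         "' must yield one logical per gene")
  }
  sel & !is.na(sel)
}

#' Compare a value between two gene strata
#'
#' Runs [mann_whitney_u()] on the chosen per-gene value between two
#' strata. A stratum is a predicate function of the dataset (or a
#' logical vector); the condition arguments pick the `WT`/`KD` column,
#' so both between-group (bound vs unbound) and between-condition
#' (WT vs KD) comparisons are expressed in the same call.
#'
#' @param data a [build_stratified_dataset()] result.
#' @param value `"pi"` or `"expression"`.
#' @param stratum_a,stratum_b predicate functions of `data` (or
#'   logical vectors).
#' @param condition_a,condition_b `"WT"` or `"KD"` column selectors
#'   (default both `"WT"`).
#' @param mode,paired passed to [mann_whitney_u()].
#' @param label optional result label.
#'
#' @return A `comparison_result`.
#' @export
compare_strata <- function(data, value = c("pi", "expression"),
                           stratum_a, stratum_b,
                           condition_a = "WT", condition_b = condition_a,
                           mode = "auto", paired = FALSE, label = NULL) {
  value <- match.arg(value)
  stopifnot(inherits(data, "stratified_dataset"))
  la <- deparse1(substitute(stratum_a))
  lb <- deparse1(substitute(stratum_b))
  sel_a <- resolve_stratum(data, stratum_a, la)
  sel_b <- resolve_stratum(data, stratum_b, lb)
  col <- function(cond) {
    paste0(if (value == "pi") "pi_" else "expr_", match.arg(cond, c("WT", "KD")))
  }
  va <- data[[col(condition_a)]][sel_a]
  vb <- data[[col(condition_b)]][sel_b]
  if (length(va) == 0L) stop("empty stratum for predicate: ", la)
  if (length(vb) == 0L) stop("empty stratum for predicate: ", lb)
  if (is.null(label)) {
    label <- sprintf("%s: [%s, %s] vs [%s, %s]", value, la, condition_a,
                     lb, condition_b)
  }
  mann_whitney_u(va, vb, mode = mode, label = label, paired = paired)
}

#' WT-vs-KD analysis of the high-pausing gene set
#'
#' Selects genes whose wild-type PI is at or above `threshold` and
#' reports (i) the WT-vs-KD comparison of PI within that set, (ii) the
#' set split by promoter-binding status, each subset summarised by the
#' Pearson and Spearman correlation of WT and KD PIs, and (iii) a
#' comparison of the per-gene PI change (`log2(pi_KD / pi_WT)`)
#' between the bound and unbound subsets — a direct check of whether
#' the knockdown effect on pausing deviates between them.
#'
#' @param data a [build_stratified_dataset()] result.
#' @param threshold WT PI selection threshold (default 4).
#' @param paired use the paired signed-rank variant for the WT-vs-KD
#'   comparison (default FALSE: unpaired Mann-Whitney).
#' @param mode passed to [mann_whitney_u()].
#'
#' @return A list of class `high_pi_comparison`: `threshold`, `n`,
#'   `overall` (comparison_result), `subsets` (data.frame: `bound`,
#'   `n`, `pearson`, `spearman`), `shift_by_binding`
#'   (comparison_result, or NULL when a subset is empty).
#' @export
high_pi_comparison <- function(data, threshold = 4, paired = FALSE,
                               mode = "auto") {
  stopifnot(inherits(data, "stratified_dataset"))
  sel <- data$pi_WT >= threshold
  if (!any(sel)) {
    stop("no genes with WT PI >= ", threshold)
  }
  hp <- data[sel, , drop = FALSE]
  overall <- mann_whitney_u(hp$pi_WT, hp$pi_KD, mode = mode,
                            label = sprintf("PI WT vs KD, WT PI >= %g",
                                            threshold),
                            paired = paired)
  subsets <- do.call(rbind, lapply(c(TRUE, FALSE), function(b) {
    s <- hp[hp$bound == b, , drop = FALSE]
    data.frame(bound = b, n = nrow(s),
               pearson = if (nrow(s) >= 3L)
                 stats::cor(s$pi_WT, s$pi_KD) else NA_real_,
               spearman = if (nrow(s) >= 3L)
                 stats::cor(s$pi_WT, s$pi_KD, method = "spearman")
               else NA_real_)
  }))
  shift <- NULL
  if (all(c(TRUE, FALSE) %in% hp$bound)) {
    ratio <- log2(hp$pi_KD / hp$pi_WT)
    shift <- mann_whitney_u(ratio[hp$bound], ratio[!hp$bound], mode = mode,
                            label = "PI change (log2 KD/WT): bound vs unbound")
  }
  structure(list(threshold = threshold, n = nrow(hp), overall = overall,
                 subsets = subsets, shift_by_binding = shift),
            class = "high_pi_comparison")
}

#' @export
print.high_pi_comparison <- function(x, ...) {
  cat(sprintf("<high_pi_comparison> %d gene(s) with WT PI >= %g\n",
              x$n, x$threshold))
  print(x$overall)
  cat("  WT-vs-KD PI correlation by promoter binding:\n")
  print(x$subsets, row.names = FALSE)
  if (!is.null(x$shift_by_binding)) print(x$shift_by_binding)
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
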