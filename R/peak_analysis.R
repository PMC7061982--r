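# Peak-set analyses: positional cross-correlation profiles, feature
# annotation by precedence, promoter-binding calls, overlap fractions.

#' Positional correlation profile between two peak sets
#'
#' For every anchor-peak midpoint `a` and target-peak midpoint `t` on
#' the same chromosome with `|t - a| <= window`, the offset `t - a` is
#' accumulated into a histogram, and the counts are normalised by the
#' product of the two set sizes so that profiles are comparable across
#' datasets. Midpoint of `[s, e)` is `floor((s + e) / 2)`.
#'
#' Bins are centred: the profile has `2 * window / bin + 1` bins with
#' centres at `seq(-window, window, by = bin)`, and each offset is
#' assigned to the nearest bin centre (ties between two centres resolve
#' to the even multiple, symmetrically in sign). This layout makes the
#' profile exactly symmetric under exchanging anchors and targets.
#'
#' @param anchors,targets [peak_set()] objects (non-empty).
#' @param window symmetric half-width in bp (default 10000).
#' @param bin bin width in bp (default 100); `window` must be a
#'   multiple of `bin`.
#'
#' @return A list of class `correlation_profile` with elements
#'   `anchor_name`, `target_name`, `window`, `bin`, `offsets` (bin
#'   centres), `counts` (integer pair counts per bin), `values`
#'   (`counts / (n_anchors * n_targets)`), `n_anchors`, `n_targets`.
#' @export
positional_correlation <- function(anchors, targets, window = 10000,
                                   bin = 100) {
  stopifnot(inherits(anchors, "peak_set"), inherits(targets, "peak_set"))
  if (nrow(anchors) == 0L) stop("empty anchor peak set")
  if (nrow(targets) == 0L) stop("empty target peak set")
  stopifnot(window > 0, bin > 0)
  if (window %% bin != 0) stop("window must be a multiple of bin")
  half <- window / bin
  offsets <- seq(-window, window, by = bin)
  counts <- integer(length(offsets))
  a_mid <- floor((anchors$start + anchors$end) / 2)
  t_mid <- floor((targets$start + targets$end) / 2)
  for (chr in intersect(unique(anchors$chrom), unique(targets$chrom))) {
    a <- a_mid[anchors$chrom == chr]
    t <- sort(t_mid[targets$chrom == chr])
    for (ai in a) {
      lo <- findInterval(ai - window - 1, t) + 1L
      hi <- findInterval(ai + window, t)
      if (hi < lo) next
      k <- round((t[lo:hi] - ai) / bin) + half + 1L
      counts <- counts + tabulate(k, nbins = length(offsets))
    }
  }
  structure(list(anchor_name = attr(anchors, "set_name"),
                 target_name = attr(targets, "set_name"),
                 window = window, bin = bin, offsets = offsets,
                 counts = counts,
                 values = counts / (nrow(anchors) * nrow(targets)),
                 n_anchors = nrow(anchors), n_targets = nrow(targets)),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("<correlation_profile> %s vs %s, window=%d bp, bin=%d bp\n",
              x$anchor_name, x$target_name, x$window, x$bin))
  cat(sprintf("  %d anchor x %d target peaks, %d pair(s) in window; peak value %.3g at offset %d\n",
              x$n_anchors, x$n_targets, sum(x$counts),
              max(x$values), x$offsets[which.max(x$values)]))
  invisible(x)
}

# Default category interval sets derived from gene models.
default_features <- function(genes, flank, tes_flank) {
  tes <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  list(
    promoter = promoter_windows(genes, flank)[, c("chrom", "start", "end")],
    tes_proximal = data.frame(chrom = genes$chrom,
                              start = pmax(tes - tes_flank, 0),
                              end = tes + tes_flank + 1,
                              stringsAsFactors = FALSE),
    gene_body = data.frame(chrom = genes$chrom, start = genes$start,
                           end = genes$end, stringsAsFactors = FALSE)
  )
}

#' Annotate peaks over genomic features
#'
#' Each peak is assigned, by its midpoint, to the first category in
#' `precedence` whose feature intervals contain it; peaks matching no
#' feature fall through to `"intergenic"`. Default categories are
#' derived from the gene models: `promoter` (TSS +/- `flank`),
#' `tes_proximal` (3' end +/- `tes_flank`), `gene_body` (the gene
#' interval), `intergenic` (fallback). Additional or replacement
#' feature sets (e.g. exons) can be supplied via `features` as a named
#' list of data.frames with `chrom`/`start`/`end` columns, and named in
#' `precedence`.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_models()] data.frame.
#' @param precedence ordered character vector of category labels; must
#'   cover every supplied feature set and end-match `"intergenic"` as
#'   the fallback label (it needs no intervals).
#' @param flank promoter half-width in bp (default 250).
#' @param tes_flank TES-proximal half-width in bp (default 250).
#' @param features optional named list of extra feature interval sets.
#'
#' @return A list of class `feature_annotation`: `assignment`
#'   (per-peak category, in peak order), `table` (data.frame of
#'   `category`, `count`, `fraction` in precedence order; fractions
#'   sum to 1).
#' @export
annotate_peaks <- function(peaks, genes,
                           precedence = c("promoter", "tes_proximal",
                                          "gene_body", "intergenic"),
                           flank = 250, tes_flank = 250, features = NULL) {
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_models"))
  feats <- default_features(genes, flank, tes_flank)
  if (!is.null(features)) {
    missing_cats <- setdiff(names(features), precedence)
    if (length(missing_cats)) {
      stop("precedence does not cover feature categor(ies): ",
           paste(missing_cats, collapse = ", "))
    }
    feats[names(features)] <- features
  }
  feats <- feats[intersect(names(feats), precedence)]
  if (!"intergenic" %in% precedence) {
    stop("precedence must include the 'intergenic' fallback category")
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  mid_gr <- as_granges0(peaks$chrom, mid, mid + 1)
  assignment <- rep(NA_character_, nrow(peaks))
  for (cat in precedence) {
    if (cat == "intergenic") next
    f <- feats[[cat]]
    if (is.null(f) || nrow(f) == 0L) next
    fgr <- as_granges0(f$chrom, f$start, f$end)
    hit <- count_overlaps0(mid_gr, fgr) > 0
    assignment[is.na(assignment) & hit] <- cat
  }
  assignment[is.na(assignment)] <- "intergenic"
  counts <- vapply(precedence, function(cat) sum(assignment == cat), 1L)
  tab <- data.frame(category = precedence, count = as.integer(counts),
                    fraction = counts / nrow(peaks),
                    stringsAsFactors = FALSE)
  structure(list(assignment = assignment, table = tab,
                 peak_set_name = attr(peaks, "set_name")),
            class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat(sprintf("<feature_annotation> %d peak(s) from '%s'\n",
              length(x$assignment), x$peak_set_name))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Promoter-binding calls per gene
#'
#' A gene is bound when at least one peak overlaps its promoter window
#' (TSS +/- `flank`) by at least 1 bp.
#'
#' @param genes a [gene_models()] data.frame.
#' @param peaks a [peak_set()].
#' @param flank promoter half-width in bp (default 250).
#'
#' @return Named logical vector, one element per gene
#'   (names = gene ids, in the gene-table order).
#' @export
promoter_binding <- function(genes, peaks, flank = 250) {
  stopifnot(inherits(genes, "gene_models"), inherits(peaks, "peak_set"))
  pw <- promoter_windows(genes, flank)
  if (nrow(peaks) == 0L) {
    return(stats::setNames(rep(FALSE, nrow(genes)), genes$gene_id))
  }
  hits <- count_overlaps0(
    as_granges0(pw$chrom, pw$start, pw$end),
    as_granges0(peaks$chrom, peaks$start, peaks$end)) > 0
  stats::setNames(as.logical(hits), genes$gene_id)
}

#' Fraction of peaks in one set overlapping another
#'
#' A peak of `set_a` counts as overlapping when it shares at least
#' 1 bp with any peak of `set_b` (half-open intervals).
#'
#' @param set_a,set_b [peak_set()] objects (non-empty).
#' @return Fraction in `[0, 1]` of `set_a` peaks overlapping `set_b`.
#' @export
overlap_fraction <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "peak_set"), inherits(set_b, "peak_set"))
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) stop("empty peak set")
  hits <- count_overlaps0(
    as_granges0(set_a$chrom, set_a$start, set_a$end),
    as_granges0(set_b$chrom, set_b$start, set_b$end)) > 0
  mean(hits)
}

#' Split a peak set by overlap with another
#'
#' Utility for stratifying one factor's peaks by co-occurrence with a
#' mark (e.g. separating peaks that fall in repressive-mark territory
#' from those that do not).
#'
#' @param set_a,set_b [peak_set()] objects.
#' @param keep `"non_overlapping"` (default) returns the peaks of
#'   `set_a` sharing no base with `set_b`; `"overlapping"` returns the
#'   complement.
#' @return A [peak_set()] subset of `set_a`.
#' @export
subtract_overlapping <- function(set_a, set_b,
                                 keep = c("non_overlapping", "overlapping")) {
  keep <- match.arg(keep)
  stopifnot(inherits(set_a, "peak_set"), inherits(set_b, "peak_set"))
  if (nrow(set_b) == 0L) {
    hit <- rep(FALSE, nrow(set_a))
  } else {
    hit <- count_overlaps0(
      as_granges0(set_a$chrom, set_a$start, set_a$end),
      as_granges0(set_b$chrom, set_b$start, set_b$end)) > 0
  }
  sel <- if (keep == "overlapping") hit else !hit
  out <- set_a[sel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  attr(out, "set_name") <- sprintf("%s_%s_%s", attr(set_a, "set_name"),
                                   if (keep == "overlapping") "with" else "minus",
                                   attr(set_b, "set_name"))
  out
}
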