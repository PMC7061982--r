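# Shared fixtures and independent oracles used across the suite.
# Fixtures are built in code; oracles are deliberately naive
# (per-base loops, all-pairs enumeration) so they stay independent of
# the implementation paths they check.

tiny_genes <- function() {
  gene_models(gene_id = c("gA", "gB", "gC"),
              chrom = c("chr1", "chr1", "chr2"),
              start = c(1000, 20000, 5000),
              end = c(6000, 28000, 10000),
              strand = c("+", "-", "+"))
}

# coverage track from explicit bin vectors
track_from_bins <- function(..., bin_size = 10) {
  coverage_track(list(...), bin_size = bin_size)
}

flat_track <- function(value, n_bins = 1000, bin_size = 10,
                       chrom = "chr1") {
  sig <- list()
  sig[[chrom]] <- rep(value, n_bins)
  coverage_track(sig, bin_size = bin_size)
}

random_peaks <- function(n, chrom_len = 50000, chroms = "chr1",
                         max_width = 400, name = "rand") {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_len - max_width))
  width <- sample.int(max_width - 1L, n, replace = TRUE)
  peak_set(chrom, start, start + width, name = name)
}

# per-base summation oracle for region_density
oracle_region_density <- function(track, chrom, start, end) {
  v <- track$signal[[chrom]]
  bs <- track$bin_size
  vals <- vapply(seq(start, end - 1), function(b) {
    i <- floor(b / bs) + 1
    if (!is.null(v) && i >= 1 && i <= length(v)) v[i] else 0
  }, 1)
  mean(vals)
}

# all-pairs enumeration oracle for positional_correlation
oracle_xcorr_counts <- function(anchors, targets, window, bin) {
  offsets <- seq(-window, window, by = bin)
  counts <- integer(length(offsets))
  a_mid <- floor((anchors$start + anchors$end) / 2)
  t_mid <- floor((targets$start + targets$end) / 2)
  for (i in seq_len(nrow(anchors))) {
    for (j in seq_len(nrow(targets))) {
      if (anchors$chrom[i] != targets$chrom[j]) next
      d <- t_mid[j] - a_mid[i]
      if (abs(d) > window) next
      k <- round(d / bin) + window / bin + 1
      counts[k] <- counts[k] + 1L
    }
  }
  counts
}

# all-pairs overlap oracle (>= 1 shared bp, half-open)
oracle_overlap_fraction <- function(a, b) {
  hit <- vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & a$end[i] > b$start)
  }, TRUE)
  mean(hit)
}

# full-enumeration oracle for the exact Mann-Whitney test (no ties):
# two-sided p over all choose(n1 + n2, n1) group labelings
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  labelings <- utils::combn(length(pooled), n1)
  u_all <- apply(labelings, 2, function(ix) {
    u_of(pooled[ix], pooled[-ix])
  })
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  list(u = u_obs, p_two_sided = min(1, 2 * min(p_lo, p_hi)),
       p_lower = p_lo, p_upper = p_hi)
}
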