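# Deterministic synthetic-data generator with planted ground truth.
# Emulates the statistical structure of the study inputs: log-normal
# expression, PolII coverage with a promoter-proximal peak whose
# height/body ratio is the planted pausing ratio, co-localising peak
# sets, and a knockdown perturbing a small gene subset.

#' Simulation configuration
#'
#' All sources of randomness are driven by `seed`; the same
#' configuration always produces byte-identical outputs.
#'
#' @param seed integer master seed. Each generator stage uses a fixed
#'   small offset from it, so stages are reproducible independently of
#'   call order.
#' @param n_chroms,chrom_length genome shape (default one 10-Mb
#'   chromosome).
#' @param n_genes number of genes (default 1000).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene-length
#'   parameters (defaults give a median of 4 kb).
#' @param min_gene_length,max_gene_length clamp on sampled lengths.
#' @param gene_spacing minimum bp between placed genes, so that
#'   promoter windows never reach a neighbouring gene.
#' @param expr_meanlog,expr_sdlog log-normal expression parameters
#'   (TPM-like scale, median `exp(2) ~ 7.4`).
#' @param pausing_mixture data.frame with columns `fraction` (summing
#'   to 1) and `rho`, the planted TSS/body density ratio of each
#'   mixture component.
#' @param depth mean PolII body signal per bp (default 5, i.e. 50 per
#'   10-bp bin).
#' @param background mean signal per bp outside genes.
#' @param bin_size coverage bin width in bp (default 10).
#' @param binding promoter-binding model: `mode = "constant"` uses
#'   probability `prob` for every gene; `mode = "graded"` (default)
#'   uses `base + expr_slope * expression quantile + rho_bonus *
#'   (rho >= rho_threshold)`, clamped to `[0, 1]` — binding then
#'   increases with expression and pausing, as observed for promoter
#'   occupancy of active genes.
#' @param kap1_peak_width width of promoter-bound factor peaks,
#'   centred on the TSS.
#' @param kap1_background counts of additional factor peaks planted by
#'   category: `n_tes` (at gene 3' ends), `n_body` (inside gene
#'   bodies, clear of promoter and TES windows), `n_intergenic`
#'   (clear of all genes and windows).
#' @param flank promoter/TES half-width used for planting (must match
#'   the analysis flank for exact label recovery; default 250).
#' @param marks per-mark co-localisation settings, each a list of
#'   `p_given_kap1` (probability of a mark peak at each factor peak;
#'   values <= 0 mean the mark avoids factor peaks entirely),
#'   `jitter_sd` (bp SD of the Gaussian offset of co-placed peaks),
#'   `width`, and `n_independent` (peaks placed uniformly at random).
#' @param kd knockdown model: fractions of genes receiving a planted
#'   up/down expression effect (defaults 1.34% / 1.45%), the
#'   multiplicative effect sizes, log-normal multiplicative expression
#'   noise (`noise_sdlog`), and a uniform multiplicative effect
#'   `pi_effect` on the pausing ratio of genes whose planted rho is at
#'   least `pi_effect_threshold` (applied regardless of binding).
#' @param max_placement_attempts rejection-sampling attempts per
#'   placed element before giving up.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 1, chrom_length = 1e7, n_genes = 1000,
                       gene_length_meanlog = log(4000),
                       gene_length_sdlog = 0.5,
                       min_gene_length = 1500, max_gene_length = 50000,
                       gene_spacing = 1000,
                       expr_meanlog = 2, expr_sdlog = 1.2,
                       pausing_mixture = data.frame(
                         fraction = c(0.5, 0.3, 0.2), rho = c(1, 4, 8)),
                       depth = 5, background = 0.2, bin_size = 10,
                       binding = list(mode = "graded", prob = 0.3,
                                      base = 0.1, expr_slope = 0.5,
                                      rho_bonus = 0.2, rho_threshold = 4),
                       kap1_peak_width = 300,
                       kap1_background = list(n_tes = 150, n_body = 350,
                                              n_intergenic = 700),
                       flank = 250,
                       marks = list(
                         PolII = list(p_given_kap1 = 0.8, jitter_sd = 100,
                                      width = 300, n_independent = 200),
                         H3K27ac = list(p_given_kap1 = 0.7, jitter_sd = 150,
                                        width = 400, n_independent = 300),
                         H3K4me1 = list(p_given_kap1 = 0.6, jitter_sd = 150,
                                        width = 400, n_independent = 400),
                         H3K9me3 = list(p_given_kap1 = 0, jitter_sd = 0,
                                        width = 600, n_independent = 500)),
                       kd = list(frac_up = 0.0134, frac_down = 0.0145,
                                 effect_up = 4, effect_down = 0.25,
                                 noise_sdlog = 0.1, pi_effect = 0.8,
                                 pi_effect_threshold = 4),
                       max_placement_attempts = 500) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_chroms >= 1, chrom_length > 0, n_genes >= 1,
            min_gene_length > 0, max_gene_length >= min_gene_length,
            depth >= 0, background >= 0, bin_size >= 1, flank > 0)
  stopifnot(is.data.frame(pausing_mixture),
            all(c("fraction", "rho") %in% colnames(pausing_mixture)),
            all(pausing_mixture$rho > 0))
  if (abs(sum(pausing_mixture$fraction) - 1) > 1e-8) {
    stop("pausing_mixture fractions must sum to 1")
  }
  probs <- c(binding$prob, binding$base,
             vapply(marks, function(m) max(m$p_given_kap1, 0), 1),
             kd$frac_up, kd$frac_down)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_chroms = n_chroms,
                 chrom_length = chrom_length, n_genes = n_genes,
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog,
                 min_gene_length = min_gene_length,
                 max_gene_length = max_gene_length,
                 gene_spacing = gene_spacing,
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 pausing_mixture = pausing_mixture, depth = depth,
                 background = background, bin_size = bin_size,
                 binding = binding, kap1_peak_width = kap1_peak_width,
                 kap1_background = kap1_background, flank = flank,
                 marks = marks, kd = kd,
                 max_placement_attempts = max_placement_attempts),
            class = "sim_config")
}

# Stage seeds: fixed offsets from the master seed, kept within 32-bit
# integer range.
stage_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) + offset) %% .Machine$integer.max)
}

#' Simulate a gene annotation with planted per-gene ground truth
#'
#' Places non-overlapping genes (with a minimum spacing) on the
#' synthetic genome by rejection sampling, assigns strands 50/50, and
#' draws every per-gene latent quantity the downstream generators
#' consume: log-normal wild-type expression, the planted pausing ratio
#' `rho` (from the mixture), promoter-binding labels, knockdown
#' expression effects and the knockdown pausing ratio `rho_kd`.
#'
#' @param cfg a [sim_config()].
#' @param gtf optional path; when given, the annotation is also
#'   written as minimal GTF.
#'
#' @return A [gene_models()] data.frame with ground-truth columns
#'   `expr_wt`, `rho`, `rho_kd`, `bound`, `kd_effect`, `de_truth`.
#' @export
simulate_genome <- function(cfg, gtf = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, 0L))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_len <- rep(cfg$chrom_length, length.out = cfg$n_chroms)
  lens <- round(pmin(pmax(
    stats::rlnorm(cfg$n_genes, cfg$gene_length_meanlog, cfg$gene_length_sdlog),
    cfg$min_gene_length), cfg$max_gene_length))
  chrom_of <- rep(seq_len(cfg$n_chroms), length.out = cfg$n_genes)
  # Non-overlapping placement by gap allocation: per chromosome, the
  # free space left after the genes and their minimum spacings is
  # split into random inter-gene gaps (uniform over the simplex), and
  # genes are laid out in shuffled order. Uniform over feasible
  # arrangements and always succeeds when the genes fit.
  starts <- numeric(cfg$n_genes)
  for (ci in seq_len(cfg$n_chroms)) {
    idx <- which(chrom_of == ci)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    k <- length(idx)
    slack <- chrom_len[ci] - sum(lens[idx]) - (k + 1) * cfg$gene_spacing
    if (slack < 0) {
      stop("cannot place ", k, " genes (total ",
           format(sum(lens[idx]), scientific = FALSE),
           " bp plus spacing) on a chromosome of ",
           format(chrom_len[ci], scientific = FALSE),
           " bp; increase chrom_length or reduce n_genes")
    }
    cuts <- sort(stats::runif(k, 0, slack))
    gaps <- diff(c(0, cuts))
    starts[idx] <- cfg$gene_spacing +
      round(cumsum(gaps) + c(0, cumsum(lens[idx][-k] + cfg$gene_spacing)))
  }
  strand <- ifelse(stats::rbinom(cfg$n_genes, 1, 0.5) == 1, "+", "-")
  expr_wt <- stats::rlnorm(cfg$n_genes, cfg$expr_meanlog, cfg$expr_sdlog)
  comp <- sample.int(nrow(cfg$pausing_mixture), cfg$n_genes, replace = TRUE,
                     prob = cfg$pausing_mixture$fraction)
  rho <- cfg$pausing_mixture$rho[comp]
  # binding probability, optionally increasing with expression and rho
  b <- cfg$binding
  p_bound <- if (identical(b$mode, "constant")) {
    rep(b$prob, cfg$n_genes)
  } else {
    q <- (rank(expr_wt, ties.method = "average") - 0.5) / cfg$n_genes
    pmin(pmax(b$base + b$expr_slope * q +
                b$rho_bonus * (rho >= b$rho_threshold), 0), 1)
  }
  bound <- stats::runif(cfg$n_genes) < p_bound
  # knockdown targets: disjoint up/down sets
  n_up <- round(cfg$kd$frac_up * cfg$n_genes)
  n_down <- round(cfg$kd$frac_down * cfg$n_genes)
  pick <- sample.int(cfg$n_genes, n_up + n_down)
  kd_effect <- rep(1, cfg$n_genes)
  kd_effect[pick[seq_len(n_up)]] <- cfg$kd$effect_up
  kd_effect[pick[n_up + seq_len(n_down)]] <- cfg$kd$effect_down
  de_truth <- rep("unchanged", cfg$n_genes)
  de_truth[pick[seq_len(n_up)]] <- "up"
  de_truth[pick[n_up + seq_len(n_down)]] <- "down"
  rho_kd <- ifelse(rho >= cfg$kd$pi_effect_threshold,
                   rho * cfg$kd$pi_effect, rho)
  genes <- gene_models(
    gene_id = sprintf("gene_%05d", seq_len(cfg$n_genes)),
    chrom = chroms[chrom_of], start = starts, end = starts + lens,
    strand = strand,
    extra = data.frame(expr_wt = expr_wt, rho = rho, rho_kd = rho_kd,
                       bound = bound, kd_effect = kd_effect,
                       de_truth = de_truth, stringsAsFactors = FALSE))
  attr(genes, "chrom_lengths") <- stats::setNames(chrom_len, chroms)
  if (!is.null(gtf)) write_gtf(genes, gtf)
  genes
}

#' Simulate a PolII coverage track with planted pausing ratios
#'
#' Per-bin Poisson counts around a piecewise-constant rate: background
#' outside genes, `depth` per bp over each gene, and `rho * depth`
#' over the TSS window (TSS +/- 250 bp, oriented by strand). Expected
#' bin masses use exact partial-bin length weighting, so the planted
#' TSS/body density ratio is recovered without binning bias. Under the
#' `"KD"` condition the planted ratio is `rho_kd`.
#'
#' @param genes output of [simulate_genome()].
#' @param cfg the same [sim_config()].
#' @param condition `"WT"` or `"KD"`.
#' @param bedgraph optional path to also write the track as bedGraph.
#'
#' @return A list: `track` (a [coverage_track()]) and `truth`
#'   (data.frame `gene_id`, `rho` planted for this condition).
#' @export
simulate_polii_coverage <- function(genes, cfg, condition = c("WT", "KD"),
                                    bedgraph = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, if (condition == "WT") 101L else 102L))
  rho <- if (condition == "WT") genes$rho else genes$rho_kd
  bs <- cfg$bin_size
  chrom_len <- attr(genes, "chrom_lengths")
  if (is.null(chrom_len)) {
    chrom_len <- tapply(genes$end, genes$chrom, max) + 10000
  }
  # piecewise-constant rate segments (relative to background)
  tw <- cfg$flank
  tss_s <- genes$tss - tw
  tss_e <- genes$tss + tw + 1
  seg <- data.frame(
    chrom = rep(genes$chrom, 3L),
    start = c(tss_s, ifelse(genes$strand == "+", tss_e, genes$start),
              rep(0, nrow(genes))),
    end = c(tss_e, ifelse(genes$strand == "+", genes$end, tss_s),
            rep(0, nrow(genes))),
    rate = c(rho * cfg$depth - cfg$background,
             rep(cfg$depth - cfg$background, 2L * nrow(genes))))
  # gene remainder on the other side of the TSS window, where present
  seg$start[(2L * nrow(genes) + 1L):(3L * nrow(genes))] <-
    ifelse(genes$strand == "+", genes$start, tss_e)
  seg$end[(2L * nrow(genes) + 1L):(3L * nrow(genes))] <-
    ifelse(genes$strand == "+", tss_s, genes$end)
  seg$start <- pmax(seg$start, 0)
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  signal <- list()
  for (chr in names(chrom_len)) {
    n_bins <- as.integer(ceiling(chrom_len[[chr]] / bs))
    mass <- rep(cfg$background * bs, n_bins)
    s <- seg[seg$chrom == chr, , drop = FALSE]
    if (nrow(s)) {
      add <- bin_records(s$start, s$end, s$rate, bs) * bs
      mass[seq_along(add)] <- mass[seq_along(add)] + add
    }
    signal[[chr]] <- stats::rpois(n_bins, pmax(mass, 0)) / bs
  }
  track <- coverage_track(signal, bs,
                          name = paste0("PolII_", condition))
  if (!is.null(bedgraph)) write_bedgraph(track, bedgraph)
  list(track = track,
       truth = data.frame(gene_id = genes$gene_id, rho = rho,
                          stringsAsFactors = FALSE))
}

# Uniform placement of n peak midpoints avoiding a set of forbidden
# intervals (half-open), by batched rejection sampling.
place_avoiding <- function(n, chroms, chrom_len, width, forbidden,
                           max_attempts) {
  half <- floor(width / 2)
  fgr <- if (nrow(forbidden)) {
    as_granges0(forbidden$chrom, forbidden$start, forbidden$end)
  }
  kept_chrom <- character(0)
  kept_mid <- numeric(0)
  rounds <- 0L
  while (length(kept_mid) < n) {
    rounds <- rounds + 1L
    if (rounds > max_attempts) {
      stop("could not place ", n, " peaks after ", max_attempts,
           " sampling rounds; genome too crowded")
    }
    m <- max(2L * (n - length(kept_mid)), 32L)
    ci <- sample.int(length(chroms), m, replace = TRUE)
    mid <- floor(stats::runif(m, half,
                              unname(chrom_len[ci]) - half))
    ok <- rep(TRUE, m)
    if (!is.null(fgr)) {
      ok <- count_overlaps0(
        as_granges0(chroms[ci], mid, mid + 1L), fgr) == 0
    }
    kept_chrom <- c(kept_chrom, chroms[ci][ok])
    kept_mid <- c(kept_mid, mid[ok])
  }
  kept_chrom <- kept_chrom[seq_len(n)]
  kept_mid <- kept_mid[seq_len(n)]
  data.frame(chrom = kept_chrom, start = kept_mid - half,
             end = kept_mid - half + width, stringsAsFactors = FALSE)
}

#' Simulate co-localising peak sets with planted labels
#'
#' The factor (KAP1) peak set comprises one promoter peak centred on
#' the TSS of every bound gene, plus background peaks planted by
#' category: at gene 3' ends (`tes_proximal`), inside gene bodies
#' clear of the promoter and TES windows (`gene_body`), and in
#' intergenic space clear of all genes extended by the promoter flank
#' (`intergenic`). Mark peak sets are placed at factor-peak midpoints
#' with the configured conditional probability and Gaussian positional
#' jitter, plus independent uniformly placed peaks; a mark with
#' `p_given_kap1 <= 0` avoids factor peaks entirely (its independent
#' peaks are rejected when they would overlap one), emulating a
#' mutually exclusive repressive mark.
#'
#' @param genes output of [simulate_genome()].
#' @param cfg the same [sim_config()].
#' @param dir optional directory; when given, each set is written as
#'   `peaks_<name>.bed`.
#'
#' @return A list: `peaks` (named list of [peak_set()]s, `KAP1` plus
#'   one per configured mark), `binding` (named logical ground-truth
#'   vector per gene), `kap1_categories` (planted category per factor
#'   peak, aligned with the sorted `KAP1` set).
#' @export
simulate_peaks <- function(genes, cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, 201L))
  chrom_len <- attr(genes, "chrom_lengths")
  chroms <- names(chrom_len)
  w <- cfg$kap1_peak_width
  half <- floor(w / 2)
  pw <- promoter_windows(genes, cfg$flank)
  tes <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  tes_w <- data.frame(chrom = genes$chrom,
                      start = pmax(tes - cfg$flank, 0),
                      end = tes + cfg$flank + 1)
  # promoter peaks at bound genes
  bnd <- genes$bound
  prom_peaks <- data.frame(chrom = genes$chrom[bnd],
                           start = genes$tss[bnd] - half,
                           end = genes$tss[bnd] - half + w,
                           category = "promoter",
                           stringsAsFactors = FALSE)
  kb <- cfg$kap1_background
  # TES peaks: midpoints at the 3' end of sampled genes
  pick_tes <- sample.int(nrow(genes), min(kb$n_tes, nrow(genes)))
  tes_peaks <- data.frame(chrom = genes$chrom[pick_tes],
                          start = tes[pick_tes] - half,
                          end = tes[pick_tes] - half + w,
                          category = "tes_proximal",
                          stringsAsFactors = FALSE)
  # body peaks: midpoints far enough inside sampled genes that the
  # peak interval stays clear of both the promoter and TES windows
  margin <- cfg$flank + half + 61
  long <- which(genes$end - genes$start > 2 * margin + 1)
  pick_body <- long[sample.int(length(long), min(kb$n_body, length(long)),
                               replace = TRUE)]
  body_mid <- floor(stats::runif(length(pick_body),
                                 genes$start[pick_body] + margin,
                                 genes$end[pick_body] - margin))
  body_peaks <- data.frame(chrom = genes$chrom[pick_body],
                           start = body_mid - half,
                           end = body_mid - half + w,
                           category = "gene_body",
                           stringsAsFactors = FALSE)
  # intergenic peaks: midpoints clear of genes extended by the flank
  forbidden <- data.frame(chrom = genes$chrom,
                          start = pmax(genes$start - cfg$flank - half - 1, 0),
                          end = genes$end + cfg$flank + half + 1)
  inter_peaks <- place_avoiding(kb$n_intergenic, chroms, chrom_len, w,
                                forbidden, cfg$max_placement_attempts)
  inter_peaks$category <- "intergenic"
  kap1_df <- rbind(prom_peaks, tes_peaks, body_peaks, inter_peaks)
  kap1_df$start <- pmax(kap1_df$start, 0)
  ord <- order(kap1_df$chrom, kap1_df$start, kap1_df$end)
  kap1_df <- kap1_df[ord, , drop = FALSE]
  kap1 <- peak_set(kap1_df$chrom, kap1_df$start, kap1_df$end, name = "KAP1")
  kap1_mid <- floor((kap1_df$start + kap1_df$end) / 2)
  peaks <- list(KAP1 = kap1)
  for (mark in names(cfg$marks)) {
    m <- cfg$marks[[mark]]
    mhalf <- floor(m$width / 2)
    co <- NULL
    if (m$p_given_kap1 > 0) {
      take <- stats::runif(nrow(kap1_df)) < m$p_given_kap1
      jit <- if (m$jitter_sd > 0) {
        round(stats::rnorm(sum(take), 0, m$jitter_sd))
      } else 0
      mid <- kap1_mid[take] + jit
      co <- data.frame(chrom = kap1_df$chrom[take],
                       start = pmax(mid - mhalf, 0),
                       end = pmax(mid - mhalf, 0) + m$width,
                       stringsAsFactors = FALSE)
    }
    avoid <- if (m$p_given_kap1 <= 0) {
      data.frame(chrom = kap1_df$chrom,
                 start = pmax(kap1_df$start - mhalf - 1, 0),
                 end = kap1_df$end + mhalf + 1)
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric())
    }
    indep <- if (m$n_independent > 0) {
      place_avoiding(m$n_independent, chroms, chrom_len, m$width, avoid,
                     cfg$max_placement_attempts)
    }
    mdf <- rbind(co, indep)
    if (is.null(mdf)) {
      mdf <- data.frame(chrom = character(), start = numeric(),
                        end = numeric())
    }
    peaks[[mark]] <- peak_set(mdf$chrom, mdf$start, mdf$end, name = mark)
  }
  if (!is.null(dir)) {
    for (nm in names(peaks)) {
      write_bed(peaks[[nm]], file.path(dir, paste0("peaks_", nm, ".bed")))
    }
  }
  list(peaks = peaks,
       binding = stats::setNames(genes$bound, genes$gene_id),
       kap1_categories = kap1_df$category)
}

#' Simulate wild-type and knockdown expression
#'
#' Wild-type expression is the log-normal latent drawn by
#' [simulate_genome()]; knockdown expression is the wild-type value
#' times the planted per-gene effect times log-normal multiplicative
#' noise. With `noise_sdlog = 0` the planted differential-expression
#' labels are recoverable exactly by the fold-change rule.
#'
#' @param genes output of [simulate_genome()].
#' @param cfg the same [sim_config()].
#' @param path optional path to also write the matrix as TSV.
#'
#' @return A list: `expression` (matrix, columns `WT` and `KD`,
#'   rownames = gene ids) and `truth` (data.frame `gene_id`,
#'   `de_status`, `kd_effect`).
#' @export
simulate_expression_and_kd <- function(genes, cfg, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, 301L))
  noise <- if (cfg$kd$noise_sdlog > 0) {
    stats::rlnorm(nrow(genes), 0, cfg$kd$noise_sdlog)
  } else 1
  mat <- cbind(WT = genes$expr_wt,
               KD = genes$expr_wt * genes$kd_effect * noise)
  rownames(mat) <- genes$gene_id
  if (!is.null(path)) write_expression_table(mat, path)
  list(expression = mat,
       truth = data.frame(gene_id = genes$gene_id,
                          de_status = genes$de_truth,
                          kd_effect = genes$kd_effect,
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs every generator stage and writes the standard-format files the
#' pipeline consumes: `genes.gtf`, `coverage_WT.bedgraph`,
#' `coverage_KD.bedgraph`, `peaks_<set>.bed` for the factor and each
#' mark, `expression.tsv`, and `ground_truth.tsv` (per-gene latents).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#'
#' @return Invisibly, a list with the in-memory objects: `genes`,
#'   `tracks` (WT/KD coverage), `peaks`, `binding`,
#'   `kap1_categories`, `expression`, `de_truth`, `paths`.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    gtf = file.path(dir, "genes.gtf"),
    coverage_wt = file.path(dir, "coverage_WT.bedgraph"),
    coverage_kd = file.path(dir, "coverage_KD.bedgraph"),
    expression = file.path(dir, "expression.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"))
  genes <- simulate_genome(cfg, gtf = paths$gtf)
  cov_wt <- simulate_polii_coverage(genes, cfg, "WT", paths$coverage_wt)
  cov_kd <- simulate_polii_coverage(genes, cfg, "KD", paths$coverage_kd)
  pk <- simulate_peaks(genes, cfg, dir = dir)
  ex <- simulate_expression_and_kd(genes, cfg, path = paths$expression)
  truth <- as.data.frame(genes)[, c("gene_id", "chrom", "start", "end",
                                    "strand", "tss", "expr_wt", "rho",
                                    "rho_kd", "bound", "kd_effect",
                                    "de_truth")]
  data.table::fwrite(truth, paths$ground_truth, sep = "\t")
  paths$peaks <- stats::setNames(
    file.path(dir, paste0("peaks_", names(pk$peaks), ".bed")),
    names(pk$peaks))
  invisible(list(genes = genes,
                 tracks = list(WT = cov_wt$track, KD = cov_kd$track),
                 peaks = pk$peaks, binding = pk$binding,
                 kap1_categories = pk$kap1_categories,
                 expression = ex$expression, de_truth = ex$truth,
                 paths = paths))
}
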