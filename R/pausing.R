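# Per-gene pausing index: ratio of PolII signal density over the
# TSS region to density over the gene body.

#' Pausing-index configuration
#'
#' @param tss_window signed offsets (upstream, downstream) of the TSS
#'   region relative to the TSS, in bp; default `c(-250, 250)`, i.e.
#'   the half-open window `[tss - 250, tss + 251)` on the plus strand
#'   (mirrored for minus-strand genes).
#' @param body_offset bp downstream of the TSS at which the gene body
#'   starts (default 500); must be at least the downstream extent of
#'   `tss_window`.
#' @param pseudocount signal density added to both the TSS and body
#'   densities before taking their ratio (default 0.001 per bp, i.e.
#'   one read-equivalent per kb). Keeps the PI of an empty track at 1.
#' @param pi_threshold PI at or above which a gene is flagged as
#'   high-PI (default 4).
#' @param min_gene_length minimum gene length in bp for PI eligibility
#'   (default 1000).
#'
#' @return A list of class `pi_config`.
#' @export
pi_config <- function(tss_window = c(-250, 250), body_offset = 500,
                      pseudocount = 0.001, pi_threshold = 4,
                      min_gene_length = 1000) {
  stopifnot(length(tss_window) == 2L, tss_window[1] <= tss_window[2],
            length(body_offset) == 1L,
            pseudocount >= 0, pi_threshold > 0, min_gene_length >= 0)
  if (body_offset < tss_window[2]) {
    stop("body_offset must be >= the downstream extent of tss_window")
  }
  structure(list(tss_window = as.numeric(tss_window),
                 body_offset = as.numeric(body_offset),
                 pseudocount = as.numeric(pseudocount),
                 pi_threshold = as.numeric(pi_threshold),
                 min_gene_length = as.numeric(min_gene_length)),
            class = "pi_config")
}

#' Mean per-base signal density over an interval
#'
#' Computed from the track's bins with partial-bin length weighting;
#' bins outside the track's extent (or on chromosomes absent from the
#' track) read as 0.
#'
#' @param track a [coverage_track()].
#' @param chrom chromosome name.
#' @param start,end half-open 0-based interval; must be non-empty.
#'
#' @return Mean signal per bp over `[start, end)`.
#' @export
region_density <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  if (end <= start) stop("empty interval: start >= end")
  start <- max(start, 0)
  if (end <= start) return(0)
  v <- track$signal[[chrom]]
  if (is.null(v)) return(0)
  bs <- track$bin_size
  sb <- floor(start / bs)
  eb <- floor((end - 1) / bs)
  idx <- sb:eb
  vals <- ifelse(idx < length(v), v[idx + 1L], 0)
  vals[is.na(vals)] <- 0
  w <- pmin(end, (idx + 1) * bs) - pmax(start, idx * bs)
  sum(vals * w) / (end - start)
}

# Strand-oriented TSS-region and body intervals for one gene.
gene_regions <- function(tss, start, end, strand, cfg) {
  if (strand == "+") {
    list(tss_region = c(max(tss + cfg$tss_window[1], 0),
                        tss + cfg$tss_window[2] + 1),
         body = c(tss + cfg$body_offset, end))
  } else {
    list(tss_region = c(max(tss - cfg$tss_window[2], 0),
                        tss - cfg$tss_window[1] + 1),
         body = c(start, tss - cfg$body_offset + 1))
  }
}

#' Pausing index of a single gene
#'
#' The pausing index (PI, also called traveling ratio) is the ratio of
#' PolII signal density over the TSS region to signal density over the
#' gene body:
#' `PI = (tss_density + eps) / (body_density + eps)`.
#' The TSS region is `tss_window` around the TSS and the body runs
#' from `body_offset` downstream of the TSS to the gene's 3' end, both
#' oriented by strand. Genes shorter than `min_gene_length`, or whose
#' body would be shorter than one coverage bin, are marked ineligible
#' (`pi = NA`) rather than dropped or given an infinite PI.
#'
#' @param track a [coverage_track()] of PolII signal.
#' @param gene one row of a [gene_models()] data.frame.
#' @param cfg a [pi_config()].
#' @param condition condition label stored in the record.
#' @param expression optional expression value stored in the record.
#'
#' @return One-row data.frame: `gene_id`, `condition`, `tss_density`,
#'   `body_density`, `pi`, `expression`, `high_pi`, `eligible`.
#' @export
pausing_index <- function(track, gene, cfg = pi_config(),
                          condition = "WT", expression = NA_real_) {
  stopifnot(inherits(cfg, "pi_config"), nrow(gene) == 1L)
  len <- gene$end - gene$start
  bs <- track$bin_size
  eligible <- len >= cfg$min_gene_length && len > cfg$body_offset + bs
  if (!eligible) {
    return(data.frame(gene_id = gene$gene_id, condition = condition,
                      tss_density = NA_real_, body_density = NA_real_,
                      pi = NA_real_, expression = expression,
                      high_pi = NA, eligible = FALSE,
                      stringsAsFactors = FALSE))
  }
  reg <- gene_regions(gene$tss, gene$start, gene$end, gene$strand, cfg)
  tssd <- region_density(track, gene$chrom, reg$tss_region[1], reg$tss_region[2])
  bodyd <- region_density(track, gene$chrom, reg$body[1], reg$body[2])
  pi <- (tssd + cfg$pseudocount) / (bodyd + cfg$pseudocount)
  data.frame(gene_id = gene$gene_id, condition = condition,
             tss_density = tssd, body_density = bodyd, pi = pi,
             expression = expression, high_pi = pi >= cfg$pi_threshold,
             eligible = TRUE, stringsAsFactors = FALSE)
}

#' Pausing-index table for a gene set
#'
#' One [pausing_index()] record per gene, ordered by `gene_id`.
#' When an expression matrix is supplied, each record carries the
#' gene's expression under `condition`; genes present in the matrix
#' but absent from the annotation are flagged with a warning and
#' recorded in `attr(, "unannotated_genes")`, never dropped silently.
#'
#' @param track a [coverage_track()] of PolII signal.
#' @param genes a [gene_models()] data.frame.
#' @param cfg a [pi_config()].
#' @param expression optional expression matrix from
#'   [read_expression_table()].
#' @param condition condition label; must be a column of `expression`
#'   when one is given.
#'
#' @return data.frame of per-gene pausing records (class `pi_table`).
#' @export
pi_table <- function(track, genes, cfg = pi_config(), expression = NULL,
                     condition = "WT") {
  stopifnot(inherits(genes, "gene_models"))
  expr <- rep(NA_real_, nrow(genes))
  unannotated <- character()
  if (!is.null(expression)) {
    if (!condition %in% colnames(expression)) {
      stop("condition '", condition, "' not found in expression table (has: ",
           paste(colnames(expression), collapse = ", "), ")")
    }
    unannotated <- setdiff(rownames(expression), genes$gene_id)
    if (length(unannotated)) {
      warning(length(unannotated),
              " gene(s) in the expression table are absent from the annotation: ",
              paste(head(unannotated, 5L), collapse = ", "),
              if (length(unannotated) > 5L) ", ..." else "")
    }
    hit <- match(genes$gene_id, rownames(expression))
    expr <- unname(expression[hit, condition])
  }
  recs <- lapply(seq_len(nrow(genes)), function(i) {
    pausing_index(track, genes[i, , drop = FALSE], cfg,
                  condition = condition, expression = expr[i])
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pi_table", "data.frame")
  attr(out, "unannotated_genes") <- unannotated
  out
}
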