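# Core containers: gene models, peak sets, coverage tracks.
# Convention: all coordinates 0-based half-open [start, end), as in BED.

#' Construct a table of gene models
#'
#' Validates and normalises a set of single-transcript gene models. The
#' TSS is the annotated 5' end: `start` for `+` genes, `end - 1` for
#' `-` genes (0-based).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom character vector of chromosome names (kept verbatim).
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param strand character vector, each `"+"` or `"-"`.
#' @param extra optional data.frame of additional per-gene columns
#'   (e.g. simulator ground truth), recycled against the genes.
#'
#' @return A data.frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, sorted by
#'   (`chrom`, `start`).
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, extra = NULL) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- as.character(strand)
  n <- length(gene_id)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(strand) == n)
  if (anyDuplicated(gene_id)) {
    dups <- unique(gene_id[duplicated(gene_id)])
    stop("duplicate gene id(s): ", paste(dups, collapse = ", "))
  }
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("unknown strand symbol(s): ",
         paste(unique(strand[bad_strand]), collapse = ", "))
  }
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(start < 0)) {
    stop("gene coordinates must be finite and non-negative")
  }
  if (any(start >= end)) {
    stop("gene(s) with start >= end: ",
         paste(gene_id[start >= end], collapse = ", "))
  }
  tss <- ifelse(strand == "+", start, end - 1)
  df <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                   end = end, strand = strand, tss = tss,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == n)
    df <- cbind(df, extra)
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Construct a peak set
#'
#' A named, sorted collection of genomic intervals (ChIP-seq peak calls),
#' 0-based half-open.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open; `start < end`.
#' @param score optional numeric score per peak (`NA` allowed).
#' @param peak_name optional character vector of per-peak names.
#' @param strand optional character vector of strands.
#' @param name name of the set (e.g. `"KAP1"`, `"PolII"`).
#'
#' @return A data.frame of class `peak_set`, sorted by
#'   (`chrom`, `start`, `end`), with the set name in
#'   `attr(, "set_name")`.
#' @export
peak_set <- function(chrom, start, end, score = NULL, peak_name = NULL,
                     strand = NULL, name = "peaks") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("peak coordinates must be finite")
  }
  if (any(start < 0)) stop("peak start < 0")
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    stop(sprintf("peak with start >= end (%s:%s-%s)",
                 chrom[i], format(start[i], scientific = FALSE),
                 format(end[i], scientific = FALSE)))
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(peak_name)) df$name <- as.character(peak_name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  attr(df, "set_name") <- name
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set '%s'> %d interval(s) on %d chromosome(s)\n",
              attr(x, "set_name"), nrow(x), length(unique(x$chrom))))
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Construct a coverage track
#'
#' Per-chromosome numeric signal at fixed bin resolution. Bin `i`
#' (0-based) covers bases `[i * bin_size, (i + 1) * bin_size)` and
#' stores the mean per-base signal level over that bin.
#'
#' @param signal named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param bin_size bin width in bp (positive integer).
#' @param name track name.
#' @param allow_negative permit negative signal values (e.g.
#'   input-subtracted tracks).
#'
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(signal, bin_size, name = "coverage",
                           allow_negative = FALSE) {
  stopifnot(is.list(signal), length(bin_size) == 1L, bin_size >= 1)
  if (is.null(names(signal)) || any(!nzchar(names(signal)))) {
    stop("signal must be a named list (chromosome names)")
  }
  for (chrom in names(signal)) {
    v <- signal[[chrom]]
    if (!is.numeric(v)) stop("signal for ", chrom, " is not numeric")
    if (any(!is.finite(v))) stop("non-finite signal values on ", chrom)
    if (!allow_negative && any(v < 0)) {
      stop("negative signal values on ", chrom,
           " (set allow_negative = TRUE to permit)")
    }
    signal[[chrom]] <- as.numeric(v)
  }
  structure(list(name = name, bin_size = as.integer(bin_size),
                 signal = signal),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  ext <- vapply(x$signal, length, 1L) * x$bin_size
  cat(sprintf("<coverage_track '%s'> bin_size=%d bp, %d chromosome(s)\n",
              x$name, x$bin_size, length(x$signal)))
  for (chrom in names(x$signal)) {
    cat(sprintf("  %s: %s bp in %d bins\n", chrom,
                format(ext[[chrom]], big.mark = ","),
                length(x$signal[[chrom]])))
  }
  invisible(x)
}

#' Promoter windows around gene TSSs
#'
#' The promoter of a gene is its annotated 5' end extended by `flank`
#' nucleotides in either direction: the half-open interval
#' `[tss - flank, tss + flank + 1)` (width `2 * flank + 1` bp), clipped
#' at the chromosome start. The window is strand-symmetric: reversing a
#' gene's strand moves it to the opposite gene end without resizing it.
#'
#' @param genes a `gene_models` data.frame.
#' @param flank extension in bp on each side of the TSS (default 250).
#'
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), one row per gene, in the input gene order.
#' @export
promoter_windows <- function(genes, flank = 250) {
  stopifnot(is.data.frame(genes), length(flank) == 1L, flank > 0)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(genes$tss - flank, 0),
             end = genes$tss + flank + 1,
             stringsAsFactors = FALSE)
}

# Internal: half-open 0-based intervals -> GRanges (1-based closed).
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start + 1,
                                                   end = end))
}

# Internal: countOverlaps without the benign "no sequence levels in
# common" warning for fully disjoint chromosome sets.
count_overlaps0 <- function(query, subject) {
  suppressWarnings(GenomicRanges::countOverlaps(query, subject))
}
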