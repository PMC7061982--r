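# Readers/writers for the plain-text genomic formats the pipeline
# touches. Internal coordinates are 0-based half-open everywhere;
# conversion happens only at the GTF boundary. Chromosome names are
# preserved verbatim.

split_data_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       line_no = which(keep))
}

#' Read a BED file of peaks
#'
#' Accepts BED3/BED6 and narrowPeak/broadPeak-style files (columns
#' beyond the sixth are ignored). BED is 0-based half-open; coordinates
#' are kept in that convention.
#'
#' @param path path to a BED file.
#' @param name name for the resulting set (default: file base name).
#'
#' @return A [peak_set()] sorted by (`chrom`, `start`); the score
#'   column is retained when present (`.` becomes `NA`).
#' @export
read_bed <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  parsed <- split_data_lines(path)
  fields <- parsed$fields
  if (length(fields) == 0L) stop("no BED records in ", path)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1L]
    stop(sprintf("malformed BED line %d in %s: fewer than 3 columns",
                 parsed$line_no[i], path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinate",
                 parsed$line_no[i], path))
  }
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    stop(sprintf("BED line %d in %s: start >= end",
                 parsed$line_no[i], path))
  }
  peak_name <- if (max(nf) >= 4L) {
    vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  }
  score <- if (max(nf) >= 5L) {
    raw <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else ".", "")
    suppressWarnings(as.numeric(ifelse(raw == ".", NA, raw)))
  }
  strand <- if (max(nf) >= 6L) {
    vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", "")
  }
  peak_set(chrom, start, end, score = score, peak_name = peak_name,
           strand = strand, name = name)
}

#' Write a peak set as BED
#'
#' Emits the columns present in the set (chrom/start/end, then name,
#' score, strand if available). For a canonical sorted 3-column input,
#' `write_bed(read_bed(f))` is byte-identical to `f`.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  cols <- list(peaks$chrom,
               format(peaks$start, scientific = FALSE, trim = TRUE),
               format(peaks$end, scientific = FALSE, trim = TRUE))
  if (!is.null(peaks$name)) {
    cols <- c(cols, list(peaks$name))
    if (!is.null(peaks$score)) {
      cols <- c(cols, list(ifelse(is.na(peaks$score), ".",
                                  format(peaks$score, scientific = FALSE,
                                         trim = TRUE))))
      if (!is.null(peaks$strand)) cols <- c(cols, list(peaks$strand))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a bedGraph coverage file onto fixed-width bins
#'
#' bedGraph records (0-based half-open, non-overlapping within a
#' chromosome) are resampled onto bins of `bin_size` bp. A bin's value
#' is the length-weighted mean of the record values overlapping it;
#' uncovered bases contribute 0. Resampling conserves total signal
#' mass: `sum(bin value * bin_size)` equals
#' `sum(record value * record length)`.
#'
#' @param path path to a bedGraph file.
#' @param bin_size bin width in bp (positive integer).
#' @param name track name (default: file base name).
#' @param allow_negative permit negative record values.
#'
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, bin_size, name = NULL,
                          allow_negative = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(length(bin_size) == 1L, bin_size >= 1)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  if (!any(keep)) stop("no bedGraph records in ", path)
  dt <- data.table::fread(text = lines[keep], header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 4L) stop("bedGraph requires 4 columns: ", path)
  data.table::setnames(dt, 1:4, c("chrom", "start", "end", "value"))
  if (!is.numeric(dt$start) || !is.numeric(dt$end) || !is.numeric(dt$value)) {
    stop("non-numeric coordinates or values in ", path)
  }
  if (any(dt$start >= dt$end)) stop("bedGraph record with start >= end in ", path)
  if (!allow_negative && any(dt$value < 0)) {
    stop("negative bedGraph values in ", path,
         " (set allow_negative = TRUE to permit)")
  }
  data.table::setorder(dt, chrom, start)
  signal <- list()
  for (chr in unique(dt$chrom)) {
    sub <- dt[dt$chrom == chr]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("overlapping bedGraph records on ", chr, " in ", path)
    }
    signal[[chr]] <- bin_records(sub$start, sub$end, sub$value, bin_size)
  }
  coverage_track(signal, bin_size, name = name,
                 allow_negative = allow_negative)
}

# Length-weighted resampling of half-open records onto fixed bins.
# Returns per-bin mean signal level (mass / bin_size).
bin_records <- function(start, end, value, bin_size) {
  n_bins <- as.integer(ceiling(max(end) / bin_size))
  mass <- numeric(n_bins)
  sb <- floor(start / bin_size)     # first bin index (0-based)
  eb <- floor((end - 1) / bin_size) # last bin index
  one <- sb == eb
  if (any(one)) {
    m <- rowsum((value * (end - start))[one], sb[one])
    idx <- as.integer(rownames(m)) + 1L
    mass[idx] <- mass[idx] + m[, 1L]
  }
  if (any(!one)) {
    s <- start[!one]; e <- end[!one]; v <- value[!one]
    fb <- sb[!one]; lb <- eb[!one]
    # partial first and last bins
    first_len <- (fb + 1) * bin_size - s
    last_len <- e - lb * bin_size
    part_idx <- c(fb, lb) + 1L
    part_mass <- c(v * first_len, v * last_len)
    m <- rowsum(part_mass, part_idx)
    idx <- as.integer(rownames(m))
    mass[idx] <- mass[idx] + m[, 1L]
    # full interior bins
    n_full <- lb - fb - 1L
    if (any(n_full > 0L)) {
      h <- n_full > 0L
      full_idx <- sequence(n_full[h], from = fb[h] + 2L, by = 1L)
      full_mass <- rep(v[h] * bin_size, n_full[h])
      m <- rowsum(full_mass, full_idx)
      idx <- as.integer(rownames(m))
      mass[idx] <- mass[idx] + m[, 1L]
    }
  }
  mass / bin_size
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal-valued adjacent bins are merged into single records;
#' zero-valued runs are omitted (uncovered bases read back as 0).
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @param drop_zero omit zero-valued runs (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  stopifnot(inherits(track, "coverage_track"))
  bs <- track$bin_size
  parts <- lapply(names(track$signal), function(chr) {
    r <- rle(track$signal[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(r$values))
    data.table::data.table(chrom = chr, start = starts[keep] * bs,
                           end = ends[keep] * bs, value = r$values[keep])
  })
  dt <- data.table::rbindlist(parts)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation (minimal GTF or BED6/BED12)
#'
#' One record per gene. GTF 1-based closed coordinates are converted
#' to the internal 0-based half-open convention; only `feature == "gene"`
#' rows are used and only the `gene_id` attribute is parsed. BED input
#' is taken as-is (columns 1-6; block columns of BED12 are ignored).
#'
#' @param path path to the annotation file.
#' @param dialect `"GTF-minimal"` or `"BED12"`.
#'
#' @return A [gene_models()] data.frame.
#' @export
read_gene_annotation <- function(path, dialect = c("GTF-minimal", "BED12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  parsed <- split_data_lines(path)
  fields <- parsed$fields
  if (length(fields) == 0L) stop("no records in ", path)
  if (dialect == "GTF-minimal") {
    nf <- lengths(fields)
    if (any(nf < 9L)) {
      stop(sprintf("malformed GTF line %d in %s: fewer than 9 columns",
                   parsed$line_no[which(nf < 9L)[1L]], path))
    }
    feature <- vapply(fields, `[[`, "", 3L)
    keep <- feature == "gene"
    if (!any(keep)) stop("no 'gene' feature records in ", path)
    fields <- fields[keep]
    chrom <- vapply(fields, `[[`, "", 1L)
    start1 <- as.numeric(vapply(fields, `[[`, "", 4L))
    end1 <- as.numeric(vapply(fields, `[[`, "", 5L))
    strand <- vapply(fields, `[[`, "", 7L)
    attrs <- vapply(fields, `[[`, "", 9L)
    m <- regmatches(attrs, regexpr('gene_id "[^"]+"', attrs))
    if (length(m) != length(attrs) || any(!nzchar(m))) {
      stop("GTF record without a gene_id attribute in ", path)
    }
    gene_id <- sub('^gene_id "', "", sub('"$', "", m))
    gene_models(gene_id, chrom, start1 - 1, end1, strand)
  } else {
    nf <- lengths(fields)
    if (any(nf < 6L)) {
      stop(sprintf("malformed BED line %d in %s: need >= 6 columns for genes",
                   parsed$line_no[which(nf < 6L)[1L]], path))
    }
    gene_models(gene_id = vapply(fields, `[[`, "", 4L),
                chrom = vapply(fields, `[[`, "", 1L),
                start = as.numeric(vapply(fields, `[[`, "", 2L)),
                end = as.numeric(vapply(fields, `[[`, "", 3L)),
                strand = vapply(fields, `[[`, "", 6L))
  }
}

#' Write gene models as a minimal GTF
#'
#' Internal 0-based half-open coordinates are converted to GTF's
#' 1-based closed convention.
#'
#' @param genes a [gene_models()] data.frame.
#' @param path output path.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "polpause") {
  stopifnot(inherits(genes, "gene_models"))
  lines <- sprintf('%s\t%s\tgene\t%s\t%s\t.\t%s\t.\tgene_id "%s";',
                   genes$chrom, source,
                   format(genes$start + 1, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$strand, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' TSV with a header line: first column `gene_id`, one numeric column
#' per condition/replicate. Values must be non-negative numbers; any
#' non-numeric cell is an error naming its row and column.
#'
#' @param path path to the TSV file.
#'
#' @return Numeric matrix, genes in rows (rownames = gene ids),
#'   conditions in columns.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty expression table: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "gene_id" || length(header) < 2L) {
    stop("missing or malformed header in ", path,
         " (expected 'gene_id' then condition columns)")
  }
  if (length(lines) < 2L) stop("expression table has no data rows: ", path)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(rows) != length(header))) {
    i <- which(lengths(rows) != length(header))[1L]
    stop(sprintf("row %d of %s has %d fields, expected %d",
                 i, path, lengths(rows)[i], length(header)))
  }
  gene_id <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(header) - 1L,
                dimnames = list(gene_id, header[-1L]))
  for (j in seq_len(ncol(mat))) {
    raw <- vapply(rows, `[[`, "", j + 1L)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      i <- which(is.na(val))[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   raw[i], i, colnames(mat)[j], path))
    }
    mat[, j] <- val
  }
  if (any(mat < 0)) stop("negative expression values in ", path)
  mat
}

#' Write a per-gene expression table
#'
#' @param mat numeric matrix, genes in rows (rownames = gene ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  dt <- data.table::data.table(gene_id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Check chromosome-name compatibility between inputs
#'
#' Joining files whose chromosome names disagree silently yields empty
#' results; this check makes the mismatch a hard error listing the
#' symmetric difference. No fuzzy ("chr" prefix) matching is attempted.
#'
#' @param ... two or more character vectors of chromosome names, named
#'   for their source (e.g. `genes = ..., coverage = ...`).
#' @return `TRUE`, invisibly, if all sources agree.
#' @export
check_chromosomes <- function(...) {
  sets <- lapply(list(...), function(x) sort(unique(as.character(x))))
  if (length(sets) < 2L) return(invisible(TRUE))
  ref <- sets[[1L]]
  for (i in seq_along(sets)[-1L]) {
    extra <- setdiff(sets[[i]], ref)
    missing <- setdiff(ref, sets[[i]])
    if (length(extra) || length(missing)) {
      nm <- names(sets)
      a <- if (!is.null(nm) && nzchar(nm[1L])) nm[1L] else "input 1"
      b <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else paste("input", i)
      stop(sprintf(
        "chromosome names differ between %s and %s; only in %s: {%s}; only in %s: {%s}",
        a, b, b, paste(extra, collapse = ", "),
        a, paste(missing, collapse = ", ")))
    }
  }
  invisible(TRUE)
}
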