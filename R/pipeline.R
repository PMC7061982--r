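# End-to-end orchestration: simulate -> pausing index -> positional
# correlation -> annotation -> binding -> stratified comparisons,
# with a serialized effective configuration for provenance.

#' Assemble a pipeline run configuration
#'
#' Collects every tunable parameter of a full run with the
#' field-anchored defaults (promoter flank 250 nt, correlation window
#' 10 kbp, PI threshold 4). When `simulate` is `TRUE` (default) the
#' inputs are generated by [simulate_dataset()]; otherwise `inputs`
#' must name existing files.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed (overrides `sim$seed`).
#' @param simulate generate inputs with the synthetic module.
#' @param sim a [sim_config()] (used when `simulate = TRUE`).
#' @param inputs when `simulate = FALSE`, a list with `genes` (GTF),
#'   `coverage_wt`/`coverage_kd` (bedGraph), `peaks` (named character
#'   vector of BED paths; the first set is the promoter-occupancy
#'   factor), `expression` (TSV).
#' @param flank promoter half-width in bp (default 250).
#' @param window,xcorr_bin positional-correlation window and bin
#'   (defaults 10000 and 100 bp).
#' @param pi a [pi_config()].
#' @param fc_threshold,fc_pseudocount fold-change labelling
#'   parameters.
#' @param bin_size coverage bin width used when reading bedGraph.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, simulate = TRUE,
                       sim = sim_config(seed = seed), inputs = NULL,
                       flank = 250, window = 10000, xcorr_bin = 100,
                       pi = pi_config(), fc_threshold = 2,
                       fc_pseudocount = 0.01, bin_size = 10) {
  stopifnot(length(out_dir) == 1L, is.character(out_dir))
  if (simulate) {
    sim$seed <- as.integer(seed)
  } else if (is.null(inputs)) {
    stop("simulate = FALSE requires an 'inputs' list")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, sim = sim, inputs = inputs,
                 flank = flank, window = window, xcorr_bin = xcorr_bin,
                 pi = pi, fc_threshold = fc_threshold,
                 fc_pseudocount = fc_pseudocount, bin_size = bin_size),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML mapping whose keys mirror the arguments of
#' [run_config()], [sim_config()] and [pi_config()] (nested under
#' `sim:` and `pi:`); unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @param out_dir output directory (overrides the YAML `out_dir` when
#'   given).
#' @return A `run_config`.
#' @export
load_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (is.null(y$out_dir)) stop("config must provide out_dir")
  sim_args <- y$sim
  if (!is.null(y$seed) && !is.null(sim_args)) sim_args$seed <- y$seed
  pi_args <- y$pi
  if (!is.null(sim_args) &&
      !is.null(sim_args$pausing_mixture)) {
    sim_args$pausing_mixture <-
      as.data.frame(lapply(sim_args$pausing_mixture, unlist))
  }
  args <- y[setdiff(names(y), c("sim", "pi"))]
  if (!is.null(sim_args)) args$sim <- do.call(sim_config, sim_args)
  if (!is.null(pi_args)) args$pi <- do.call(pi_config, pi_args)
  if (!is.null(args$inputs) && !is.null(args$inputs$peaks)) {
    args$inputs$peaks <- unlist(args$inputs$peaks)
  }
  do.call(run_config, args)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

comparison_to_list <- function(cr) {
  if (is.null(cr)) return(NULL)
  list(label = cr$label, n_group1 = cr$n_group1, n_group2 = cr$n_group2,
       statistic = cr$statistic, p_value = cr$p_value,
       median_group1 = unname(cr$medians[1]),
       median_group2 = unname(cr$medians[2]),
       effect_direction = cr$effect_direction)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> read inputs -> chromosome check ->
#' per-condition pausing-index tables -> positional correlation of the
#' factor against each mark -> feature annotation -> promoter-binding
#' calls -> stratified comparisons, writing all artifacts into the
#' output directory:
#'
#' * `sim/` — generated inputs (when simulating),
#' * `pi_WT.tsv`, `pi_KD.tsv` — per-gene pausing records,
#' * `xcorr_<mark>.tsv` — correlation profiles (offset, count, value),
#' * `annotation.tsv` — per-category peak counts and fractions,
#' * `binding.tsv` — per-gene promoter-binding calls,
#' * `report.tsv` — per-gene table (`gene_id`, `pi_WT`, `pi_KD`,
#'   `abs_log2_fc`, `bound`, `de_status`),
#' * `comparisons.json` — every comparison result,
#' * `config.yaml` — the effective configuration,
#' * `run_log.txt` — versions and stage log (the only artifact with a
#'   timestamp; all TSV/JSON outputs are byte-reproducible under a
#'   fixed seed).
#'
#' Any stage error aborts the run with the stage name.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the main in-memory results
#'   (`pi_wt`, `pi_kd`, `profiles`, `annotation`, `binding`,
#'   `dataset`, `comparisons`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("polpause %s | R %s.%s",
                         as.character(utils::packageVersion("polpause")),
                         R.version$major, R.version$minor),
                 sprintf("started: %s", format(Sys.time(), usetz = TRUE)))
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  if (config$simulate) {
    with_stage("simulate", {
      sim_dir <- file.path(out, "sim")
      simulate_dataset(config$sim, sim_dir)
      config$inputs <- list(
        genes = file.path(sim_dir, "genes.gtf"),
        coverage_wt = file.path(sim_dir, "coverage_WT.bedgraph"),
        coverage_kd = file.path(sim_dir, "coverage_KD.bedgraph"),
        peaks = stats::setNames(
          file.path(sim_dir,
                    paste0("peaks_", c("KAP1", names(config$sim$marks)),
                           ".bed")),
          c("KAP1", names(config$sim$marks))),
        expression = file.path(sim_dir, "expression.tsv"))
      note("simulate: wrote %s", sim_dir)
    })
  }

  inp <- config$inputs
  genes <- with_stage("read_genes", {
    if (is.null(inp$genes) || !file.exists(inp$genes)) {
      stop("gene annotation file not found: ", inp$genes)
    }
    read_gene_annotation(inp$genes, "GTF-minimal")
  })
  track_wt <- with_stage("read_coverage", {
    if (is.null(inp$coverage_wt) || !file.exists(inp$coverage_wt)) {
      stop("WT coverage file not found: ", inp$coverage_wt)
    }
    read_bedgraph(inp$coverage_wt, config$bin_size, name = "PolII_WT")
  })
  track_kd <- with_stage("read_coverage", {
    if (is.null(inp$coverage_kd) || !file.exists(inp$coverage_kd)) {
      stop("KD coverage file not found: ", inp$coverage_kd)
    }
    read_bedgraph(inp$coverage_kd, config$bin_size, name = "PolII_KD")
  })
  peaks <- with_stage("read_peaks", {
    lapply(stats::setNames(nm = names(inp$peaks)), function(nm) {
      read_bed(inp$peaks[[nm]], name = nm)
    })
  })
  expression <- with_stage("read_expression", {
    read_expression_table(inp$expression)
  })
  factor_name <- names(peaks)[1L]
  with_stage("chromosome_check", {
    do.call(check_chromosomes,
            c(list(genes = genes$chrom,
                   coverage = names(track_wt$signal)),
              stats::setNames(list(peaks[[factor_name]]$chrom),
                              factor_name)))
  })
  note("inputs: %d genes, %d peak sets, %d expression conditions",
       nrow(genes), length(peaks), ncol(expression))

  pi_wt <- with_stage("pi", {
    pi_table(track_wt, genes, config$pi, expression, "WT")
  })
  pi_kd <- with_stage("pi", {
    pi_table(track_kd, genes, config$pi, expression, "KD")
  })
  paths <- list(pi_wt = file.path(out, "pi_WT.tsv"),
                pi_kd = file.path(out, "pi_KD.tsv"))
  data.table::fwrite(pi_wt, paths$pi_wt, sep = "\t")
  data.table::fwrite(pi_kd, paths$pi_kd, sep = "\t")
  note("pi: %d/%d eligible genes (WT)", sum(pi_wt$eligible), nrow(pi_wt))

  profiles <- with_stage("xcorr", {
    targets <- setdiff(names(peaks), factor_name)
    lapply(stats::setNames(nm = targets), function(nm) {
      positional_correlation(peaks[[factor_name]], peaks[[nm]],
                             window = config$window,
                             bin = config$xcorr_bin)
    })
  })
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    data.table::fwrite(
      data.table::data.table(offset = p$offsets, count = p$counts,
                             value = p$values),
      file.path(out, paste0("xcorr_", nm, ".tsv")), sep = "\t")
  }
  note("xcorr: %s vs %s", factor_name,
       paste(names(profiles), collapse = ", "))

  annotation <- with_stage("annotate", {
    annotate_peaks(peaks[[factor_name]], genes, flank = config$flank)
  })
  data.table::fwrite(annotation$table, file.path(out, "annotation.tsv"),
                     sep = "\t")
  binding <- with_stage("binding", {
    promoter_binding(genes, peaks[[factor_name]], flank = config$flank)
  })
  data.table::fwrite(
    data.table::data.table(gene_id = names(binding), bound = binding),
    file.path(out, "binding.tsv"), sep = "\t")
  note("annotate: %.1f%% of %s peaks at promoters; binding: %d/%d genes bound",
       100 * annotation$table$fraction[annotation$table$category == "promoter"],
       factor_name, sum(binding), length(binding))

  results <- with_stage("compare", {
    ds <- build_stratified_dataset(
      pi_wt, pi_kd, binding, expression,
      fc_threshold = config$fc_threshold,
      pseudocount = config$fc_pseudocount,
      pi_threshold = config$pi$pi_threshold)
    comparisons <- list(
      expr_bound_vs_unbound_WT = compare_strata(
        ds, "expression", function(d) d$bound, function(d) !d$bound,
        label = "expression (WT): bound vs unbound promoters"),
      pi_bound_vs_unbound_WT = compare_strata(
        ds, "pi", function(d) d$bound, function(d) !d$bound,
        label = "PI (WT): bound vs unbound promoters"),
      expr_WT_vs_KD = compare_strata(
        ds, "expression", function(d) rep(TRUE, nrow(d)),
        function(d) rep(TRUE, nrow(d)), condition_a = "WT",
        condition_b = "KD", label = "expression: WT vs KD, all genes"),
      pi_WT_vs_KD = compare_strata(
        ds, "pi", function(d) rep(TRUE, nrow(d)),
        function(d) rep(TRUE, nrow(d)), condition_a = "WT",
        condition_b = "KD", label = "PI: WT vs KD, all genes"))
    for (st in c("up", "down")) {
      if (sum(ds$de_status == st) >= 2L) {
        comparisons[[paste0("expr_WT_vs_KD_", st)]] <- compare_strata(
          ds, "expression",
          function(d) d$de_status == st, function(d) d$de_status == st,
          condition_a = "WT", condition_b = "KD",
          label = paste("expression: WT vs KD,", st, "genes"))
      }
    }
    hp <- high_pi_comparison(ds, threshold = config$pi$pi_threshold)
    list(dataset = ds, comparisons = comparisons, high_pi = hp)
  })
  ds <- results$dataset
  report <- ds[, c("gene_id", "pi_WT", "pi_KD", "abs_log2_fc", "bound",
                   "de_status")]
  data.table::fwrite(report, file.path(out, "report.tsv"), sep = "\t")
  hp <- results$high_pi
  summary_json <- list(
    n_genes = nrow(genes),
    n_eligible = nrow(ds),
    n_bound = sum(ds$bound),
    n_up = sum(ds$de_status == "up"),
    n_down = sum(ds$de_status == "down"),
    promoter_peak_fraction =
      annotation$table$fraction[annotation$table$category == "promoter"],
    comparisons = lapply(results$comparisons, comparison_to_list),
    high_pi = list(threshold = hp$threshold, n = hp$n,
                   overall = comparison_to_list(hp$overall),
                   subsets = hp$subsets,
                   shift_by_binding =
                     comparison_to_list(hp$shift_by_binding)))
  jsonlite::write_json(summary_json, file.path(out, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  note("compare: %d comparisons; %d high-PI genes",
       length(results$comparisons), hp$n)

  cfg_out <- list(seed = config$seed, simulate = config$simulate,
                  flank = config$flank, window = config$window,
                  xcorr_bin = config$xcorr_bin,
                  bin_size = config$bin_size,
                  fc_threshold = config$fc_threshold,
                  fc_pseudocount = config$fc_pseudocount,
                  pi = unclass(config$pi),
                  # input paths relative to the run directory where
                  # possible, so identically seeded runs serialize
                  # identical configurations
                  inputs = lapply(config$inputs, function(p) {
                    sub(paste0("^", normalizePath(out, mustWork = FALSE),
                               "/"), "",
                        normalizePath(as.character(p), mustWork = FALSE))
                  }))
  yaml::write_yaml(cfg_out, file.path(out, "config.yaml"))
  note("finished: %s", format(Sys.time(), usetz = TRUE))
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(list(pi_wt = pi_wt, pi_kd = pi_kd, profiles = profiles,
                 annotation = annotation, binding = binding,
                 dataset = ds, comparisons = results$comparisons,
                 high_pi = hp, out_dir = out))
}
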