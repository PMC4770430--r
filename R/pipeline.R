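#' Assemble a pipeline run configuration
#'
#' @param annotation Path to the gene annotation (refFlat, BED12 or GTF).
#' @param chrom_sizes Path to a chrom.sizes TSV (optional).
#' @param sample_sheet Path to the sample sheet TSV.
#' @param coverage Directory of per-sample bedGraphs (named
#'   `<sample_id>.bedGraph`, optionally gzipped) or a single bin-matrix TSV.
#' @param de_tables Named character vector of DE table paths, one per tumor
#'   group (optional; the expression stage is skipped when absent).
#' @param comparisons Comparison tibble from [comparison_plan()]; `NULL`
#'   selects every available tumor/control combination.
#' @param params A [dmr_params()] object.
#' @param deg_p,deg_min_abs_log2fc,deg_max_low_samples Expression thresholds.
#' @param bin_size Bin width in bp.
#' @param annotation_format Passed to [load_gene_models()].
#' @param seed Recorded in the log (the analysis itself is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(annotation, sample_sheet, coverage,
                       chrom_sizes = NULL, de_tables = NULL,
                       comparisons = NULL, params = dmr_params(),
                       deg_p = 0.05, deg_min_abs_log2fc = 0.5,
                       deg_max_low_samples = 150, bin_size = 100,
                       annotation_format = "auto", seed = 1L) {
  structure(
    list(annotation = annotation, chrom_sizes = chrom_sizes,
         sample_sheet = sample_sheet, coverage = coverage,
         de_tables = de_tables, comparisons = comparisons, params = params,
         deg_p = deg_p, deg_min_abs_log2fc = deg_min_abs_log2fc,
         deg_max_low_samples = deg_max_low_samples,
         bin_size = as.integer(bin_size),
         annotation_format = annotation_format, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `params` may be a mapping of
#' [dmr_params()] overrides, `comparisons` a mapping with `tumor` and
#' `control` lists, and relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path Path to the YAML config.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(grepl("^/", p), p, file.path(base, p))
    if (!is.null(names(p))) names(out) <- names(p)
    out
  }
  params <- do.call(dmr_params, y$params %||% list())
  comparisons <- if (!is.null(y$comparisons)) {
    comparison_plan(unlist(y$comparisons$tumor),
                    unlist(y$comparisons$control))
  }
  run_config(
    annotation = resolve(y$annotation),
    chrom_sizes = resolve(y$chrom_sizes),
    sample_sheet = resolve(y$sample_sheet),
    coverage = resolve(y$coverage),
    de_tables = resolve(unlist(y$de_tables)),
    comparisons = comparisons,
    params = params,
    deg_p = y$deg_p %||% 0.05,
    deg_min_abs_log2fc = y$deg_min_abs_log2fc %||% 0.5,
    deg_max_low_samples = y$deg_max_low_samples %||% 150,
    bin_size = y$bin_size %||% 100,
    annotation_format = y$annotation_format %||% "auto",
    seed = y$seed %||% 1L
  )
}

.load_coverage <- function(config, sheet) {
  if (dir.exists(config$coverage)) {
    files <- list.files(config$coverage,
                        pattern = "\\.(bedgraph|bedGraph|bg)(\\.gz)?$",
                        full.names = TRUE)
    if (length(files) == 0) {
      stop("no bedGraph files in coverage directory: ", config$coverage)
    }
    counts <- dplyr::bind_rows(lapply(files, read_bin_counts,
                                      bin_size = config$bin_size))
  } else {
    counts <- read_bin_counts(config$coverage, bin_size = config$bin_size)
  }
  build_bin_matrix(counts, sheet, config$bin_size)
}

#' Run the full analysis pipeline
#'
#' Executes annotation -> coverage -> DMR calling (all planned comparisons)
#' -> CDMP classification -> expression integration, writing every stage's
#' table, a JSON summary and a log into `out_dir`. Reruns on identical
#' inputs produce identical outputs.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @param out_dir Output directory.
#' @return The output directory path, invisibly. Key files:
#'   `regions.tsv`, `dmrs.tsv`, `dmrs.bed`, `status.tsv`,
#'   `cdmp_assignments.tsv`, `pattern_counts.tsv`, `overlap_tests.tsv`,
#'   `mean_matrix.tsv`, `dmr_profile.tsv`, `expression_crosstab.tsv` (when
#'   DE tables are given), `summary.json`, `log.txt`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$annotation, config$sample_sheet, config$coverage,
              config$chrom_sizes, unname(config$de_tables))) {
    if (!file.exists(p) && !dir.exists(p)) {
      stop("input path does not exist: ", p)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("dmrpatterns %s | R %s",
            as.character(utils::packageVersion("dmrpatterns")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("params: %s", paste(names(config$params),
                                unlist(config$params), sep = "=",
                                collapse = " "))
  )
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort_stage(stage, conditionMessage(e))
    })
  }

  # annotation
  genes <- run_stage("annotation", {
    models <- load_gene_models(config$annotation, config$annotation_format)
    models <- select_unique_transcripts(models)
    sizes <- if (!is.null(config$chrom_sizes)) {
      read_chrom_sizes(config$chrom_sizes)
    }
    regions <- partition_gene_regions(models, sizes)
    write_region_table(regions, file.path(out_dir, "regions.tsv"))
    note("annotation", sprintf("%d genes after transcript selection",
                               nrow(models)))
    list(models = models, regions = regions)
  })

  # coverage
  bm <- run_stage("coverage", {
    sheet <- read_sample_sheet(config$sample_sheet)
    bm <- .load_coverage(config, sheet)
    note("coverage", sprintf("%d bins x %d samples", nrow(bm$bins),
                             ncol(bm$raw)))
    bm
  })

  # dmr
  dmr_out <- run_stage("dmr", {
    region_bins <- assign_bins_to_regions(genes$regions, config$bin_size)
    dmrs <- call_dmrs(bm, region_bins, config$comparisons, config$params)
    readr::write_tsv(tidy(dmrs), file.path(out_dir, "dmrs.tsv"))
    write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
    if (nrow(dmrs) > 0) {
      prof <- dmr_mean_profile(dmrs, bm)
      readr::write_tsv(prof, file.path(out_dir, "dmr_profile.tsv"))
    }
    mm <- group_region_mean_matrix(bm, genes$regions)
    readr::write_tsv(mm, file.path(out_dir, "mean_matrix.tsv"))
    note("dmr", sprintf("%d DMRs in %d genes", nrow(dmrs),
                        dplyr::n_distinct(dmrs$gene_id)))
    list(dmrs = dmrs, region_bins = region_bins)
  })

  # cdmp
  cdmp_out <- run_stage("cdmp", {
    dmrs <- dmr_out$dmrs
    statuses <- gene_region_status(dmrs, genes$models$gene_id)
    union_controls <- intersect(c("N", "ADJ"), unique(statuses$control))
    statuses_all <- if (length(union_controls) == 2) {
      dplyr::bind_rows(statuses, union_across_controls(statuses))
    } else {
      statuses
    }
    readr::write_tsv(statuses_all, file.path(out_dir, "status.tsv"))
    assignments <- classify_cdmp(statuses_all)
    readr::write_tsv(assignments, file.path(out_dir, "cdmp_assignments.tsv"))
    counts <- summarize_pattern_counts(assignments)
    readr::write_tsv(counts, file.path(out_dir, "pattern_counts.tsv"))

    # overlap tests on the union gene sets; universe = genes with bins in
    # TSS and at least one partner region
    testable <- dmr_out$region_bins |>
      dplyr::distinct(.data$gene_id, .data$region)
    universe <- intersect(
      testable$gene_id[testable$region == "TSS"],
      testable$gene_id[testable$region != "TSS"]
    )
    union_label <- if (length(union_controls) == 2) "N|ADJ" else NULL
    sets <- cdmp_gene_sets(assignments, control = union_label)
    overlaps <- cdmp_overlap_tests(sets, universe)
    readr::write_tsv(tidy(overlaps), file.path(out_dir, "overlap_tests.tsv"))
    note("cdmp", sprintf("%d labeled gene-comparison pairs",
                         nrow(assignments)))
    list(assignments = assignments, counts = counts, overlaps = overlaps,
         universe = universe)
  })

  # expression
  expr_out <- NULL
  if (!is.null(config$de_tables)) {
    expr_out <- run_stage("expression", {
      tabs <- purrr::imap(config$de_tables, function(p, g) {
        load_de_table(p, tumor_group = if (nzchar(g)) g else NULL)
      })
      records <- dplyr::bind_rows(tabs)
      kept <- filter_low_expression(records, config$deg_max_low_samples)
      degs <- flag_degs(kept, config$deg_p, config$deg_min_abs_log2fc)
      crosstab <- cross_tabulate(degs, cdmp_out$assignments,
                                 meth_genes = genes$models$gene_id,
                                 expr_genes = unique(kept$gene_id))
      readr::write_tsv(crosstab,
                       file.path(out_dir, "expression_crosstab.tsv"))
      uniq <- risk_unique_degs(degs)
      readr::write_tsv(uniq, file.path(out_dir, "risk_unique_degs.tsv"))
      note("expression", sprintf("%d DEGs across %d groups", nrow(degs),
                                 dplyr::n_distinct(degs$tumor_group)))
      list(degs = degs, crosstab = crosstab)
    })
  } else {
    note("expression", "skipped (no DE tables configured)")
  }

  summary <- list(
    n_genes = nrow(genes$models),
    n_bins = nrow(bm$bins),
    n_samples = ncol(bm$raw),
    n_dmrs = nrow(dmr_out$dmrs),
    pattern_counts = cdmp_out$counts,
    universe_size = length(cdmp_out$universe),
    n_degs = if (is.null(expr_out)) NULL else nrow(expr_out$degs)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Generate a markdown report from a completed run
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param path Output markdown path (default `report.md` inside `run_dir`).
#' @return `path`, invisibly.
#' @export
generate_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  need <- c("pattern_counts.tsv", "dmrs.tsv", "overlap_tests.tsv",
            "summary.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0) {
    stop("incomplete run; missing stage outputs: ",
         paste(missing, collapse = ", "))
  }
  smry <- jsonlite::read_json(file.path(run_dir, "summary.json"))
  dmrs <- readr::read_tsv(file.path(run_dir, "dmrs.tsv"),
                          show_col_types = FALSE)
  counts <- readr::read_tsv(file.path(run_dir, "pattern_counts.tsv"),
                            show_col_types = FALSE)
  overlaps <- readr::read_tsv(file.path(run_dir, "overlap_tests.tsv"),
                              show_col_types = FALSE)

  md_table <- function(df) {
    if (nrow(df) == 0) return("(empty)")
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
    paste(c(hdr, sep, rows), collapse = "\n")
  }

  pattern_tbl <- counts |>
    dplyr::filter(.data$tumor != "ANY") |>
    tidyr::pivot_wider(names_from = c("tumor", "control"),
                       values_from = "n_genes")

  lines <- c(
    "# Differential methylation pattern report", "",
    sprintf("- genes analyzed: %s", smry$n_genes),
    sprintf("- bins x samples: %s x %s", smry$n_bins, smry$n_samples),
    sprintf("- DMRs called: %s", smry$n_dmrs),
    if (identical(smry$n_dmrs, 0L) || smry$n_dmrs == 0) {
      "- note: zero DMRs were called under the configured thresholds"
    },
    "",
    "## Genes per collaborative methylation pattern", "",
    md_table(pattern_tbl), "",
    "## Pattern gene-set overlaps (hypergeometric upper tail)", "",
    md_table(dplyr::mutate(
      overlaps,
      p_value = signif(.data$p_value, 3),
      log10_p = round(.data$log10_p, 2)
    )), ""
  )
  crosstab_path <- file.path(run_dir, "expression_crosstab.tsv")
  if (file.exists(crosstab_path)) {
    crosstab <- readr::read_tsv(crosstab_path, show_col_types = FALSE)
    lines <- c(lines,
               "## Differential expression by pattern", "",
               md_table(crosstab), "")
  } else {
    lines <- c(lines,
               "## Differential expression by pattern", "",
               "No expression tables were configured for this run.", "")
  }
  if (file.exists(file.path(run_dir, "dmr_profile.tsv"))) {
    lines <- c(lines,
               "Per-group DMR-centered mean profiles: `dmr_profile.tsv`.")
  }
  writeLines(lines, path)
  invisible(path)
}
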