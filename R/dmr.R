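#' DMR calling parameters
#'
#' Bundles the thresholds of the consecutive-bin DMR caller. A bin qualifies
#' when its rank-sum p-value is below `p_threshold` and the absolute log2
#' fold change of its group means (with pseudocount `fc_pseudocount`) is at
#' least `min_log2fc`; a maximal run of same-direction qualifying bins is a
#' DMR when it spans at least `min_run_default` bins (`min_run_genic` for the
#' gene-body region) and the run-averaged rpm of the higher-methylated group
#' is at least `min_mean_rpm_high`.
#'
#' @param bin_size Bin width in bp.
#' @param p_threshold Per-bin rank-sum p-value threshold.
#' @param min_mean_rpm_high Minimum run-averaged rpm in the higher group.
#' @param min_log2fc Minimum per-bin |log2 fold change| of group means.
#' @param min_run_default Minimum run length (bins) for Distal, TSS, TES.
#' @param min_run_genic Minimum run length (bins) for the Genic region.
#' @param fc_pseudocount Pseudocount (rpm) added to both group means in the
#'   fold change.
#' @param exact_max Largest per-group size at which the exact rank-sum
#'   distribution is used (ties force the normal approximation).
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(bin_size = 100, p_threshold = 0.05,
                       min_mean_rpm_high = 0.2, min_log2fc = 1,
                       min_run_default = 3L, min_run_genic = 5L,
                       fc_pseudocount = 0.1, exact_max = 10L) {
  stopifnot(
    bin_size > 0, p_threshold > 0, min_mean_rpm_high > 0, min_log2fc > 0,
    min_run_default > 0, min_run_genic >= min_run_default, fc_pseudocount > 0
  )
  structure(
    list(bin_size = as.integer(bin_size), p_threshold = p_threshold,
         min_mean_rpm_high = min_mean_rpm_high, min_log2fc = min_log2fc,
         min_run_default = as.integer(min_run_default),
         min_run_genic = as.integer(min_run_genic),
         fc_pseudocount = fc_pseudocount, exact_max = as.integer(exact_max)),
    class = "dmr_params"
  )
}

min_run_for <- function(region, params) {
  ifelse(region == "GENIC", params$min_run_genic, params$min_run_default)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact two-sided p-value when both groups have at most `exact_max`
#' observations and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction. Two identical constant samples
#' give p = 1.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param exact_max Exact-distribution cutoff per group (default 10).
#' @return The two-sided p-value.
#' @export
rank_sum_test <- function(a, b, exact_max = 10L) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 observations")
  }
  rank_sum_rows_cpp(matrix(c(a, b), nrow = 1), length(a),
                    as.integer(exact_max))[1]
}

# Per-row rank-sum p-values for matrices a (n_bins x n_a), b (n_bins x n_b).
.rank_sum_matrix <- function(a, b, exact_max = 10L) {
  rank_sum_rows_cpp(cbind(a, b), ncol(a), as.integer(exact_max))
}

#' Per-bin differential methylation tests for one region
#'
#' Runs the rank-sum test on every bin (row) of two rpm matrices and derives
#' the per-bin group means, log2 fold change (tumor over control, with
#' pseudocount) and direction relative to the tumor group.
#'
#' @param values_a Numeric matrix of rpm values, bins x tumor samples.
#' @param values_b Numeric matrix of rpm values, bins x control samples
#'   (same row order as `values_a`).
#' @param params A [dmr_params()] object.
#' @param bins Optional integer vector of bin indices (row labels).
#' @return A tibble with columns `bin`, `p_value`, `mean_a`, `mean_b`,
#'   `log2fc`, `direction` ("hyper", "hypo" or "none").
#' @export
test_region_bins <- function(values_a, values_b, params = dmr_params(),
                             bins = NULL) {
  values_a <- rbind(values_a)
  values_b <- rbind(values_b)
  if (ncol(values_a) < 2 || ncol(values_b) < 2) {
    stop("both groups need at least 2 samples")
  }
  stopifnot(nrow(values_a) == nrow(values_b))
  p <- .rank_sum_matrix(values_a, values_b, params$exact_max)
  mean_a <- rowMeans(values_a)
  mean_b <- rowMeans(values_b)
  cc <- params$fc_pseudocount
  tibble::tibble(
    bin = bins %||% seq_len(nrow(values_a)),
    p_value = p,
    mean_a = mean_a,
    mean_b = mean_b,
    log2fc = log2((mean_a + cc) / (mean_b + cc)),
    direction = dplyr::case_when(
      mean_a > mean_b ~ "hyper",
      mean_a < mean_b ~ "hypo",
      TRUE ~ "none"
    )
  )
}

#' Call DMRs as maximal runs of qualifying consecutive bins
#'
#' A bin qualifies iff `p_value < p_threshold`, `|log2fc| >= min_log2fc` and
#' its direction is not "none". Maximal runs of qualifying bins with uniform
#' direction (never split or merged across a non-qualifying bin) are emitted
#' as DMRs when they span at least the region's minimum number of bins and
#' the run-averaged rpm of the higher-methylated group reaches
#' `min_mean_rpm_high`.
#'
#' @param results Tibble from [test_region_bins()], ordered along the region
#'   with contiguous `bin` indices (a gap in `bin` also breaks a run).
#' @param region Region class ("DISTAL", "TSS", "GENIC" or "TES"); Genic
#'   requires `min_run_genic` consecutive bins, the others
#'   `min_run_default`.
#' @param params A [dmr_params()] object.
#' @return A tibble with one row per DMR: `start_bin`, `end_bin`
#'   (inclusive), `n_bins`, `direction`, `min_p`, `max_p`, `mean_rpm_high`,
#'   `run_log2fc`.
#' @export
scan_runs <- function(results, region, params = dmr_params()) {
  empty <- tibble::tibble(
    start_bin = integer(), end_bin = integer(), n_bins = integer(),
    direction = character(), min_p = numeric(), max_p = numeric(),
    mean_rpm_high = numeric(), run_log2fc = numeric()
  )
  if (nrow(results) == 0) return(empty)
  res <- dplyr::arrange(results, .data$bin)
  qual <- res$p_value < params$p_threshold &
    abs(res$log2fc) >= params$min_log2fc &
    res$direction != "none"
  if (!any(qual)) return(empty)

  # a run starts at a qualifying bin not continuing the previous one
  n <- nrow(res)
  prev_qual <- c(FALSE, qual[-n])
  prev_dir <- c(NA_character_, res$direction[-n])
  prev_bin <- c(NA_integer_, res$bin[-n])
  new_run <- qual & !(prev_qual &
    prev_dir == res$direction &
    res$bin == prev_bin + 1L)
  run_id <- cumsum(new_run)
  run_id[!qual] <- NA_integer_

  cc <- params$fc_pseudocount
  runs <- res[qual, , drop = FALSE] |>
    dplyr::mutate(.run = run_id[qual]) |>
    dplyr::group_by(.data$.run) |>
    dplyr::summarise(
      start_bin = min(.data$bin),
      end_bin = max(.data$bin),
      n_bins = dplyr::n(),
      direction = dplyr::first(.data$direction),
      min_p = min(.data$p_value),
      max_p = max(.data$p_value),
      run_mean_a = mean(.data$mean_a),
      run_mean_b = mean(.data$mean_b),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_rpm_high = ifelse(.data$direction == "hyper",
                             .data$run_mean_a, .data$run_mean_b),
      run_log2fc = log2((.data$run_mean_a + cc) / (.data$run_mean_b + cc))
    )

  min_run <- min_run_for(region, params)
  runs |>
    dplyr::filter(.data$n_bins >= min_run,
                  .data$mean_rpm_high >= params$min_mean_rpm_high) |>
    dplyr::select("start_bin", "end_bin", "n_bins", "direction",
                  "min_p", "max_p", "mean_rpm_high", "run_log2fc")
}

# Core caller on explicit sample id sets. region_bins as from
# assign_bins_to_regions(); returns the dmr_set tibble (without class).
.call_dmrs_samples <- function(bm, region_bins, samples_a, samples_b,
                               params, label_a, label_b) {
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop(sprintf("comparison %s vs %s needs at least 2 samples per group",
                 label_a, label_b))
  }
  empty <- tibble::tibble(
    gene_id = character(), region = factor(character(), REGION_LEVELS),
    chrom = character(), strand = character(), start = integer(),
    end = integer(), n_bins = integer(), direction = character(),
    min_p = numeric(), max_p = numeric(), mean_rpm_high = numeric(),
    run_log2fc = numeric(), tumor = character(), control = character()
  )
  if (nrow(region_bins) == 0) return(empty)

  rb <- dplyr::arrange(region_bins, .data$gene_id, .data$region, .data$bin)
  rows <- .bin_rows(bm, rb$chrom, rb$bin)

  # test each distinct matrix row once; absent bins are all-zero -> p 1
  urows <- unique(rows[!is.na(rows)])
  stats_for <- test_region_bins(
    bm$rpm[urows, samples_a, drop = FALSE],
    bm$rpm[urows, samples_b, drop = FALSE],
    params
  )
  at <- match(rows, urows)
  p <- ifelse(is.na(at), 1, stats_for$p_value[at])
  mean_a <- ifelse(is.na(at), 0, stats_for$mean_a[at])
  mean_b <- ifelse(is.na(at), 0, stats_for$mean_b[at])
  lfc <- ifelse(is.na(at), 0, stats_for$log2fc[at])
  dir_num <- sign(mean_a - mean_b)

  qual <- p < params$p_threshold & abs(lfc) >= params$min_log2fc & dir_num != 0
  if (!any(qual)) return(empty)

  n <- nrow(rb)
  grp_key <- paste(rb$gene_id, rb$region)
  prev_qual <- c(FALSE, qual[-n])
  prev_dir <- c(0, dir_num[-n])
  prev_bin <- c(NA_integer_, rb$bin[-n])
  prev_key <- c("", grp_key[-n])
  new_run <- qual & !(prev_qual & prev_dir == dir_num &
                        grp_key == prev_key & rb$bin == prev_bin + 1L)
  run_id <- cumsum(new_run)

  cc <- params$fc_pseudocount
  keep <- which(qual)
  runs <- tibble::tibble(
    run = run_id[keep],
    gene_id = rb$gene_id[keep], region = rb$region[keep],
    chrom = rb$chrom[keep], strand = rb$strand[keep], bin = rb$bin[keep],
    p = p[keep], mean_a = mean_a[keep], mean_b = mean_b[keep],
    dir = dir_num[keep]
  ) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      gene_id = dplyr::first(.data$gene_id),
      region = dplyr::first(.data$region),
      chrom = dplyr::first(.data$chrom),
      strand = dplyr::first(.data$strand),
      start = min(.data$bin) * params$bin_size,
      end = (max(.data$bin) + 1L) * params$bin_size,
      n_bins = dplyr::n(),
      direction = ifelse(dplyr::first(.data$dir) > 0, "hyper", "hypo"),
      min_p = min(.data$p),
      max_p = max(.data$p),
      run_mean_a = mean(.data$mean_a),
      run_mean_b = mean(.data$mean_b),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_rpm_high = ifelse(.data$direction == "hyper",
                             .data$run_mean_a, .data$run_mean_b),
      run_log2fc = log2((.data$run_mean_a + cc) / (.data$run_mean_b + cc)),
      tumor = label_a, control = label_b
    )

  runs |>
    dplyr::filter(.data$n_bins >= min_run_for(.data$region, params),
                  .data$mean_rpm_high >= params$min_mean_rpm_high) |>
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end),
                  n_bins = as.integer(.data$n_bins)) |>
    dplyr::select(dplyr::all_of(names(empty))) |>
    dplyr::arrange(.data$gene_id, .data$region, .data$start)
}

#' Comparison plan between tumor and control groups
#'
#' @param tumor Tumor-side labels; any of "ALL" (pooled L+H+VH), "L", "H",
#'   "VH".
#' @param control Control-side labels; any of "N", "ADJ", "N+ADJ" (pooled).
#' @return A tibble with columns `tumor` and `control`, one row per
#'   comparison.
#' @export
comparison_plan <- function(tumor = c("ALL", "L", "H", "VH"),
                            control = c("N", "ADJ", "N+ADJ")) {
  tidyr::expand_grid(tumor = tumor, control = control)
}

#' Call DMRs for all genes and comparisons
#'
#' For every planned tumor-vs-control comparison, tests every 100-bp bin of
#' every gene region with the rank-sum test and calls maximal qualifying
#' consecutive-bin runs as DMRs.
#'
#' @param bm A `bin_matrix` from [build_bin_matrix()].
#' @param regions Region tibble from [partition_gene_regions()], or a
#'   precomputed bin assignment from [assign_bins_to_regions()].
#' @param comparisons Tibble with columns `tumor`, `control` (see
#'   [comparison_plan()]); defaults to all available groups.
#' @param params A [dmr_params()] object.
#' @return A `dmr_set` tibble with one row per DMR: `gene_id`, `region`,
#'   `chrom`, `strand`, `start`, `end` (half-open bp), `n_bins`,
#'   `direction`, `min_p`, `max_p`, `mean_rpm_high`, `run_log2fc`, `tumor`,
#'   `control`.
#' @export
call_dmrs <- function(bm, regions, comparisons = NULL, params = dmr_params()) {
  region_bins <- if ("bin" %in% names(regions)) {
    regions
  } else {
    assign_bins_to_regions(regions, params$bin_size)
  }
  if (is.null(comparisons)) {
    present <- levels(droplevels(bm$sample_sheet$group))
    tumor <- intersect(c("L", "H", "VH"), present)
    if (length(tumor) > 1) tumor <- c("ALL", tumor)
    control <- intersect(c("N", "ADJ"), present)
    if (length(control) == 2) control <- c(control, "N+ADJ")
    comparisons <- tidyr::expand_grid(tumor = tumor, control = control)
  }
  if (nrow(comparisons) == 0) stop("empty comparison plan")

  out <- purrr::pmap(comparisons, function(tumor, control) {
    .call_dmrs_samples(
      bm, region_bins,
      resolve_group_samples(bm$sample_sheet, tumor),
      resolve_group_samples(bm$sample_sheet, control),
      params, tumor, control
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "params") <- params
  attr(res, "comparisons") <- comparisons
  class(res) <- c("dmr_set", class(res))
  res
}

#' Call DMRs for a single gene and one pair of sample sets
#'
#' @param bm A `bin_matrix`.
#' @param gene_regions Region tibble rows for one gene (from
#'   [partition_gene_regions()]).
#' @param samples_a,samples_b Character vectors of sample ids for the tumor
#'   and control side.
#' @param params A [dmr_params()] object.
#' @return A tibble of DMRs as in [call_dmrs()] (with `tumor` = "A",
#'   `control` = "B").
#' @export
call_gene_dmrs <- function(bm, gene_regions, samples_a, samples_b,
                           params = dmr_params()) {
  region_bins <- assign_bins_to_regions(gene_regions, params$bin_size)
  .call_dmrs_samples(bm, region_bins, samples_a, samples_b, params, "A", "B")
}

#' Summarize DMRs to a per-gene, per-region methylation status
#'
#' @param dmrs A `dmr_set` tibble from [call_dmrs()].
#' @param gene_ids Optional character vector of all analyzed genes; genes
#'   (and regions) without DMRs are completed with status "none".
#' @param comparisons Optional tibble (`tumor`, `control`) used when
#'   completing; defaults to the comparisons present in `dmrs` (or the ones
#'   recorded by [call_dmrs()]).
#' @return A tibble with columns `gene_id`, `region`, `tumor`, `control`,
#'   `status` ("hyper", "hypo", "both" or "none").
#' @export
gene_region_status <- function(dmrs, gene_ids = NULL, comparisons = NULL) {
  status <- dmrs |>
    dplyr::group_by(.data$gene_id, .data$region, .data$tumor, .data$control) |>
    dplyr::summarise(
      status = dplyr::case_when(
        any(.data$direction == "hyper") & any(.data$direction == "hypo") ~ "both",
        any(.data$direction == "hyper") ~ "hyper",
        TRUE ~ "hypo"
      ),
      .groups = "drop"
    )
  if (is.null(gene_ids)) return(status)
  comparisons <- comparisons %||%
    attr(dmrs, "comparisons") %||%
    dplyr::distinct(tibble::as_tibble(dmrs)[c("tumor", "control")])
  if (nrow(comparisons) == 0) {
    stop("no comparisons to complete statuses over")
  }
  full <- tidyr::expand_grid(
    gene_id = gene_ids,
    region = factor(REGION_LEVELS, REGION_LEVELS),
    comparisons
  )
  dplyr::left_join(
    full, status,
    by = c("gene_id", "region", "tumor", "control")
  ) |>
    dplyr::mutate(status = dplyr::coalesce(.data$status, "none"))
}

#' Union of methylation statuses across the two control groups
#'
#' A gene region is marked differential for a tumor group if it is
#' differential against the healthy-normal or the tumor-adjacent control.
#' The union keeps the direction when the two controls agree or one is
#' silent, and yields "both" on a hyper/hypo conflict (such genes are
#' excluded from single-direction pattern classes downstream).
#'
#' @param statuses Status tibble from [gene_region_status()], containing the
#'   comparisons to be united.
#' @param controls The control labels to unite (default `c("N", "ADJ")`).
#' @return A status tibble with `control` set to the joined label (e.g.
#'   `"N|ADJ"`).
#' @export
union_across_controls <- function(statuses, controls = c("N", "ADJ")) {
  statuses |>
    dplyr::filter(.data$control %in% controls) |>
    dplyr::group_by(.data$gene_id, .data$region, .data$tumor) |>
    dplyr::summarise(
      status = dplyr::case_when(
        any(.data$status == "both") ~ "both",
        any(.data$status == "hyper") & any(.data$status == "hypo") ~ "both",
        any(.data$status == "hyper") ~ "hyper",
        any(.data$status == "hypo") ~ "hypo",
        TRUE ~ "none"
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(control = paste(controls, collapse = "|"))
}

#' Mean methylation profile around DMR midpoints
#'
#' Averages rpm per group over a window of bins centered at each DMR's
#' midpoint (the bin containing the midpoint is the first bin of the
#' downstream half), then averages across DMRs. With the defaults
#' (`half_window` 500 bp, 100 bp bins) the profile has 10 points.
#'
#' @param dmrs A tibble of DMRs (must be non-empty).
#' @param bm A `bin_matrix`.
#' @param half_window Half window width in bp (default 500).
#' @param groups Group labels to profile; defaults to all groups present.
#' @return A `dmr_profile` tibble with columns `group`, `offset` (bp of the
#'   bin start relative to the DMR midpoint bin) and `mean_rpm`.
#' @export
dmr_mean_profile <- function(dmrs, bm, half_window = 500, groups = NULL) {
  if (nrow(dmrs) == 0) stop("empty DMR list")
  bs <- bm$bin_size
  k <- as.integer(half_window / bs)
  groups <- groups %||% as.character(levels(droplevels(bm$sample_sheet$group)))
  mid_bin <- as.integer(((dmrs$start + dmrs$end) %/% 2) %/% bs)
  offsets <- (-k):(k - 1)

  window_bins <- as.vector(outer(offsets, mid_bin, `+`))
  window_chrom <- rep(dmrs$chrom, each = length(offsets))
  rows <- .bin_rows(bm, window_chrom, window_bins)

  out <- purrr::map(groups, function(g) {
    ids <- resolve_group_samples(bm$sample_sheet, g)
    vals <- rep(0, length(rows))
    ok <- !is.na(rows)
    vals[ok] <- rowMeans(bm$rpm[rows[ok], ids, drop = FALSE])
    m <- matrix(vals, nrow = length(offsets))
    tibble::tibble(group = g, offset = offsets * bs, mean_rpm = rowMeans(m))
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("dmr_profile", class(res))
  res
}

#' Write DMRs as a BED6+ file
#'
#' Columns: chrom, start, end, `gene|region|tumor_vs_control`, score
#' (`-10 * log10(min_p)` capped at 1000), strand, then `n_bins`,
#' `direction`, `mean_rpm_high`, `run_log2fc`.
#'
#' @param dmrs A `dmr_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- tibble::tibble(
    chrom = dmrs$chrom,
    start = dmrs$start,
    end = dmrs$end,
    name = paste0(dmrs$gene_id, "|", dmrs$region, "|",
                  dmrs$tumor, "_vs_", dmrs$control),
    score = round(pmin(1000, -10 * log10(pmax(dmrs$min_p, 1e-100))), 2),
    strand = dmrs$strand,
    n_bins = dmrs$n_bins,
    direction = dmrs$direction,
    mean_rpm_high = dmrs$mean_rpm_high,
    run_log2fc = dmrs$run_log2fc
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @exportS3Method generics::glance
glance.dmr_set <- function(x, ...) {
  tibble::tibble(
    n_dmrs = nrow(x),
    n_genes = dplyr::n_distinct(x$gene_id),
    n_hyper = sum(x$direction == "hyper"),
    n_hypo = sum(x$direction == "hypo"),
    n_comparisons = nrow(dplyr::distinct(
      tibble::as_tibble(x)[c("tumor", "control")]
    ))
  )
}

#' @exportS3Method generics::tidy
tidy.dmr_set <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "params") <- NULL
  attr(out, "comparisons") <- NULL
  out
}
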