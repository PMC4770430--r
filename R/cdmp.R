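#' Classify genes into collaborative differential methylation patterns
#'
#' A CDMP label joins the TSS methylation state (`S1` hyper, `S0` hypo) with
#' the state of one partner region — Distal (`D`), Genic (`G`) or TES (`E`)
#' — giving the 12 TSS-anchored labels S1D1 ... S0E0 (e.g. S1D0 = hyper-TSS
#' with hypo-Distal). A gene is labeled only when its TSS status is cleanly
#' hyper or hypo in that comparison; mixed ("both") or silent ("none")
#' statuses, on either side, yield no label for that pairing.
#'
#' @param statuses Status tibble from [gene_region_status()] or
#'   [union_across_controls()] (columns `gene_id`, `region`, `tumor`,
#'   `control`, `status`).
#' @return A tibble with columns `gene_id`, `tumor`, `control`, `label`.
#' @export
classify_cdmp <- function(statuses) {
  tss <- statuses |>
    dplyr::filter(.data$region == "TSS",
                  .data$status %in% c("hyper", "hypo")) |>
    dplyr::select("gene_id", "tumor", "control", tss_status = "status")
  partners <- statuses |>
    dplyr::filter(.data$region != "TSS",
                  .data$status %in% c("hyper", "hypo")) |>
    dplyr::select("gene_id", "tumor", "control",
                  partner = "region", partner_status = "status")
  dplyr::inner_join(tss, partners,
                    by = c("gene_id", "tumor", "control")) |>
    dplyr::mutate(
      label = paste0(
        ifelse(.data$tss_status == "hyper", "S1", "S0"),
        PARTNER_LETTER[as.character(.data$partner)],
        ifelse(.data$partner_status == "hyper", "1", "0")
      )
    ) |>
    dplyr::select("gene_id", "tumor", "control", "label") |>
    dplyr::arrange(.data$gene_id, .data$tumor, .data$control, .data$label)
}

#' Count genes per CDMP label and comparison
#'
#' Counts distinct genes per (label, tumor group, control), and adds
#' `tumor = "ANY"` rows giving, per label and control, the union of genes
#' differential in any of the tumor groups.
#'
#' @param assignments Tibble from [classify_cdmp()].
#' @return A `cdmp_counts` tibble with columns `label`, `tumor`, `control`,
#'   `n_genes`; every label appears for every observed (tumor, control)
#'   combination, with zero counts where no gene carries it.
#' @export
summarize_pattern_counts <- function(assignments) {
  combos <- dplyr::distinct(assignments[c("tumor", "control")])
  if (nrow(combos) == 0) {
    combos <- tibble::tibble(tumor = character(), control = character())
  }
  per <- assignments |>
    dplyr::distinct(.data$label, .data$tumor, .data$control, .data$gene_id) |>
    dplyr::count(.data$label, .data$tumor, .data$control, name = "n_genes")
  any_t <- assignments |>
    dplyr::distinct(.data$label, .data$control, .data$gene_id) |>
    dplyr::count(.data$label, .data$control, name = "n_genes") |>
    dplyr::mutate(tumor = "ANY")
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(label = CDMP_LABELS, combos),
    tidyr::expand_grid(label = CDMP_LABELS,
                       tumor = "ANY",
                       control = unique(combos$control))
  )
  out <- grid |>
    dplyr::left_join(dplyr::bind_rows(per, any_t),
                     by = c("label", "tumor", "control")) |>
    dplyr::mutate(
      n_genes = as.integer(dplyr::coalesce(.data$n_genes, 0L)),
      label = factor(.data$label, levels = CDMP_LABELS)
    ) |>
    dplyr::arrange(.data$label, .data$tumor, .data$control)
  class(out) <- c("cdmp_counts", class(out))
  out
}

#' Gene sets per CDMP label
#'
#' Collapses assignments to one gene set per label, taking the union over
#' tumor groups and controls present (the "differential in any tumor group,
#' against normal or adjacent" summary used for overlap testing and
#' expression integration).
#'
#' @param assignments Tibble from [classify_cdmp()].
#' @param tumor,control Optional filters applied before the union.
#' @return A named list of character vectors, one per label (labels with no
#'   genes map to empty vectors).
#' @export
cdmp_gene_sets <- function(assignments, tumor = NULL, control = NULL) {
  a <- assignments
  if (!is.null(tumor)) a <- dplyr::filter(a, .data$tumor %in% !!tumor)
  if (!is.null(control)) a <- dplyr::filter(a, .data$control %in% !!control)
  sets <- split(a$gene_id, factor(a$label, levels = CDMP_LABELS))
  lapply(sets, function(g) sort(unique(g)))
}

#' Upper-tail hypergeometric overlap test between two gene sets
#'
#' Tests whether the overlap of two gene sets drawn from a common universe
#' is larger than expected by chance: `p = P(X >= overlap)` with X
#' hypergeometric (population `|universe|`, `|A|` successes, `|B|` draws).
#' Computed through the log-space upper tail for numerical stability at
#' extreme significance.
#'
#' @param set_a,set_b Character vectors of gene ids (subsets of `universe`).
#' @param universe Character vector: the gene universe.
#' @param label_a,label_b Optional names for the report.
#' @return An `overlap_test` tibble with one row: `set_a_label`,
#'   `set_b_label`, `universe_size`, `size_a`, `size_b`, `overlap`,
#'   `p_value`, `log10_p`.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe,
                              label_a = "A", label_b = "B") {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) > 0 ||
      length(setdiff(set_b, universe)) > 0) {
    stop("gene sets must be subsets of the universe")
  }
  m <- length(universe)
  k <- length(intersect(set_a, set_b))
  log_p <- phyper(k - 1, length(set_a), m - length(set_a), length(set_b),
                  lower.tail = FALSE, log.p = TRUE)
  out <- tibble::tibble(
    set_a_label = label_a, set_b_label = label_b,
    universe_size = m, size_a = length(set_a), size_b = length(set_b),
    overlap = k,
    p_value = exp(log_p),
    log10_p = log_p / log(10)
  )
  class(out) <- c("overlap_test", class(out))
  out
}

#' Pairwise hypergeometric overlap tests between CDMP gene sets
#'
#' @param gene_sets Named list of gene sets (e.g. from [cdmp_gene_sets()]).
#' @param universe Character vector: the gene universe (all genes testable
#'   in both regions of each pairing; see the methods vignette).
#' @param pairs Optional 2-column matrix/data frame of set names to test;
#'   defaults to all unordered pairs of non-empty sets.
#' @return An `overlap_test` tibble, one row per pair.
#' @export
cdmp_overlap_tests <- function(gene_sets, universe, pairs = NULL) {
  if (is.null(pairs)) {
    keep <- names(gene_sets)[vapply(gene_sets, length, integer(1)) > 0]
    if (length(keep) < 2) {
      return(hypergeom_overlap(character(), character(), universe)[0, ])
    }
    pairs <- t(utils::combn(keep, 2))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  out <- purrr::pmap(
    list(pairs[[1]], pairs[[2]]),
    function(a, b) hypergeom_overlap(gene_sets[[a]], gene_sets[[b]],
                                     universe, a, b)
  )
  res <- dplyr::bind_rows(out)
  class(res) <- c("overlap_test", class(res))
  res
}

#' @exportS3Method generics::tidy
tidy.overlap_test <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' Mean rpm per gene, genomic region and sample group
#'
#' For every gene, region and sample group, averages rpm over all the
#' region's bins and the group's samples — the gene-by-(group, region) mean
#' matrix used for clustering-style overviews. Regions with no bins (e.g.
#' the empty gene body of a short transcript) are `NA`.
#'
#' @param bm A `bin_matrix`.
#' @param regions Region tibble from [partition_gene_regions()].
#' @param groups Group labels; defaults to all groups present.
#' @param bin_size Bin width used for the region-bin assignment.
#' @return A tibble with columns `gene_id`, `group`, `region`, `mean_rpm`.
#' @export
group_region_mean_matrix <- function(bm, regions, groups = NULL,
                                     bin_size = NULL) {
  bin_size <- bin_size %||% bm$bin_size
  groups <- groups %||% as.character(levels(droplevels(bm$sample_sheet$group)))
  rb <- assign_bins_to_regions(regions, bin_size)
  rows <- .bin_rows(bm, rb$chrom, rb$bin)
  ok <- !is.na(rows)

  per_group <- purrr::map(groups, function(g) {
    ids <- resolve_group_samples(bm$sample_sheet, g)
    vals <- rep(0, nrow(rb))
    vals[ok] <- rowMeans(bm$rpm[rows[ok], ids, drop = FALSE])
    tibble::tibble(gene_id = rb$gene_id, region = rb$region,
                   group = g, rpm = vals)
  })
  means <- dplyr::bind_rows(per_group) |>
    dplyr::group_by(.data$gene_id, .data$group, .data$region) |>
    dplyr::summarise(mean_rpm = mean(.data$rpm), .groups = "drop")

  # complete with NA for regions that have no bins
  grid <- tidyr::expand_grid(
    gene_id = unique(regions$gene_id),
    group = groups,
    region = factor(REGION_LEVELS, REGION_LEVELS)
  )
  dplyr::left_join(grid, means, by = c("gene_id", "group", "region")) |>
    dplyr::arrange(.data$gene_id, .data$group, .data$region)
}
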