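#' Load a differential-expression table
#'
#' Reads a TSV with columns `gene_id`, `log2fc`, `p_value` and either an
#' `n_low_expr_samples` column or per-sample log2-cpm columns (names starting
#' with `logcpm`), which are reduced to the count of samples with log2-cpm
#' below zero (i.e. cpm < 1).
#'
#' @param path Path to the DE table TSV.
#' @param tumor_group Optional tumor-group label to stamp on the records
#'   (read from a `tumor_group` column when present).
#' @return A tibble with columns `gene_id`, `tumor_group`, `log2fc`,
#'   `p_value`, `n_low_expr_samples`.
#' @export
load_de_table <- function(path, tumor_group = NULL) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  hdr <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE, show_col_types = FALSE))
  spec <- setNames(rep(list("d"), length(hdr)), hdr)
  for (col in intersect(c("gene_id", "tumor_group"), hdr)) spec[[col]] <- "c"
  # malformed numeric cells surface as NA below, with a clearer message
  tbl <- suppressWarnings(
    readr::read_tsv(path, col_types = do.call(readr::cols, spec),
                    progress = FALSE, show_col_types = FALSE)
  )
  miss <- setdiff(c("gene_id", "log2fc", "p_value"), names(tbl))
  if (length(miss) > 0) {
    stop("DE table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyNA(tbl$p_value) || anyNA(tbl$log2fc)) {
    stop("non-numeric log2fc or p_value in DE table ", path)
  }
  logcpm_cols <- grep("^logcpm", names(tbl), value = TRUE)
  n_low <- if ("n_low_expr_samples" %in% names(tbl)) {
    as.integer(tbl$n_low_expr_samples)
  } else if (length(logcpm_cols) > 0) {
    as.integer(rowSums(tbl[logcpm_cols] < 0))
  } else {
    stop("DE table ", path,
         " needs an n_low_expr_samples column or per-sample logcpm columns")
  }
  group <- if (!is.null(tumor_group)) {
    tumor_group
  } else if ("tumor_group" %in% names(tbl)) {
    as.character(tbl$tumor_group)
  } else {
    NA_character_
  }
  tibble::tibble(
    gene_id = tbl$gene_id,
    tumor_group = group,
    log2fc = tbl$log2fc,
    p_value = tbl$p_value,
    n_low_expr_samples = n_low
  )
}

#' Exclude lowly expressed genes
#'
#' Drops genes with below-zero log2-cpm in more than `max_low_samples`
#' samples (strictly more than; a gene at exactly the cutoff is retained).
#'
#' @param records DE records from [load_de_table()].
#' @param max_low_samples Cutoff (default 150).
#' @return The retained records.
#' @export
filter_low_expression <- function(records, max_low_samples = 150) {
  dplyr::filter(records, .data$n_low_expr_samples <= max_low_samples)
}

#' Flag differentially expressed genes
#'
#' A gene is up-regulated when `p_value < p_threshold` and
#' `log2fc > min_abs_log2fc`, down-regulated when `p_value < p_threshold`
#' and `log2fc < -min_abs_log2fc`; both inequalities are strict.
#'
#' @param records DE records, already filtered by
#'   [filter_low_expression()].
#' @param p_threshold P-value threshold (default 0.05).
#' @param min_abs_log2fc Absolute log2 fold-change threshold (default 0.5).
#' @return A tibble of DEGs only: `gene_id`, `tumor_group`, `log2fc`,
#'   `p_value`, `direction` ("up" or "down").
#' @export
flag_degs <- function(records, p_threshold = 0.05, min_abs_log2fc = 0.5) {
  records |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$p_value < p_threshold & .data$log2fc > min_abs_log2fc ~ "up",
      .data$p_value < p_threshold & .data$log2fc < -min_abs_log2fc ~ "down",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$direction)) |>
    dplyr::select("gene_id", "tumor_group", "log2fc", "p_value", "direction")
}

#' Cross-tabulate DEGs with CDMP labels
#'
#' For every CDMP label and tumor group, counts the label's genes (a gene
#' carries a label for a tumor group if it does so in any comparison of
#' that group, per the normal-or-adjacent union) and how many of them are
#' differentially expressed, split by direction. Only genes present in both
#' the methylation and the expression data are counted.
#'
#' @param deg_sets DEG tibble from [flag_degs()] (columns `gene_id`,
#'   `tumor_group`, `direction`).
#' @param assignments CDMP assignments from [classify_cdmp()].
#' @param meth_genes Character vector: genes analyzed on the methylation
#'   side (the label universe).
#' @param expr_genes Character vector: genes present in the expression
#'   tables after filtering.
#' @return A tibble with columns `label`, `tumor_group`, `n_labeled`,
#'   `n_deg`, `n_up`, `n_down`.
#' @export
cross_tabulate <- function(deg_sets, assignments, meth_genes, expr_genes) {
  shared <- intersect(tolower(meth_genes), tolower(expr_genes))
  lab <- assignments |>
    dplyr::mutate(gene_id = tolower(.data$gene_id)) |>
    dplyr::filter(.data$gene_id %in% shared,
                  .data$tumor != "ANY") |>
    dplyr::distinct(.data$label, .data$tumor, .data$gene_id)
  degs <- deg_sets |>
    dplyr::mutate(gene_id = tolower(.data$gene_id)) |>
    dplyr::filter(.data$gene_id %in% shared) |>
    dplyr::distinct(.data$gene_id, .data$tumor_group, .data$direction)

  tumor_groups <- sort(unique(degs$tumor_group))
  if (length(tumor_groups) == 0) tumor_groups <- sort(unique(lab$tumor))
  grid <- tidyr::expand_grid(label = CDMP_LABELS, tumor_group = tumor_groups)

  cells <- purrr::pmap(grid, function(label, tumor_group) {
    genes <- unique(lab$gene_id[lab$label == label & lab$tumor == tumor_group])
    d <- degs[degs$tumor_group == tumor_group & degs$gene_id %in% genes, ]
    tibble::tibble(
      label = label, tumor_group = tumor_group,
      n_labeled = length(genes),
      n_deg = dplyr::n_distinct(d$gene_id),
      n_up = dplyr::n_distinct(d$gene_id[d$direction == "up"]),
      n_down = dplyr::n_distinct(d$gene_id[d$direction == "down"])
    )
  })
  dplyr::bind_rows(cells) |>
    dplyr::mutate(label = factor(.data$label, levels = CDMP_LABELS)) |>
    dplyr::arrange(.data$label, .data$tumor_group)
}

#' Risk-group-exclusive DEG sets
#'
#' For each tumor risk group, the genes differentially expressed in that
#' group and in no other — the exclusive zones of the DEG Venn diagram.
#'
#' @param deg_sets DEG tibble (columns `gene_id`, `tumor_group`); filter it
#'   to one CDMP label's genes first for label-wise exclusives.
#' @return A tibble with columns `tumor_group`, `gene_id`, one row per
#'   exclusive gene.
#' @export
risk_unique_degs <- function(deg_sets) {
  groups <- sort(unique(deg_sets$tumor_group))
  sets <- lapply(groups, function(g) {
    unique(deg_sets$gene_id[deg_sets$tumor_group == g])
  })
  names(sets) <- groups
  out <- purrr::imap(sets, function(genes, g) {
    others <- unique(unlist(sets[setdiff(groups, g)], use.names = FALSE))
    tibble::tibble(tumor_group = g, gene_id = sort(setdiff(genes, others)))
  })
  dplyr::bind_rows(out)
}
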