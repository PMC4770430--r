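#' Simulation configuration
#'
#' Defines a seeded synthetic study: a toy genome of well-separated genes,
#' grouped MBD-seq-like binned coverage with negative-binomial noise and
#' planted region-specific methylation shifts, and per-group
#' differential-expression tables with planted DEGs. The group sizes default
#' to the study design the caller emulates (8 normal, 12 adjacent, 13 low /
#' 12 high / 7 very-high risk tumors).
#'
#' @param seed Integer seed; identical configs reproduce identical outputs.
#' @param n_genes,n_chroms Number of genes and chromosomes.
#' @param samples_per_group Named vector of group sizes (names among N, ADJ,
#'   L, H, VH).
#' @param baseline_mean Expected raw count per 100-bp bin.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param gene_span_range Transcript span range in bp (min, max).
#' @param bin_size Bin width in bp.
#' @param n_planted_dmrs Number of genes given one random planted DMR each
#'   (ignored when `planted` is supplied).
#' @param planted Optional tibble of explicit plants with columns `gene_id`,
#'   `region`, `direction`, `n_bins`, `shift`, `groups` (comma-separated
#'   tumor groups, e.g. `"L,H,VH"`).
#' @param planted_patterns Optional tibble (`label`, `n`) planting `n` genes
#'   per CDMP label as a TSS plant plus the matching partner-region plant.
#' @param planted_shift Fold change of planted shifts (hyper multiplies the
#'   tumor mean by `shift`, hypo divides it).
#' @param planted_degs Named list, per tumor group, of `c(up = , down = )`
#'   planted DEG counts; defaults to 30 up / 20 down per tumor group.
#' @param frac_low_expressed Fraction of unplanted genes marked lowly
#'   expressed in the DE tables.
#' @param n_expr_samples Cohort size the low-expression counts refer to.
#' @param adj_attenuation Fraction (0-1) of the planted shift leaked into
#'   the ADJ group; 0 keeps ADJ at baseline, emulating adjacent tissue that
#'   behaves like normal.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 100L, n_chroms = 2L,
                       samples_per_group = c(N = 8, ADJ = 12, L = 13,
                                             H = 12, VH = 7),
                       baseline_mean = 10, dispersion = 0.1,
                       gene_span_range = c(5000, 8000), bin_size = 100L,
                       n_planted_dmrs = 0L, planted = NULL,
                       planted_patterns = NULL, planted_shift = 4,
                       planted_degs = NULL, frac_low_expressed = 0.1,
                       n_expr_samples = 523L, adj_attenuation = 0) {
  stopifnot(
    n_genes >= 1, n_chroms >= 1, baseline_mean > 0, dispersion > 0,
    length(gene_span_range) == 2, gene_span_range[1] >= 4000,
    all(samples_per_group >= 0), planted_shift > 1,
    adj_attenuation >= 0, adj_attenuation <= 1
  )
  bad <- setdiff(names(samples_per_group), GROUP_LEVELS)
  if (length(bad) > 0) stop("unknown group in samples_per_group: ", bad[1])
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_chroms = as.integer(n_chroms),
         samples_per_group = samples_per_group,
         baseline_mean = baseline_mean, dispersion = dispersion,
         gene_span_range = gene_span_range, bin_size = as.integer(bin_size),
         n_planted_dmrs = as.integer(n_planted_dmrs), planted = planted,
         planted_patterns = planted_patterns, planted_shift = planted_shift,
         planted_degs = planted_degs,
         frac_low_expressed = frac_low_expressed,
         n_expr_samples = as.integer(n_expr_samples),
         adj_attenuation = adj_attenuation),
    class = "sim_config"
  )
}

# Gene territory stride; with anchor jitter of at most 9.9 kb this keeps
# every pair of same-chromosome anchors >= 204 kb apart, so the 100-kb
# distal windows of neighbouring genes can never be forced to overlap.
SIM_TERRITORY <- 216000

#' Simulate a toy genome
#'
#' Places `n_genes` transcripts on `n_chroms` chromosomes with at least
#' 204 kb between transcript anchors, mixed strands, and spans large enough
#' that every gene has a non-empty gene-body region. All coordinates fall on
#' the bin grid.
#'
#' @param config A [sim_config()].
#' @return A list with `models` (gene-model tibble as from
#'   [load_gene_models()]) and `chrom_sizes` (tibble `chrom`, `length`).
#' @export
simulate_genome <- function(config) {
  if (config$n_genes < 1) stop("n_genes must be >= 1")
  set.seed(config$seed)
  bs <- config$bin_size
  n <- config$n_genes
  chroms <- sprintf("chr%d", 1 + (seq_len(n) - 1) %% config$n_chroms)
  slot <- (seq_len(n) - 1) %/% config$n_chroms

  span <- round(runif(n, config$gene_span_range[1],
                      config$gene_span_range[2]) / bs) * bs
  strand <- sample(c("+", "-"), n, replace = TRUE)
  jitter <- sample(0:99, n, replace = TRUE) * bs
  origin <- 102000 + slot * SIM_TERRITORY + jitter

  start <- origin
  end <- origin + span
  models <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    transcript_id = sprintf("g%04d.1", seq_len(n)),
    chrom = chroms,
    strand = strand,
    tss = ifelse(strand == "+", start, end),
    tes = ifelse(strand == "+", end, start),
    start = start,
    end = end
  )
  chrom_sizes <- models |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(length = max(.data$end) + 110000, .groups = "drop")
  list(models = models, chrom_sizes = chrom_sizes)
}

# Build the sample sheet implied by a config: ids, groups, and (for tumor
# samples) four per-method risk calls whose maximum equals the group.
.sim_sample_sheet <- function(config) {
  spg <- config$samples_per_group[config$samples_per_group > 0]
  groups <- rep(names(spg), times = spg)
  ids <- unlist(lapply(names(spg), function(g) {
    sprintf("%s%02d", g, seq_len(spg[[g]]))
  }), use.names = FALSE)
  risk <- lapply(groups, function(g) {
    if (!g %in% RISK_LEVELS) return(NULL)
    lvl <- match(g, RISK_LEVELS)
    calls <- RISK_LEVELS[sample.int(lvl, 4, replace = TRUE)]
    calls[sample.int(4, 1)] <- g
    calls
  })
  tibble::tibble(
    sample_id = ids,
    group = factor(groups, levels = GROUP_LEVELS),
    total_reads = NA_real_,
    risk_labels = risk
  )
}

# Expand planted_patterns (label, n) into per-region plants on unused genes.
.expand_pattern_plants <- function(labels, gene_pool, config) {
  purrr::map2(labels$label, labels$n, function(lab, n) {
    stopifnot(lab %in% CDMP_LABELS)
    genes <- gene_pool(n)
    tss_dir <- ifelse(substr(lab, 2, 2) == "1", "hyper", "hypo")
    partner <- names(PARTNER_LETTER)[match(substr(lab, 3, 3), PARTNER_LETTER)]
    part_dir <- ifelse(substr(lab, 4, 4) == "1", "hyper", "hypo")
    dplyr::bind_rows(
      tibble::tibble(gene_id = genes, region = "TSS", direction = tss_dir),
      tibble::tibble(gene_id = genes, region = partner, direction = part_dir)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      n_bins = NA_integer_, shift = config$planted_shift,
      groups = paste(intersect(RISK_LEVELS,
                               names(config$samples_per_group)),
                     collapse = ",")
    )
}

#' Simulate grouped binned methylation coverage with planted DMRs
#'
#' Draws a negative-binomial raw count for every 100-bp bin of every gene
#' region and every sample (expected value `baseline_mean`, dispersion
#' `dispersion`). Planted shifts multiply (hyper) or divide (hypo) the
#' expected count in a contiguous stretch of bins of one gene region, for
#' the samples of the affected tumor groups; N and ADJ stay at baseline
#' (ADJ optionally attenuated via `adj_attenuation`).
#'
#' @param genome From [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A list with `bm` (a `bin_matrix`), `sample_sheet`, `regions`
#'   (the per-gene region tibble) and `truth` (list with `planted` — plant
#'   coordinates and affected groups — and `cdmp` — the pattern labels the
#'   plants imply per gene).
#' @export
simulate_methylation_counts <- function(genome, config) {
  set.seed(config$seed + 1L)
  bs <- config$bin_size
  regions <- partition_gene_regions(genome$models, genome$chrom_sizes)
  rb <- assign_bins_to_regions(regions, bs) |>
    dplyr::arrange(.data$chrom, .data$bin)
  sheet <- .sim_sample_sheet(config)

  bins <- dplyr::distinct(rb, .data$chrom, .data$bin)
  n_bins <- nrow(bins)
  n_samp <- nrow(sheet)
  bin_key <- paste(bins$chrom, bins$bin)

  # plants
  planted <- config$planted
  pool_used <- character(0)
  gene_pool <- function(k) {
    avail <- setdiff(genome$models$gene_id, pool_used)
    if (k > length(avail)) stop("not enough genes left to plant")
    g <- sample(avail, k)
    pool_used <<- c(pool_used, g)
    g
  }
  if (is.null(planted) && !is.null(config$planted_patterns)) {
    planted <- .expand_pattern_plants(config$planted_patterns, gene_pool,
                                      config)
  }
  if (is.null(planted) && config$n_planted_dmrs > 0) {
    genes <- gene_pool(config$n_planted_dmrs)
    params <- dmr_params(bin_size = bs)
    region <- sample(REGION_LEVELS, length(genes), replace = TRUE)
    planted <- tibble::tibble(
      gene_id = genes,
      region = region,
      direction = sample(c("hyper", "hypo"), length(genes), replace = TRUE),
      n_bins = as.integer(min_run_for(region, params) +
                            sample(0:3, length(genes), replace = TRUE)),
      shift = config$planted_shift,
      groups = paste(intersect(RISK_LEVELS, names(config$samples_per_group)),
                     collapse = ",")
    )
  }
  if (is.null(planted)) {
    planted <- tibble::tibble(
      gene_id = character(), region = character(), direction = character(),
      n_bins = integer(), shift = numeric(), groups = character()
    )
  }

  # locate each plant on the bin grid inside its gene region
  params <- dmr_params(bin_size = bs)
  placed <- purrr::pmap(planted, function(gene_id, region, direction, n_bins,
                                          shift, groups, ...) {
    rbins <- sort(rb$bin[rb$gene_id == gene_id & rb$region == region])
    if (is.na(n_bins)) {
      n_bins <- min_run_for(region, params) + sample(0:3, 1)
    }
    if (length(rbins) < n_bins) {
      stop(sprintf("region %s of %s has %d bins; cannot plant %d",
                   region, gene_id, length(rbins), n_bins))
    }
    off <- sample.int(length(rbins) - n_bins + 1, 1) - 1
    sel <- rbins[(off + 1):(off + n_bins)]
    tibble::tibble(
      gene_id = gene_id, region = region, direction = direction,
      chrom = rb$chrom[rb$gene_id == gene_id][1],
      start = min(sel) * bs, end = (max(sel) + 1) * bs,
      n_bins = as.integer(n_bins), shift = shift, groups = groups
    )
  })
  placed <- if (length(placed) > 0) dplyr::bind_rows(placed) else
    tibble::tibble(
      gene_id = character(), region = character(), direction = character(),
      chrom = character(), start = integer(), end = integer(),
      n_bins = integer(), shift = numeric(), groups = character()
    )

  # expected-count matrix, then NB draws
  mu <- matrix(config$baseline_mean, nrow = n_bins, ncol = n_samp,
               dimnames = list(NULL, sheet$sample_id))
  if (nrow(placed) > 0) {
    for (i in seq_len(nrow(placed))) {
      pl <- placed[i, ]
      sel_bins <- which(bins$chrom == pl$chrom &
                          bins$bin >= pl$start / bs & bins$bin < pl$end / bs)
      grps <- strsplit(pl$groups, ",")[[1]]
      cols <- which(sheet$group %in% grps)
      fac <- if (pl$direction == "hyper") pl$shift else 1 / pl$shift
      mu[sel_bins, cols] <- mu[sel_bins, cols] * fac
      if (config$adj_attenuation > 0) {
        adj_cols <- which(sheet$group == "ADJ")
        mu[sel_bins, adj_cols] <- mu[sel_bins, adj_cols] *
          fac^config$adj_attenuation
      }
    }
  }
  raw <- matrix(rnbinom(n_bins * n_samp, mu = mu, size = 1 / config$dispersion),
                nrow = n_bins, ncol = n_samp,
                dimnames = list(NULL, sheet$sample_id))

  totals <- colSums(raw)
  sheet$total_reads <- totals
  bm <- structure(
    list(bins = bins, raw = raw,
         rpm = sweep(raw, 2, 1e6 / totals, `*`),
         sample_sheet = sheet, bin_size = bs),
    class = "bin_matrix"
  )

  truth <- list(planted = placed, cdmp = .implied_cdmp(placed))
  list(bm = bm, sample_sheet = sheet, regions = regions, truth = truth)
}

# CDMP labels implied by plants: genes carrying a TSS plant plus a partner
# plant; the label's groups are the intersection of the two plants' groups.
.implied_cdmp <- function(placed) {
  if (nrow(placed) == 0) {
    return(tibble::tibble(gene_id = character(), label = character(),
                          groups = character()))
  }
  tss <- placed[placed$region == "TSS", ]
  part <- placed[placed$region != "TSS", ]
  joined <- dplyr::inner_join(
    dplyr::select(tss, "gene_id", tss_dir = "direction", tss_groups = "groups"),
    dplyr::select(part, "gene_id", partner = "region",
                  part_dir = "direction", part_groups = "groups"),
    by = "gene_id", relationship = "many-to-many"
  )
  if (nrow(joined) == 0) {
    return(tibble::tibble(gene_id = character(), label = character(),
                          groups = character()))
  }
  joined |>
    dplyr::mutate(
      label = paste0(
        ifelse(.data$tss_dir == "hyper", "S1", "S0"),
        PARTNER_LETTER[.data$partner],
        ifelse(.data$part_dir == "hyper", "1", "0")
      ),
      groups = purrr::map2_chr(.data$tss_groups, .data$part_groups, function(a, b) {
        paste(intersect(strsplit(a, ",")[[1]], strsplit(b, ",")[[1]]),
              collapse = ",")
      })
    ) |>
    dplyr::select("gene_id", "label", "groups")
}

#' Simulate differential-expression tables with planted DEGs
#'
#' Planted DEGs receive `|log2fc|` above 0.5 and p-values below 0.05;
#' unplanted genes receive either a null p-value above 0.05 or a small fold
#' change, so the standard thresholds recover exactly the planted sets. A
#' fraction of unplanted genes is marked lowly expressed
#' (`n_low_expr_samples > 150`) to exercise the expression filter.
#'
#' @param genome From [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A list with `tables` (one tibble per tumor group, bound, with a
#'   `tumor_group` column) and `truth` (tibble `gene_id`, `tumor_group`,
#'   `direction` of planted DEGs).
#' @export
simulate_de_table <- function(genome, config) {
  set.seed(config$seed + 2L)
  genes <- genome$models$gene_id
  groups <- intersect(RISK_LEVELS, names(config$samples_per_group))
  degs <- config$planted_degs
  if (is.null(degs)) {
    degs <- setNames(rep(list(c(up = 30, down = 20)), length(groups)), groups)
  }
  degs <- degs[intersect(names(degs), groups)]

  truth <- list()
  tables <- list()
  for (g in names(degs)) {
    n_up <- min(degs[[g]][["up"]], length(genes))
    n_down <- min(degs[[g]][["down"]], length(genes) - n_up)
    chosen <- sample(genes, n_up + n_down)
    up <- chosen[seq_len(n_up)]
    down <- chosen[n_up + seq_len(n_down)]
    rest <- setdiff(genes, chosen)
    n_low_pool <- rest[seq_len(floor(config$frac_low_expressed * length(rest)))]

    lfc <- runif(length(genes), -0.5, 0.5)
    p <- runif(length(genes), 0.051, 1)
    names(lfc) <- names(p) <- genes
    lfc[up] <- runif(n_up, 0.8, 2.5)
    lfc[down] <- -runif(n_down, 0.8, 2.5)
    p[chosen] <- runif(length(chosen), 1e-8, 0.049)
    # half of the null genes get a significant p but a sub-threshold fold
    # change, so both DEG conditions are exercised
    mixed <- sample(rest, length(rest) %/% 2)
    p[mixed] <- runif(length(mixed), 1e-4, 1)

    n_low <- sample(0:150, length(genes), replace = TRUE)
    names(n_low) <- genes
    n_low[n_low_pool] <- sample(
      151:min(config$n_expr_samples, 300), length(n_low_pool), replace = TRUE
    )

    tables[[g]] <- tibble::tibble(
      gene_id = genes, tumor_group = g, log2fc = unname(lfc[genes]),
      p_value = unname(p[genes]),
      n_low_expr_samples = as.integer(unname(n_low[genes]))
    )
    truth[[g]] <- tibble::tibble(
      gene_id = c(up, down), tumor_group = g,
      direction = rep(c("up", "down"), c(n_up, n_down))
    )
  }
  list(tables = dplyr::bind_rows(tables), truth = dplyr::bind_rows(truth))
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits every artifact the pipeline consumes: BED12 annotation,
#' chrom.sizes, sample sheet TSV, one bedGraph per sample, one DE table per
#' tumor group, a ground-truth JSON, and a manifest of MD5 checksums.
#' Identical configs reproduce byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble (`file`, `md5`), invisibly; also written as
#'   `manifest.tsv`.
#' @export
write_fixture_set <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  genome <- simulate_genome(config)
  sim <- simulate_methylation_counts(genome, config)
  de <- simulate_de_table(genome, config)

  m <- genome$models
  bed <- tibble::tibble(
    chrom = m$chrom, start = m$start, end = m$end, name = m$gene_id,
    score = 0L, strand = m$strand, thickStart = m$start, thickEnd = m$end,
    itemRgb = "0,0,0", blockCount = 1L,
    blockSizes = paste0(m$end - m$start, ","), blockStarts = "0,"
  )
  readr::write_tsv(bed, file.path(out_dir, "annotation.bed"),
                   col_names = FALSE)
  readr::write_tsv(genome$chrom_sizes, file.path(out_dir, "chrom.sizes"),
                   col_names = FALSE)

  sheet <- sim$sample_sheet
  sheet_out <- tibble::tibble(
    sample_id = sheet$sample_id,
    group = as.character(sheet$group),
    total_reads = sheet$total_reads
  )
  has_risk <- vapply(sheet$risk_labels, function(x) !is.null(x), logical(1))
  if (any(has_risk)) {
    for (i in 1:4) {
      sheet_out[[paste0("risk_m", i)]] <- vapply(
        sheet$risk_labels,
        function(x) if (is.null(x)) NA_character_ else x[i],
        character(1)
      )
    }
  }
  readr::write_tsv(sheet_out, file.path(out_dir, "samples.tsv"), na = "")

  bm <- sim$bm
  cov_dir <- file.path(out_dir, "coverage")
  dir.create(cov_dir, showWarnings = FALSE)
  for (s in colnames(bm$raw)) {
    nz <- which(bm$raw[, s] != 0)
    bg <- tibble::tibble(
      chrom = bm$bins$chrom[nz],
      start = bm$bins$bin[nz] * bm$bin_size,
      end = (bm$bins$bin[nz] + 1) * bm$bin_size,
      count = bm$raw[nz, s]
    )
    readr::write_tsv(bg, file.path(cov_dir, paste0(s, ".bedGraph")),
                     col_names = FALSE)
  }

  for (g in unique(de$tables$tumor_group)) {
    readr::write_tsv(de$tables[de$tables$tumor_group == g, ],
                     file.path(out_dir, sprintf("de_%s.tsv", g)))
  }

  truth <- list(
    planted_dmrs = sim$truth$planted,
    implied_cdmp = sim$truth$cdmp,
    planted_degs = de$truth
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)

  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE),
    "manifest.tsv"
  ))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Score recovery of planted DMRs
#'
#' A planted record is expanded to one expected hit per affected tumor
#' group; it counts as recovered when a called DMR of the same gene, region
#' and direction, from a comparison whose tumor side is that group,
#' overlaps the planted interval. A called DMR is a true positive when it
#' overlaps a plant of matching gene, region and direction whose affected
#' groups include the DMR's tumor group ("ALL" matches any plant with at
#' least one affected group).
#'
#' @param dmrs A `dmr_set` tibble from [call_dmrs()].
#' @param truth The `truth$planted` tibble from
#'   [simulate_methylation_counts()].
#' @return A list with `recall`, `precision`, `n_expected`, `n_called`,
#'   `expected` (per-expectation tibble with a `recovered` flag) and
#'   `calls` (per-DMR tibble with a `true_positive` flag).
#' @export
score_dmr_recovery <- function(dmrs, truth) {
  expected <- truth |>
    dplyr::mutate(group = strsplit(.data$groups, ",")) |>
    tidyr::unnest("group")
  hit <- function(gene_id, region, direction, start, end, group) {
    any(dmrs$gene_id == gene_id & dmrs$region == region &
          dmrs$direction == direction &
          (dmrs$tumor == group | dmrs$tumor == "ALL") &
          dmrs$start < end & dmrs$end > start)
  }
  expected$recovered <- purrr::pmap_lgl(
    expected[c("gene_id", "region", "direction", "start", "end", "group")],
    hit
  )
  tp <- function(gene_id, region, direction, start, end, tumor) {
    idx <- truth$gene_id == gene_id & truth$region == region &
      truth$direction == direction &
      truth$start < end & truth$end > start
    if (!any(idx)) return(FALSE)
    if (tumor == "ALL") return(TRUE)
    any(vapply(truth$groups[idx],
               function(g) tumor %in% strsplit(g, ",")[[1]], logical(1)))
  }
  calls <- tibble::as_tibble(dmrs)
  calls$true_positive <- purrr::pmap_lgl(
    calls[c("gene_id", "region", "direction", "start", "end", "tumor")],
    tp
  )
  list(
    recall = if (nrow(expected) == 0) NA_real_ else mean(expected$recovered),
    precision = if (nrow(calls) == 0) NA_real_ else mean(calls$true_positive),
    n_expected = nrow(expected),
    n_called = nrow(calls),
    expected = expected,
    calls = calls
  )
}
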