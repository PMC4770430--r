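#' Read a two-column chromosome sizes file
#'
#' Reads the UCSC `chrom.sizes` dialect: tab-separated, no header, one
#' `chrom<TAB>length` pair per line.
#'
#' @param path Path to the chrom.sizes file.
#' @return A tibble with columns `chrom` (character) and `length` (integer bp).
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom sizes file not found: ", path)
  tbl <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = "cd", progress = FALSE)
  if (nrow(tbl) == 0 || anyNA(tbl$length) || any(tbl$length <= 0)) {
    stop("malformed chrom sizes file: ", path)
  }
  tbl
}

#' Load transcript models from an annotation file
#'
#' Reads gene annotation in refFlat, BED12 or GTF format and extracts one
#' transcript model per record: chromosome, strand, and the strand-aware
#' transcription start (TSS) and end (TES) coordinates. On the plus strand
#' the TSS is the lower coordinate; on the minus strand it is the higher one.
#' All coordinates are 0-based half-open internally (GTF's 1-based starts are
#' converted on load).
#'
#' @param path Path to the annotation file.
#' @param format One of `"auto"`, `"refFlat"`, `"bed12"`, `"gtf"`. `"auto"`
#'   guesses from the file extension (`.bed` -> BED12, `.gtf`/`.gff` -> GTF,
#'   otherwise refFlat).
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `tss`, `tes`, `start`, `end` (transcript span, BED-style).
#' @export
load_gene_models <- function(path, format = c("auto", "refFlat", "bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bed = "bed12",
      gtf = "gtf",
      gff = "gtf",
      "refFlat"
    )
  }
  models <- switch(format,
    bed12 = .load_bed12(path),
    gtf = .load_gtf(path),
    refFlat = .load_refflat(path)
  )
  .validate_strands(models, path)
  models |>
    dplyr::mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      tes = ifelse(.data$strand == "+", .data$end, .data$start)
    ) |>
    dplyr::select("gene_id", "transcript_id", "chrom", "strand",
                  "tss", "tes", "start", "end")
}

.validate_strands <- function(models, path) {
  bad <- which(!models$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop(sprintf("record %d of %s has unknown strand symbol '%s'",
                 bad[1], path, models$strand[bad[1]]))
  }
  invisible(models)
}

.load_bed12 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("failed to parse BED file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  tibble::tibble(
    gene_id = as.character(gr$name),
    transcript_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |>
    dplyr::mutate(strand = ifelse(.data$strand == "*", ".", .data$strand))
}

.load_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[gr$type == "transcript"]
  if (length(gr) == 0) stop("no transcript features in GTF file: ", path)
  tibble::tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |>
    dplyr::mutate(strand = ifelse(.data$strand == "*", ".", .data$strand))
}

.load_refflat <- function(path) {
  cols <- c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  tbl <- tryCatch(
    readr::read_tsv(path, col_names = cols, col_types = "ccccdddddcc",
                    progress = FALSE),
    error = function(e) stop("failed to parse refFlat file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  bad <- which(is.na(tbl$txStart) | is.na(tbl$txEnd))
  if (length(bad) > 0) {
    stop(sprintf("unparseable refFlat record at line %d of %s", bad[1], path))
  }
  tibble::tibble(
    gene_id = tbl$geneName,
    transcript_id = tbl$name,
    chrom = tbl$chrom,
    strand = tbl$strand,
    start = as.integer(tbl$txStart),
    end = as.integer(tbl$txEnd)
  )
}

#' Keep transcripts with unique TSS/TES and collapse isoforms
#'
#' Drops transcripts whose TSS or TES coordinate is shared with a transcript
#' of a *different* gene (both colliding parties are dropped), then keeps the
#' longest isoform per gene so downstream gene-level pattern classification
#' sees exactly one record per gene. With `collision_scope = "any"` a shared
#' coordinate is disqualifying regardless of gene identity, so within-gene
#' isoform collisions also drop both records.
#'
#' @param models Tibble from [load_gene_models()].
#' @param collision_scope `"across_genes"` (default) or `"any"`.
#' @return A tibble of the same shape with unique `gene_id`s.
#' @export
select_unique_transcripts <- function(models,
                                      collision_scope = c("across_genes", "any")) {
  collision_scope <- match.arg(collision_scope)
  if (nrow(models) == 0) return(models)

  collides <- function(key) {
    # for each transcript, is its key shared with an offending transcript?
    if (collision_scope == "any") {
      dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
      return(dup)
    }
    # shared with a transcript of a different gene
    genes_at <- split(models$gene_id, key)
    n_genes <- vapply(genes_at, function(g) length(unique(g)), integer(1))
    unname(n_genes[key] > 1)
  }

  tss_key <- paste(models$chrom, models$tss)
  tes_key <- paste(models$chrom, models$tes)
  keep <- !(collides(tss_key) | collides(tes_key))
  out <- models[keep, , drop = FALSE]

  # longest isoform per gene; transcript_id order breaks ties deterministically
  out |>
    dplyr::mutate(.span = abs(.data$tes - .data$tss)) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$.span), .data$transcript_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select(-".span")
}

#' Partition transcripts into the four gene-anchored genomic regions
#'
#' For each transcript the four regions are, on the plus strand:
#' Distal `[tss-100000, tss-2000)`, TSS `[tss-2000, tss+2000)`,
#' Genic `[tss+2000, tes-1000)` and TES `[tes-1000, tes+1000)`; the layout is
#' mirrored on the minus strand. Intervals are clipped to
#' `[0, chrom_length)`. The Genic interval is empty (zero width) for
#' transcripts spanning 3 kb or less; such rows are kept with
#' `start == end` so that region accounting stays complete, and they simply
#' yield no bins downstream.
#'
#' @param models Tibble of gene models (one row per gene), as returned by
#'   [select_unique_transcripts()].
#' @param chrom_sizes Optional tibble from [read_chrom_sizes()]; when `NULL`
#'   only the lower bound (0) is clipped.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `region`
#'   (factor DISTAL/TSS/GENIC/TES), `start`, `end`, `width`.
#' @export
partition_gene_regions <- function(models, chrom_sizes = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "tes") %in% names(models)))
  plus <- models$strand == "+"
  tss <- models$tss
  tes <- models$tes

  mk <- function(region, s, e) {
    tibble::tibble(
      gene_id = models$gene_id, chrom = models$chrom, strand = models$strand,
      region = region, start = s, end = e
    )
  }
  regions <- dplyr::bind_rows(
    mk("DISTAL", ifelse(plus, tss - 100000, tss + 2000),
                 ifelse(plus, tss - 2000, tss + 100000)),
    mk("TSS", tss - 2000, tss + 2000),
    mk("GENIC", ifelse(plus, tss + 2000, tes + 1000),
                ifelse(plus, tes - 1000, tss - 2000)),
    mk("TES", tes - 1000, tes + 1000)
  )
  # empty genic for short transcripts
  regions$end <- pmax(regions$start, regions$end)

  # clip to chromosome bounds
  regions$start <- pmax(regions$start, 0)
  regions$end <- pmax(regions$end, 0)
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes$length[match(regions$chrom, chrom_sizes$chrom)]
    if (anyNA(len)) {
      stop("chromosome missing from chrom sizes: ",
           regions$chrom[which(is.na(len))[1]])
    }
    regions$start <- pmin(regions$start, len)
    regions$end <- pmin(regions$end, len)
  }
  regions$start <- pmin(regions$start, regions$end)

  regions |>
    dplyr::mutate(
      region = factor(.data$region, levels = REGION_LEVELS),
      width = .data$end - .data$start
    ) |>
    dplyr::arrange(.data$gene_id, .data$region)
}

#' Assign genome-anchored bins to gene regions
#'
#' Bin `i` covers `[i * bin_size, (i + 1) * bin_size)`. A bin belongs to a
#' region iff its start coordinate lies inside the region interval, which
#' makes bin membership unambiguous and the four regions' bin lists pairwise
#' disjoint within a gene. Bins are ordered 5' to 3' along the transcript's
#' strand.
#'
#' @param regions Region tibble from [partition_gene_regions()].
#' @param bin_size Bin width in bp (default 100).
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `region`,
#'   `bin` (integer index), `ord` (1-based 5'->3' order within the
#'   gene-region).
#' @export
assign_bins_to_regions <- function(regions, bin_size = 100) {
  stopifnot(bin_size > 0)
  first_bin <- ceiling(regions$start / bin_size)
  last_bin <- ceiling(regions$end / bin_size) - 1
  n <- pmax(0, last_bin - first_bin + 1)
  idx <- rep.int(seq_len(nrow(regions)), n)
  bin <- as.integer(unlist(
    purrr::map2(first_bin, n, function(f, k) if (k > 0) f + 0:(k - 1) else integer(0)),
    use.names = FALSE
  ))
  out <- tibble::tibble(
    gene_id = regions$gene_id[idx],
    chrom = regions$chrom[idx],
    strand = regions$strand[idx],
    region = regions$region[idx],
    bin = bin
  )
  out |>
    dplyr::group_by(.data$gene_id, .data$region) |>
    dplyr::mutate(ord = as.integer(ifelse(.data$strand == "+",
                                          rank(.data$bin),
                                          rank(-.data$bin)))) |>
    dplyr::ungroup()
}

#' Write the per-gene region table
#'
#' @param regions Region tibble from [partition_gene_regions()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  readr::write_tsv(
    dplyr::select(regions, "gene_id", "chrom", "strand", "region",
                  "start", "end"),
    path
  )
  invisible(path)
}
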