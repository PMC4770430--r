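#' Read a sample sheet
#'
#' The sample sheet is a TSV with header columns `sample_id` and `group`
#' (case-insensitive tokens among N, ADJ, L, H, VH), an optional
#' `total_reads` column, and optional per-method clinical risk-call columns
#' (any columns whose names start with `risk`). When risk columns are
#' present they are collected into a `risk_labels` list-column.
#'
#' @param path Path to the sample sheet TSV.
#' @return A tibble with columns `sample_id`, `group` (factor with levels
#'   N, ADJ, L, H, VH), `total_reads` (may be `NA`), and `risk_labels`
#'   (list-column, possibly all `NULL`).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(tbl))
  if (length(miss) > 0) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tbl$sample_id)) {
    dup <- tbl$sample_id[duplicated(tbl$sample_id)][1]
    stop("duplicate sample_id in sample sheet: ", dup)
  }
  grp <- toupper(trimws(tbl$group))
  bad <- setdiff(unique(grp), GROUP_LEVELS)
  if (length(bad) > 0) {
    stop("unknown group token in sample sheet: ", bad[1])
  }
  total_reads <- if ("total_reads" %in% names(tbl)) {
    as.numeric(tbl$total_reads)
  } else {
    rep(NA_real_, nrow(tbl))
  }
  if (any(!is.na(total_reads) & total_reads <= 0)) {
    stop("total_reads must be > 0 when provided")
  }
  risk_cols <- grep("^risk", names(tbl), value = TRUE)
  risk_labels <- if (length(risk_cols) > 0) {
    apply(tbl[risk_cols], 1, function(r) {
      r <- toupper(trimws(r[!is.na(r) & nzchar(r)]))
      if (length(r) == 0) NULL else unname(r)
    }, simplify = FALSE)
  } else {
    rep(list(NULL), nrow(tbl))
  }
  tibble::tibble(
    sample_id = tbl$sample_id,
    group = factor(grp, levels = GROUP_LEVELS),
    total_reads = total_reads,
    risk_labels = risk_labels
  )
}

#' Combine per-method clinical risk calls into one risk group
#'
#' Each sample carries one risk call per classification method on the ordered
#' scale L < H < VH; the combined group is the highest risk among the
#' methods.
#'
#' @param risk_labels A character vector of risk calls for one sample, or a
#'   list of such vectors for several samples.
#' @return A character scalar (or vector, for list input) among "L", "H",
#'   "VH".
#' @export
assign_risk_group <- function(risk_labels) {
  if (is.list(risk_labels)) {
    return(vapply(risk_labels, assign_risk_group, character(1)))
  }
  if (length(risk_labels) == 0) stop("empty risk call list")
  labels <- toupper(trimws(risk_labels))
  bad <- setdiff(labels, RISK_LEVELS)
  if (length(bad) > 0) stop("unknown risk call: ", bad[1])
  RISK_LEVELS[max(match(labels, RISK_LEVELS))]
}

#' Read binned read counts
#'
#' Reads either a 4-column bedGraph (`chrom start end count`, no header; one
#' sample per file) or a bin-matrix TSV with header
#' `chrom<TAB>bin_start<TAB><sample1><TAB><sample2>...`. bedGraph intervals
#' must align to the bin grid: `start` a multiple of `bin_size` and width
#' exactly `bin_size`. Absent bins mean zero coverage.
#'
#' @param path Input file (bedGraph files may be gzip-compressed).
#' @param bin_size Bin width in bp (default 100).
#' @param sample_id Sample name for bedGraph input; defaults to the file name
#'   without extensions.
#' @return A long tibble with columns `chrom`, `bin` (integer index,
#'   `start / bin_size`), `sample_id`, `count`.
#' @export
read_bin_counts <- function(path, bin_size = 100, sample_id = NULL) {
  if (!file.exists(path)) stop("count file not found: ", path)
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) {
    return(tibble::tibble(chrom = character(), bin = integer(),
                          sample_id = character(), count = numeric()))
  }
  if (grepl("^chrom\tbin_start", first)) {
    return(.read_bin_matrix_tsv(path, bin_size))
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(bedgraph|bedGraph|bg|txt)(\\.gz)?$", "",
                     basename(path))
  }
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "count"),
                         col_types = "cddd", progress = FALSE)
  .check_bin_grid(tbl, bin_size, path)
  tibble::tibble(
    chrom = tbl$chrom,
    bin = as.integer(tbl$start / bin_size),
    sample_id = sample_id,
    count = tbl$count
  )
}

.check_bin_grid <- function(tbl, bin_size, path) {
  off <- which(tbl$start %% bin_size != 0 | (tbl$end - tbl$start) != bin_size)
  if (length(off) > 0) {
    i <- off[1]
    stop(sprintf("interval %s:%d-%d in %s is not aligned to the %d bp bin grid",
                 tbl$chrom[i], tbl$start[i], tbl$end[i], path, bin_size))
  }
  neg <- which(tbl$count < 0)
  if (length(neg) > 0) {
    i <- neg[1]
    stop(sprintf("negative count at %s:%d in %s", tbl$chrom[i], tbl$start[i], path))
  }
  invisible(tbl)
}

.read_bin_matrix_tsv <- function(path, bin_size) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", bin_start = "d", .default = "d"
  ), progress = FALSE)
  samples <- setdiff(names(tbl), c("chrom", "bin_start"))
  if (length(samples) == 0) stop("bin-matrix TSV has no sample columns: ", path)
  if (any(tbl$bin_start %% bin_size != 0)) {
    i <- which(tbl$bin_start %% bin_size != 0)[1]
    stop(sprintf("bin_start %d in %s is not a multiple of %d",
                 tbl$bin_start[i], path, bin_size))
  }
  long <- tidyr::pivot_longer(tbl, dplyr::all_of(samples),
                              names_to = "sample_id", values_to = "count")
  if (any(long$count < 0, na.rm = TRUE)) stop("negative count in ", path)
  tibble::tibble(
    chrom = long$chrom,
    bin = as.integer(long$bin_start / bin_size),
    sample_id = long$sample_id,
    count = long$count
  )
}

#' Normalize raw counts to reads per million
#'
#' @param counts Numeric vector or matrix of raw counts.
#' @param total_reads Total read count of the sample (scalar, > 0).
#' @return `counts * 1e6 / total_reads`.
#' @export
normalize_rpm <- function(counts, total_reads) {
  if (length(total_reads) != 1 || is.na(total_reads) || total_reads <= 0) {
    stop("total_reads must be a single value > 0")
  }
  counts * 1e6 / total_reads
}

#' Build a bin matrix from long-format counts
#'
#' Assembles per-sample binned counts into an aligned bins-by-samples
#' container holding raw counts and rpm values side by side. Samples absent
#' from `counts` but present in the sheet get all-zero columns; bins absent
#' for a sample are zero coverage. When the sheet's `total_reads` is missing
#' for a sample it is computed as the sum of that sample's bin counts.
#'
#' @param counts Long tibble (`chrom`, `bin`, `sample_id`, `count`) as
#'   returned by [read_bin_counts()] (rows for several samples may be bound
#'   together).
#' @param sample_sheet Tibble from [read_sample_sheet()].
#' @param bin_size Bin width in bp (default 100).
#' @return A `bin_matrix` object: list with `bins` (tibble `chrom`, `bin`),
#'   `raw` and `rpm` matrices (rows = bins, columns = samples),
#'   `sample_sheet` (with `total_reads` filled in) and `bin_size`.
#' @export
build_bin_matrix <- function(counts, sample_sheet, bin_size = 100) {
  extra <- setdiff(unique(counts$sample_id), sample_sheet$sample_id)
  if (length(extra) > 0) {
    stop("counts contain sample absent from the sample sheet: ", extra[1])
  }
  bins <- dplyr::distinct(counts, .data$chrom, .data$bin) |>
    dplyr::arrange(.data$chrom, .data$bin)
  samples <- sample_sheet$sample_id
  raw <- matrix(0, nrow = nrow(bins), ncol = length(samples),
                dimnames = list(NULL, samples))
  if (nrow(counts) > 0) {
    ri <- match(paste(counts$chrom, counts$bin), paste(bins$chrom, bins$bin))
    ci <- match(counts$sample_id, samples)
    raw[cbind(ri, ci)] <- counts$count
  }
  totals <- sample_sheet$total_reads
  from_matrix <- is.na(totals)
  totals[from_matrix] <- colSums(raw)[from_matrix]
  if (any(totals <= 0)) {
    stop("sample with zero total reads: ", samples[which(totals <= 0)[1]])
  }
  rpm <- sweep(raw, 2, 1e6 / totals, `*`)
  sheet <- sample_sheet
  sheet$total_reads <- totals
  structure(
    list(bins = bins, raw = raw, rpm = rpm,
         sample_sheet = sheet, bin_size = bin_size),
    class = "bin_matrix"
  )
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix> %d bins x %d samples (bin size %d bp)\n",
              nrow(x$bins), ncol(x$raw), x$bin_size))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$sample_sheet$group)),
                               table(x$sample_sheet$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.bin_matrix <- function(x) c(nrow(x$bins), ncol(x$raw))

#' Long-format view of a bin matrix
#'
#' @param x A `bin_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `bin`, `sample_id`, `count`, `rpm`
#'   (zero cells omitted).
#' @exportS3Method tibble::as_tibble
as_tibble.bin_matrix <- function(x, ...) {
  nz <- which(x$raw != 0 | x$rpm != 0, arr.ind = TRUE)
  tibble::tibble(
    chrom = x$bins$chrom[nz[, 1]],
    bin = x$bins$bin[nz[, 1]],
    sample_id = colnames(x$raw)[nz[, 2]],
    count = x$raw[nz],
    rpm = x$rpm[nz]
  ) |>
    dplyr::arrange(.data$chrom, .data$bin, .data$sample_id)
}

# Row indices of (chrom, bin) pairs in a bin_matrix; NA = bin absent (zero).
.bin_rows <- function(bm, chrom, bin) {
  match(paste(chrom, bin), paste(bm$bins$chrom, bm$bins$bin))
}

# rpm sub-matrix for given bins (rows, NA rows -> 0) and sample columns.
.region_matrix <- function(bm, chrom, bins, samples, what = "rpm") {
  unknown <- setdiff(samples, colnames(bm[[what]]))
  if (length(unknown) > 0) stop("unknown sample_id: ", unknown[1])
  rows <- .bin_rows(bm, chrom, bins)
  out <- matrix(0, nrow = length(bins), ncol = length(samples),
                dimnames = list(NULL, samples))
  ok <- !is.na(rows)
  out[ok, ] <- bm[[what]][rows[ok], samples, drop = FALSE]
  out
}

#' Extract per-bin rpm values for a set of samples
#'
#' @param bm A `bin_matrix`.
#' @param chrom Chromosome of the bins.
#' @param bins Integer vector of bin indices (ordered as desired).
#' @param samples Character vector of sample ids.
#' @return A tibble with columns `bin`, `sample_id`, `rpm`, ordered by the
#'   input bin and sample order; bins absent from the matrix yield zeros.
#' @export
region_values <- function(bm, chrom, bins, samples) {
  m <- .region_matrix(bm, chrom, bins, samples)
  if (length(bins) == 0) {
    return(tibble::tibble(bin = integer(), sample_id = character(),
                          rpm = numeric()))
  }
  tibble::tibble(
    bin = rep(bins, times = length(samples)),
    sample_id = rep(samples, each = length(bins)),
    rpm = as.vector(m)
  )
}

#' Write a bin matrix as a bin-matrix TSV
#'
#' Writes the raw counts in the header dialect accepted back by
#' [read_bin_counts()] (`chrom`, `bin_start`, one column per sample).
#'
#' @param bm A `bin_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bin_matrix <- function(bm, path) {
  out <- tibble::as_tibble(as.data.frame(bm$raw))
  out <- dplyr::bind_cols(
    tibble::tibble(chrom = bm$bins$chrom,
                   bin_start = bm$bins$bin * bm$bin_size),
    out
  )
  readr::write_tsv(out, path)
  invisible(path)
}

# Resolve a comparison-group label to sample ids. "ALL" pools the tumor
# groups L, H, VH; "N+ADJ" pools both control groups.
resolve_group_samples <- function(sample_sheet, label) {
  groups <- switch(label,
    "ALL" = RISK_LEVELS,
    "N+ADJ" = c("N", "ADJ"),
    label
  )
  bad <- setdiff(groups, GROUP_LEVELS)
  if (length(bad) > 0) stop("unknown group label: ", label)
  sample_sheet$sample_id[sample_sheet$group %in% groups]
}
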