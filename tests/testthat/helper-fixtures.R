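# Small in-code fixtures shared across test files.

toy_models <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    transcript_id = c("gA.1", "gB.1", "gC.1"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(150000, 460000, 150000),
    tes = c(160000, 450000, 156000),
    start = c(150000, 450000, 150000),
    end = c(160000, 460000, 156000)
  )
}

toy_chrom_sizes <- function() {
  tibble::tibble(chrom = c("chr1", "chr2"), length = c(600000, 400000))
}

# Build a bin_matrix directly from a dense count matrix on one chromosome.
toy_bin_matrix <- function(counts, bins, groups, chrom = "chr1",
                           bin_size = 100, total_reads = NULL) {
  samples <- sprintf("%s%02d", groups, stats::ave(seq_along(groups),
                                                  groups, FUN = seq_along))
  colnames(counts) <- samples
  sheet <- tibble::tibble(
    sample_id = samples,
    group = factor(groups, levels = c("N", "ADJ", "L", "H", "VH")),
    total_reads = total_reads %||% colSums(counts),
    risk_labels = rep(list(NULL), length(samples))
  )
  structure(
    list(
      bins = tibble::tibble(chrom = chrom, bin = as.integer(bins)),
      raw = counts,
      rpm = sweep(counts, 2, 1e6 / sheet$total_reads, `*`),
      sample_sheet = sheet,
      bin_size = bin_size
    ),
    class = "bin_matrix"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Write a minimal sample sheet TSV and return its path.
write_toy_sheet <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}
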