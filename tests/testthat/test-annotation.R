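test_that("BED records map to strand-aware TSS/TES models", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t150000\t160000\ttx1\t0\t+",
    "chr1\t150000\t160000\ttx2\t0\t-"
  ), bed)
  models <- load_gene_models(bed)
  expect_equal(models$tss, c(150000, 160000))
  expect_equal(models$tes, c(160000, 150000))
  expect_equal(models$strand, c("+", "-"))

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t150000\t160000\ttx3\t0\t.", bad)
  expect_error(load_gene_models(bad), "strand")
})

test_that("refFlat and GTF dialects load to the same model", {
  rf <- tempfile()
  writeLines(paste(
    "GENE1", "NM_1", "chr1", "-", "450000", "460000",
    "450000", "460000", "1", "450000,", "460000,", sep = "\t"
  ), rf)
  m_rf <- load_gene_models(rf, format = "refFlat")
  expect_equal(m_rf$gene_id, "GENE1")
  expect_equal(m_rf$tss, 460000)
  expect_equal(m_rf$tes, 450000)

  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste(
    "chr1", "test", "transcript", "450001", "460000", ".", "-", ".",
    'gene_id "GENE1"; transcript_id "NM_1";', sep = "\t"
  ), gtf)
  m_gtf <- load_gene_models(gtf)
  expect_equal(m_gtf$tss, m_rf$tss)
  expect_equal(m_gtf$tes, m_rf$tes)
  expect_equal(m_gtf$start, m_rf$start)
})

test_that("transcript selection drops cross-gene TSS/TES collisions", {
  models <- tibble::tibble(
    gene_id = c("A", "B", "C"),
    transcript_id = c("A.1", "B.1", "C.1"),
    chrom = "chr1",
    strand = "+",
    tss = c(1000, 1000, 90000),   # A and B share a TSS
    tes = c(5000, 8000, 99000),
    start = c(1000, 1000, 90000),
    end = c(5000, 8000, 99000)
  )
  kept <- select_unique_transcripts(models)
  expect_equal(kept$gene_id, "C")

  # a single clean transcript passes through unchanged
  single <- models[3, ]
  expect_equal(select_unique_transcripts(single), single)
})

test_that("longest isoform is kept within a gene", {
  models <- tibble::tibble(
    gene_id = "A",
    transcript_id = c("A.1", "A.2"),
    chrom = "chr1",
    strand = "+",
    tss = c(1000, 1000),
    tes = c(11000, 5000),      # 10 kb vs 4 kb isoforms
    start = c(1000, 1000),
    end = c(11000, 5000)
  )
  kept <- select_unique_transcripts(models)
  expect_equal(kept$transcript_id, "A.1")

  # under "any" scope the shared TSS coordinate disqualifies both isoforms
  expect_equal(nrow(select_unique_transcripts(models, "any")), 0)
})

test_that("region partition matches the coordinate conventions", {
  plus <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                         tss = 150000, tes = 160000)
  r <- partition_gene_regions(plus)
  got <- setNames(split(r[c("start", "end")], r$region), levels(r$region))
  expect_equal(unlist(got$TSS), c(start = 148000, end = 152000))
  expect_equal(unlist(got$GENIC), c(start = 152000, end = 159000))
  expect_equal(unlist(got$TES), c(start = 159000, end = 161000))
  expect_equal(unlist(got$DISTAL), c(start = 50000, end = 148000))

  minus <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "-",
                          tss = 160000, tes = 150000)
  r2 <- partition_gene_regions(minus)
  got2 <- setNames(split(r2[c("start", "end")], r2$region), levels(r2$region))
  expect_equal(unlist(got2$TSS), c(start = 158000, end = 162000))
  expect_equal(unlist(got2$DISTAL), c(start = 162000, end = 260000))
  expect_equal(unlist(got2$GENIC), c(start = 151000, end = 158000))
  expect_equal(unlist(got2$TES), c(start = 149000, end = 151000))
})

test_that("short transcripts get an empty gene body", {
  short <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                          tss = 150000, tes = 152500)
  r <- partition_gene_regions(short)
  genic <- r[r$region == "GENIC", ]
  expect_equal(genic$width, 0)
  expect_equal(nrow(assign_bins_to_regions(genic)), 0)
})

test_that("clipping respects chromosome bounds", {
  near_start <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                               tss = 30000, tes = 40000)
  sizes <- tibble::tibble(chrom = "chr1", length = 41000)
  r <- partition_gene_regions(near_start, sizes)
  expect_equal(r$start[r$region == "DISTAL"], 0)
  expect_equal(r$end[r$region == "TES"], 41000)
  expect_true(all(r$start >= 0 & r$end <= 41000))
  expect_error(partition_gene_regions(near_start,
                                      tibble::tibble(chrom = "chrX",
                                                     length = 1e6)),
               "missing")
})

test_that("the four regions tile the gene territory without gaps or overlap", {
  set.seed(41)
  n <- 200
  strand <- sample(c("+", "-"), n, replace = TRUE)
  span <- sample(3100:50000, n, replace = TRUE)
  anchor <- sample(150000:5000000, n, replace = TRUE)
  models <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), chrom = "chr1", strand = strand,
    tss = ifelse(strand == "+", anchor, anchor + span),
    tes = ifelse(strand == "+", anchor + span, anchor)
  )
  r <- partition_gene_regions(models)
  widths <- tidyr::pivot_wider(r[c("gene_id", "region", "width")],
                               names_from = "region",
                               values_from = "width")
  expect_true(all(widths$DISTAL == 98000))
  expect_true(all(widths$TSS == 4000))
  expect_true(all(widths$TES == 2000))
  expect_equal(widths$GENIC,
               span[match(widths$gene_id, models$gene_id)] - 3000)

  by_gene <- split(r, r$gene_id)
  for (g in by_gene[sample(seq_along(by_gene), 25)]) {
    iv <- g[order(g$start), ]
    iv <- iv[iv$width > 0, ]
    expect_true(all(iv$start[-1] == iv$end[-nrow(iv)]))  # abutting, no gaps
    lo <- min(iv$start); hi <- max(iv$end)
    m <- models[models$gene_id == iv$gene_id[1], ]
    if (m$strand == "+") {
      expect_equal(c(lo, hi), c(m$tss - 100000, m$tes + 1000))
    } else {
      expect_equal(c(lo, hi), c(m$tes - 1000, m$tss + 100000))
    }
  }
})

test_that("strand flip mirrors the partition about the transcript", {
  fwd <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                        tss = 500000, tes = 510000)
  rev <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "-",
                        tss = 510000, tes = 500000)
  rf <- partition_gene_regions(fwd)
  rr <- partition_gene_regions(rev)
  # reflect the forward intervals about the transcript midpoint
  mid <- (500000 + 510000) / 2
  reflected_start <- 2 * mid - rf$end
  reflected_end <- 2 * mid - rf$start
  ord <- order(rf$region)
  expect_equal(rr$start[ord], reflected_start[ord])
  expect_equal(rr$end[ord], reflected_end[ord])
})

test_that("bin assignment follows the bin-start-in-region rule", {
  one <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                        region = factor("TSS", levels(factor(c("DISTAL",
                          "TSS", "GENIC", "TES")))), start = 148000,
                        end = 152000, width = 4000)
  bins <- assign_bins_to_regions(one)
  expect_equal(bins$bin, 1480:1519)
  expect_equal(bins$ord, 1:40)

  # brute-force enumeration oracle on an off-grid interval
  frag <- one
  frag$start <- 50; frag$end <- 250
  got <- assign_bins_to_regions(frag)$bin
  all_starts <- 0:5 * 100
  expect_equal(got, all_starts[all_starts >= 50 & all_starts < 250] / 100)
  expect_equal(got, c(1L, 2L))
})

test_that("region bin lists are disjoint and 5'->3' ordered", {
  models <- toy_models()
  r <- partition_gene_regions(models, toy_chrom_sizes())
  bins <- assign_bins_to_regions(r)
  for (g in split(bins, bins$gene_id)) {
    per_region <- split(g$bin, droplevels(g$region))
    expect_equal(anyDuplicated(unlist(per_region)), 0)
  }
  minus <- bins[bins$gene_id == "gB", ]
  tssb <- minus[minus$region == "TSS", ]
  expect_equal(tssb$bin[order(tssb$ord)], sort(tssb$bin, decreasing = TRUE))
})

test_that("region table round-trips through its TSV writer", {
  r <- partition_gene_regions(toy_models(), toy_chrom_sizes())
  path <- tempfile(fileext = ".tsv")
  write_region_table(r, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(r))
  expect_equal(back$start, r$start)
})
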