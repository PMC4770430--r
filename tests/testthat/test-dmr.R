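test_that("per-bin tests report means, fold change and direction", {
  # two bins: clear hyper shift, and all-zero
  a <- rbind(c(0.9, 0.8, 0.7), c(0, 0, 0))
  b <- rbind(c(0.1, 0.3, 0.2), c(0, 0, 0))
  res <- test_region_bins(a, b, dmr_params(fc_pseudocount = 0.1))
  expect_equal(res$mean_a[1], 0.8)
  expect_equal(res$mean_b[1], 0.2)
  expect_equal(res$log2fc[1], log2(0.9 / 0.3))
  expect_equal(res$direction[1], "hyper")
  expect_equal(res$p_value[2], 1)
  expect_equal(res$direction[2], "none")

  res2 <- test_region_bins(rbind(c(0.1, 0.1, 0.1)), rbind(c(0.7, 0.7, 0.7)))
  expect_equal(res2$direction, "hypo")
  expect_error(test_region_bins(rbind(1), rbind(c(1, 2))), "at least 2")
})

test_that("run scanning applies the consecutive-bin rules per region", {
  params <- dmr_params()
  stats <- tibble::tibble(
    bin = 1:5,
    p_value = c(0.2, 0.01, 0.02, 0.04, 0.3),
    mean_a = 0.5, mean_b = 0.1,
    log2fc = log2(0.6 / 0.2),
    direction = "hyper"
  )
  # three consecutive qualifying bins suffice outside the gene body
  dmrs <- scan_runs(stats, "TSS", params)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start_bin, 2L)
  expect_equal(dmrs$end_bin, 4L)
  expect_equal(dmrs$n_bins, 3L)
  expect_equal(dmrs$direction, "hyper")

  # the same run is too short for the gene body (needs five)
  stats4 <- dplyr::mutate(stats, p_value = c(0.01, 0.01, 0.02, 0.04, 0.3))
  expect_equal(nrow(scan_runs(stats4, "GENIC", params)), 0)
  expect_equal(nrow(scan_runs(stats4, "TSS", params)), 1)

  # a qualifying run below the rpm floor in the higher group is discarded
  weak <- dplyr::mutate(stats, mean_a = 0.1, mean_b = 0.01,
                        log2fc = log2(0.2 / 0.11))
  expect_equal(nrow(scan_runs(weak, "TSS", params)), 0)
})

test_that("direction flips break runs and runs never merge across gaps", {
  params <- dmr_params()
  base <- tibble::tibble(
    bin = 1:7,
    p_value = 0.01,
    mean_a = c(0.6, 0.6, 0.6, 0.05, 0.05, 0.05, 0.05),
    mean_b = c(0.05, 0.05, 0.05, 0.6, 0.6, 0.6, 0.6),
    direction = c(rep("hyper", 3), rep("hypo", 4))
  )
  base$log2fc <- log2((base$mean_a + 0.1) / (base$mean_b + 0.1))
  out <- scan_runs(base, "DISTAL", params)
  expect_equal(nrow(out), 2)
  expect_equal(out$direction, c("hyper", "hypo"))
  expect_equal(out$n_bins, c(3L, 4L))

  # a bin-index gap splits an otherwise uniform run
  gapped <- dplyr::mutate(base[base$direction == "hypo", ],
                          bin = c(10L, 11L, 13L, 14L))
  expect_equal(nrow(scan_runs(gapped, "DISTAL", params)), 0)
})

test_that("run scanning equals the exhaustive window oracle", {
  params <- dmr_params()
  set.seed(301)
  for (i in 1:200) {
    stats <- random_bin_stats(sample(5:30, 1), params)
    region <- sample(c("DISTAL", "TSS", "GENIC", "TES"), 1)
    got <- scan_runs(stats, region, params)
    want <- oracle_scan_runs(stats, region, params)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 label = sprintf("case %d (%s)", i, region))
  }
})

test_that("p-threshold relaxation and run-length tightening are monotone", {
  set.seed(302)
  for (i in 1:40) {
    stats <- random_bin_stats(25)
    loose <- scan_runs(stats, "TSS", dmr_params(p_threshold = 0.10))
    strict <- scan_runs(stats, "TSS", dmr_params(p_threshold = 0.05))
    # every strict DMR lies inside some loose DMR
    if (nrow(strict) > 0) {
      covered <- vapply(seq_len(nrow(strict)), function(j) {
        any(loose$start_bin <= strict$start_bin[j] &
              loose$end_bin >= strict$end_bin[j] &
              loose$direction == strict$direction[j])
      }, logical(1))
      expect_true(all(covered))
    }
    # raising the minimum run length can only drop runs, never add them
    longer <- scan_runs(stats, "TSS", dmr_params(min_run_default = 5,
                                                 min_run_genic = 5))
    expect_equal(as.data.frame(longer),
                 as.data.frame(strict[strict$n_bins >= 5, ]))
  }
})

test_that("gene-level calling finds exactly the planted noise-free shift", {
  models <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                           tss = 150000, tes = 160000)
  regions <- partition_gene_regions(models)
  # genic spans bins 1520..1589; plant a 5-bin hyper block at 1530..1534
  bins <- 500:1609
  n_bins <- length(bins)
  counts <- matrix(10, nrow = n_bins, ncol = 8)
  plant <- bins >= 1530 & bins <= 1534
  counts[plant, 1:4] <- 60
  bm <- toy_bin_matrix(counts, bins, groups = rep(c("L", "N"), each = 4),
                       total_reads = rep(1e6, 8))
  tumor <- bm$sample_sheet$sample_id[1:4]
  ctrl <- bm$sample_sheet$sample_id[5:8]

  dmrs <- call_gene_dmrs(bm, regions, tumor, ctrl)
  expect_equal(nrow(dmrs), 1)
  expect_equal(as.character(dmrs$region), "GENIC")
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$start, 153000L)
  expect_equal(dmrs$end, 153500L)
  expect_equal(dmrs$n_bins, 5L)

  # no group difference -> no DMRs
  flat <- toy_bin_matrix(matrix(10, n_bins, 8), bins,
                         groups = rep(c("L", "N"), each = 4),
                         total_reads = rep(1e6, 8))
  expect_equal(nrow(call_gene_dmrs(flat, regions, tumor, ctrl)), 0)

  # short transcript: no genic tests attempted, but the shifted bins now
  # fall in its TES region [151500, 153500) and are still found there
  short <- tibble::tibble(gene_id = "s", chrom = "chr1", strand = "+",
                          tss = 150000, tes = 152500)
  sregions <- partition_gene_regions(short)
  sdmrs <- call_gene_dmrs(bm, sregions, tumor, ctrl)
  expect_false(any(sdmrs$region == "GENIC"))
  expect_equal(as.character(sdmrs$region), "TES")
})

test_that("swapping the groups mirrors every DMR's direction", {
  set.seed(303)
  bins <- 1000:1099
  counts <- matrix(rnbinom(100 * 10, mu = 10, size = 10), 100)
  counts[20:30, 1:5] <- counts[20:30, 1:5] + 60
  bm <- toy_bin_matrix(counts, bins, groups = rep(c("L", "N"), each = 5),
                       total_reads = rep(1e6, 10))
  models <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                           tss = 102000, tes = 112000)
  regions <- partition_gene_regions(models)
  a <- bm$sample_sheet$sample_id[1:5]
  b <- bm$sample_sheet$sample_id[6:10]
  fwd <- call_gene_dmrs(bm, regions, a, b)
  rev <- call_gene_dmrs(bm, regions, b, a)
  expect_equal(nrow(fwd), nrow(rev))
  if (nrow(fwd) > 0) {
    expect_equal(fwd$start, rev$start)
    expect_equal(fwd$end, rev$end)
    expect_equal(fwd$min_p, rev$min_p)
    flip <- c(hyper = "hypo", hypo = "hyper")
    expect_equal(unname(flip[fwd$direction]), rev$direction)
    expect_equal(fwd$run_log2fc, -rev$run_log2fc)
  }
})

test_that("gene region statuses summarize and unite across controls", {
  dmrs <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g3"),
    region = factor(c("TSS", "DISTAL", "DISTAL", "TSS"),
                    levels = c("DISTAL", "TSS", "GENIC", "TES")),
    direction = c("hyper", "hyper", "hypo", "hypo"),
    tumor = "L", control = c("N", "N", "N", "ADJ")
  )
  st <- gene_region_status(dmrs)
  expect_equal(st$status[st$gene_id == "g1"], "hyper")
  expect_equal(st$status[st$gene_id == "g2"], "both")

  full <- gene_region_status(dmrs, gene_ids = c("g1", "g2", "g3", "g4"))
  expect_equal(nrow(full), 4 * 4 * 2)
  expect_true(all(full$status[full$gene_id == "g4"] == "none"))

  uni <- union_across_controls(full)
  # hyper vs N, none vs ADJ -> hyper
  expect_equal(uni$status[uni$gene_id == "g1" & uni$region == "TSS"], "hyper")
  # none vs N, hypo vs ADJ -> hypo
  expect_equal(uni$status[uni$gene_id == "g3" & uni$region == "TSS"], "hypo")
  expect_equal(unique(uni$control), "N|ADJ")

  conflict <- tibble::tibble(
    gene_id = "g", region = "TSS", tumor = "L",
    control = c("N", "ADJ"), status = c("hyper", "hypo")
  )
  expect_equal(union_across_controls(conflict)$status, "both")
})

test_that("DMR-centered profiles average the surrounding window", {
  bins <- 90:119
  counts <- matrix(10, length(bins), 4)
  bm <- toy_bin_matrix(counts, bins, groups = c("N", "N", "L", "L"),
                       total_reads = rep(1e7, 4))
  dmrs <- tibble::tibble(gene_id = "g", chrom = "chr1",
                         start = 10200L, end = 10500L)
  prof <- dmr_mean_profile(dmrs, bm)
  expect_equal(nrow(prof), 2 * 10)   # two groups x ten offsets
  expect_true(all(prof$mean_rpm == 1))
  expect_equal(sort(unique(prof$offset)), seq(-500, 400, by = 100))

  # two DMRs average elementwise; windows beyond coverage contribute zeros
  two <- dplyr::bind_rows(dmrs,
                          tibble::tibble(gene_id = "g2", chrom = "chr1",
                                         start = 50000L, end = 50300L))
  prof2 <- dmr_mean_profile(two, bm)
  expect_true(all(prof2$mean_rpm == 0.5))
  expect_error(dmr_mean_profile(dmrs[0, ], bm), "empty")
})

test_that("DMR BED export carries the score and annotation columns", {
  dmrs <- tibble::tibble(
    gene_id = "g1", region = "TSS", chrom = "chr1", strand = "+",
    start = 1000L, end = 1300L, n_bins = 3L, direction = "hyper",
    min_p = 1e-4, max_p = 0.03, mean_rpm_high = 0.8, run_log2fc = 1.7,
    tumor = "L", control = "N"
  )
  path <- tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, path)
  line <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(line[4], "g1|TSS|L_vs_N")
  expect_equal(as.numeric(line[5]), 40)   # -10 log10(1e-4)
  expect_equal(line[8], "hyper")
})
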