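status_row <- function(gene, region, status, tumor = "L", control = "N") {
  tibble::tibble(gene_id = gene, region = region, tumor = tumor,
                 control = control, status = status)
}

test_that("pattern classification anchors on the TSS state", {
  st <- dplyr::bind_rows(
    status_row("g1", "TSS", "hyper"), status_row("g1", "DISTAL", "hypo"),
    status_row("g2", "TSS", "hypo"), status_row("g2", "GENIC", "hyper"),
    status_row("g2", "TES", "hypo"),
    status_row("g3", "TSS", "none"), status_row("g3", "DISTAL", "hyper"),
    status_row("g4", "TSS", "both"), status_row("g4", "DISTAL", "hyper")
  )
  got <- classify_cdmp(st)
  expect_equal(got$label[got$gene_id == "g1"], "S1D0")
  expect_setequal(got$label[got$gene_id == "g2"], c("S0G1", "S0E0"))
  # no TSS anchor (none/both) -> no labels
  expect_false(any(got$gene_id %in% c("g3", "g4")))
})

test_that("the four classes of one partner region partition the genes", {
  set.seed(71)
  genes <- sprintf("g%03d", 1:120)
  pick <- function() sample(c("hyper", "hypo", "none", "both"), 120,
                            replace = TRUE, prob = c(.35, .35, .2, .1))
  st <- dplyr::bind_rows(
    status_row(genes, "TSS", pick()),
    status_row(genes, "DISTAL", pick())
  )
  got <- classify_cdmp(st)
  d_labels <- c("S1D1", "S1D0", "S0D1", "S0D0")
  sets <- lapply(d_labels, function(l) got$gene_id[got$label == l])
  names(sets) <- d_labels
  all_genes <- unlist(sets)
  expect_equal(anyDuplicated(all_genes), 0)  # pairwise disjoint
})

test_that("exchanging hyper and hypo everywhere mirrors all 12 labels", {
  set.seed(72)
  genes <- sprintf("g%03d", 1:200)
  pick <- function() sample(c("hyper", "hypo", "none"), 200,
                            replace = TRUE)
  st <- dplyr::bind_rows(
    status_row(genes, "TSS", pick()), status_row(genes, "DISTAL", pick()),
    status_row(genes, "GENIC", pick()), status_row(genes, "TES", pick())
  )
  flip <- function(s) dplyr::recode(s, hyper = "hypo", hypo = "hyper")
  st_flipped <- dplyr::mutate(st, status = flip(.data$status))
  fwd <- classify_cdmp(st)
  rev <- classify_cdmp(st_flipped)
  # S<x>P<y> -> S<1-x>P<1-y>
  mirror <- function(lab) {
    paste0("S", 1 - as.integer(substr(lab, 2, 2)),
           substr(lab, 3, 3), 1 - as.integer(substr(lab, 4, 4)))
  }
  fwd_m <- dplyr::mutate(fwd, label = mirror(.data$label)) |>
    dplyr::arrange(gene_id, tumor, control, label)
  expect_equal(as.data.frame(fwd_m), as.data.frame(rev))
  # all 12 labels appear in a sample this size
  expect_equal(sort(unique(as.character(fwd$label))),
               sort(c("S1D1", "S1G1", "S1E1", "S1D0", "S1G0", "S1E0",
                      "S0D1", "S0G1", "S0E1", "S0D0", "S0G0", "S0E0")))
})

test_that("pattern counts use distinct genes and any-tumor unions", {
  asg <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g1", "g2", "g1"),
    tumor = c("L", "L", "L", "L", "L", "H"),
    control = c("N", "N", "N", "ADJ", "ADJ", "N"),
    label = "S1D1"
  )
  counts <- summarize_pattern_counts(asg)
  cell <- function(l, t, c) {
    counts$n_genes[counts$label == l & counts$tumor == t &
                     counts$control == c]
  }
  expect_equal(cell("S1D1", "L", "N"), 3L)
  expect_equal(cell("S1D1", "L", "ADJ"), 2L)
  expect_equal(cell("S1D1", "ANY", "N"), 3L)   # g1 counted once
  expect_equal(cell("S1D1", "H", "N"), 1L)
  expect_equal(cell("S0E0", "L", "N"), 0L)
  expect_equal(nrow(counts[counts$tumor != "ANY", ]), 12 * 3)

  none <- summarize_pattern_counts(asg[0, ])
  expect_true(all(none$n_genes == 0))
})

test_that("hypergeometric overlap matches the worked case and edge cases", {
  u <- sprintf("u%02d", 1:10)
  res <- hypergeom_overlap(u[1:5], u[2:5], u)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)

  disjoint <- hypergeom_overlap(u[1:5], u[6:9], u)
  expect_equal(disjoint$p_value, 1)           # P(X >= 0) = 1
  expect_equal(hypergeom_overlap(u, u, u)$p_value, 1)
  expect_error(hypergeom_overlap(c(u[1], "zz"), u[1:2], u), "subsets")
})

test_that("hypergeometric p matches subset enumeration and is monotone", {
  set.seed(73)
  cases <- expand.grid(m = c(8, 10, 12), a = c(3, 5), b = c(2, 4, 6))
  cases <- cases[cases$a + cases$b <= cases$m, ]  # disjoint construction fits
  for (i in seq_len(nrow(cases))) {
    m <- cases$m[i]; a <- cases$a[i]; b <- cases$b[i]
    u <- sprintf("x%02d", seq_len(m))
    for (k in 0:min(a, b)) {
      set_b <- c(u[seq_len(k)], u[a + seq_len(b - k)])
      res <- hypergeom_overlap(u[seq_len(a)], set_b, u)
      expect_equal(res$overlap, k)
      expect_equal(res$p_value, oracle_hypergeom(m, a, b, k),
                   tolerance = 1e-12)
    }
    ps <- vapply(0:min(a, b), function(k) {
      set_b <- c(u[seq_len(k)], u[a + seq_len(b - k)])
      hypergeom_overlap(u[seq_len(a)], set_b, u)$p_value
    }, numeric(1))
    expect_true(all(diff(ps) < 0))   # decreasing in overlap
  }
})

test_that("pairwise overlap tests cover the non-empty label pairs", {
  sets <- list(S1D1 = c("a", "b", "c"), S1D0 = c("b", "c", "d"),
               S0D1 = character(0), S0D0 = c("e"))
  u <- letters[1:10]
  res <- cdmp_overlap_tests(sets, u)
  expect_equal(nrow(res), 3)   # pairs among the 3 non-empty sets
  row <- res[res$set_a_label == "S1D1" & res$set_b_label == "S1D0", ]
  expect_equal(row$overlap, 2L)
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("group-region mean matrix averages bins and samples", {
  models <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                           tss = 150000, tes = 152500)  # empty genic
  regions <- partition_gene_regions(models)
  bins <- 1480:1519                                    # the TSS region
  counts <- matrix(rep(c(1, 3), 20 * 2), ncol = 2)     # bins alternate 1,3
  bm <- toy_bin_matrix(counts, bins, groups = c("N", "N"),
                       total_reads = c(1e6, 1e6))
  mm <- group_region_mean_matrix(bm, regions)
  expect_equal(mm$mean_rpm[mm$region == "TSS"], 2)
  expect_true(is.na(mm$mean_rpm[mm$region == "GENIC"]))
  expect_equal(nrow(mm), 4)   # one group x four regions
})
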