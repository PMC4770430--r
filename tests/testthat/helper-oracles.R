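# Independent brute-force oracles used to verify the implementation.

# Two-sided rank-sum p by full enumeration of all C(n, n_a) group
# assignments (no ties assumed); doubles the smaller tail, capped at 1.
oracle_rank_sum <- function(a, b) {
  n_a <- length(a)
  vals <- c(a, b)
  ranks <- rank(vals)
  u_of <- function(idx) sum(ranks[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  us <- combn(length(vals), n_a, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Upper-tail hypergeometric p by enumerating every size-b draw from a
# universe of size m with a successes: P(overlap >= k).
oracle_hypergeom <- function(m, a, b, k) {
  draws <- combn(m, b)
  mean(apply(draws, 2, function(d) sum(d <= a) >= k))
}

# DMR run caller by exhaustive window enumeration: every contiguous window
# of qualifying, direction-uniform, gap-free bins that cannot be extended is
# a candidate; candidates are then filtered by run length and the rpm floor.
oracle_scan_runs <- function(results, region, params) {
  res <- results[order(results$bin), , drop = FALSE]
  q <- res$p_value < params$p_threshold &
    abs(res$log2fc) >= params$min_log2fc &
    res$direction != "none"
  n <- nrow(res)
  min_run <- if (region == "GENIC") params$min_run_genic else
    params$min_run_default
  cc <- params$fc_pseudocount
  joins <- function(i, j) {
    q[i] && q[j] && res$direction[i] == res$direction[j] &&
      res$bin[j] == res$bin[i] + 1L
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      idx <- i:j
      if (!all(q[idx])) next
      if (length(unique(res$direction[idx])) != 1) next
      if (j > i && !all(diff(res$bin[idx]) == 1)) next
      if (i > 1 && joins(i - 1, i)) next      # extendable left
      if (j < n && joins(j, j + 1)) next      # extendable right
      run_mean_a <- mean(res$mean_a[idx])
      run_mean_b <- mean(res$mean_b[idx])
      high <- if (res$direction[i] == "hyper") run_mean_a else run_mean_b
      if (length(idx) < min_run || high < params$min_mean_rpm_high) next
      out[[length(out) + 1]] <- tibble::tibble(
        start_bin = res$bin[i], end_bin = res$bin[j],
        n_bins = length(idx), direction = res$direction[i],
        min_p = min(res$p_value[idx]), max_p = max(res$p_value[idx]),
        mean_rpm_high = high,
        run_log2fc = log2((run_mean_a + cc) / (run_mean_b + cc))
      )
    }
  }
  if (length(out) == 0) {
    tibble::tibble(
      start_bin = integer(), end_bin = integer(), n_bins = integer(),
      direction = character(), min_p = numeric(), max_p = numeric(),
      mean_rpm_high = numeric(), run_log2fc = numeric()
    )
  } else {
    dplyr::arrange(dplyr::bind_rows(out), start_bin)
  }
}

# Random per-bin statistics shaped like test_region_bins() output, with the
# log2fc derived from the means exactly as the implementation derives it.
random_bin_stats <- function(n, params = dmr_params()) {
  mean_a <- round(runif(n, 0, 1.2), 2)
  mean_b <- round(runif(n, 0, 1.2), 2)
  same <- runif(n) < 0.15
  mean_b[same] <- mean_a[same]
  cc <- params$fc_pseudocount
  tibble::tibble(
    bin = seq_len(n) + 99L,
    p_value = ifelse(runif(n) < 0.6, runif(n, 1e-4, 0.049),
                     runif(n, 0.05, 1)),
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
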