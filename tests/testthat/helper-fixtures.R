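# Shared fixtures: small maps/panels built in code at test time.

tiny_map <- function(n_chrom = 2, len = 1, n_markers = 10) {
  build_map(n_chrom, len, n_markers, spacing = "uniform")
}

tiny_panel <- function(seed = 1, n_markers = 40, pool_divergence = 0.3) {
  simulate_founders(tiny_map(2, 1, n_markers),
                    pool_divergence = pool_divergence, seed = seed)
}

# independent brute-force re-application of the three QC rules, used as the
# oracle for filter_markers on random fixtures
brute_force_filter <- function(geno, max_miss_m = 0.10, min_div = 0.10,
                               max_miss_l = 0.15) {
  keep_m <- logical(ncol(geno))
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    miss <- mean(is.na(g))
    gg <- g[!is.na(g)]
    div <- if (length(gg) == 0) NA else 1 - sum((table(gg) / length(gg))^2)
    keep_m[j] <- miss <= max_miss_m && !is.na(div) && div >= min_div
  }
  g2 <- geno[, keep_m, drop = FALSE]
  keep_l <- logical(nrow(g2))
  for (i in seq_len(nrow(g2))) keep_l[i] <- mean(is.na(g2[i, ])) <= max_miss_l
  g2[keep_l, , drop = FALSE]
}
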