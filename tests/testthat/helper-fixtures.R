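# Shared fixtures, all generated in code.

# small two-group config for module-level tests: same generative model as
# the full-size benchmark, scaled down for speed
small_config <- function(seed = 1L, missing_rate = 0.10, outlier_rate = 0,
                         p = 120L, n1 = 25L, n2 = 20L, effect_mean = 3) {
  sim_config(p = p, n1 = n1, n2 = n2, up_indices = 1:6,
             down_indices = 31:36, effect_mean = effect_mean,
             missing_rate = missing_rate, outlier_rate = outlier_rate,
             seed = seed)
}

# exact rank-1 matrix with known factors
rank1_matrix <- function(p = 6L, n = 5L, lambda = 3) {
  u <- seq_len(p) / sqrt(sum(seq_len(p)^2))
  v <- rev(seq_len(n)) / sqrt(sum(seq_len(n)^2))
  list(x = lambda * u %*% t(v), u = u, v = v, lambda = lambda)
}

write_temp_csv <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent AUC oracle: probability a random DE score precedes a random
# EE score, ties counted half (brute-force over all pairs)
pairwise_auc <- function(scores, is_de) {
  de <- scores[is_de]
  ee <- scores[!is_de]
  tot <- 0
  for (a in de) tot <- tot + sum(a < ee) + 0.5 * sum(a == ee)
  100 * tot / (length(de) * length(ee))
}
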