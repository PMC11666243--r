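# Independent brute-force oracles used by the tests. These deliberately
# recompute statistics by the most literal route available so they stay
# independent of the package implementation.

# Full O(N) weighted Kolmogorov running sum; ES = value at the point of
# maximum absolute deviation.
oracle_gsea_es <- function(score_abs, hit_positions, weight_p = 1) {
  n <- length(score_abs)
  is_hit <- seq_len(n) %in% hit_positions
  w <- score_abs^weight_p
  nr <- sum(w[is_hit])
  step <- numeric(n)
  step[is_hit] <- w[is_hit] / nr
  step[!is_hit] <- -1 / (n - sum(is_hit))
  running <- cumsum(step)
  running[which.max(abs(running))]
}

# Exact permutation p for class-vs-all K-S by explicit enumeration of
# every label assignment, with D computed from sorted ECDF evaluation.
oracle_ks_exact_p <- function(class_vals, all_vals) {
  d_of <- function(x, y) {
    grid <- sort(c(x, y))
    dx <- vapply(grid, function(g) mean(x <= g), numeric(1))
    dy <- vapply(grid, function(g) mean(y <= g), numeric(1))
    max(abs(dx - dy))
  }
  d_obs <- d_of(class_vals, all_vals)
  combos <- utils::combn(length(all_vals), length(class_vals))
  d_null <- apply(combos, 2, function(i) d_of(all_vals[i], all_vals))
  mean(d_null >= d_obs - 1e-12)
}

# Median-of-ratios size factors computed the literal way: per-guide
# geometric means, per-sample median of count/geomean over all-nonzero
# guides.
oracle_size_factors <- function(mat) {
  keep <- apply(mat, 1, function(r) all(r > 0))
  geo <- apply(mat[keep, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  apply(mat[keep, , drop = FALSE], 2, function(col) median(col / geo))
}

# Benjamini-Hochberg step-up written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Squared Pearson correlation from raw moment sums.
oracle_r2 <- function(x, y) {
  n <- length(x)
  num <- (n * sum(x * y) - sum(x) * sum(y))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num / den
}

# Small screen simulation settings reused across tests.
small_screen_params <- function(...) {
  screen_sim_params(n_genes = 100, guides_per_gene = 5, n_nt_guides = 100,
                    cells_per_guide = 100, reads_per_bin = 2e5, ...)
}
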