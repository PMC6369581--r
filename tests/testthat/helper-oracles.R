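# Independent oracles used to freeze expected values. These deliberately
# use brute force / enumeration, never the package's own code paths.

# Exact two-sided rank-sum p-value by enumerating all C(n, nx) group
# assignments of the combined sample (tie-free inputs only).
oracle_wilcoxon_exact <- function(x, y) {
  v <- c(x, y)
  n <- length(v)
  nx <- length(x)
  r <- rank(v)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Step-up BH by explicit sorted cumulative minimum.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive per-position PWM rescoring of a sequence (plus strand only).
oracle_scan_scores <- function(seq, lo) {
  bases <- strsplit(seq, "")[[1]]
  idx <- match(bases, c("A", "C", "G", "T"))
  L <- nrow(lo)
  vapply(0:(length(idx) - L), function(off) {
    s <- 0
    for (j in seq_len(L)) {
      b <- idx[off + j]
      if (!is.na(b)) s <- s + lo[j, b]
    }
    s
  }, numeric(1))
}

# Exhaustive PWM score distribution over all 4^L words under a background.
oracle_pwm_tail <- function(lo, background, score) {
  L <- nrow(lo)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- apply(words, 1, function(w) sum(lo[cbind(seq_len(L), w)]))
  pr <- apply(words, 1, function(w) prod(background[w]))
  vapply(score, function(s) sum(pr[sc >= s - 1e-9]), numeric(1))
}

# Brute-force Venn partition via per-element membership strings.
oracle_venn_sizes <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  key <- vapply(universe, function(el) {
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(key)
}

# Small fully-matched cohort used by several modules.
tiny_cohort <- function(seed = 42, n = 10, ...) {
  generate_cohort(cohort_config(
    n_probes = 40, n_genes = 30, n_tfs = 5,
    samples_per_phenotype = c(normal = n, I = n, II = n, III = n, IV = n),
    n_planted_pairs = 6, n_flipped_promoters_per_stage = 2,
    seed = seed, ...))
}
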