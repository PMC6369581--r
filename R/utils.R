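# Internal helpers shared across modules.

# Convert a feature-by-sample tibble (first column = feature id) to a
# numeric matrix with feature ids as rownames.
as_feature_matrix <- function(tb, id_col = 1L) {
  stopifnot(is.data.frame(tb))
  ids <- as.character(tb[[id_col]])
  m <- as.matrix(tb[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_as_tibble <- function(m, id_name) {
  tb <- as_tibble(m, rownames = id_name)
  tb
}

# Deterministic per-stage / per-unit seed derivation kept inside 32-bit
# integer range (Lehmer step modulo the Mersenne prime 2^31 - 1).
derive_seed <- function(seed, offset = 0L) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(offset) * 9973) %% 2147483647)
}

check_probabilities <- function(p, what = "p") {
  if (!is.numeric(p)) abort(sprintf("`%s` must be numeric.", what))
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(sprintf("`%s` contains values outside [0, 1].", what))
  }
  invisible(p)
}

check_phenotype_table <- function(phenotypes) {
  if (!is.data.frame(phenotypes) ||
      !all(c("sample_id", "phenotype") %in% names(phenotypes))) {
    abort("`phenotypes` must be a data frame with columns sample_id and phenotype.")
  }
  unknown <- setdiff(unique(as.character(phenotypes$phenotype)),
                     methnet_phenotypes())
  if (length(unknown) > 0) {
    abort(sprintf("Unknown phenotype label(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  invisible(phenotypes)
}

samples_of <- function(phenotypes, phenotype) {
  sort(phenotypes$sample_id[as.character(phenotypes$phenotype) == phenotype])
}

# Rank-based AUROC (Mann-Whitney), midranks for ties. Used by simulations
# and the acceptance surface; NA scores are dropped with their labels.
auroc <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
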