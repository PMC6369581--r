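#' Filter methylation probes by mask and chromosome
#'
#' Removes probes flagged as masked (SNP/repeat/NA overlap) and probes on
#' the sex chromosomes, keeping input order.
#'
#' @param probes Probe annotation tibble with columns `probe_id`, `chrom`,
#'   `position`, and optionally `masked` and `sex_chrom` flags. When the
#'   `sex_chrom` flag is absent it is derived from `chrom`.
#' @return The retained rows of `probes`, order-stable.
#' @export
filter_probes <- function(probes) {
  stopifnot(is.data.frame(probes))
  if (nrow(probes) == 0) return(as_tibble(probes))
  masked <- if ("masked" %in% names(probes)) probes$masked else FALSE
  sexed <- if ("sex_chrom" %in% names(probes)) {
    probes$sex_chrom
  } else {
    rep(FALSE, nrow(probes))
  }
  sexed <- sexed | probes$chrom %in% c("chrX", "chrY", "X", "Y")
  as_tibble(probes[!masked & !sexed, , drop = FALSE])
}

#' Candidate probe-gene pairs by promoter location
#'
#' A probe is a candidate for a gene when both lie on the same chromosome
#' and the probe coordinate is within `half_window` bp of the gene's TSS
#' (inclusive on both boundaries). A probe may map to multiple genes and a
#' gene to multiple probes.
#'
#' @param probes Filtered probe annotation (`probe_id`, `chrom`, `position`).
#' @param genes Gene annotation (`gene_id`, `chrom`, `tss`).
#' @param half_window Promoter half-width in bp (default 2000, the +/-2 kb
#'   promoter definition).
#' @return Tibble `probe_id`, `gene_id`, `chrom`, `position`, `tss`,
#'   `distance` (signed, probe minus TSS).
#' @export
candidate_pairs <- function(probes, genes, half_window = 2000) {
  stopifnot(is.data.frame(probes), is.data.frame(genes))
  if (nrow(probes) > 0 && nrow(genes) > 0 &&
      length(intersect(unique(probes$chrom), unique(genes$chrom))) == 0) {
    abort("Probe and gene chromosome names do not overlap; check naming conventions.")
  }
  inner_join(
    select(probes, "probe_id", "chrom", "position"),
    select(genes, "gene_id", "chrom", "tss"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    mutate(distance = .data$position - .data$tss) |>
    filter(abs(.data$distance) <= half_window) |>
    arrange(.data$probe_id, .data$gene_id)
}

#' Spearman correlation with the closed-form t test
#'
#' Computes the Spearman rank correlation (average ranks for ties) between
#' paired methylation and expression values, the statistic
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, and the two-sided p-value from the
#' Student t distribution with `n - 2` degrees of freedom. A correlation of
#' +/-1 yields `t = +/-Inf` and `p = 0`. A constant input vector makes the
#' correlation undefined; the result is flagged (`r`, `t`, `p` all `NA`)
#' rather than an error, so such candidates can be excluded downstream.
#'
#' @param meth,expr Paired numeric vectors of equal length `n >= 4`.
#' @return One-row tibble with `r`, `t`, `p`, `n`.
#' @examples
#' spearman_t(1:10, 10:1)
#' @export
spearman_t <- function(meth, expr) {
  if (length(meth) != length(expr)) abort("Vectors must have equal length.")
  keep <- !is.na(meth) & !is.na(expr)
  meth <- meth[keep]; expr <- expr[keep]
  n <- length(meth)
  if (n < 4) abort("At least 4 paired observations are required.")
  r <- suppressWarnings(cor(meth, expr, method = "spearman"))
  if (is.na(r)) {
    return(tibble(r = NA_real_, t = NA_real_, p = NA_real_, n = n))
  }
  if (abs(r) >= 1 - 1e-12) {
    return(tibble(r = sign(r), t = sign(r) * Inf, p = 0, n = n))
  }
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  tibble(r = r, t = t_stat, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Input order is preserved; adjusted values are clipped at 1 and monotone
#' non-decreasing in sorted order. Thin validated wrapper over the standard
#' step-up adjustment.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  check_probabilities(pvals, "pvals")
  p.adjust(pvals, method = "BH")
}

#' Confirm probe-gene pairs by negative methylation-expression correlation
#'
#' For each candidate pair and each tumor stage, the Spearman correlation
#' between the probe's beta values and the gene's expression is tested over
#' the samples matched between both data types; p-values are BH-adjusted
#' within each stage across all candidates tested in that stage. A pair is
#' confirmed when in at least one stage the adjusted p-value is below
#' `alpha` and the correlation is negative. The normal phenotype is
#' excluded by default, mirroring cohorts without matched normal samples;
#' set `include_normal = TRUE` for fully matched data.
#'
#' @param candidates Tibble with `probe_id`, `gene_id` (from
#'   [candidate_pairs()]).
#' @param beta Beta-value tibble (`probe_id` + sample columns).
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param phenotypes Tibble `sample_id`, `phenotype`.
#' @param alpha Significance level on the adjusted p-value.
#' @param include_normal Also test the normal phenotype.
#' @param bh_family `"per_stage"` (default) adjusts within each stage;
#'   `"pooled"` adjusts across all stage-candidate tests jointly.
#' @param min_samples Minimum matched samples per stage; stages below it
#'   are skipped with a warning.
#' @return List with `pairs` (tibble `probe_id`, `gene_id`,
#'   `confirming_phenotypes` comma-separated) and `results` (per
#'   stage-candidate correlation results `r`, `n`, `t`, `p`, `p_adj`).
#' @export
confirm_pairs <- function(candidates, beta, expr, phenotypes,
                          alpha = 0.05, include_normal = FALSE,
                          bh_family = c("per_stage", "pooled"),
                          min_samples = 4) {
  bh_family <- match.arg(bh_family)
  check_phenotype_table(phenotypes)
  cand <- distinct(candidates, .data$probe_id, .data$gene_id)
  bm <- as_feature_matrix(beta)
  em <- as_feature_matrix(expr)
  cand <- filter(cand, .data$probe_id %in% rownames(bm),
                 .data$gene_id %in% rownames(em))
  stages <- methnet_stages()
  if (include_normal) stages <- c("normal", stages)

  res <- purrr::map_dfr(stages, function(st) {
    samples <- intersect(samples_of(phenotypes, st),
                         intersect(colnames(bm), colnames(em)))
    if (length(samples) < min_samples) {
      warn(sprintf("Phenotype '%s' has %d matched samples (< %d); skipped.",
                   st, length(samples), min_samples))
      return(tibble())
    }
    # Rank once per involved probe/gene row, then Pearson on ranks.
    bsub <- bm[unique(cand$probe_id), samples, drop = FALSE]
    esub <- em[unique(cand$gene_id), samples, drop = FALSE]
    rank_rows <- function(m) {
      r <- t(apply(m, 1, rank))
      rownames(r) <- rownames(m)
      r
    }
    br <- rank_rows(bsub)
    er <- rank_rows(esub)
    bc <- br - rowMeans(br); ec <- er - rowMeans(er)
    bs <- sqrt(rowSums(bc^2)); es <- sqrt(rowSums(ec^2))
    i <- match(cand$probe_id, rownames(bsub))
    j <- match(cand$gene_id, rownames(esub))
    denom <- bs[i] * es[j]
    r <- ifelse(denom > 0, rowSums(bc[i, , drop = FALSE] *
                                     ec[j, , drop = FALSE]) / denom, NA_real_)
    n <- length(samples)
    t_stat <- ifelse(abs(r) >= 1 - 1e-12, sign(r) * Inf,
                     r * sqrt(n - 2) / sqrt(1 - r^2))
    p <- ifelse(is.infinite(t_stat), 0,
                2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE))
    tibble(probe_id = cand$probe_id, gene_id = cand$gene_id,
           phenotype = st, r = r, n = n, t = t_stat, p = p)
  })
  if (nrow(res) == 0) {
    return(list(pairs = tibble(probe_id = character(0), gene_id = character(0),
                               confirming_phenotypes = character(0)),
                results = res))
  }
  res <- filter(res, !is.na(.data$r))
  res <- if (bh_family == "per_stage") {
    res |> group_by(.data$phenotype) |>
      mutate(p_adj = bh_adjust(.data$p)) |> ungroup()
  } else {
    mutate(res, p_adj = bh_adjust(.data$p))
  }
  confirmed <- res |>
    filter(.data$p_adj < alpha, .data$r < 0) |>
    group_by(.data$probe_id, .data$gene_id) |>
    summarise(confirming_phenotypes = paste(
      methnet_phenotypes()[sort(match(.data$phenotype, methnet_phenotypes()))],
      collapse = ","), .groups = "drop") |>
    arrange(.data$probe_id, .data$gene_id)
  list(pairs = confirmed, results = res)
}
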