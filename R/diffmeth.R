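#' Trim the extremes of a value vector
#'
#' Removes the `floor(frac * n)` smallest and `floor(frac * n)` largest
#' values. Ties are resolved stably: among equal values, lower indices are
#' removed first on each side.
#'
#' @param values Non-empty numeric vector.
#' @param frac Fraction trimmed from each side, in \[0, 0.5).
#' @return The surviving values in their original order.
#' @examples
#' trim_extremes(1:20, 0.1)
#' @export
trim_extremes <- function(values, frac = 0.10) {
  if (length(values) == 0) abort("`values` must be non-empty.")
  if (frac < 0 || frac >= 0.5) abort("`frac` must be in [0, 0.5).")
  values[trim_keep_index(values, frac)]
}

# Logical keep-index of the trim; shared by per-group and pooled scopes.
trim_keep_index <- function(values, frac) {
  n <- length(values)
  k <- floor(frac * n)
  keep <- rep(TRUE, n)
  if (k > 0) {
    low <- order(values, seq_len(n))[seq_len(k)]
    high <- order(-values, seq_len(n))[seq_len(k)]
    keep[c(low, high)] <- FALSE
  }
  keep
}

#' Wilcoxon rank-sum test
#'
#' Two-sided test of equality of distributions. The exact null enumeration
#' is used when the combined sample size is at most `exact_max_n` and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction applies.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max_n Largest combined size for the exact branch.
#' @return One-row tibble with `statistic` (the Mann-Whitney statistic of
#'   `x`), `p`,
#'   and `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 12) {
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  all_values <- c(x, y)
  if (length(unique(all_values)) == 1) {
    return(tibble(statistic = length(x) * length(y) / 2, p = 1,
                  method = "degenerate"))
  }
  ties <- anyDuplicated(all_values) > 0
  use_exact <- !ties && length(all_values) <= exact_max_n
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = use_exact, correct = TRUE)
  )
  p <- ht$p.value
  if (is.na(p)) p <- 1
  tibble(statistic = unname(ht$statistic), p = min(1, p),
         method = if (use_exact) "exact" else "normal")
}

#' Differentially methylated probes for one tumor stage vs normal
#'
#' For each probe, samples of the stage and of the normal phenotype are
#' trimmed by `trim` at each extreme and compared with the Wilcoxon
#' rank-sum test; p-values are BH-adjusted across all tested probes in the
#' stage comparison. A probe is significant when the adjusted p-value is
#' below `alpha` and the absolute trimmed mean difference exceeds
#' `min_diff`.
#'
#' Trimming scope: `"pooled"` (default) removes the extremes of the
#' combined stage + normal sample for the probe, which preserves
#' exchangeability under the null; `"per_group"` trims each group
#' independently (anticonservative under the null, retained for
#' comparison).
#'
#' @param beta Beta-value tibble (`probe_id` + sample columns).
#' @param phenotypes Tibble `sample_id`, `phenotype`.
#' @param stage One of I, II, III, IV.
#' @param alpha Significance level on the adjusted p-value.
#' @param min_diff Minimum absolute trimmed mean difference.
#' @param trim Trim fraction per extreme.
#' @param trim_scope `"pooled"` or `"per_group"`.
#' @return Tibble `probe_id`, `stage`, `delta_mean` (trimmed tumor mean
#'   minus trimmed normal mean), `p`, `p_adj`, `significant`, `direction`
#'   (hyper / hypo / none).
#' @export
differential_probes <- function(beta, phenotypes, stage,
                                alpha = 0.05, min_diff = 0.2, trim = 0.10,
                                trim_scope = c("pooled", "per_group")) {
  trim_scope <- match.arg(trim_scope)
  check_phenotype_table(phenotypes)
  if (!stage %in% methnet_stages()) {
    abort(sprintf("`stage` must be one of %s.",
                  paste(methnet_stages(), collapse = ", ")))
  }
  if (!stage %in% phenotypes$phenotype) {
    abort(sprintf("Stage '%s' has no samples.", stage))
  }
  bm <- as_feature_matrix(beta)
  tumor <- intersect(samples_of(phenotypes, stage), colnames(bm))
  normal <- intersect(samples_of(phenotypes, "normal"), colnames(bm))
  if (length(tumor) == 0 || length(normal) == 0) {
    abort("Both the stage and the normal phenotype need samples in `beta`.")
  }
  one_probe <- function(v) {
    xt <- v[tumor]; xn <- v[normal]
    xt <- xt[!is.na(xt)]; xn <- xn[!is.na(xn)]
    if (trim_scope == "per_group") {
      xt <- trim_extremes(xt, trim)
      xn <- trim_extremes(xn, trim)
    } else {
      nt <- length(xt)
      keep <- trim_keep_index(c(xt, xn), trim)
      xt <- xt[keep[seq_len(nt)]]
      xn <- xn[keep[nt + seq_along(xn)]]
    }
    if (length(xt) < 3 || length(xn) < 3) {
      return(c(NA_real_, NA_real_))
    }
    w <- wilcoxon_rank_sum(xt, xn)
    c(mean(xt) - mean(xn), w$p)
  }
  out <- t(apply(bm, 1, one_probe))
  res <- tibble(probe_id = rownames(bm), stage = stage,
                delta_mean = out[, 1], p = out[, 2])
  res$p_adj <- NA_real_
  tested <- !is.na(res$p)
  res$p_adj[tested] <- bh_adjust(res$p[tested])
  res |>
    mutate(
      significant = !is.na(.data$p_adj) & .data$p_adj < alpha &
        abs(.data$delta_mean) > min_diff,
      direction = dplyr::case_when(
        .data$significant & .data$delta_mean > 0 ~ "hyper",
        .data$significant & .data$delta_mean < 0 ~ "hypo",
        TRUE ~ "none"
      )
    )
}

#' Top differentially methylated genes by trimmed mean difference
#'
#' Maps significant probes to genes through the confirmed pairs and ranks
#' genes by the trimmed mean difference of their most extreme significant
#' probe: one list for the largest positive differences, one for the
#' largest negative. Ties are broken by descending absolute difference,
#' then probe id.
#'
#' @param results Output of [differential_probes()].
#' @param pairs Confirmed probe-gene pairs (`probe_id`, `gene_id`).
#' @param k Maximum list length per direction.
#' @return Tibble `list` ("positive"/"negative"), `rank`, `gene_id`,
#'   `probe_id`, `delta_mean`, `p_adj`.
#' @export
top_differential <- function(results, pairs, k = 20) {
  sig <- results |>
    filter(.data$significant) |>
    inner_join(select(pairs, "probe_id", "gene_id"), by = "probe_id",
               relationship = "many-to-many")
  pick <- function(df, sign_dir) {
    df <- if (sign_dir > 0) filter(df, .data$delta_mean > 0) else
      filter(df, .data$delta_mean < 0)
    df |>
      arrange(dplyr::desc(abs(.data$delta_mean)), .data$probe_id) |>
      group_by(.data$gene_id) |>
      slice_head(n = 1) |>
      ungroup() |>
      arrange(dplyr::desc(abs(.data$delta_mean)), .data$probe_id) |>
      slice_head(n = k) |>
      mutate(rank = row_number())
  }
  bind_rows(
    pick(sig, +1) |> mutate(list = "positive"),
    pick(sig, -1) |> mutate(list = "negative")
  ) |>
    select("list", "rank", "gene_id", "probe_id", "delta_mean", "p_adj")
}

#' Venn partition of differentially methylated genes across stages
#'
#' @param results_list Named list of [differential_probes()] outputs for
#'   stages I-IV.
#' @param pairs Confirmed probe-gene pairs (`probe_id`, `gene_id`).
#' @return List with per-direction Venn partitions (`hyper`, `hypo`), the
#'   underlying gene `sets`, and stage-`exclusive` genes per direction.
#' @export
stage_venn <- function(results_list, pairs) {
  stages <- names(results_list)
  direction_sets <- function(dir) {
    lapply(setNames(stages, stages), function(st) {
      sig <- filter(results_list[[st]], .data$direction == dir)
      sort(unique(inner_join(sig, select(pairs, "probe_id", "gene_id"),
                             by = "probe_id",
                             relationship = "many-to-many")$gene_id))
    })
  }
  hyper_sets <- direction_sets("hyper")
  hypo_sets <- direction_sets("hypo")
  exclusive <- function(sets) {
    purrr::map_dfr(names(sets), function(st) {
      others <- unique(unlist(sets[setdiff(names(sets), st)], use.names = FALSE))
      tibble(stage = st, gene_id = setdiff(sets[[st]], others))
    })
  }
  list(hyper = venn_partition(hyper_sets), hypo = venn_partition(hypo_sets),
       sets = list(hyper = hyper_sets, hypo = hypo_sets),
       exclusive = list(hyper = exclusive(hyper_sets),
                        hypo = exclusive(hypo_sets)))
}
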