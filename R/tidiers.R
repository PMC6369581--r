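#' Tidy a phenotype network into an edge list
#'
#' @param x A `methnet_network`.
#' @param dense Return the dense post-normalization importances instead of
#'   the sparsified weights.
#' @param ... Unused.
#' @return Tibble `phenotype`, `tf`, `target`, `weight` (nonzero rows for
#'   the sparse view, all candidate edges for the dense view).
#' @export
tidy.methnet_network <- function(x, dense = FALSE, ...) {
  w <- if (dense) x$importances else x$weights
  keep <- if (dense) which(x$mask) else which(w > 0)
  tibble(
    phenotype = x$phenotype,
    tf = rownames(w)[((keep - 1) %% nrow(w)) + 1],
    target = colnames(w)[((keep - 1) %/% nrow(w)) + 1],
    weight = w[keep]
  ) |> arrange(dplyr::desc(.data$weight), .data$tf, .data$target)
}

#' One-row summary of a phenotype network
#'
#' @param x A `methnet_network`.
#' @param ... Unused.
#' @export
glance.methnet_network <- function(x, ...) {
  tibble(phenotype = x$phenotype, n_tfs = nrow(x$weights),
         n_targets = ncol(x$weights), n_candidate_edges = sum(x$mask),
         n_edges = sum(x$weights > 0), n_samples = x$n_samples,
         density = x$params$density, gamma = x$params$gamma)
}

#' Tidy a differential network
#'
#' @param x A `methnet_diffnet`.
#' @param ... Unused.
#' @return The differential edge tibble with a `stage` column.
#' @export
tidy.methnet_diffnet <- function(x, ...) {
  mutate(x$edges, stage = x$stage %||% NA_character_, .before = 1)
}

#' One-row summary of a differential network
#'
#' @param x A `methnet_diffnet`.
#' @param ... Unused.
#' @export
glance.methnet_diffnet <- function(x, ...) {
  tibble(stage = x$stage %||% NA_character_, n_edges = nrow(x$edges),
         n_gain = sum(x$edges$direction == "gain"),
         n_loss = sum(x$edges$direction == "loss"),
         n_targets = dplyr::n_distinct(x$edges$target),
         n_retained = sum(x$summaries$retained),
         retained_fraction = mean(x$summaries$retained))
}
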