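# Align two weight matrices on the union of their TFs and targets,
# treating absent edges as weight 0.
align_weights <- function(w_a, w_b) {
  tfs <- sort(union(rownames(w_a), rownames(w_b)))
  targets <- sort(union(colnames(w_a), colnames(w_b)))
  expand <- function(w) {
    out <- matrix(0, length(tfs), length(targets),
                  dimnames = list(tfs, targets))
    out[rownames(w), colnames(w)] <- w
    out
  }
  list(a = expand(w_a), b = expand(w_b))
}

#' Differential edges between a tumor and the normal network
#'
#' Subtracts the normal weight matrix from the tumor weight matrix over the
#' union of their candidate edges, ranks edges by absolute weight
#' difference (descending, ties broken by TF id then target id), and
#' returns the top `k` nonzero-difference edges labeled gain
#' (`delta_w > 0`) or loss.
#'
#' @param net_tumor,net_normal `methnet_network` objects (or bare weight
#'   matrices).
#' @param k Maximum number of edges retained (default 1000).
#' @return Tibble `tf`, `target`, `delta_w`, `direction`, `rank` with
#'   attribute `stage` when `net_tumor` carries a phenotype.
#' @export
differential_edges <- function(net_tumor, net_normal, k = 1000) {
  w_t <- if (inherits(net_tumor, "methnet_network")) net_tumor$weights else net_tumor
  w_n <- if (inherits(net_normal, "methnet_network")) net_normal$weights else net_normal
  al <- align_weights(w_t, w_n)
  delta <- al$a - al$b
  nz <- which(delta != 0)
  if (length(nz) == 0) {
    out <- tibble(tf = character(0), target = character(0),
                  delta_w = numeric(0), direction = character(0),
                  rank = integer(0))
    if (inherits(net_tumor, "methnet_network")) {
      attr(out, "stage") <- net_tumor$phenotype
    }
    return(out)
  }
  tf_id <- rownames(delta)[((nz - 1) %% nrow(delta)) + 1]
  tg_id <- colnames(delta)[((nz - 1) %/% nrow(delta)) + 1]
  d <- delta[nz]
  ord <- order(-abs(d), tf_id, tg_id)
  take <- ord[seq_len(min(k, length(ord)))]
  out <- tibble(
    tf = tf_id[take], target = tg_id[take], delta_w = d[take],
    direction = ifelse(d[take] > 0, "gain", "loss"),
    rank = seq_along(take)
  )
  if (inherits(net_tumor, "methnet_network")) {
    attr(out, "stage") <- net_tumor$phenotype
  }
  out
}

#' In-degree of every target in a sparsified network
#'
#' @param net A `methnet_network` (or weight matrix); in-degree counts
#'   nonzero incoming weights per target.
#' @return Tibble `target`, `in_degree`.
#' @export
in_degrees <- function(net) {
  w <- if (inherits(net, "methnet_network")) net$weights else net
  tibble(target = colnames(w), in_degree = unname(colSums(w > 0)))
}

#' Methylation-consistency summaries for target genes
#'
#' For each target in either network: in-degrees in normal and tumor, the
#' methylation direction of its most significant assigned probe in the
#' stage comparison (smallest adjusted p, ties by largest absolute
#' difference; the raw difference sign when no probe is significant;
#' `"none"` without an assigned probe), and the retention flag. A target is
#' retained when its in-degree increased and its promoter is
#' hypo-methylated, or its in-degree decreased and its promoter is
#' hyper-methylated; equal in-degrees are never retained.
#'
#' @param net_tumor,net_normal `methnet_network` objects.
#' @param diffmeth [differential_probes()] results for the same stage.
#' @param pairs Confirmed probe-gene pairs (`probe_id`, `gene_id`).
#' @return Tibble `target`, `in_deg_normal`, `in_deg_tumor`,
#'   `meth_direction`, `retained`.
#' @export
consistency_filter <- function(net_tumor, net_normal, diffmeth, pairs) {
  deg_t <- in_degrees(net_tumor) |> rename(in_deg_tumor = "in_degree")
  deg_n <- in_degrees(net_normal) |> rename(in_deg_normal = "in_degree")
  targets <- tidyr::replace_na(
    dplyr::full_join(deg_n, deg_t, by = "target"),
    list(in_deg_normal = 0L, in_deg_tumor = 0L)
  )
  probe_dir <- pairs |>
    select("probe_id", target = "gene_id") |>
    inner_join(diffmeth, by = "probe_id", relationship = "many-to-many") |>
    group_by(.data$target) |>
    arrange(.data$p_adj, dplyr::desc(abs(.data$delta_mean)),
            .data$probe_id, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    mutate(meth_direction = dplyr::case_when(
      .data$significant ~ .data$direction,
      .data$delta_mean > 0 ~ "hyper",
      .data$delta_mean < 0 ~ "hypo",
      TRUE ~ "none"
    )) |>
    select("target", "meth_direction")
  targets |>
    left_join(probe_dir, by = "target") |>
    mutate(
      meth_direction = dplyr::coalesce(.data$meth_direction, "none"),
      retained = (.data$in_deg_tumor > .data$in_deg_normal &
                    .data$meth_direction == "hypo") |
        (.data$in_deg_tumor < .data$in_deg_normal &
           .data$meth_direction == "hyper")
    ) |>
    arrange(.data$target)
}

#' Tumor-vs-normal differential network with consistency filtering
#'
#' Composes [consistency_filter()] and [differential_edges()]. With
#' `order = "filter_first"` (default) the weight matrices are restricted to
#' retained targets before the top-`k` ranking; with `"rank_first"` edges
#' are ranked globally and then restricted.
#'
#' @inheritParams consistency_filter
#' @param k Maximum differential edges retained.
#' @param order `"filter_first"` or `"rank_first"`.
#' @return A `methnet_diffnet`: list with `stage`, `edges`, `summaries`
#'   (consistency table), `k`, `order`.
#' @export
differential_network <- function(net_tumor, net_normal, diffmeth, pairs,
                                 k = 1000,
                                 order = c("filter_first", "rank_first")) {
  order <- match.arg(order)
  summaries <- consistency_filter(net_tumor, net_normal, diffmeth, pairs)
  retained <- summaries$target[summaries$retained]
  if (order == "filter_first") {
    sub <- function(w) w[, intersect(colnames(w), retained), drop = FALSE]
    edges <- differential_edges(sub(net_tumor$weights),
                                sub(net_normal$weights), k)
  } else {
    edges <- differential_edges(net_tumor, net_normal, k) |>
      filter(.data$target %in% retained) |>
      mutate(rank = row_number())
  }
  counts <- edges |>
    group_by(.data$target) |>
    summarise(n_gain = sum(.data$direction == "gain"),
              n_loss = sum(.data$direction == "loss"), .groups = "drop")
  summaries <- summaries |>
    left_join(counts, by = "target") |>
    tidyr::replace_na(list(n_gain = 0L, n_loss = 0L))
  structure(list(stage = net_tumor$phenotype, edges = edges,
                 summaries = summaries, k = k, order = order),
            class = "methnet_diffnet")
}

#' @export
print.methnet_diffnet <- function(x, ...) {
  cat(sprintf(
    "<methnet_diffnet> stage %s: %d edges (%d gain / %d loss), %d/%d targets retained\n",
    x$stage %||% "?", nrow(x$edges), sum(x$edges$direction == "gain"),
    sum(x$edges$direction == "loss"), sum(x$summaries$retained),
    nrow(x$summaries)))
  invisible(x)
}

#' Rank target genes by number of gained or lost regulations
#'
#' Counts gains and losses per target over the differential edges
#' (optionally restricted to retained targets) and returns the two top
#' lists plus the subgraph of edges incident to the listed targets.
#'
#' @param edges Differential edge tibble (from [differential_edges()] or a
#'   `methnet_diffnet`'s `edges`).
#' @param retained Optional character vector of retained targets.
#' @param top_n List length per direction.
#' @return List with `gain` and `loss` tibbles (`target`, `n`, `rank`) and
#'   `subgraph` (edges incident to listed targets, with `list` column).
#' @export
rank_targets <- function(edges, retained = NULL, top_n = 10) {
  if (inherits(edges, "methnet_diffnet")) {
    retained <- retained %||% edges$summaries$target[edges$summaries$retained]
    edges <- edges$edges
  }
  if (!is.null(retained)) edges <- filter(edges, .data$target %in% retained)
  top_list <- function(dir) {
    edges |>
      filter(.data$direction == dir) |>
      group_by(.data$target) |>
      summarise(n = dplyr::n(), .groups = "drop") |>
      arrange(dplyr::desc(.data$n), .data$target) |>
      slice_head(n = top_n) |>
      mutate(rank = row_number())
  }
  gain <- top_list("gain")
  loss <- top_list("loss")
  subgraph <- bind_rows(
    edges |> filter(.data$target %in% gain$target) |> mutate(list = "gain"),
    edges |> filter(.data$target %in% loss$target) |> mutate(list = "loss")
  )
  list(gain = gain, loss = loss, subgraph = subgraph)
}

#' Gain/loss counts per stage
#'
#' @param diffnets Named list of `methnet_diffnet` (or differential edge
#'   tibbles), one per stage.
#' @return Tibble `stage`, `gain`, `loss`, `total`; gain + loss partitions
#'   the retained edge set of each stage.
#' @export
gain_loss_table <- function(diffnets) {
  purrr::map_dfr(names(diffnets), function(st) {
    e <- diffnets[[st]]
    if (inherits(e, "methnet_diffnet")) e <- e$edges
    tibble(stage = st,
           gain = sum(e$direction == "gain"),
           loss = sum(e$direction == "loss"),
           total = nrow(e))
  })
}
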