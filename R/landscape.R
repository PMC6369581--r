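#' Per-probe mean beta within one phenotype
#'
#' @param beta Beta-value tibble (`probe_id` + sample columns).
#' @param phenotypes Tibble `sample_id`, `phenotype`.
#' @param phenotype One of normal, I, II, III, IV.
#' @return Tibble `probe_id`, `mean_beta` (NA when all values are missing).
#' @export
phenotype_mean <- function(beta, phenotypes, phenotype) {
  check_phenotype_table(phenotypes)
  if (!phenotype %in% phenotypes$phenotype) {
    abort(sprintf("Phenotype '%s' has no samples.", phenotype))
  }
  bm <- as_feature_matrix(beta)
  samples <- intersect(samples_of(phenotypes, phenotype), colnames(bm))
  m <- rowMeans(bm[, samples, drop = FALSE], na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  tibble(probe_id = rownames(bm), mean_beta = unname(m))
}

#' Classify mean beta into three methylation states
#'
#' Values strictly below `t_low` are unmethylated, strictly above `t_high`
#' fully methylated, and everything in between (boundaries included)
#' hemi-methylated.
#'
#' @param mean_beta Numeric vector in \[0, 1\] (NA propagated).
#' @param t_low,t_high Thresholds with `t_low < t_high`.
#' @return Factor with levels unmethylated, hemi, full.
#' @export
classify_methylation <- function(mean_beta, t_low = 0.25, t_high = 0.75) {
  if (t_low >= t_high) abort("`t_low` must be below `t_high`.")
  check_probabilities(mean_beta, "mean_beta")
  state <- ifelse(is.na(mean_beta), NA_character_,
                  ifelse(mean_beta < t_low, "unmethylated",
                         ifelse(mean_beta > t_high, "full", "hemi")))
  factor(state, levels = c("unmethylated", "hemi", "full"))
}

#' Methylation state of every probe in every phenotype
#'
#' @inheritParams phenotype_mean
#' @inheritParams classify_methylation
#' @return Tibble `probe_id`, `phenotype`, `mean_beta`, `state`.
#' @export
methylation_states <- function(beta, phenotypes, t_low = 0.25, t_high = 0.75) {
  check_phenotype_table(phenotypes)
  present <- intersect(methnet_phenotypes(), unique(phenotypes$phenotype))
  purrr::map_dfr(present, function(ph) {
    phenotype_mean(beta, phenotypes, ph) |>
      mutate(phenotype = ph,
             state = classify_methylation(.data$mean_beta, t_low, t_high)) |>
      select("probe_id", "phenotype", "mean_beta", "state")
  })
}

#' Agreement of methylation states between two phenotypes
#'
#' Fraction of probes assigned the same state in both phenotypes, over the
#' intersection of their non-missing probes.
#'
#' @param states_a,states_b Tibbles `probe_id`, `state` (e.g. slices of
#'   [methylation_states()] output).
#' @return Agreement fraction in \[0, 1\].
#' @export
conservation <- function(states_a, states_b) {
  j <- inner_join(select(states_a, "probe_id", a = "state"),
                  select(states_b, "probe_id", b = "state"),
                  by = "probe_id") |>
    filter(!is.na(.data$a), !is.na(.data$b))
  if (nrow(j) == 0) abort("No shared non-missing probes between the two phenotypes.")
  mean(as.character(j$a) == as.character(j$b))
}

#' Pairwise conservation matrix across phenotypes
#'
#' @param states Output of [methylation_states()].
#' @return Symmetric phenotype x phenotype matrix of agreement fractions
#'   with unit diagonal, class `methnet_conservation`.
#' @export
conservation_matrix <- function(states) {
  phen <- intersect(methnet_phenotypes(), unique(states$phenotype))
  m <- matrix(1, length(phen), length(phen), dimnames = list(phen, phen))
  for (i in seq_along(phen)) {
    for (j in seq_len(i - 1L)) {
      v <- conservation(filter(states, .data$phenotype == phen[i]),
                        filter(states, .data$phenotype == phen[j]))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("methnet_conservation", class(m)))
}

# Membership-pattern partition over named sets (the Venn regions).
venn_partition <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) {
    return(tibble(region = character(0), n = integer(0), items = list()))
  }
  membership <- vapply(names(sets), function(nm) universe %in% sets[[nm]],
                       logical(length(universe)))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = 1)
  key <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  out <- tibble(item = universe, region = key) |>
    group_by(.data$region) |>
    summarise(n = dplyr::n(), items = list(sort(.data$item)), .groups = "drop") |>
    arrange(.data$region)
  out
}

#' Phenotype-exclusive gene sets for a methylation state
#'
#' A gene belongs to a phenotype's set when at least one of its assigned
#' probes has the state of interest in that phenotype. The full Venn
#' partition over the phenotype sets is returned along with the
#' single-phenotype exclusive regions.
#'
#' @param states Output of [methylation_states()].
#' @param pairs Confirmed probe-gene pairs (tibble `probe_id`, `gene_id`).
#' @param state One of `"unmethylated"`, `"hemi"`, `"full"`.
#' @return List with `sets` (named list of gene vectors), `partition`
#'   (tibble `region`, `n`, `items`), and `exclusive` (tibble `phenotype`,
#'   `gene_id` for genes in exactly one phenotype's set).
#' @export
exclusive_sets <- function(states, pairs, state = c("full", "unmethylated", "hemi")) {
  state <- match.arg(state)
  phen <- intersect(methnet_phenotypes(), unique(states$phenotype))
  linked <- inner_join(states, select(pairs, "probe_id", "gene_id"),
                       by = "probe_id", relationship = "many-to-many")
  sets <- lapply(setNames(phen, phen), function(ph) {
    sort(unique(linked$gene_id[linked$phenotype == ph &
                                 !is.na(linked$state) &
                                 as.character(linked$state) == state]))
  })
  part <- venn_partition(sets)
  excl <- purrr::map_dfr(phen, function(ph) {
    others <- unique(unlist(sets[setdiff(phen, ph)], use.names = FALSE))
    tibble(phenotype = ph, gene_id = setdiff(sets[[ph]], others))
  })
  list(sets = sets, partition = part, exclusive = excl)
}
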