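#' Configuration for the synthetic multi-phenotype cohort generator
#'
#' The generator emulates the structure of a tumor-staging methylation +
#' expression study: five phenotypes (normal and tumor stages I-IV), a
#' bimodal beta-value landscape, planted negative promoter
#' methylation-expression couplings, motif-permitted TF-to-target regulation
#' gated by promoter methylation, and stage-specific methylation flips that
#' rewire regulatory edges. Default per-phenotype sample counts
#' (27/37/102/111/25) are typical of archival tumor-staging array cohorts,
#' where mid-stage tumors dominate and normal tissue is scarce.
#'
#' @param n_probes Number of methylation probes (>= `n_genes`; one promoter
#'   probe per gene, the rest intergenic).
#' @param n_genes Number of genes.
#' @param n_tfs Number of transcription factor genes (the first `n_tfs`
#'   genes double as TFs with motifs).
#' @param samples_per_phenotype Named counts for exactly
#'   normal, I, II, III, IV.
#' @param beta_modes Means of the unmethylated and methylated beta modes.
#' @param beta_concentration Concentration of the per-mode Beta distribution
#'   (`shape1 = m * conc`, `shape2 = (1 - m) * conc`).
#' @param p_high Marginal probability that a probe sits in the methylated
#'   mode (drives the ~15% fully methylated landscape).
#' @param coupling_strength Target absolute correlation for planted
#'   probe-gene couplings (in (0, 1)).
#' @param n_planted_pairs Number of genes with a planted negative
#'   methylation-expression coupling.
#' @param n_flipped_promoters_per_stage Number of target-gene promoters whose
#'   methylation mode flips in each tumor stage (rewiring the planted edges
#'   into or out of that stage).
#' @param regulators_per_target Integer range `c(min, max)` of planted TF
#'   regulators per target gene.
#' @param edge_effect_size Absolute regression coefficient of a TF on its
#'   target (sign randomized per edge).
#' @param noise_sd Gaussian noise standard deviation on expression.
#' @param gate_midpoint,gate_width Sigmoid methylation gate on TF terms:
#'   coefficient x `plogis((gate_midpoint - beta) / gate_width)`, so a
#'   methylated promoter (beta near the high mode) silences regulation.
#' @param decoy_motifs_per_target Number of non-regulator TF consensus
#'   sequences embedded in each gene's promoter window. Decoys model
#'   sequence affinity without actual binding: the motif scan reports them
#'   as candidates, but no regulatory signal backs them, so network
#'   inference must separate bound from merely permitted TFs.
#' @param motif_length Length of each TF's motif.
#' @param window_halfwidth Half-width (bp) of the promoter scan window
#'   around each probe; window length is `2 * window_halfwidth + 1`.
#' @param masked_frac,sex_frac Fractions of the intergenic probes flagged as
#'   masked (SNP/repeat overlap) or placed on chrX (both removed by probe
#'   filtering).
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return A `methnet_config` list.
#' @export
cohort_config <- function(n_probes = 500,
                          n_genes = 400,
                          n_tfs = 40,
                          samples_per_phenotype = c(normal = 27, I = 37,
                                                    II = 102, III = 111,
                                                    IV = 25),
                          beta_modes = c(low = 0.1, high = 0.85),
                          beta_concentration = 20,
                          p_high = 0.15,
                          coupling_strength = 0.8,
                          n_planted_pairs = 50,
                          n_flipped_promoters_per_stage = 20,
                          regulators_per_target = c(1, 3),
                          edge_effect_size = 1.0,
                          noise_sd = 0.3,
                          gate_midpoint = 0.5,
                          gate_width = 0.1,
                          decoy_motifs_per_target = 3,
                          motif_length = 8,
                          window_halfwidth = 100,
                          masked_frac = 0.05,
                          sex_frac = 0.02,
                          seed = 1) {
  cfg <- list(
    n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
    n_tfs = as.integer(n_tfs),
    samples_per_phenotype = samples_per_phenotype,
    beta_modes = unname(beta_modes), beta_concentration = beta_concentration,
    p_high = p_high, coupling_strength = coupling_strength,
    n_planted_pairs = as.integer(n_planted_pairs),
    n_flipped_promoters_per_stage = as.integer(n_flipped_promoters_per_stage),
    regulators_per_target = as.integer(regulators_per_target),
    edge_effect_size = edge_effect_size, noise_sd = noise_sd,
    gate_midpoint = gate_midpoint, gate_width = gate_width,
    decoy_motifs_per_target = as.integer(decoy_motifs_per_target),
    motif_length = as.integer(motif_length),
    window_halfwidth = as.integer(window_halfwidth),
    masked_frac = masked_frac, sex_frac = sex_frac,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "methnet_config")
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_probes, cfg$n_genes, cfg$n_tfs, cfg$n_planted_pairs,
              cfg$n_flipped_promoters_per_stage)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("Counts in the cohort configuration must be nonnegative integers.")
  }
  if (cfg$n_probes < cfg$n_genes) {
    abort("`n_probes` must be at least `n_genes` (one promoter probe per gene).")
  }
  if (cfg$n_planted_pairs > cfg$n_genes) {
    abort("`n_planted_pairs` cannot exceed `n_genes`.")
  }
  if (cfg$n_tfs + cfg$n_planted_pairs > cfg$n_genes) {
    abort("`n_tfs` + `n_planted_pairs` cannot exceed `n_genes`.")
  }
  sp <- cfg$samples_per_phenotype
  if (!setequal(names(sp), methnet_phenotypes())) {
    abort("`samples_per_phenotype` must name exactly normal, I, II, III, IV.")
  }
  if (any(sp < 1)) abort("Every phenotype needs at least one sample.")
  if (!(cfg$beta_modes[1] < cfg$beta_modes[2]) ||
      any(cfg$beta_modes < 0) || any(cfg$beta_modes > 1)) {
    abort("`beta_modes` must satisfy 0 <= low < high <= 1.")
  }
  if (cfg$beta_concentration <= 0) abort("`beta_concentration` must be positive.")
  if (cfg$noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (cfg$coupling_strength <= 0 || cfg$coupling_strength >= 1) {
    abort("`coupling_strength` must be in (0, 1).")
  }
  if (cfg$motif_length > 2 * cfg$window_halfwidth + 1) {
    abort("`motif_length` exceeds the promoter scan window.")
  }
  if (length(cfg$regulators_per_target) != 2 ||
      cfg$regulators_per_target[1] < 1 ||
      cfg$regulators_per_target[1] > cfg$regulators_per_target[2]) {
    abort("`regulators_per_target` must be c(min, max) with 1 <= min <= max.")
  }
  invisible(cfg)
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces methylation beta values, expression, probe/gene annotation,
#' promoter window sequences, a motif library, and the planted ground truth
#' (probe-gene couplings, stage-specific differential probes, regulatory
#' edges, and rewired edges).
#'
#' Per-probe beta values are drawn from one of two Beta-distributed modes.
#' For planted probe-gene pairs, gene expression decreases monotonically in
#' the promoter probe's beta with coupling calibrated to
#' `coupling_strength`. Each target gene's expression is a linear
#' combination of its planted TFs' expression with the TF term attenuated
#' multiplicatively by a sigmoid gate of the target's promoter beta, so
#' edges are silenced in phenotypes where the promoter is methylated. Each
#' planted TF's consensus is embedded in the target's promoter window on a
#' random strand.
#'
#' @param config A [cohort_config()].
#' @return A `methnet_cohort` list: `beta` and `expr` tibbles (feature id +
#'   one column per sample), `phenotypes`, `probes`, `genes`, `sequences`
#'   (named character), `motifs` (list of [motif()]), `truth` (list of
#'   tibbles: `planted_pairs`, `planted_diff_probes`, `structural_edges`,
#'   `planted_edges` per phenotype, `rewired_edges`), and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_probes = 40, n_genes = 30, n_tfs = 5,
#'   samples_per_phenotype = c(normal = 8, I = 8, II = 8, III = 8, IV = 8),
#'   n_planted_pairs = 5, n_flipped_promoters_per_stage = 2, seed = 7))
#' dim(cohort$beta)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  phen <- methnet_phenotypes()
  sp <- cfg$samples_per_phenotype[phen]
  sample_ids <- unlist(lapply(phen, function(ph) {
    sprintf("%s_s%03d", ph, seq_len(sp[[ph]]))
  }), use.names = FALSE)
  pheno_tb <- tibble(
    sample_id = sample_ids,
    phenotype = rep(phen, times = sp)
  )
  n_total <- length(sample_ids)

  ng <- cfg$n_genes
  np <- cfg$n_probes
  gene_ids <- if (ng > 0) sprintf("g%04d", seq_len(ng)) else character(0)
  probe_ids <- if (np > 0) sprintf("p%05d", seq_len(np)) else character(0)
  tf_ids <- gene_ids[seq_len(cfg$n_tfs)]

  # Gene annotation: genes laid out 10 kb apart on five autosomes, so each
  # promoter window contains exactly its own gene's probe.
  chroms <- paste0("chr", ((seq_len(ng) - 1) %% 5) + 1)
  within_idx <- stats::ave(seq_len(ng), chroms, FUN = seq_along)
  genes <- tibble(
    gene_id = gene_ids, chrom = chroms,
    tss = as.integer(10000 * within_idx),
    strand = if (ng > 0) sample(c("+", "-"), ng, replace = TRUE) else character(0)
  )

  # Probes: one per promoter (within +/-1.5 kb of the TSS), remainder
  # intergenic at midpoints; a slice of the intergenic probes is flagged
  # masked or moved to chrX to exercise probe filtering.
  n_extra <- np - ng
  promoter_offset <- if (ng > 0) sample(-1500:1500, ng, replace = TRUE) else integer(0)
  host <- if (n_extra > 0) sample(seq_len(max(ng, 1)), n_extra, replace = TRUE) else integer(0)
  probes <- tibble(
    probe_id = probe_ids,
    chrom = c(genes$chrom, genes$chrom[host]),
    position = as.integer(c(
      genes$tss + promoter_offset,
      genes$tss[host] + 5000L +
        (if (n_extra > 0) sample(0:400, n_extra, replace = TRUE) else integer(0))
    )),
    masked = FALSE, sex_chrom = FALSE,
    gene_id = c(gene_ids, rep(NA_character_, n_extra))
  )
  if (n_extra > 0) {
    n_masked <- floor(cfg$masked_frac * n_extra)
    n_sex <- floor(cfg$sex_frac * n_extra)
    extra_rows <- ng + seq_len(n_extra)
    if (n_masked > 0) probes$masked[extra_rows[seq_len(n_masked)]] <- TRUE
    if (n_sex > 0) {
      sex_rows <- extra_rows[n_masked + seq_len(n_sex)]
      probes$chrom[sex_rows] <- "chrX"
      probes$sex_chrom[sex_rows] <- TRUE
    }
  }

  # Roles: TFs, planted-pair genes, regulated targets.
  non_tf <- setdiff(gene_ids, tf_ids)
  pair_genes <- if (cfg$n_planted_pairs > 0) {
    sort(sample(non_tf, cfg$n_planted_pairs))
  } else character(0)
  target_genes <- setdiff(non_tf, pair_genes)

  # Planted structural edges: each target gets 1..k TF regulators with a
  # random coefficient sign.
  edges <- if (length(target_genes) > 0 && cfg$n_tfs > 0) {
    purrr::map_dfr(target_genes, function(tg) {
      kk <- seq(cfg$regulators_per_target[1], cfg$regulators_per_target[2])
      k <- min(if (length(kk) == 1) kk else sample(kk, 1), cfg$n_tfs)
      tibble(tf = sample(tf_ids, k), target = tg,
             sign = sample(c(-1, 1), k, replace = TRUE),
             effect = cfg$edge_effect_size)
    }) |> arrange(.data$tf, .data$target)
  } else {
    tibble(tf = character(0), target = character(0),
           sign = numeric(0), effect = numeric(0))
  }

  # Stage-specific promoter flips on target genes, disjoint across stages;
  # a "gain" target is methylated (edges off) in normal and unmethylated
  # (edges on) in its stage, and conversely for "loss".
  stages <- methnet_stages()
  n_flip <- cfg$n_flipped_promoters_per_stage
  if (4 * n_flip > length(target_genes)) {
    abort("Not enough target genes for the requested promoter flips per stage.")
  }
  flip_pool <- if (n_flip > 0) sample(target_genes, 4 * n_flip) else character(0)
  rewired <- if (n_flip > 0) {
    purrr::map_dfr(seq_along(stages), function(i) {
      g <- flip_pool[(i - 1) * n_flip + seq_len(n_flip)]
      tibble(stage = stages[i], target = g,
             direction = sample(rep_len(c("gain", "loss"), n_flip)))
    })
  } else {
    tibble(stage = character(0), target = character(0), direction = character(0))
  }

  # Per-probe, per-phenotype mode means.
  m_low <- cfg$beta_modes[1]; m_high <- cfg$beta_modes[2]
  base_high <- runif(np) < cfg$p_high
  mode_mean <- matrix(ifelse(base_high, m_high, m_low), nrow = np,
                      ncol = length(phen), dimnames = list(probe_ids, phen))
  probe_of_gene <- setNames(probe_ids[seq_len(ng)], gene_ids)
  for (r in seq_len(nrow(rewired))) {
    pr <- probe_of_gene[[rewired$target[r]]]
    st <- rewired$stage[r]
    if (rewired$direction[r] == "gain") {
      mode_mean[pr, ] <- m_high
      mode_mean[pr, st] <- m_low
    } else {
      mode_mean[pr, ] <- m_low
      mode_mean[pr, st] <- m_high
    }
  }

  # Beta values: Beta(m * conc, (1 - m) * conc) within the assigned mode.
  conc <- cfg$beta_concentration
  beta <- matrix(NA_real_, np, n_total, dimnames = list(probe_ids, sample_ids))
  for (ph in phen) {
    cols <- pheno_tb$sample_id[pheno_tb$phenotype == ph]
    if (np == 0) next
    m <- mode_mean[, ph]
    beta[, cols] <- matrix(
      rbeta(np * length(cols), shape1 = rep(m * conc, times = length(cols)),
            shape2 = rep((1 - m) * conc, times = length(cols))),
      nrow = np
    )
  }

  # Expression.
  expr <- matrix(NA_real_, ng, n_total, dimnames = list(gene_ids, sample_ids))
  if (cfg$n_tfs > 0) {
    expr[tf_ids, ] <- matrix(rnorm(cfg$n_tfs * n_total), cfg$n_tfs)
  }
  rho <- cfg$coupling_strength
  for (g in pair_genes) {
    pr <- probe_of_gene[[g]]
    e <- numeric(n_total)
    for (ph in phen) {
      cols <- which(pheno_tb$phenotype == ph)
      m <- mode_mean[pr, ph]
      sigma_b <- sqrt(m * (1 - m) / (conc + 1))
      cc <- rho * cfg$noise_sd / (sigma_b * sqrt(1 - rho^2))
      e[cols] <- -cc * (beta[pr, cols] - m) + rnorm(length(cols), 0, cfg$noise_sd)
    }
    expr[g, ] <- e
  }
  gate <- function(b) plogis((cfg$gate_midpoint - b) / cfg$gate_width)
  for (g in target_genes) {
    pr <- probe_of_gene[[g]]
    gt <- gate(beta[pr, ])
    eg <- edges[edges$target == g, , drop = FALSE]
    e <- rnorm(n_total, 0, cfg$noise_sd)
    for (r in seq_len(nrow(eg))) {
      e <- e + eg$sign[r] * eg$effect[r] * gt * expr[eg$tf[r], ]
    }
    expr[g, ] <- e
  }

  # Promoter window sequences with planted motif consensus per edge.
  W <- 2 * cfg$window_halfwidth + 1
  sequences <- setNames(random_dna(np, W), probe_ids)
  motifs <- list()
  if (cfg$n_tfs > 0) {
    consensus <- setNames(random_dna(cfg$n_tfs, cfg$motif_length), tf_ids)
    motifs <- lapply(tf_ids, function(tf) {
      cs <- strsplit(consensus[[tf]], "")[[1]]
      pfm <- matrix(0.05, cfg$motif_length, 4,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
      for (i in seq_along(cs)) pfm[i, cs[i]] <- 0.85
      motif(tf, pfm, source = "synthetic")
    })
    names(motifs) <- tf_ids
    embed <- function(probe, tf) {
      off <- sample(0:(W - cfg$motif_length), 1)
      planted <- consensus[[tf]]
      if (sample(c(TRUE, FALSE), 1)) planted <- revcomp_chr(planted)
      s <- sequences[[probe]]
      substr(s, off + 1, off + cfg$motif_length) <- planted
      sequences[[probe]] <<- s
    }
    # Decoy embeddings first: sequence affinity without regulation, so
    # candidate sets carry motif-permitted but unbound TFs, as real
    # promoters do. Planted regulator motifs are embedded afterwards so an
    # overlapping decoy can never erase a true edge's motif.
    if (cfg$decoy_motifs_per_target > 0) {
      for (g in gene_ids) {
        regs <- edges$tf[edges$target == g]
        pool <- setdiff(tf_ids, regs)
        n_dec <- min(cfg$decoy_motifs_per_target, length(pool))
        if (n_dec == 0) next
        for (tf in sample(pool, n_dec)) embed(probe_of_gene[[g]], tf)
      }
    }
    for (r in seq_len(nrow(edges))) {
      embed(probe_of_gene[[edges$target[r]]], edges$tf[r])
    }
  }

  # Ground truth tables.
  planted_pairs <- tibble(probe_id = unname(probe_of_gene[pair_genes]),
                          gene_id = pair_genes)
  planted_diff <- if (nrow(rewired) > 0) {
    tibble(stage = rewired$stage,
           probe_id = unname(probe_of_gene[rewired$target]),
           direction = ifelse(rewired$direction == "gain", "hypo", "hyper"))
  } else {
    tibble(stage = character(0), probe_id = character(0), direction = character(0))
  }
  planted_edges <- purrr::map_dfr(phen, function(ph) {
    if (nrow(edges) == 0) {
      return(tibble(phenotype = character(0), tf = character(0),
                    target = character(0)))
    }
    active <- mode_mean[unname(probe_of_gene[edges$target]), ph] == m_low
    tibble(phenotype = ph, tf = edges$tf[active], target = edges$target[active])
  })
  rewired_edges <- if (nrow(rewired) > 0 && nrow(edges) > 0) {
    inner_join(rewired, edges, by = "target") |>
      select("stage", "tf", "target", "direction") |>
      arrange(.data$stage, .data$tf, .data$target)
  } else {
    tibble(stage = character(0), tf = character(0), target = character(0),
           direction = character(0))
  }

  structure(list(
    beta = matrix_as_tibble(beta, "probe_id"),
    expr = matrix_as_tibble(expr, "gene_id"),
    phenotypes = pheno_tb,
    probes = probes,
    genes = genes,
    sequences = sequences,
    motifs = motifs,
    truth = list(planted_pairs = planted_pairs,
                 planted_diff_probes = planted_diff,
                 structural_edges = edges,
                 planted_edges = planted_edges,
                 rewired_edges = rewired_edges),
    config = cfg
  ), class = "methnet_cohort")
}

#' @export
print.methnet_cohort <- function(x, ...) {
  cat(sprintf(
    "<methnet_cohort> %d probes x %d samples; %d genes (%d TFs); %d planted pairs; %d planted edges\n",
    nrow(x$beta), nrow(x$phenotypes), nrow(x$expr), length(x$motifs),
    nrow(x$truth$planted_pairs), nrow(x$truth$structural_edges)))
  invisible(x)
}

#' All motif-permitted TF x target combinations of a cohort
#'
#' The full grid of TF genes by (non-TF, non-pair) target genes, used as an
#' unrestricted candidate set when benchmarking network inference against
#' the planted edges.
#'
#' @param cohort A `methnet_cohort`.
#' @return Tibble with columns `tf` and `target`.
#' @export
cohort_candidate_grid <- function(cohort) {
  tfs <- names(cohort$motifs)
  targets <- sort(unique(cohort$truth$structural_edges$target))
  tidyr::expand_grid(tf = tfs, target = targets)
}

#' Write a cohort to plain-text files
#'
#' Emits beta and expression matrices as TSV, probe and gene annotation as
#' BED (0-based half-open, flags in extra columns), promoter windows as
#' FASTA, motifs in MEME minimal format, the phenotype table and ground
#' truth as TSV, and the configuration as YAML.
#'
#' @param cohort A `methnet_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(cohort$beta, p("beta.tsv"))
  readr::write_tsv(cohort$expr, p("expression.tsv"))
  readr::write_tsv(cohort$phenotypes, p("phenotypes.tsv"))
  probes_bed <- tibble(
    chrom = cohort$probes$chrom, start = cohort$probes$position,
    end = cohort$probes$position + 1L, name = cohort$probes$probe_id,
    score = 0L, strand = ".",
    masked = as.integer(cohort$probes$masked)
  )
  readr::write_tsv(probes_bed, p("probes.bed"), col_names = FALSE)
  genes_bed <- tibble(
    chrom = cohort$genes$chrom, start = cohort$genes$tss,
    end = cohort$genes$tss + 1L, name = cohort$genes$gene_id,
    score = 0L, strand = cohort$genes$strand
  )
  readr::write_tsv(genes_bed, p("genes.bed"), col_names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(cohort$sequences), p("promoters.fa"))
  write_meme(cohort$motifs, p("motifs.meme"))
  readr::write_tsv(cohort$truth$planted_pairs, p("truth_pairs.tsv"))
  readr::write_tsv(cohort$truth$planted_diff_probes, p("truth_diff_probes.tsv"))
  readr::write_tsv(cohort$truth$structural_edges, p("truth_edges.tsv"))
  readr::write_tsv(cohort$truth$planted_edges, p("truth_active_edges.tsv"))
  readr::write_tsv(cohort$truth$rewired_edges, p("truth_rewired_edges.tsv"))
  cfg <- unclass(cohort$config)
  cfg$samples_per_phenotype <- as.list(cfg$samples_per_phenotype)
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `methnet_cohort`.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("beta.tsv", "expression.tsv", "phenotypes.tsv")) {
    if (!file.exists(p(f))) abort(sprintf("Missing cohort file '%s'.", p(f)))
  }
  spec_chr1 <- readr::cols(.default = readr::col_double(),
                           probe_id = readr::col_character())
  beta <- readr::read_tsv(p("beta.tsv"), col_types = spec_chr1)
  expr <- readr::read_tsv(p("expression.tsv"),
                          col_types = readr::cols(.default = readr::col_double(),
                                                  gene_id = readr::col_character()))
  pheno <- readr::read_tsv(p("phenotypes.tsv"), col_types = "cc")
  probes_bed <- readr::read_tsv(p("probes.bed"),
                                col_names = c("chrom", "start", "end", "name",
                                              "score", "strand", "masked"),
                                col_types = "ciicicl")
  probes <- tibble(probe_id = probes_bed$name, chrom = probes_bed$chrom,
                   position = probes_bed$start,
                   masked = as.logical(probes_bed$masked),
                   sex_chrom = probes_bed$chrom %in% c("chrX", "chrY"))
  genes_bed <- readr::read_tsv(p("genes.bed"),
                               col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                               col_types = "ciicic")
  genes <- tibble(gene_id = genes_bed$name, chrom = genes_bed$chrom,
                  tss = genes_bed$start, strand = genes_bed$strand)
  seqs <- Biostrings::readDNAStringSet(p("promoters.fa"))
  sequences <- setNames(as.character(seqs), names(seqs))
  motifs <- read_meme(p("motifs.meme"))
  truth <- list(
    planted_pairs = readr::read_tsv(p("truth_pairs.tsv"), col_types = "cc"),
    planted_diff_probes = readr::read_tsv(p("truth_diff_probes.tsv"),
                                          col_types = "ccc"),
    structural_edges = readr::read_tsv(p("truth_edges.tsv"), col_types = "ccdd"),
    planted_edges = readr::read_tsv(p("truth_active_edges.tsv"), col_types = "ccc"),
    rewired_edges = readr::read_tsv(p("truth_rewired_edges.tsv"),
                                    col_types = "cccc")
  )
  cfg <- yaml::read_yaml(p("config.yaml"))
  cfg$samples_per_phenotype <- unlist(cfg$samples_per_phenotype)
  structure(list(beta = beta, expr = expr, phenotypes = pheno, probes = probes,
                 genes = genes, sequences = sequences, motifs = motifs,
                 truth = truth, config = structure(cfg, class = "methnet_config")),
            class = "methnet_cohort")
}
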