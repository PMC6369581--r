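#' Default end-to-end pipeline configuration
#'
#' @param out_dir Result directory.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param cohort A [cohort_config()] for the simulated cohort, or `NULL`
#'   with `cohort_dir` pointing at files written by [write_cohort()].
#' @param cohort_dir Optional directory of an existing cohort.
#' @param half_window Promoter half-width for candidate pairs (bp).
#' @param alpha Significance level (pair confirmation and differential
#'   methylation).
#' @param min_diff,trim Differential-methylation effect-size filter and
#'   trim fraction.
#' @param t_low,t_high Methylation-state thresholds.
#' @param p_thresh Motif hit p-value threshold.
#' @param grn A [grn_params()].
#' @param k Differential-network edge count.
#' @param top_n Target list length.
#' @return A `methnet_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, cohort = cohort_config(seed = seed),
                            cohort_dir = NULL, half_window = 2000,
                            alpha = 0.05, min_diff = 0.2, trim = 0.10,
                            t_low = 0.25, t_high = 0.75, p_thresh = 1e-4,
                            grn = grn_params(), k = 1000, top_n = 10) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 cohort_dir = cohort_dir, half_window = half_window,
                 alpha = alpha, min_diff = min_diff, trim = trim,
                 t_low = t_low, t_high = t_high, p_thresh = p_thresh,
                 grn = grn, k = k, top_n = top_n),
            class = "methnet_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the seven stages in dependency order - simulate (or load),
#' assign, landscape, differential methylation, motif scan, network
#' inference, differential networks - writing each stage's outputs under
#' `out_dir` and a JSON manifest recording versions, parameters, seeds and
#' output checksums. Re-running with an identical configuration reproduces
#' identical outputs and checksums.
#'
#' @param config A [pipeline_config()], or a path to a YAML file with the
#'   same fields.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("Configuration file '%s' does not exist.", config))
    }
    raw <- yaml::read_yaml(config)
    cohort_cfg <- if (!is.null(raw$cohort)) {
      raw$cohort$samples_per_phenotype <- unlist(raw$cohort$samples_per_phenotype)
      do.call(cohort_config, raw$cohort)
    } else {
      cohort_config(seed = raw$seed %||% 1)
    }
    grn_cfg <- if (!is.null(raw$grn)) do.call(grn_params, raw$grn) else grn_params()
    keep <- raw[intersect(names(raw), c("out_dir", "seed", "cohort_dir",
                                        "half_window", "alpha", "min_diff",
                                        "trim", "t_low", "t_high", "p_thresh",
                                        "k", "top_n"))]
    config <- do.call(pipeline_config,
                      c(keep, list(cohort = cohort_cfg, grn = grn_cfg)))
  }
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- function(name) {
    d <- file.path(cfg$out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  manifest <- list(package = "methnet",
                   version = as.character(utils::packageVersion("methnet")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed, stages = list())
  written <- character(0)
  log_stage <- function(name, params, files) {
    written <<- c(written, files)
    manifest$stages[[name]] <<- list(params = params,
                                     files = basename(files))
  }

  # 1. cohort --------------------------------------------------------------
  d1 <- stage_dir("01_cohort")
  if (!is.null(cfg$cohort_dir)) {
    required <- c("beta.tsv", "expression.tsv", "phenotypes.tsv",
                  "probes.bed", "genes.bed", "promoters.fa", "motifs.meme")
    for (f in required) {
      path <- file.path(cfg$cohort_dir, f)
      if (!file.exists(path)) {
        abort(sprintf("Pipeline input missing: '%s'.", path))
      }
    }
    cohort <- read_cohort(cfg$cohort_dir)
  } else {
    cohort <- generate_cohort(cfg$cohort)
  }
  write_cohort(cohort, d1)
  log_stage("simulate", list(seed = cohort$config$seed),
            list.files(d1, full.names = TRUE))

  # 2. probe-gene assignment ----------------------------------------------
  d2 <- stage_dir("02_pairs")
  kept <- filter_probes(cohort$probes)
  cand <- candidate_pairs(kept, cohort$genes, cfg$half_window)
  conf <- confirm_pairs(cand, cohort$beta, cohort$expr, cohort$phenotypes,
                        alpha = cfg$alpha)
  readr::write_tsv(conf$pairs, file.path(d2, "pairs.tsv"))
  readr::write_tsv(conf$results, file.path(d2, "correlations.tsv"))
  log_stage("assign", list(half_window = cfg$half_window, alpha = cfg$alpha),
            file.path(d2, c("pairs.tsv", "correlations.tsv")))

  # 3. methylation landscape ----------------------------------------------
  d3 <- stage_dir("03_landscape")
  states <- methylation_states(cohort$beta, cohort$phenotypes,
                               cfg$t_low, cfg$t_high)
  cons <- conservation_matrix(states)
  excl_full <- exclusive_sets(states, conf$pairs, "full")
  readr::write_tsv(states, file.path(d3, "states.tsv"))
  readr::write_tsv(as_tibble(unclass(cons), rownames = "phenotype"),
                   file.path(d3, "conservation.tsv"))
  readr::write_tsv(
    mutate(excl_full$partition,
           items = purrr::map_chr(.data$items, paste, collapse = ",")),
    file.path(d3, "venn_full.tsv"))
  log_stage("landscape", list(t_low = cfg$t_low, t_high = cfg$t_high),
            file.path(d3, c("states.tsv", "conservation.tsv", "venn_full.tsv")))

  # 4. differential methylation -------------------------------------------
  d4 <- stage_dir("04_diffmeth")
  dm <- lapply(setNames(methnet_stages(), methnet_stages()), function(st) {
    differential_probes(cohort$beta, cohort$phenotypes, st,
                        alpha = cfg$alpha, min_diff = cfg$min_diff,
                        trim = cfg$trim)
  })
  dm_files <- character(0)
  for (st in names(dm)) {
    f <- file.path(d4, sprintf("diffmeth_%s.tsv", st))
    readr::write_tsv(dm[[st]], f)
    dm_files <- c(dm_files, f)
  }
  log_stage("diffmeth", list(alpha = cfg$alpha, min_diff = cfg$min_diff,
                             trim = cfg$trim), dm_files)

  # 5. motif scan -----------------------------------------------------------
  d5 <- stage_dir("05_scan")
  scan <- candidate_regulators(cohort$sequences, conf$pairs, cohort$motifs,
                               p_thresh = cfg$p_thresh)
  readr::write_tsv(scan$edges, file.path(d5, "edges_candidate.tsv"))
  readr::write_tsv(scan$hits, file.path(d5, "hits.tsv"))
  log_stage("scan", list(p_thresh = cfg$p_thresh),
            file.path(d5, c("edges_candidate.tsv", "hits.tsv")))

  # 6. network inference ----------------------------------------------------
  d6 <- stage_dir("06_networks")
  cand_edges <- scan$edges
  nets <- list()
  net_files <- character(0)
  for (ph in methnet_phenotypes()) {
    nets[[ph]] <- build_phenotype_network(
      cohort$expr, cohort$phenotypes, ph, cand_edges, cfg$grn,
      seed = derive_seed(cfg$seed, match(ph, methnet_phenotypes())))
    f <- file.path(d6, sprintf("net_%s.tsv", ph))
    readr::write_tsv(tidy(nets[[ph]]), f)
    net_files <- c(net_files, f)
  }
  log_stage("infer", unclass(cfg$grn), net_files)

  # 7. differential networks ------------------------------------------------
  d7 <- stage_dir("07_diffnet")
  diffnets <- list()
  dn_files <- character(0)
  for (st in methnet_stages()) {
    diffnets[[st]] <- differential_network(nets[[st]], nets$normal,
                                           dm[[st]], conf$pairs, k = cfg$k)
    f <- file.path(d7, sprintf("diffnet_%s.tsv", st))
    readr::write_tsv(diffnets[[st]]$edges, f)
    fs <- file.path(d7, sprintf("summaries_%s.tsv", st))
    readr::write_tsv(diffnets[[st]]$summaries, fs)
    rt <- rank_targets(diffnets[[st]], top_n = cfg$top_n)
    ft <- file.path(d7, sprintf("top_targets_%s.tsv", st))
    readr::write_tsv(bind_rows(mutate(rt$gain, list = "gain"),
                               mutate(rt$loss, list = "loss")), ft)
    dn_files <- c(dn_files, f, fs, ft)
  }
  glt <- gain_loss_table(diffnets)
  f_glt <- file.path(d7, "gain_loss_table.tsv")
  readr::write_tsv(glt, f_glt)
  log_stage("diffnet", list(k = cfg$k, top_n = cfg$top_n),
            c(dn_files, f_glt))

  manifest$checksums <- as.list(tools::md5sum(sort(written)))
  names(manifest$checksums) <- substring(names(manifest$checksums),
                                         nchar(cfg$out_dir) + 2)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
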