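test_that("trimming removes floor(frac*n) values from each extreme, stably", {
  expect_length(trim_extremes(rnorm(10), 0.1), 8)
  expect_length(trim_extremes(rnorm(5), 0.1), 5)
  expect_equal(sort(trim_extremes(1:20, 0.1)), 3:18)
  # stable under ties: lowest indices removed first
  v <- c(1, 1, 1, 5, 9, 9, 9)
  got <- trim_extremes(v, 1 / 7)
  expect_equal(got, c(1, 1, 5, 9, 9))
  expect_error(trim_extremes(numeric(0)), "non-empty")
  expect_error(trim_extremes(1:5, 0.5), "frac")
  # frac = 0 is the identity
  expect_equal(trim_extremes(c(3, 1, 2), 0), c(3, 1, 2))
  # output is a sub-multiset of the input
  withr::with_seed(6, {
    for (i in 1:20) {
      v <- sample(1:10, 15, replace = TRUE)
      tr <- trim_extremes(v, 0.2)
      expect_true(all(table(tr) <= table(factor(v, levels = 1:10))[names(table(tr))]))
    }
  })
})

test_that("rank-sum p-values match exact enumeration and behave at the null", {
  got <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(got$p, 1 / 3, tolerance = 1e-12)
  expect_equal(got$method, "exact")
  expect_equal(got$p, oracle_wilcoxon_exact(c(1, 2), c(3, 4)), tolerance = 1e-12)

  # exact branch equals enumeration for all tie-free splits with n <= 10
  withr::with_seed(12, {
    for (n_total in 6:10) {
      v <- sample(seq(0, 1, length.out = 50), n_total)
      for (nx in 2:(n_total - 2)) {
        x <- v[seq_len(nx)]
        y <- v[-seq_len(nx)]
        expect_equal(wilcoxon_rank_sum(x, y)$p, oracle_wilcoxon_exact(x, y),
                     tolerance = 1e-12)
      }
    }
  })

  # identical multisets give p = 1 under the approximation
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 0.9)
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 5))$p, 1)

  # exact and approximate branches agree closely on tie-free cases; the
  # bound 0.0306 is the exhaustively computed worst case over every
  # possible tie-free split with 8 <= n <= 12 (continuity-corrected
  # normal approximation)
  withr::with_seed(13, {
    for (i in 1:40) {
      n_total <- sample(8:12, 1)
      v <- rnorm(n_total)
      nx <- sample(3:(n_total - 3), 1)
      x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
      p_exact <- wilcoxon_rank_sum(x, y, exact_max_n = 12)$p
      p_norm <- wilcoxon_rank_sum(x, y, exact_max_n = 0)$p
      expect_lt(abs(p_exact - p_norm), 0.0306)
    }
  })
})

test_that("a stochastic shift on the methylation scale is detected with high power", {
  withr::with_seed(14, {
    hits <- vapply(1:100, function(i) {
      x <- rnorm(50, mean = 0.5, sd = 0.2)
      y <- rnorm(50, mean = 0.0, sd = 0.2)
      wilcoxon_rank_sum(x, y)$p < 0.01
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("differential probes apply both the significance and effect-size filters", {
  withr::with_seed(15, {
    n <- 30
    samples <- sprintf("s%02d", 1:(2 * n))
    phen <- tibble::tibble(sample_id = samples,
                           phenotype = rep(c("normal", "I"), each = n))
    # p_null: identical; p_small: tiny but real shift (clear p, delta < 0.2);
    # p_big: strong shift
    base <- runif(n, 0.3, 0.5)
    beta <- tibble::tibble(probe_id = c("p_null", "p_small", "p_big"))
    beta[, samples] <- as.data.frame(rbind(
      c(base, base),
      c(base, base + 0.1),
      c(base, pmin(base + 0.45, 1))))
  })
  res <- differential_probes(beta, phen, "I", min_diff = 0.2)
  expect_false(res$significant[res$probe_id == "p_null"])
  small <- res[res$probe_id == "p_small", ]
  expect_lt(small$p_adj, 0.05)        # significant by p...
  expect_false(small$significant)     # ...but fails the |delta| > 0.2 filter
  expect_equal(small$direction, "none")
  big <- res[res$probe_id == "p_big", ]
  expect_true(big$significant)
  expect_equal(big$direction, "hyper")
  expect_gt(big$delta_mean, 0.2)
  expect_error(differential_probes(beta, phen, "IV"), "no samples")
  expect_error(differential_probes(beta, phen, "V"), "stage")
})

test_that("the significant set shrinks as min_diff or alpha tighten", {
  co <- tiny_cohort(seed = 16, n = 20)
  n_sig_d <- vapply(c(0, 0.2, 0.5), function(d) {
    sum(differential_probes(co$beta, co$phenotypes, "I", min_diff = d)$significant)
  }, numeric(1))
  expect_true(all(diff(n_sig_d) <= 0))
  n_sig_a <- vapply(c(0.2, 0.05, 0.001), function(a) {
    sum(differential_probes(co$beta, co$phenotypes, "I", alpha = a)$significant)
  }, numeric(1))
  expect_true(all(diff(n_sig_a) <= 0))
})

test_that("planted differential probes are recovered from the cohort", {
  co <- generate_cohort(cohort_config(
    n_probes = 80, n_genes = 60, n_tfs = 6,
    samples_per_phenotype = c(normal = 30, I = 30, II = 30, III = 30, IV = 30),
    n_planted_pairs = 0, n_flipped_promoters_per_stage = 8, seed = 17))
  res <- differential_probes(co$beta, co$phenotypes, "I")
  truth <- co$truth$planted_diff_probes
  truth_I <- truth[truth$stage == "I", ]
  found <- res[res$significant, ]
  expect_gte(mean(truth_I$probe_id %in% found$probe_id), 0.9)
  # direction labels agree with the planted flip direction
  j <- dplyr::inner_join(truth_I, found, by = "probe_id")
  expect_true(all(j$direction.x == j$direction.y))
})

test_that("top differential gene lists follow the ranking and tie rules", {
  results <- tibble::tibble(
    probe_id = paste0("p", 1:6), stage = "I",
    delta_mean = c(0.5, 0.5, 0.3, -0.4, -0.6, 0.25),
    p = 1e-5, p_adj = 1e-4,
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    direction = c("hyper", "hyper", "hyper", "hypo", "hypo", "none"))
  pairs <- tibble::tibble(probe_id = paste0("p", 1:6),
                          gene_id = c("gB", "gA", "gC", "gD", "gE", "gF"))
  got <- top_differential(results, pairs, k = 2)
  pos <- got[got$list == "positive", ]
  # tie at 0.5 broken by probe_id: p1 (gB) before p2 (gA)
  expect_equal(pos$gene_id, c("gB", "gA"))
  neg <- got[got$list == "negative", ]
  expect_equal(neg$gene_id, c("gE", "gD"))
  # non-significant probes never enter
  expect_false("gF" %in% got$gene_id)
  # matches a brute-force sort on a random fixture
  withr::with_seed(18, {
    rs <- tibble::tibble(
      probe_id = sprintf("q%02d", 1:30), stage = "I",
      delta_mean = round(runif(30, -1, 1), 1), p = 1e-6, p_adj = 1e-5,
      significant = TRUE,
      direction = "hyper")
    prs <- tibble::tibble(probe_id = rs$probe_id,
                          gene_id = sprintf("g%02d", 1:30))
  })
  got2 <- top_differential(rs, prs, k = 10)
  pos2 <- got2[got2$list == "positive", ]
  brute <- rs[rs$delta_mean > 0, ]
  brute <- brute[order(-abs(brute$delta_mean), brute$probe_id), ][1:10, ]
  expect_equal(pos2$probe_id, brute$probe_id)
})

test_that("the cross-stage venn partition matches brute-force set algebra", {
  co <- tiny_cohort(seed = 19, n = 15)
  res <- lapply(setNames(c("I", "II", "III", "IV"), c("I", "II", "III", "IV")),
                function(st) differential_probes(co$beta, co$phenotypes, st))
  pairs <- dplyr::filter(co$probes, !is.na(gene_id)) |>
    dplyr::select(probe_id, gene_id)
  sv <- stage_venn(res, pairs)
  for (dir in c("hyper", "hypo")) {
    sets <- sv$sets[[dir]]
    if (length(unlist(sets)) == 0) next
    brute <- oracle_venn_sizes(sets)
    part <- sv[[dir]]
    expect_equal(sort(setNames(part$n, part$region)), sort(unclass(c(brute))))
    expect_equal(sum(part$n), length(unique(unlist(sets))))
  }
})
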