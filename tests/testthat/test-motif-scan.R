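one_hot_motif <- function(consensus, pseudocount = 1e-9) {
  bases <- strsplit(consensus, "")[[1]]
  pfm <- matrix(0, length(bases), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(bases)) pfm[i, bases[i]] <- 1
  motif(paste0("TF_", consensus), pfm, pseudocount = pseudocount)
}

test_that("log-odds scores follow the closed forms", {
  uniform <- motif("U", matrix(0.25, 3, 4))
  expect_equal(unname(pwm_logodds(uniform)), matrix(0, 3, 4))
  # one-hot column with vanishing pseudocount: 2 bits for the hot base
  oh <- one_hot_motif("ACG")
  lo <- pwm_logodds(oh)
  expect_equal(unname(lo[1, "A"]), 2, tolerance = 1e-6)
  # hand-computed column (0.5, 0.5, 0, 0) with pseudocount 0.01
  m <- motif("H", matrix(c(0.5, 0.5, 0, 0), 1, 4, byrow = TRUE),
             pseudocount = 0.01)
  lo2 <- pwm_logodds(m)
  expect_equal(unname(lo2[1, "A"]), log2(((0.5 + 0.01 * 0.25) / 1.01) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(lo2[1, "G"]), log2(((0 + 0.01 * 0.25) / 1.01) / 0.25),
               tolerance = 1e-12)
  expect_error(pwm_logodds(m, background = c(0, 0.5, 0.25, 0.25)),
               "positive")
})

test_that("window scanning finds the consensus on both strands", {
  oh <- one_hot_motif("ACGTG")
  hits <- scan_window("ACGTG", oh)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$offset, 0)
  expect_equal(best$strand, "+")
  expect_equal(best$score, 10, tolerance = 1e-5)
  # reverse complement scores identically on the minus strand
  rc <- scan_window("CACGT", oh)
  best_rc <- rc[which.max(rc$score), ]
  expect_equal(best_rc$strand, "-")
  expect_equal(best_rc$score, 10, tolerance = 1e-5)
  # strand symmetry on a longer random sequence
  withr::with_seed(23, {
    seq <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                 collapse = "")
  })
  m <- motif("R", matrix(c(6, 2, 1, 1,
                           1, 7, 1, 1,
                           2, 2, 4, 2), 3, 4, byrow = TRUE))
  fwd <- scan_window(seq, m)
  rev <- scan_window(methnet:::revcomp_chr(seq), m)
  expect_equal(max(fwd$score), max(rev$score), tolerance = 1e-12)
  expect_equal(sort(fwd$score), sort(rev$score), tolerance = 1e-12)
  # shorter than the motif: empty hit list
  expect_equal(nrow(scan_window("AC", m)), 0)
})

test_that("scanning agrees with a naive position-by-position rescorer", {
  withr::with_seed(24, {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
  })
  m <- motif("R", matrix(c(5, 3, 1, 1,
                           1, 1, 6, 2,
                           3, 3, 3, 1,
                           1, 8, 1, 0.5), 4, 4, byrow = TRUE))
  lo <- pwm_logodds(m)
  got <- scan_window(seq, m, both_strands = FALSE)
  expect_equal(got$score, oracle_scan_scores(seq, lo), tolerance = 1e-12)
})

test_that("DP p-values match exhaustive enumeration for short motifs", {
  # one-hot L = 3: p(max) = (1/4)^3
  oh <- one_hot_motif("ACG")
  lo <- pwm_logodds(oh)
  dist <- pwm_score_distribution(lo)
  expect_equal(pwm_pvalue(sum(apply(lo, 1, max)), dist), 0.015625,
               tolerance = 1e-9)
  # minimum possible score has p = 1
  expect_equal(pwm_pvalue(sum(apply(lo, 1, min)), dist), 1)
  expect_error(pwm_score_distribution(lo, granularity = 0), "granularity")

  # random motifs of length <= 6: DP agrees with 4^L enumeration within
  # the discretization tolerance
  withr::with_seed(25, {
    for (L in c(2, 4, 6)) {
      pfm <- matrix(stats::rgamma(L * 4, 1) + 0.05, L, 4)
      m <- motif("X", pfm)
      lo <- pwm_logodds(m)
      g <- 1e-3
      dist <- pwm_score_distribution(lo, granularity = g)
      words_scores <- {
        words <- as.matrix(expand.grid(rep(list(1:4), L)))
        apply(words, 1, function(w) sum(lo[cbind(seq_len(L), w)]))
      }
      probe_scores <- quantile(words_scores, c(0, 0.25, 0.5, 0.9, 0.99, 1))
      p_dp <- pwm_pvalue(probe_scores, dist)
      upper <- oracle_pwm_tail(lo, rep(0.25, 4), probe_scores - 2 * g * L)
      lower <- oracle_pwm_tail(lo, rep(0.25, 4), probe_scores + 2 * g * L)
      expect_true(all(p_dp <= upper + 1e-12))
      expect_true(all(p_dp >= lower - 1e-12))
    }
  })
})

test_that("p-values are monotone non-increasing in the score", {
  withr::with_seed(26, {
    pfm <- matrix(stats::rgamma(8 * 4, 1) + 0.05, 8, 4)
  })
  m <- motif("M", pfm)
  lo <- pwm_logodds(m)
  dist <- pwm_score_distribution(lo)
  s <- seq(sum(apply(lo, 1, min)), sum(apply(lo, 1, max)), length.out = 200)
  p <- pwm_pvalue(s, dist)
  expect_true(all(diff(p) <= 1e-15))
  expect_true(all(p > 0 & p <= 1))
})

test_that("candidate regulators require a sub-threshold hit at an assigned probe", {
  co <- tiny_cohort(seed = 27)
  pairs <- dplyr::filter(co$probes, !is.na(gene_id)) |>
    dplyr::select(probe_id, gene_id)
  got <- suppressWarnings(candidate_regulators(co$sequences, pairs, co$motifs))
  truth <- paste(co$truth$structural_edges$tf, co$truth$structural_edges$target)
  found <- paste(got$edges$tf, got$edges$target)
  # nearly all planted edges carry their embedded consensus
  expect_gte(mean(truth %in% found), 0.9)
  # determinism
  got2 <- suppressWarnings(candidate_regulators(co$sequences, pairs, co$motifs))
  expect_identical(got, got2)
  # gene with the motif at only one of two probes still gets the edge
  two_probe_pairs <- dplyr::bind_rows(
    pairs[pairs$gene_id == pairs$gene_id[1], ],
    tibble::tibble(probe_id = "scrambled", gene_id = pairs$gene_id[1]))
  seqs <- c(co$sequences,
            scrambled = paste(rep("A", 201), collapse = ""))
  got3 <- suppressWarnings(
    candidate_regulators(seqs, two_probe_pairs, co$motifs))
  edges_first <- got$edges[got$edges$target == pairs$gene_id[1], ]
  expect_true(all(paste(edges_first$tf, edges_first$target) %in%
                    paste(got3$edges$tf, got3$edges$target)))
  # probes without sequences are skipped with a warning
  expect_warning(
    candidate_regulators(co$sequences[-1], pairs, co$motifs[1]),
    "no window sequence")
})

test_that("scrambled windows produce few false candidate edges", {
  withr::with_seed(28, {
    n_false <- vapply(1:20, function(i) {
      seqs <- setNames(
        vapply(1:30, function(j) paste(sample(c("A", "C", "G", "T"), 201,
                                              replace = TRUE), collapse = ""),
               character(1)),
        sprintf("pr%02d", 1:30))
      pairs <- tibble::tibble(probe_id = names(seqs),
                              gene_id = sprintf("g%02d", 1:30))
      pfm <- matrix(0.05, 8, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
      cons <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
      for (k in 1:8) pfm[k, cons[k]] <- 0.85
      m <- motif("F", pfm)
      nrow(candidate_regulators(seqs, pairs, list(m))$edges)
    }, numeric(1))
  })
  # expected false edges per run: <= 30 windows * 2*194 positions * 1e-4
  # ~ 1.2; the observed mean should be of that order, not systematically
  # larger
  expect_lte(mean(n_false), 2.5)
})

test_that("MEME round-trip preserves motifs", {
  co <- tiny_cohort(seed = 29)
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(co$motifs, path)
  back <- read_meme(path)
  expect_equal(names(back), names(co$motifs))
  for (nm in names(back)) {
    expect_equal(back[[nm]]$pfm, co$motifs[[nm]]$pfm, tolerance = 1e-5)
  }
})
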