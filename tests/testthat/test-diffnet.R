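toy_net <- function(w, phenotype = "I") {
  structure(list(phenotype = phenotype, weights = w, importances = w,
                 mask = w >= 0, params = grn_params(), seed = 1,
                 n_samples = 10),
            class = "methnet_network")
}

test_that("differential edges rank, label, and clip per the rules", {
  w_t <- matrix(c(0.9, 0, 0, 0.1), 2, 2,
                dimnames = list(c("tfA", "tfB"), c("t1", "t2")))
  w_n <- matrix(c(0.1, 0, 0, 0.9), 2, 2,
                dimnames = list(c("tfA", "tfB"), c("t1", "t2")))
  got <- differential_edges(w_t, w_n, k = 2)
  expect_equal(nrow(got), 2)
  # equal |delta| = 0.8: gain (tfA, t1) ranked first by tie-break
  expect_equal(got$tf, c("tfA", "tfB"))
  expect_equal(got$delta_w, c(0.8, -0.8))
  expect_equal(got$direction, c("gain", "loss"))
  expect_equal(got$rank, c(1, 2))
  # identical networks: empty differential set
  expect_equal(nrow(differential_edges(w_t, w_t, k = 10)), 0)
  # k larger than the nonzero-delta count returns them all
  expect_equal(nrow(differential_edges(w_t, w_n, k = 100)), 2)
})

test_that("differential edge selection returns exactly k when enough deltas exist", {
  withr::with_seed(51, {
    w_t <- matrix(runif(60 * 40), 60, 40,
                  dimnames = list(sprintf("tf%02d", 1:60), sprintf("t%02d", 1:40)))
    w_n <- matrix(runif(60 * 40), 60, 40, dimnames = dimnames(w_t))
  })
  expect_gt(sum(w_t != w_n), 1000)
  got <- differential_edges(w_t, w_n, k = 1000)
  expect_equal(nrow(got), 1000)
  expect_equal(got$rank, 1:1000)
  # ranking is by |delta| descending
  expect_true(all(diff(abs(got$delta_w)) <= 1e-12))
  # gain + loss partitions the retained set
  expect_equal(sum(got$direction == "gain") + sum(got$direction == "loss"),
               1000)
})

test_that("swapping tumor and normal swaps gain and loss and preserves ranks", {
  withr::with_seed(52, {
    w_a <- matrix(runif(25), 5, 5,
                  dimnames = list(paste0("tf", 1:5), paste0("t", 1:5)))
    w_b <- matrix(runif(25), 5, 5, dimnames = dimnames(w_a))
  })
  fwd <- differential_edges(w_a, w_b, k = 25)
  bwd <- differential_edges(w_b, w_a, k = 25)
  expect_equal(fwd$tf, bwd$tf)
  expect_equal(fwd$target, bwd$target)
  expect_equal(fwd$rank, bwd$rank)
  expect_equal(fwd$delta_w, -bwd$delta_w)
  expect_equal(fwd$direction == "gain", bwd$direction == "loss")
})

test_that("in-degrees count nonzero incoming edges", {
  w <- matrix(0, 3, 3, dimnames = list(paste0("tf", 1:3), paste0("t", 1:3)))
  expect_equal(in_degrees(w)$in_degree, c(0, 0, 0))
  w["tf1", "t1"] <- 0.5; w["tf2", "t1"] <- 0.2; w["tf3", "t1"] <- 0.1
  w["tf1", "t3"] <- 0.4
  got <- in_degrees(w)
  expect_equal(got$in_degree[got$target == "t1"], 3)
  expect_equal(got$in_degree[got$target == "t2"], 0)
  # brute-force recount from the edge list
  edges <- which(w > 0)
  brute <- table(colnames(w)[((edges - 1) %/% nrow(w)) + 1])
  expect_equal(got$in_degree[got$target == "t3"], unname(brute["t3"]))
})

test_that("the consistency filter applies the in-degree/methylation rule", {
  w_n <- matrix(0, 8, 3, dimnames = list(sprintf("tf%d", 1:8),
                                         c("gUp", "gDown", "gFlat")))
  w_t <- w_n
  w_n[1:5, "gUp"] <- 0.5; w_t[1:8, "gUp"] <- 0.5       # 5 -> 8
  w_n[1:5, "gDown"] <- 0.5; w_t[1:2, "gDown"] <- 0.5   # 5 -> 2
  w_n[1:4, "gFlat"] <- 0.5; w_t[5:8, "gFlat"] <- 0.5   # 4 -> 4
  dm <- tibble::tibble(
    probe_id = c("pUp", "pDown", "pFlat"), stage = "I",
    delta_mean = c(-0.5, 0.6, -0.4), p = 1e-6, p_adj = 1e-5,
    significant = TRUE, direction = c("hypo", "hyper", "hypo"))
  pairs <- tibble::tibble(probe_id = c("pUp", "pDown", "pFlat"),
                          gene_id = c("gUp", "gDown", "gFlat"))
  got <- consistency_filter(toy_net(w_t), toy_net(w_n, "normal"), dm, pairs)
  expect_true(got$retained[got$target == "gUp"])      # up + hypo
  expect_true(got$retained[got$target == "gDown"])    # down + hyper
  expect_false(got$retained[got$target == "gFlat"])   # equal in-degree
  # reversed methylation direction discards the in-degree-increase gene
  dm2 <- dplyr::mutate(dm, direction = c("hyper", "hypo", "hypo"),
                       delta_mean = -delta_mean)
  got2 <- consistency_filter(toy_net(w_t), toy_net(w_n, "normal"), dm2, pairs)
  expect_false(got2$retained[got2$target == "gUp"])
  # no assigned probe: meth_direction none, never retained
  got3 <- consistency_filter(toy_net(w_t), toy_net(w_n, "normal"), dm,
                             pairs[0, ])
  expect_true(all(got3$meth_direction == "none"))
  expect_false(any(got3$retained))
  # most significant probe wins for multi-probe targets
  dm4 <- tibble::tibble(
    probe_id = c("pA", "pB"), stage = "I",
    delta_mean = c(-0.5, 0.6), p = c(1e-8, 1e-3), p_adj = c(1e-7, 1e-2),
    significant = c(TRUE, TRUE), direction = c("hypo", "hyper"))
  pairs4 <- tibble::tibble(probe_id = c("pA", "pB"), gene_id = c("gUp", "gUp"))
  got4 <- consistency_filter(toy_net(w_t), toy_net(w_n, "normal"), dm4, pairs4)
  expect_equal(got4$meth_direction[got4$target == "gUp"], "hypo")
})

test_that("target ranking counts gains and losses with deterministic ties", {
  edges <- tibble::tibble(
    tf = c("a", "b", "c", "d", "e", "f", "g"),
    target = c("t1", "t1", "t1", "t1", "t2", "t3", "t3"),
    delta_w = c(0.9, 0.8, 0.7, 0.6, 0.5, -0.4, -0.3),
    direction = c("gain", "gain", "gain", "gain", "gain", "loss", "loss"),
    rank = 1:7)
  got <- rank_targets(edges, top_n = 2)
  expect_equal(got$gain$target[1], "t1")
  expect_equal(got$gain$n[1], 4)
  expect_equal(got$loss$target[1], "t3")
  # tie on count ordered by target id
  edges2 <- dplyr::mutate(edges, target = c("tB", "tB", "tB", "tA", "tA", "tA", "x"))
  got2 <- rank_targets(dplyr::filter(edges2, direction == "gain"), top_n = 5)
  counts <- table(edges2$target[edges2$direction == "gain"])
  expect_equal(got2$gain$target[1], "tB")   # 3 gains beats 2
  expect_equal(got2$gain$n, as.integer(sort(counts, decreasing = TRUE)))
  # subgraph holds exactly the edges of the listed targets
  expect_setequal(got$subgraph$target[got$subgraph$list == "gain"],
                  c("t1", "t2"))
})

test_that("gain/loss table partitions every differential network", {
  stages <- c("I", "II", "III", "IV")
  withr::with_seed(53, {
    nets <- lapply(setNames(stages, stages), function(st) {
      w_t <- matrix(runif(36), 6, 6,
                    dimnames = list(paste0("tf", 1:6), paste0("t", 1:6)))
      w_n <- matrix(runif(36), 6, 6, dimnames = dimnames(w_t))
      differential_edges(w_t, w_n, k = 20)
    })
  })
  glt <- gain_loss_table(nets)
  expect_equal(glt$gain + glt$loss, glt$total)
  expect_equal(glt$total, vapply(nets, nrow, numeric(1), USE.NAMES = FALSE))
  # all tumor weights >= normal implies zero losses
  w_hi <- matrix(2, 3, 3, dimnames = list(paste0("tf", 1:3), paste0("t", 1:3)))
  w_lo <- matrix(1, 3, 3, dimnames = dimnames(w_hi))
  glt2 <- gain_loss_table(list(I = differential_edges(w_hi, w_lo, k = 9)))
  expect_equal(glt2$loss, 0)
  expect_equal(glt2$gain, 9)
})
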