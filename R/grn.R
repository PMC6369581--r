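#' Parameters for per-phenotype network inference
#'
#' @param n_trees Trees per forest.
#' @param gamma Guide strength in \[0, 1\]: pass-2 split gains on feature
#'   `f` are scaled by `(1 - gamma) + gamma * imp0[f] / max(imp0)`, where
#'   `imp0` are the importances of an unguided pass-1 forest. `gamma = 0`
#'   (or `guided = FALSE`) gives a plain ensemble.
#' @param q Norm order for the per-target normalization.
#' @param density Fraction of candidate edges retained by the sparsity
#'   refinement, in (0, 1\]. Encodes the analyst's prior on true network
#'   density; small for genome-scale candidate sets, larger when the
#'   candidate set is already heavily motif-restricted.
#' @param min_samples_leaf Minimum terminal-node size.
#' @param guided Use the two-pass guided regularization.
#' @param q_norm_scope Scope of the q-norm normalization; see
#'   [q_normalize()].
#' @return A `methnet_grn_params` list.
#' @export
grn_params <- function(n_trees = 500, gamma = 0.5, q = 2, density = 0.05,
                       min_samples_leaf = 2, guided = TRUE,
                       q_norm_scope = c("global", "per_target")) {
  q_norm_scope <- match.arg(q_norm_scope)
  if (gamma < 0 || gamma > 1) abort("`gamma` must be in [0, 1].")
  if (q <= 0) abort("`q` must be positive.")
  if (density <= 0 || density > 1) abort("`density` must be in (0, 1].")
  if (n_trees < 1 || min_samples_leaf < 1) {
    abort("`n_trees` and `min_samples_leaf` must be positive.")
  }
  structure(list(n_trees = as.integer(n_trees), gamma = gamma, q = q,
                 density = density,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 guided = isTRUE(guided), q_norm_scope = q_norm_scope),
            class = "methnet_grn_params")
}

#' Guided tree-ensemble importances for one target gene
#'
#' Two-pass procedure: a baseline random forest regression of the target
#' on its candidate TFs collects per-feature impurity importances `imp0`;
#' a second, guided forest penalizes the split gain of feature `f` by
#' `(1 - gamma) + gamma * imp0[f] / max(imp0)`. Importances of the guided
#' forest (total impurity reduction, clipped at 0) are normalized to sum 1.
#'
#' @param y Target expression over samples.
#' @param x Samples x candidate-TF matrix (column names are TF ids).
#' @param params A [grn_params()].
#' @param seed Integer seed (both passes are deterministic given it).
#' @return Named nonnegative importance vector over `colnames(x)` (raw
#'   total impurity reduction; normalization is applied across targets by
#'   [q_normalize()]); all zeros for a zero-variance target, length 0
#'   without candidates.
#' @export
fit_target <- function(y, x, params = grn_params(), seed = 1) {
  if (is.null(dim(x))) x <- as.matrix(x)
  if (ncol(x) == 0) return(setNames(numeric(0), character(0)))
  tfs <- colnames(x)
  zero <- setNames(numeric(ncol(x)), tfs)
  if (length(y) < 4 || var(y) == 0) return(zero)
  df <- as.data.frame(x)
  safe <- sprintf("f%04d", seq_len(ncol(x)))
  names(df) <- safe
  df$.y <- y
  base_fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = params$n_trees, importance = "impurity",
    min.bucket = params$min_samples_leaf,
    num.threads = 1, seed = seed, verbose = FALSE
  )
  imp0 <- pmax(base_fit$variable.importance[safe], 0)
  imp <- imp0
  if (params$guided && params$gamma > 0 && max(imp0) > 0) {
    reg <- (1 - params$gamma) + params$gamma * imp0 / max(imp0)
    guided_fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = params$n_trees, importance = "impurity",
      min.bucket = params$min_samples_leaf,
      regularization.factor = unname(reg), regularization.usedepth = FALSE,
      num.threads = 1, seed = seed, verbose = FALSE
    )
    imp <- pmax(guided_fit$variable.importance[safe], 0)
  }
  setNames(unname(imp), tfs)
}

#' q-norm normalization of a weight matrix
#'
#' Reduces scale bias between per-target regressions. With
#' `scope = "global"` (default) the whole matrix is divided by its q-norm
#' over all entries, which calibrates networks against each other while
#' preserving the relative magnitude of well-fit versus poorly-fit
#' targets - the signal the gain/loss analysis rests on, since a
#' methylation-silenced target's regression reduces far less variance than
#' an active one. With `scope = "per_target"` each target's column is
#' rescaled to unit q-norm (every target contributes equally, at the cost
#' of erasing fit-quality differences). All-zero vectors are left
#' unchanged; both scopes are idempotent.
#'
#' @param weights Nonnegative TF x target matrix.
#' @param q Norm order (> 0).
#' @param scope `"global"` or `"per_target"`.
#' @return Matrix of the same shape.
#' @export
q_normalize <- function(weights, q = 2, scope = c("global", "per_target")) {
  scope <- match.arg(scope)
  if (q <= 0) abort("`q` must be positive.")
  if (any(weights < 0, na.rm = TRUE)) abort("Importances must be nonnegative.")
  if (scope == "global") {
    nrm <- sum(abs(weights)^q)^(1 / q)
    if (nrm > 0) weights <- weights / nrm
    return(weights)
  }
  norms <- apply(weights, 2, function(w) sum(abs(w)^q)^(1 / q))
  nz <- norms > 0
  weights[, nz] <- sweep(weights[, nz, drop = FALSE], 2, norms[nz], "/")
  weights
}

#' Global sparsity refinement of a weight matrix
#'
#' Retains the top `ceiling(density * n_candidate_edges)` candidate edges
#' by weight and zeroes the rest. Ties are broken deterministically by
#' (TF id, target id) lexicographic order.
#'
#' @param weights TF x target weight matrix.
#' @param density Retained fraction of candidate edges, in (0, 1\].
#' @param mask Logical TF x target candidate mask; defaults to all TRUE.
#' @return Sparsified matrix of the same shape.
#' @export
refine_sparsity <- function(weights, density = 0.05, mask = NULL) {
  if (density <= 0 || density > 1) abort("`density` must be in (0, 1].")
  if (is.null(mask)) mask <- array(TRUE, dim(weights))
  cand <- which(mask)
  if (length(cand) == 0) return(weights * 0)
  k <- ceiling(density * length(cand))
  tf_id <- rownames(weights)[((cand - 1) %% nrow(weights)) + 1]
  tg_id <- colnames(weights)[((cand - 1) %/% nrow(weights)) + 1]
  ord <- order(-weights[cand], tf_id, tg_id)
  keep <- cand[ord[seq_len(min(k, length(cand)))]]
  out <- weights * 0
  out[keep] <- weights[keep]
  out
}

#' Infer a motif-restricted regulatory network for one phenotype
#'
#' Restricts each target gene's regression to its motif-permitted candidate
#' TFs (self-loops removed), fits [fit_target()] on the phenotype's
#' samples, applies the per-target q-norm normalization, and the global
#' sparsity refinement. The motif restriction is a hard constraint: weights
#' are zero outside the candidate mask.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param phenotypes Tibble `sample_id`, `phenotype`.
#' @param phenotype Phenotype whose samples are used.
#' @param candidates Candidate edges (tibble `tf`, `target`).
#' @param params A [grn_params()].
#' @param seed Integer seed; per-target seeds are derived deterministically
#'   from it and the target id, so results are invariant to sample and
#'   candidate ordering.
#' @return A `methnet_network`: list with `phenotype`, `weights`
#'   (sparsified TF x target matrix), `importances` (dense post-q-norm
#'   matrix), `mask`, `params`, `seed`, `n_samples`.
#' @export
build_phenotype_network <- function(expr, phenotypes, phenotype, candidates,
                                    params = grn_params(), seed = 1) {
  check_phenotype_table(phenotypes)
  em <- as_feature_matrix(expr)
  samples <- intersect(samples_of(phenotypes, phenotype), colnames(em))
  if (length(samples) < 5) {
    abort(sprintf("Phenotype '%s' has %d samples; at least 5 are required.",
                  phenotype, length(samples)))
  }
  if (length(samples) < 10) {
    warn(sprintf("Phenotype '%s' has only %d samples; estimates will be noisy.",
                 phenotype, length(samples)))
  }
  candidates <- distinct(candidates, .data$tf, .data$target)
  n_missing_tf <- length(setdiff(unique(candidates$tf), rownames(em)))
  if (n_missing_tf > 0) {
    inform(sprintf("%d candidate TF(s) absent from the expression matrix; dropped.",
                   n_missing_tf))
  }
  candidates <- filter(candidates, .data$tf %in% rownames(em),
                       .data$target %in% rownames(em),
                       .data$tf != .data$target)
  tfs <- sort(unique(candidates$tf))
  targets <- sort(unique(candidates$target))
  W <- matrix(0, length(tfs), length(targets), dimnames = list(tfs, targets))
  mask <- matrix(FALSE, length(tfs), length(targets),
                 dimnames = list(tfs, targets))
  esub <- em[, samples, drop = FALSE]
  for (tg in targets) {
    ctfs <- sort(candidates$tf[candidates$target == tg])
    mask[ctfs, tg] <- TRUE
    x <- t(esub[ctfs, , drop = FALSE])
    imp <- fit_target(esub[tg, ], x, params,
                      seed = derive_seed(seed, sum(utf8ToInt(tg))))
    W[ctfs, tg] <- imp[ctfs]
  }
  importances <- q_normalize(W, params$q, params$q_norm_scope)
  weights <- refine_sparsity(importances, params$density, mask)
  structure(list(phenotype = phenotype, weights = weights,
                 importances = importances, mask = mask, params = params,
                 seed = seed, n_samples = length(samples)),
            class = "methnet_network")
}

#' @export
print.methnet_network <- function(x, ...) {
  cat(sprintf(
    "<methnet_network> phenotype %s: %d TFs x %d targets, %d/%d edges retained (n = %d samples)\n",
    x$phenotype, nrow(x$weights), ncol(x$weights), sum(x$weights > 0),
    sum(x$mask), x$n_samples))
  invisible(x)
}
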