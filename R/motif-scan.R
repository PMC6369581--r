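#' Log-odds score matrix of a motif
#'
#' Position frequencies are regularized with the motif's pseudocount
#' against the background, `p'[i, b] = (f[i, b] + pc * bg[b]) / (1 + pc)`,
#' and scored as `log2(p'[i, b] / bg[b])` (bits).
#'
#' @param m A [motif()].
#' @param background Strictly positive length-4 base frequencies (A, C, G,
#'   T) summing to 1.
#' @return L x 4 numeric matrix of scores in bits.
#' @export
pwm_logodds <- function(m, background = rep(0.25, 4)) {
  if (length(background) != 4 || any(background <= 0)) {
    abort("`background` must be four strictly positive frequencies.")
  }
  background <- background / sum(background)
  pc <- m$pseudocount
  pp <- sweep(m$pfm, 2, pc * background, "+") / (1 + pc)
  log2(sweep(pp, 2, background, "/"))
}

# Encode a DNA string as integer indices 1..4 (A, C, G, T); N and any other
# character become NA (scores as background, contribution 0).
encode_dna <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(v, c("A", "C", "G", "T"))
}

# Sum log-odds at every offset of an encoded sequence (NA bases add 0).
slide_scores <- function(enc, lo) {
  L <- nrow(lo)
  n_off <- length(enc) - L + 1
  if (n_off < 1) return(numeric(0))
  sc <- numeric(n_off)
  for (j in seq_len(L)) {
    contrib <- unname(lo[j, ])[enc[j:(j + n_off - 1)]]
    contrib[is.na(contrib)] <- 0
    sc <- sc + contrib
  }
  sc
}

#' Scan a sequence window with a motif
#'
#' Scores every offset of the window (and of its reverse complement when
#' `both_strands`) with the motif's log-odds matrix. Hits on the minus
#' strand are reported in plus-strand coordinates: `offset` is always the
#' 0-based start of the matched window segment on the input sequence.
#' Bases outside A/C/G/T contribute 0 (background-equivalent).
#'
#' @param seq DNA string over A, C, G, T, N.
#' @param m A [motif()].
#' @param background Background base frequencies.
#' @param both_strands Scan the reverse complement as well.
#' @return Tibble `offset`, `strand`, `score` with one row per scanned
#'   position; empty when the sequence is shorter than the motif.
#' @export
scan_window <- function(seq, m, background = rep(0.25, 4), both_strands = TRUE) {
  lo <- pwm_logodds(m, background)
  L <- nrow(lo)
  enc <- encode_dna(seq)
  n <- length(enc)
  if (n < L) {
    return(tibble(offset = integer(0), strand = character(0),
                  score = numeric(0)))
  }
  fwd <- slide_scores(enc, lo)
  out <- tibble(offset = seq_along(fwd) - 1L, strand = "+", score = fwd)
  if (both_strands) {
    enc_rc <- rev(5L - enc)  # A<->T, C<->G on the reversed sequence
    rev_sc <- slide_scores(enc_rc, lo)
    # offset o on the reverse complement corresponds to plus-strand start
    # n - L - o (0-based).
    out <- bind_rows(out, tibble(
      offset = n - L - (seq_along(rev_sc) - 1L),
      strand = "-", score = rev_sc
    ))
  }
  arrange(out, .data$offset, .data$strand)
}

#' Exact discretized null distribution of motif scores
#'
#' Dynamic program over score bins of width `granularity`: the exact
#' distribution of the log-odds score of a random L-mer drawn from the
#' background, from which p-values `P(S >= s)` are read off. The p-value
#' function is non-increasing in the score.
#'
#' @param lo Log-odds matrix from [pwm_logodds()].
#' @param background Background base frequencies used for the null.
#' @param granularity Score bin width in bits.
#' @return An object of class `methnet_score_dist` with elements `bins`
#'   (integer support), `tail` (upper-tail probabilities), `granularity`,
#'   and `L`.
#' @export
pwm_score_distribution <- function(lo, background = rep(0.25, 4),
                                   granularity = 1e-3) {
  if (granularity <= 0) abort("`granularity` must be positive.")
  if (any(!is.finite(lo))) abort("Log-odds scores must be finite.")
  background <- background / sum(background)
  B <- round(lo / granularity)
  L <- nrow(B)
  lo_min <- sum(apply(B, 1, min))
  lo_max <- sum(apply(B, 1, max))
  width <- lo_max - lo_min + 1
  # probs[k] = P(discretized partial score == lo_min_partial + k - 1)
  probs <- 1
  offset <- 0  # current minimum achievable partial score
  for (j in seq_len(L)) {
    row <- B[j, ]
    rmin <- min(row)
    new_width <- length(probs) + max(row) - rmin
    acc <- numeric(new_width)
    for (b in 1:4) {
      shift <- row[b] - rmin
      idx <- seq_along(probs) + shift
      acc[idx] <- acc[idx] + probs * background[b]
    }
    probs <- acc
    offset <- offset + rmin
  }
  tail <- rev(cumsum(rev(probs)))
  structure(list(bins = offset + seq_along(probs) - 1L, tail = tail,
                 granularity = granularity, L = L),
            class = "methnet_score_dist")
}

#' p-value of motif scores under the background model
#'
#' Scores are discretized with half-a-bin-per-position slack so that any
#' achievable score maps into the support (the p-value of the maximum
#' score is exact, never 0).
#'
#' @param score Numeric vector of log-odds scores (bits).
#' @param dist A `methnet_score_dist` from [pwm_score_distribution()].
#' @return p-values in (0, 1\].
#' @export
pwm_pvalue <- function(score, dist) {
  g <- dist$granularity
  qbin <- round((score - g * dist$L / 2 - 1e-12) / g)
  idx <- findInterval(qbin, dist$bins)
  # findInterval gives the last bin <= qbin; the tail at bin index i covers
  # scores >= bins[i]. A query below the support gets p = 1; above it, the
  # smallest positive tail.
  p <- numeric(length(score))
  n_bins <- length(dist$bins)
  for (i in seq_along(score)) {
    k <- idx[i]
    if (k <= 0) {
      p[i] <- 1
    } else if (dist$bins[k] == qbin[i]) {
      p[i] <- dist$tail[k]
    } else if (k >= n_bins) {
      p[i] <- dist$tail[n_bins]
    } else {
      p[i] <- dist$tail[k + 1]
    }
  }
  pmin(1, pmax(p, min(dist$tail[dist$tail > 0])))
}

#' Candidate TF regulators from motif hits in promoter windows
#'
#' Scans the window around every assigned probe of every gene with each
#' motif and creates a TF-to-gene candidate edge when some window of an
#' assigned probe contains a hit with p-value below `p_thresh`. For
#' both-strand scanning the per-position p-value is Bonferroni-combined
#' over the two strands (doubled, capped at 1) before thresholding.
#'
#' @param sequences Named character vector of window sequences (names are
#'   probe ids), e.g. the `sequences` element of a cohort.
#' @param pairs Confirmed probe-gene pairs (`probe_id`, `gene_id`).
#' @param motifs List of [motif()] objects.
#' @param p_thresh Hit p-value threshold (default 1e-4).
#' @param background Background base frequencies.
#' @param both_strands Scan both strands.
#' @return List with `edges` (tibble `tf`, `target`) and `hits` (tibble
#'   `tf`, `probe_id`, `gene_id`, `offset`, `strand`, `score`, `p`).
#' @export
candidate_regulators <- function(sequences, pairs, motifs, p_thresh = 1e-4,
                                 background = rep(0.25, 4),
                                 both_strands = TRUE) {
  pairs <- distinct(pairs, .data$probe_id, .data$gene_id)
  probes <- unique(pairs$probe_id)
  missing <- setdiff(probes, names(sequences))
  if (length(missing) > 0) {
    warn(sprintf("%d assigned probe(s) have no window sequence; skipped.",
                 length(missing)))
    probes <- setdiff(probes, missing)
  }
  strand_mult <- if (both_strands) 2 else 1
  # Windows are scanned in equal-width batches: scores for every offset of
  # every window are accumulated with vectorized matrix indexing, the hit
  # p-value threshold is inverted into a score cutoff through the null
  # distribution, and exact p-values are computed only for the few
  # positions above it.
  widths <- nchar(sequences[probes])
  hits <- purrr::map_dfr(motifs, function(m) {
    lo <- pwm_logodds(m, background)
    dist <- pwm_score_distribution(lo, background)
    g <- dist$granularity
    i_star <- match(TRUE, strand_mult * dist$tail < p_thresh)
    if (is.na(i_star)) return(tibble())
    s_cut <- g * (dist$bins[i_star] - 1)
    purrr::map_dfr(unique(widths), function(W) {
      batch <- probes[widths == W]
      L <- nrow(lo)
      if (W < L) return(tibble())
      enc <- t(vapply(sequences[batch], encode_dna, integer(W)))
      n_off <- W - L + 1
      strand_scores <- function(e) {
        sc <- matrix(0, nrow(e), n_off)
        for (j in seq_len(L)) {
          v <- unname(lo[j, ])[e[, j:(j + n_off - 1), drop = FALSE]]
          v[is.na(v)] <- 0
          sc <- sc + matrix(v, nrow(e), n_off)
        }
        sc
      }
      per_strand <- function(sc, strand) {
        idx <- which(sc >= s_cut, arr.ind = TRUE)
        if (nrow(idx) == 0) return(tibble())
        score <- sc[idx]
        p <- pmin(1, strand_mult * pwm_pvalue(score, dist))
        keep <- p < p_thresh
        if (!any(keep)) return(tibble())
        off <- idx[keep, 2] - 1L
        if (strand == "-") off <- W - L - off
        tibble(offset = as.integer(off), strand = strand,
               score = score[keep], p = p[keep],
               probe_id = batch[idx[keep, 1]])
      }
      out <- per_strand(strand_scores(enc), "+")
      if (both_strands) {
        enc_rc <- (5L - enc)[, W:1, drop = FALSE]
        out <- bind_rows(out, per_strand(strand_scores(enc_rc), "-"))
      }
      if (nrow(out) == 0) return(out)
      mutate(out, tf = m$tf_name) |>
        arrange(.data$probe_id, .data$offset, .data$strand)
    })
  })
  if (nrow(hits) == 0) {
    return(list(edges = tibble(tf = character(0), target = character(0)),
                hits = tibble(tf = character(0), probe_id = character(0),
                              gene_id = character(0), offset = integer(0),
                              strand = character(0), score = numeric(0),
                              p = numeric(0))))
  }
  hits <- inner_join(hits, pairs, by = "probe_id",
                     relationship = "many-to-many") |>
    select("tf", "probe_id", "gene_id", "offset", "strand", "score", "p")
  edges <- hits |>
    distinct(.data$tf, target = .data$gene_id) |>
    arrange(.data$tf, .data$target)
  list(edges = edges, hits = hits)
}
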