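#' Construct a motif (position frequency matrix)
#'
#' A motif holds a transcription factor's binding preference as an L x 4
#' position frequency matrix over A, C, G, T. Rows may be counts or
#' frequencies; they are normalized to frequencies on construction. The
#' pseudocount is applied later, at log-odds scoring time.
#'
#' @param tf_name Transcription factor (and motif) name.
#' @param pfm Numeric L x 4 matrix, columns A, C, G, T, nonnegative, each
#'   row with positive sum.
#' @param pseudocount Positive pseudocount weight used when scoring.
#' @param source Free-text provenance label.
#' @return An object of class `methnet_motif`.
#' @examples
#' m <- motif("TF1", matrix(c(10, 0, 0, 0, 0, 10, 0, 0), 2, 4, byrow = TRUE))
#' motif_consensus(m)
#' @export
motif <- function(tf_name, pfm, pseudocount = 0.01, source = "") {
  pfm <- as.matrix(pfm)
  if (ncol(pfm) != 4 || nrow(pfm) < 1) {
    abort("`pfm` must be an L x 4 matrix with L >= 1.")
  }
  if (any(pfm < 0) || any(rowSums(pfm) <= 0)) {
    abort("`pfm` rows must be nonnegative with positive sums.")
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be a positive number.")
  }
  pfm <- pfm / rowSums(pfm)
  colnames(pfm) <- c("A", "C", "G", "T")
  rownames(pfm) <- NULL
  structure(
    list(tf_name = as.character(tf_name), pfm = pfm,
         pseudocount = pseudocount, source = source),
    class = "methnet_motif"
  )
}

#' @export
print.methnet_motif <- function(x, ...) {
  cat(sprintf("<methnet_motif> %s  (length %d, consensus %s)\n",
              x$tf_name, nrow(x$pfm), motif_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' @param m A `methnet_motif`.
#' @return Character scalar, the highest-frequency base at each position.
#' @export
motif_consensus <- function(m) {
  bases <- colnames(m$pfm)
  paste(bases[apply(m$pfm, 1, which.max)], collapse = "")
}

#' Write motifs in MEME minimal format
#'
#' @param motifs A list of `methnet_motif` objects.
#' @param path Output file path.
#' @param background Background letter frequencies (A, C, G, T).
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", background[1], background[2],
            background[3], background[4]),
    ""
  )
  for (m in motifs) {
    lines <- c(
      lines,
      sprintf("MOTIF %s", m$tf_name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
              nrow(m$pfm)),
      apply(m$pfm, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                          r[1], r[2], r[3], r[4])),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' Parses the minimal subset of the format: the background line (if present)
#' and `MOTIF` blocks with letter-probability matrices.
#'
#' @param path Path to a MEME-format motif file.
#' @param pseudocount Pseudocount assigned to each motif read.
#' @return A named list of `methnet_motif` objects.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  idx <- grep("^MOTIF\\s+", lines)
  if (length(idx) == 0) return(list())
  motifs <- vector("list", length(idx))
  names(motifs) <- character(length(idx))
  for (i in seq_along(idx)) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[idx[i]])), "\\s+")[[1]][1]
    j <- idx[i] + 1
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) {
      j <- j + 1
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1):(j + w)]
    pfm <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    motifs[[i]] <- motif(name, pfm, pseudocount = pseudocount,
                         source = basename(path))
    names(motifs)[i] <- name
  }
  motifs
}
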