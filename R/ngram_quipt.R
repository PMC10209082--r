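# Gapped n-gram featurization and QuiPT exact permutation-test selection.
#
# Pattern universe: unigrams; bigrams with a wildcard gap of 0-3 residues;
# trigrams with wildcard gaps of 0-1 residues in each of the two slots.
# Pattern ids write the gap as underscores, e.g. "DP_G" = D, P, any, G.
# Census: 20 + 4*400 + 4*8000 = 33,620 patterns.

TRIGRAM_GAPS <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
BIGRAM_GAPS <- 0:3

pattern_id <- function(residues, gaps) {
  if (length(residues) == 1) return(residues)
  out <- residues[1]
  for (i in seq_along(gaps)) {
    out <- paste0(out, strrep("_", gaps[i]), residues[i + 1])
  }
  out
}

#' Enumerate the full gapped n-gram pattern universe
#'
#' All unigrams, bigrams (gap 0-3) and trigrams (each gap 0-1) over the
#' 20-letter alphabet, canonically ordered: by length, then gap
#' configuration, then residues. Yields 33,620 unique patterns.
#'
#' @return A data.frame with columns `id`, `n` (pattern length), `g1`, `g2`
#'   (gap lengths; NA where not applicable) and `span` (matched window width).
#' @export
enumerate_patterns <- function() {
  aa <- AA_ALPHABET
  uni <- data.frame(id = aa, n = 1L, g1 = NA_integer_, g2 = NA_integer_,
                    span = 1L, stringsAsFactors = FALSE)
  bi <- do.call(rbind, lapply(BIGRAM_GAPS, function(g) {
    grid <- expand.grid(b = aa, a = aa, stringsAsFactors = FALSE)
    data.frame(id = paste0(grid$a, strrep("_", g), grid$b),
               n = 2L, g1 = g, g2 = NA_integer_, span = 2L + g,
               stringsAsFactors = FALSE)
  }))
  tri <- do.call(rbind, lapply(seq_len(nrow(TRIGRAM_GAPS)), function(k) {
    g1 <- TRIGRAM_GAPS[k, 1]; g2 <- TRIGRAM_GAPS[k, 2]
    grid <- expand.grid(c = aa, b = aa, a = aa, stringsAsFactors = FALSE)
    data.frame(id = paste0(grid$a, strrep("_", g1), grid$b,
                           strrep("_", g2), grid$c),
               n = 3L, g1 = g1, g2 = g2, span = 3L + g1 + g2,
               stringsAsFactors = FALSE)
  }))
  out <- rbind(uni, bi, tri)
  rownames(out) <- NULL
  out
}

# Column index arithmetic matching enumerate_patterns() order.
# codes: integer residue codes 1..20 per position of one sequence.
sequence_pattern_cols <- function(codes) {
  L <- length(codes)
  cols <- unique(codes)
  if (L >= 2) {
    for (gi in seq_along(BIGRAM_GAPS)) {
      g <- BIGRAM_GAPS[gi]
      if (L >= 2 + g) {
        a <- codes[1:(L - g - 1)]
        b <- codes[(2 + g):L]
        cols <- c(cols, unique(20L + (gi - 1L) * 400L + (a - 1L) * 20L + b))
      }
    }
  }
  if (L >= 3) {
    for (k in seq_len(nrow(TRIGRAM_GAPS))) {
      g1 <- TRIGRAM_GAPS[k, 1]; g2 <- TRIGRAM_GAPS[k, 2]
      span <- 3L + g1 + g2
      if (L >= span) {
        a <- codes[1:(L - span + 1)]
        b <- codes[(2 + g1):(L - g2 - 1)]
        cc <- codes[span:L]
        cols <- c(cols, unique(1620L + (k - 1L) * 8000L +
                                 (a - 1L) * 400L + (b - 1L) * 20L + cc))
      }
    }
  }
  sort(unique(cols))
}

#' Binary presence/absence n-gram feature matrix
#'
#' One row per record, one column per pattern of the full universe; a cell is
#' 1 iff the pattern matches anywhere in the sequence (wildcard positions
#' match any residue). Presence, never counts. Stored sparse.
#'
#' @param dataset A `plastid_dataset` (or character vector of sequences,
#'   optionally named).
#' @param patterns Pattern table from [enumerate_patterns()]; computed if
#'   omitted.
#' @return A sparse `dgCMatrix` with record ids as rownames and pattern ids
#'   as colnames.
#' @export
extract_presence <- function(dataset, patterns = NULL) {
  if (inherits(dataset, "plastid_dataset")) {
    seqs <- stats::setNames(dataset$sequence, dataset$id)
  } else {
    seqs <- dataset
    if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  }
  if (is.null(patterns)) patterns <- enumerate_patterns()
  code <- stats::setNames(seq_along(AA_ALPHABET), AA_ALPHABET)
  per_seq <- lapply(seqs, function(s) {
    sequence_pattern_cols(unname(code[strsplit(s, "")[[1]]]))
  })
  j <- unlist(per_seq, use.names = FALSE)
  i <- rep.int(seq_along(per_seq), lengths(per_seq))
  Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(seqs), nrow(patterns)),
    dimnames = list(names(seqs), patterns$id)
  )
}

#' Does a gapped pattern match within a motif string?
#'
#' @param pattern A pattern id (underscores are wildcards), e.g. `"D_LG"`.
#' @param motif A plain amino-acid string, e.g. `"DPLG"`.
#' @return TRUE iff the pattern's match window embeds fully in the motif.
#' @export
pattern_matches_motif <- function(pattern, motif) {
  rx <- gsub("_", ".", pattern, fixed = TRUE)
  grepl(rx, motif)
}

# -- QuiPT --------------------------------------------------------------------

# Mutual information (bits) of the 2x2 table with margins (n, K, n1) and
# overlap m (vectorized over m).
mi_bits <- function(m, n, K, n1) {
  len <- max(length(m), length(K))
  m <- rep_len(m, len); K <- rep_len(K, len)
  cells <- cbind(m, K - m, n1 - m, n - K - n1 + m)
  rowm <- cbind(K, K, n - K, n - K)
  colm <- matrix(rep(c(n1, n - n1, n1, n - n1), each = len), nrow = len)
  p <- cells / n
  term <- ifelse(cells > 0, p * log2(cells * n / (rowm * colm)), 0)
  rowSums(term)
}

# Exact p-values for columns sharing margins (n, n1): for each (K, m) pair,
# p = P(stat(M) >= stat(m)) with M ~ Hypergeometric(n1, n - n1, K).
quipt_pvalues <- function(K, m, n, n1) {
  stats_obs <- mi_bits(m, n, K, n1)
  p <- numeric(length(K))
  for (kk in unique(K)) {
    idx <- which(K == kk)
    lo <- max(0L, kk + n1 - n)
    hi <- min(kk, n1)
    mp <- lo:hi
    st <- mi_bits(mp, n, kk, n1)
    pr <- stats::dhyper(mp, n1, n - n1, kk)
    for (i in idx) {
      p[i] <- sum(pr[st >= stats_obs[i] - 1e-12])
    }
  }
  list(statistic = stats_obs, p = pmin(p, 1))
}

#' QuiPT exact permutation p-value for a binary feature
#'
#' The test statistic is the mutual information (bits) of the 2x2
#' feature-by-target contingency table. Because the statistic depends on the
#' permuted target only through the overlap count, the exact permutation
#' distribution is hypergeometric in the overlap: the p-value sums
#' hypergeometric probabilities of all overlaps whose statistic is at least
#' the observed one — identical to exhaustively permuting the target.
#'
#' @param feature,target Equal-length binary (0/1 or logical) vectors, n >= 2.
#' @return List with `statistic` (bits) and `p` (exact p-value in (0, 1\]).
#' @examples
#' quipt_pvalue(c(1, 1, 0, 0), c(1, 1, 0, 0))  # p = 1/3
#' @export
quipt_pvalue <- function(feature, target) {
  feature <- as.integer(feature); target <- as.integer(target)
  if (length(feature) != length(target)) stop("length mismatch")
  n <- length(feature)
  if (n < 2) stop("need n >= 2")
  res <- quipt_pvalues(sum(feature), sum(feature & target), n, sum(target))
  list(statistic = res$statistic, p = res$p)
}

#' QuiPT feature selection at a significance level
#'
#' Tests every column of a binary feature matrix against a binary target and
#' retains exactly the columns with p < `alpha`. Constant columns have
#' statistic 0 and p = 1 and are never retained. Deterministic and invariant
#' to row order.
#'
#' @param matrix Binary feature matrix (sparse or dense) with named columns.
#' @param target Binary vector aligned with the matrix rows.
#' @param alpha Significance level (default 0.01).
#' @return List with `matrix` (retained columns), `result` (data.frame:
#'   pattern, statistic, p, selected) ordered as the input columns.
#' @export
select_features <- function(matrix, target, alpha = 0.01) {
  target <- as.integer(target)
  n <- nrow(matrix)
  if (length(target) != n) stop("target length must match matrix rows")
  n1 <- sum(target)
  K <- as.integer(Matrix::colSums(matrix))
  m <- as.integer(Matrix::colSums(matrix[target == 1L, , drop = FALSE]))
  nonconst <- K > 0L & K < n
  stat <- numeric(length(K))
  p <- rep(1, length(K))
  if (any(nonconst)) {
    res <- quipt_pvalues(K[nonconst], m[nonconst], n, n1)
    stat[nonconst] <- res$statistic
    p[nonconst] <- res$p
  }
  selected <- p < alpha
  if (!any(selected)) {
    warning("no feature passes alpha = ", alpha, "; empty matrix returned")
  }
  list(
    matrix = matrix[, selected, drop = FALSE],
    result = data.frame(pattern = colnames(matrix), statistic = stat,
                        p = p, selected = selected,
                        stringsAsFactors = FALSE)
  )
}

#' Write a feature matrix as sparse triplets plus a pattern dictionary
#'
#' @param matrix Sparse feature matrix from [extract_presence()].
#' @param triplets_path Output TSV (`row_id`, `pattern_id`, `value`).
#' @param dictionary_path Optional output TSV of the column pattern ids.
#' @return Invisibly, `triplets_path`.
#' @export
write_feature_matrix <- function(matrix, triplets_path,
                                 dictionary_path = NULL) {
  tm <- methods::as(matrix, "TsparseMatrix")
  df <- data.frame(row_id = rownames(matrix)[tm@i + 1L],
                   pattern_id = colnames(matrix)[tm@j + 1L],
                   value = 1L, stringsAsFactors = FALSE)
  utils::write.table(df, triplets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dictionary_path)) {
    utils::write.table(
      data.frame(pattern_id = colnames(matrix)),
      dictionary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(triplets_path)
}
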