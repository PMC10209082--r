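# Independent oracles used across the suite. Each implements the checked
# quantity by a different route than the package (enumeration, naive DP),
# and is deliberately slow/simple.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Mutual information (bits) of a 2x2 table from two binary vectors.
oracle_mi_bits <- function(f, t) {
  n <- length(f)
  tot <- 0
  for (a in 0:1) for (b in 0:1) {
    nab <- sum(f == a & t == b)
    if (nab > 0) {
      tot <- tot + (nab / n) * log2((nab * n) / (sum(f == a) * sum(t == b)))
    }
  }
  tot
}

# Brute-force QuiPT p-value: enumerate every distinct permutation of the
# binary target (all position subsets of its ones) and count those whose
# statistic reaches the observed one.
oracle_quipt_p <- function(feature, target) {
  n <- length(feature)
  n1 <- sum(target)
  obs <- oracle_mi_bits(feature, target)
  subsets <- utils::combn(n, n1)
  hits <- 0
  for (cc in seq_len(ncol(subsets))) {
    perm <- integer(n)
    perm[subsets[, cc]] <- 1L
    if (oracle_mi_bits(feature, perm) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(subsets)
}

# Exhaustive path enumeration (DFS, no memoization) of the profile-HMM
# forward probability, as log2 odds against the background null.
oracle_hmm_score <- function(hmm, codes, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  comb <- if (mode == "sum") `+` else max
  k <- hmm$n_match
  L <- length(codes)
  allowed <- plastidstack:::allowed_targets
  trow <- function(s, j) {
    switch(s, M = hmm$from_M[j + 1, ], I = hmm$from_I[j + 1, ],
           D = hmm$from_D[j, ])
  }
  g <- function(s, j, pos) {
    row <- trow(s, j)
    tot <- 0
    for (t in allowed(s, j, k)) {
      p <- row[[t]]
      if (p <= 0) next
      if (t == "E") {
        if (pos == L) tot <- comb(tot, p)
      } else if (t == "M") {
        if (pos < L) {
          tot <- comb(tot, p * hmm$match_emissions[j + 1, codes[pos + 1]] *
                        g("M", j + 1, pos + 1))
        }
      } else if (t == "I") {
        if (pos < L) {
          tot <- comb(tot, p * hmm$background[codes[pos + 1]] *
                        g("I", j, pos + 1))
        }
      } else if (t == "D") {
        tot <- comb(tot, p * g("D", j + 1, pos))
      }
    }
    tot
  }
  unname(log2(g("M", 0L, 0L)) - sum(log2(hmm$background[codes])))
}

# Random toy profile with valid transition rows over the allowed moves.
random_toy_hmm <- function(k) {
  allowed <- plastidstack:::allowed_targets
  em <- matrix(stats::rgamma(k * 20, 1), k, 20)
  em <- em / rowSums(em)
  colnames(em) <- AA20
  bg <- stats::rgamma(20, 1)
  bg <- stats::setNames(bg / sum(bg), AA20)
  mk <- function(n_rows, state) {
    m <- matrix(0, n_rows, 4, dimnames = list(NULL, c("M", "I", "D", "E")))
    for (r in seq_len(n_rows)) {
      j <- if (state == "D") r else r - 1
      a <- allowed(state, j, k)
      v <- stats::rgamma(length(a), 1)
      m[r, a] <- v / sum(v)
    }
    m
  }
  plastidstack:::new_profile_hmm(em, bg, mk(k + 1, "M"), mk(k + 1, "I"),
                                 mk(k, "D"))
}

# Naive Gotoh affine-gap global alignment, optimal score only (a gap of
# length g costs open + g * extend, matching the package's convention).
oracle_nw_score <- function(a, b, open = 10, extend = 0.5) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- get("BLOSUM62", envir = e)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # end in match
  X <- matrix(NEG, n + 1, m + 1)   # end in gap in b (A aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)   # end in gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Random sequence dataset with planted homology families, used for
# partitioning soundness checks.
random_family_dataset <- function(n_fam, copies, L = 50, mut = 0.3) {
  seqs <- character(0)
  for (f in seq_len(n_fam)) {
    base <- sample(AA20, L, replace = TRUE)
    for (cp in seq_len(copies)) {
      s <- base
      pos <- sample(L, round(L * mut))
      s[pos] <- sample(AA20, length(pos), replace = TRUE)
      seqs <- c(seqs, paste(s, collapse = ""))
    }
  }
  plastid_dataset(sprintf("s%03d", seq_along(seqs)), seqs)
}
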