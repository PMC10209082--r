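# Profile hidden Markov models for targeting-signal scoring.
#
# Architecture: one match (M), insert (I) and delete (D) state per match
# column, Plan7-like (no D<->I transitions), with begin treated as M0 and an
# I0 state for inserts before the first match column. Scoring is glocal: the
# whole profile is aligned against the N-terminal window of the sequence
# (default first 100 residues, where targeting signals live), with flanking
# residues absorbed by insert states. Insert emissions are tied to the
# background, so log-odds scores reflect the match-state signal. Log base 2
# throughout (bits).

TRANS_NAMES <- c("M", "I", "D", "E")

new_profile_hmm <- function(match_emissions, background, from_M, from_I,
                            from_D) {
  k <- nrow(match_emissions)
  stopifnot(k >= 1, ncol(match_emissions) == 20)
  hmm <- structure(list(
    n_match = k,
    match_emissions = match_emissions,   # k x 20, rows sum to 1
    insert_emissions = background,       # tied to background
    background = background,             # length 20, sums to 1
    from_M = from_M,                     # (k+1) x 4, row j+1 = from M_j (M0 = begin)
    from_I = from_I,                     # (k+1) x 4, row j+1 = from I_j
    from_D = from_D                      # k x 4,     row j   = from D_j
  ), class = "profile_hmm")
  validate_profile_hmm(hmm)
  hmm
}

validate_profile_hmm <- function(hmm) {
  ok <- function(v) abs(sum(v) - 1) < 1e-9
  stopifnot(ok(hmm$background), all(apply(hmm$match_emissions, 1, ok)),
            all(apply(hmm$from_M, 1, ok)), all(apply(hmm$from_I, 1, ok)),
            all(apply(hmm$from_D, 1, ok)))
  invisible(hmm)
}

# Allowed targets per source state (Plan7-like, begin = M0; no I<->D):
#   M_j (j<k): M_{j+1}, I_j, D_{j+1}      M_k: I_k, E
#   I_j (j<k): M_{j+1}, I_j               I_k: I_k, E
#   D_j (j<k): M_{j+1}, D_{j+1}           D_k: E
allowed_targets <- function(state, j, k) {
  if (state == "M") {
    if (j < k) c("M", "I", "D") else c("I", "E")
  } else if (state == "I") {
    if (j < k) c("M", "I") else c("I", "E")
  } else {
    if (j < k) c("M", "D") else "E"
  }
}

normalize_trans_row <- function(counts, allowed, pseudocount) {
  row <- stats::setNames(rep(0, 4), TRANS_NAMES)
  cnt <- counts[allowed] + pseudocount
  row[allowed] <- cnt / sum(cnt)
  row
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns whose gap fraction is below `gap_fraction_threshold` become match
#' states; the rest are insert columns. Match emissions are
#' (count + pseudocount) / (n_rows + 20 * pseudocount); transitions are
#' estimated from the observed per-row state paths with the same pseudocount;
#' insert emissions are tied to the background. The effective sequence
#' number is the raw row count (no sequence weighting).
#'
#' @param msa An `AAStringSet` of equal-length aligned rows (gaps `-` or
#'   `.`), a character vector, or a path to an aligned FASTA file.
#' @param gap_fraction_threshold Columns with gap fraction >= this value
#'   become insert columns (default 0.5).
#' @param pseudocount Additive pseudocount for emissions and transitions.
#' @param background `"uniform"` (default) for the flat 1/20 null, or
#'   `"msa"` to estimate the null from the alignment's residue frequencies.
#'   A signal alignment is composition-biased (e.g. the hydrophobic
#'   h-region), so an MSA-derived null absorbs exactly the signal the
#'   profile should score; the flat null keeps that contrast.
#' @return A `profile_hmm`.
#' @export
build_from_msa <- function(msa, gap_fraction_threshold = 0.5,
                           pseudocount = 1.0,
                           background = c("uniform", "msa")) {
  background <- match.arg(background)
  if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    msa <- Biostrings::readAAStringSet(msa)
  }
  rows <- toupper(as.character(msa))
  if (length(rows) < 2) stop("MSA must have >= 2 rows")
  if (length(unique(nchar(rows))) != 1) stop("MSA rows must have equal length")
  mat <- do.call(rbind, strsplit(rows, ""))
  mat[mat == "."] <- "-"
  n <- nrow(mat); ncol_ <- ncol(mat)
  gap_frac <- colMeans(mat == "-")
  is_match <- gap_frac < gap_fraction_threshold
  k <- sum(is_match)
  if (k == 0) stop("no match columns under gap fraction threshold ",
                   gap_fraction_threshold)
  match_cols <- which(is_match)
  if (background == "msa") {
    res_all <- mat[mat != "-"]
    bg_counts <- table(factor(res_all, levels = AA_ALPHABET))
    bg <- (as.numeric(bg_counts) + pseudocount) /
      (length(res_all) + 20 * pseudocount)
  } else {
    bg <- rep(1 / 20, 20)
  }
  names(bg) <- AA_ALPHABET
  # match emissions
  match_emissions <- t(vapply(match_cols, function(cc) {
    counts <- table(factor(mat[, cc][mat[, cc] != "-"], levels = AA_ALPHABET))
    (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
  }, numeric(20)))
  colnames(match_emissions) <- AA_ALPHABET
  # the fixed-denominator emission rule leaves rows of gappy match columns
  # slightly under 1; renormalize to satisfy the probability invariant
  match_emissions <- match_emissions / rowSums(match_emissions)
  # transition counts from observed state paths
  cM <- matrix(0, k + 1, 4, dimnames = list(NULL, TRANS_NAMES))
  cI <- matrix(0, k + 1, 4, dimnames = list(NULL, TRANS_NAMES))
  cD <- matrix(0, max(k, 1), 4, dimnames = list(NULL, TRANS_NAMES))
  col_state <- ifelse(is_match, "match", "insert")
  match_index <- cumsum(is_match)
  add_count <- function(from_state, from_j, target) {
    # transitions the architecture forbids (I->D, D->I) are skipped
    if (!(target %in% allowed_targets(from_state, from_j, k))) return(invisible())
    if (from_state == "M") cM[from_j + 1, target] <<- cM[from_j + 1, target] + 1
    if (from_state == "I") cI[from_j + 1, target] <<- cI[from_j + 1, target] + 1
    if (from_state == "D") cD[from_j, target] <<- cD[from_j, target] + 1
    invisible()
  }
  for (r in seq_len(n)) {
    prev_state <- "M"; prev_j <- 0L  # begin = M0
    for (cc in seq_len(ncol_)) {
      resident <- mat[r, cc] != "-"
      if (col_state[cc] == "match") {
        st <- if (resident) "M" else "D"
        j <- match_index[cc]
      } else {
        if (!resident) next
        st <- "I"
        j <- match_index[cc]  # inserts sit between match j and j+1
      }
      add_count(prev_state, prev_j, st)
      prev_state <- st; prev_j <- j
    }
    add_count(prev_state, prev_j, "E")
  }
  from_M <- t(vapply(0:k, function(j) {
    normalize_trans_row(cM[j + 1, ], allowed_targets("M", j, k), pseudocount)
  }, numeric(4)))
  from_I <- t(vapply(0:k, function(j) {
    normalize_trans_row(cI[j + 1, ], allowed_targets("I", j, k), pseudocount)
  }, numeric(4)))
  from_D <- t(vapply(seq_len(k), function(j) {
    normalize_trans_row(cD[j, ], allowed_targets("D", j, k), pseudocount)
  }, numeric(4)))
  new_profile_hmm(match_emissions, bg, from_M, from_I, from_D)
}

# Forward probability (natural scale with per-position scaling) of emitting
# the full coded sequence, begin to end. Returns log2 probability.
#
# State vectors: fM[j+1] = M_j (M0 = begin, only occupied before the first
# emission), fI[j+1] = I_j, fD[j] = D_j. Delete states are non-emitting and
# are propagated left-to-right within the same emission count.
forward_log2 <- function(hmm, codes) {
  k <- hmm$n_match
  L <- length(codes)
  tM <- hmm$from_M; tI <- hmm$from_I; tD <- hmm$from_D
  em <- hmm$match_emissions; bg <- hmm$background
  fM <- numeric(k + 1); fI <- numeric(k + 1); fD <- numeric(k)
  fM[1] <- 1
  # delete chain reachable before any emission: B -> D1 -> D2 -> ...
  fD[1] <- tM[1, "D"]
  if (k >= 2) for (j in 2:k) fD[j] <- fD[j - 1] * tD[j - 1, "D"]
  log2p <- 0
  jj <- seq_len(k)
  # hoist transition columns out of the position loop
  tMM <- unname(tM[, "M"]); tIM <- unname(tI[, "M"]); tDM <- unname(tD[, "M"])
  tMI <- unname(tM[, "I"]); tII <- unname(tI[, "I"])
  tMD <- unname(tM[, "D"]); tDD <- unname(tD[, "D"])
  em <- unname(em); bg <- unname(bg)
  for (pos in seq_len(L)) {
    x <- codes[pos]
    # into M_j from M_{j-1}, I_{j-1}, D_{j-1} at the previous position
    inflow <- fM[jj] * tMM[jj] + fI[jj] * tIM[jj] +
      c(0, (fD * tDM)[jj[-k]])
    nM <- c(0, em[, x] * inflow)
    nI <- bg[x] * (fM * tMI + fI * tII)
    # into D_j from M_{j-1} (this position) and D_{j-1} (this position);
    # B -> D1 is only available before the first emission
    nD <- numeric(k)
    if (k >= 2) {
      for (j in 2:k) nD[j] <- nM[j] * tMD[j] + nD[j - 1] * tDD[j - 1]
    }
    fM <- nM; fI <- nI; fD <- nD
    sc <- sum(fM) + sum(fI) + sum(fD)
    if (sc <= 0) return(-Inf)
    fM <- fM / sc; fI <- fI / sc; fD <- fD / sc
    log2p <- log2p + log2(sc)
  }
  tail_p <- fM[k + 1] * tM[k + 1, "E"] + fI[k + 1] * tI[k + 1, "E"] +
    fD[k] * tD[k, "E"]
  if (tail_p <= 0) return(-Inf)
  log2p + log2(tail_p)
}

#' Log-odds score of a sequence under a profile HMM
#'
#' log2 forward probability of the N-terminal window under the profile minus
#' its log2 probability under the background null. Finite for any sequence
#' the profile can emit; bits.
#'
#' @param hmm A `profile_hmm`.
#' @param sequence Non-empty amino-acid sequence.
#' @param window Number of N-terminal residues scored (default 100; targeting
#'   signals are N-terminal).
#' @return Log-odds score in bits.
#' @export
score_logodds <- function(hmm, sequence, window = 100L) {
  if (!nzchar(sequence)) stop("empty sequence")
  s <- substr(toupper(sequence), 1, window)
  codes <- match(strsplit(s, "")[[1]], AA_ALPHABET)
  if (anyNA(codes)) stop("non-standard residue in sequence")
  fwd <- forward_log2(hmm, codes)
  null <- sum(log2(hmm$background[codes]))
  unname(fwd - null)
}

#' Serialize a profile HMM to JSON
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_hmm <- function(hmm, path) {
  obj <- list(schema = "plastidstack-profile-hmm/1",
              n_match = hmm$n_match,
              alphabet = AA_ALPHABET,
              match_emissions = unclass(hmm$match_emissions),
              background = as.numeric(hmm$background),
              from_M = unclass(hmm$from_M),
              from_I = unclass(hmm$from_I),
              from_D = unclass(hmm$from_D))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a profile HMM from JSON written by [write_profile_hmm()]
#' @param path Input path.
#' @return A `profile_hmm`.
#' @export
read_profile_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "plastidstack-profile-hmm/1")) {
    stop("unrecognized profile schema")
  }
  me <- as.matrix(obj$match_emissions)
  colnames(me) <- AA_ALPHABET
  mk <- function(m) {
    m <- as.matrix(m); colnames(m) <- TRANS_NAMES; m
  }
  new_profile_hmm(me, stats::setNames(obj$background, AA_ALPHABET),
                  mk(obj$from_M), mk(obj$from_I), mk(obj$from_D))
}
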