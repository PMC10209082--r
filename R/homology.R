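# Pairwise global identity, homology reduction and homology partitioning.
#
# Identity is computed from exact Needleman-Wunsch global alignments
# (Biostrings) rather than k-mer heuristics: at desk scale the exact
# computation honours the same contract (no retained cross-set or
# within-class pair at/above the threshold) without approximation.

#' Alignment parameters for percent-identity computation
#'
#' Defaults mirror the EMBOSS needle defaults: BLOSUM62, gap open 10, gap
#' extend 0.5, identity denominator = alignment length. The
#' `shorter_sequence` denominator mimics CD-HIT-style identity.
#'
#' @param substitution_matrix Name of a substitution matrix ("BLOSUM62", ...).
#' @param gap_open Non-negative gap opening penalty.
#' @param gap_extend Non-negative gap extension penalty.
#' @param denominator `"alignment_length"` or `"shorter_sequence"`.
#' @return An `identity_params` list.
#' @export
identity_params <- function(substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5,
                            denominator = c("alignment_length",
                                            "shorter_sequence")) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 denominator = match.arg(denominator)),
            class = "identity_params")
}

.subst_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(name) {
  if (!exists(name, envir = .subst_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .subst_cache)
  }
  get(name, envir = .subst_cache)
}

# Align many patterns against one subject; returns percent identities.
# In a global alignment every column consumes a residue from one or both
# sequences, so the alignment length is len_a + len_b - aligned pairs.
align_identity <- function(patterns, subject, params) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = Biostrings::AAString(subject),
    substitutionMatrix = substitution_matrix(params$substitution_matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global"
  )
  ident <- Biostrings::nmatch(aln)
  pairs <- ident + Biostrings::nmismatch(aln)
  den <- switch(params$denominator,
    alignment_length = nchar(patterns) + nchar(subject) - pairs,
    shorter_sequence = pmin(nchar(patterns), nchar(subject))
  )
  100 * ident / den
}

#' Percent identity of a global pairwise alignment
#'
#' Needleman-Wunsch global alignment under `params`; identity is
#' 100 x identical aligned positions / denominator. Symmetric in (a, b).
#'
#' @param a,b Non-empty amino-acid sequences.
#' @param params An [identity_params()].
#' @return Percent identity in \[0, 100\].
#' @examples
#' pairwise_identity("ACDE", "ACD")  # 75
#' @export
pairwise_identity <- function(a, b, params = identity_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  pair <- sort(c(a, b))
  align_identity(pair[1], pair[2], params)
}

# Full identity matrix. One batched alignment call per sequence: visiting
# sequences in lexicographic order with all smaller sequences as patterns
# reproduces pairwise_identity's canonical orientation exactly.
identity_matrix <- function(seqs, params = identity_params()) {
  n <- length(seqs)
  m <- diag(100, n)
  if (n < 2) return(m)
  ord <- order(seqs)
  for (jj in 2:n) {
    j <- ord[jj]
    prev <- ord[1:(jj - 1)]
    vals <- align_identity(seqs[prev], seqs[j], params)
    m[prev, j] <- vals
    m[j, prev] <- vals
  }
  m
}

greedy_reduce_idx <- function(seqs, threshold, params) {
  ord <- order(-nchar(seqs), names(seqs) %||% as.character(seq_along(seqs)))
  reps <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      if (pairwise_identity(seqs[i], seqs[r], params) >= threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, i)
  }
  sort(reps)
}

#' Greedy homology reduction of a dataset
#'
#' CD-HIT-style greedy incremental clustering with exact pairwise identity:
#' sequences are visited longest-first; each joins the first existing cluster
#' whose representative it matches at >= `threshold`, otherwise it founds a
#' new cluster. Cluster representatives are returned. When fine labels are
#' present, reduction is applied per class (each class-specific set reduced
#' independently).
#'
#' @param dataset A `plastid_dataset`.
#' @param threshold Identity threshold in percent, in (0, 100\].
#' @param params An [identity_params()].
#' @return The reduced `plastid_dataset` (original record order preserved).
#' @export
homology_reduce <- function(dataset, threshold = 90,
                            params = identity_params()) {
  if (threshold <= 0 || threshold > 100) stop("threshold must be in (0, 100]")
  groups <- if (all(is.na(dataset$fine))) {
    list(seq_len(nrow(dataset)))
  } else {
    split(seq_len(nrow(dataset)), dataset$fine[seq_len(nrow(dataset))],
          drop = TRUE)
  }
  keep <- integer(0)
  for (idx in groups) {
    seqs <- stats::setNames(dataset$sequence[idx], dataset$id[idx])
    keep <- c(keep, idx[greedy_reduce_idx(seqs, threshold, params)])
  }
  out <- dataset[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("plastid_dataset", "data.frame")
  out
}

#' Homology partitioning into train-test and independent sets
#'
#' Single-linkage clusters are formed over the graph whose edges connect
#' sequence pairs with identity >= `threshold`; whole clusters are then
#' assigned to partitions by a largest-first greedy that moves a cluster to
#' the independent partition whenever doing so brings the achieved fraction
#' closer to `independent_fraction`. With `allow_moving = FALSE` (default) no
#' record ever leaves its cluster, so every cross-partition pair has identity
#' strictly below the threshold.
#'
#' @param dataset A `plastid_dataset`.
#' @param threshold Identity threshold in percent.
#' @param independent_fraction Target fraction of records in the independent
#'   set, in (0, 1).
#' @param allow_moving If TRUE, singleton relocation between partitions would
#'   be permitted; only FALSE (the studied setting) is implemented.
#' @param params An [identity_params()].
#' @return List with `train_test`, `independent` (both `plastid_dataset`),
#'   `clusters` (integer cluster id per record, named by record id) and
#'   `achieved_fraction`.
#' @export
homology_partition <- function(dataset, threshold = 40,
                               independent_fraction = 0.15,
                               allow_moving = FALSE,
                               params = identity_params()) {
  if (independent_fraction <= 0 || independent_fraction >= 1) {
    stop("independent_fraction must be in (0, 1)")
  }
  if (isTRUE(allow_moving)) {
    stop("allow_moving = TRUE is not supported; partitions keep clusters whole")
  }
  n <- nrow(dataset)
  if (n < 2) stop("dataset must contain at least 2 records")
  im <- identity_matrix(dataset$sequence, params)
  adj <- (im >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  if (max(comp) == 1L) {
    stop("all records fall into a single homology cluster; ",
         "both partitions cannot be non-empty")
  }
  # clusters ordered by (size desc, smallest member id)
  cl_ids <- sort(unique(comp))
  sizes <- vapply(cl_ids, function(c) sum(comp == c), integer(1))
  firsts <- vapply(cl_ids, function(c) min(dataset$id[comp == c]), character(1))
  ord <- cl_ids[order(-sizes, firsts)]
  ind_n <- 0L
  ind_clusters <- integer(0)
  for (c in ord) {
    sz <- sum(comp == c)
    if (abs((ind_n + sz) / n - independent_fraction) <
        abs(ind_n / n - independent_fraction)) {
      ind_clusters <- c(ind_clusters, c)
      ind_n <- ind_n + sz
    }
  }
  if (length(ind_clusters) == 0) {
    # keep both partitions non-empty: move the best-fitting cluster
    fit <- abs(sizes / n - independent_fraction)
    ind_clusters <- cl_ids[which.min(fit)]
    ind_n <- sizes[which.min(fit)]
  }
  if (ind_n == n) stop("independent partition would swallow every record")
  in_ind <- comp %in% ind_clusters
  as_ds <- function(d) {
    rownames(d) <- NULL
    class(d) <- c("plastid_dataset", "data.frame")
    d
  }
  list(
    train_test = as_ds(dataset[!in_ind, , drop = FALSE]),
    independent = as_ds(dataset[in_ind, , drop = FALSE]),
    clusters = stats::setNames(as.integer(comp), dataset$id),
    achieved_fraction = ind_n / n
  )
}

#' Per-class mean cross-set identity
#'
#' For each fine class present in both datasets, the mean pairwise identity
#' over all cross-set pairs of that class. Classes absent from either set are
#' reported as NA (missing), never zero. Unlabelled datasets are treated as a
#' single pooled class `"all"`.
#'
#' @param a,b Non-empty `plastid_dataset`s.
#' @param params An [identity_params()].
#' @return Named numeric vector of mean percent identities.
#' @export
mean_cross_identity <- function(a, b, params = identity_params()) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("both datasets must be non-empty")
  pooled <- all(is.na(a$fine)) && all(is.na(b$fine))
  classes <- if (pooled) "all" else fine_classes()
  out <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cls in classes) {
    sa <- if (pooled) a$sequence else a$sequence[!is.na(a$fine) & a$fine == cls]
    sb <- if (pooled) b$sequence else b$sequence[!is.na(b$fine) & b$fine == cls]
    if (length(sa) == 0 || length(sb) == 0) next
    vals <- outer(seq_along(sa), seq_along(sb), Vectorize(function(i, j) {
      pairwise_identity(sa[i], sb[j], params)
    }))
    out[cls] <- mean(vals)
  }
  out
}
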