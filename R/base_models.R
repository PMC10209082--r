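# Lower-level task models: QuiPT-selected n-gram random forests, the Sec/Tat
# profile-HMM scorers, SMOTE oversampling, and the naive multiclass baseline.

NUCLEAR_CLASSES <- c("N_E", "N_TM", "N_S", "N_TL_SEC", "N_TL_TAT")
PLASTID_CLASSES <- c("P_IM", "P_TM", "P_S")
MEMBRANE_CLASSES <- c("N_E", "N_TM", "P_IM", "P_TM")

#' Specification of one lower-level model
#'
#' @param name Model name (unique within an ensemble).
#' @param positive Fine classes forming the positive side of the task.
#' @param negative Fine classes forming the negative side, or `"rest"` (all
#'   other classes). Training uses only records of positive + negative
#'   classes.
#' @param algorithm `"random_forest"` (n-gram features) or `"profile_hmm"`.
#' @param smote Oversample the minority side with SMOTE before fitting.
#' @param feature_alpha QuiPT significance level for feature selection.
#' @param msa_name For `profile_hmm` models: name of the signal MSA (e.g.
#'   `"Sec"`) looked up in the `msas` list at training time.
#' @return A `model_spec`.
#' @export
model_spec <- function(name, positive, negative = "rest",
                       algorithm = c("random_forest", "profile_hmm"),
                       smote = FALSE, feature_alpha = 0.01,
                       msa_name = NULL) {
  algorithm <- match.arg(algorithm)
  if (!identical(negative, "rest") &&
      length(intersect(positive, negative)) > 0) {
    stop("positive and negative class sets must be disjoint")
  }
  if (algorithm == "profile_hmm" && is.null(msa_name)) {
    stop("profile_hmm specs reference an MSA (msa_name)")
  }
  structure(list(name = name, positive = positive, negative = negative,
                 algorithm = algorithm, smote = smote,
                 feature_alpha = feature_alpha, msa_name = msa_name),
            class = "model_spec")
}

#' The default registry of eight lower-level models
#'
#' Reconstructs the eight-model architecture: origin (Nuclear), membrane
#' (Membrane, with SMOTE), plastid membrane (P_IM vs P_TM), nuclear membrane
#' discrimination (N_E vs N_TM), nuclear stroma (N_S vs other nuclear),
#' nuclear membrane vs aqueous nuclear (Nuclear_membrane), and the Sec and
#' Tat profile-HMM signal scorers.
#'
#' @return List of eight `model_spec`s.
#' @export
default_registry <- function() {
  list(
    model_spec("Nuclear", NUCLEAR_CLASSES, PLASTID_CLASSES),
    model_spec("Membrane", MEMBRANE_CLASSES, "rest", smote = TRUE),
    model_spec("Plastid_membrane", "P_IM", "P_TM"),
    model_spec("N_E_vs_N_TM", "N_E", "N_TM"),
    model_spec("N_S_vs_other_nuclear", "N_S",
               setdiff(NUCLEAR_CLASSES, "N_S")),
    model_spec("Nuclear_membrane", c("N_E", "N_TM"),
               c("N_S", "N_TL_SEC", "N_TL_TAT")),
    model_spec("Sec", "N_TL_SEC", "N_TL_TAT",
               algorithm = "profile_hmm", msa_name = "Sec"),
    model_spec("Tat", "N_TL_TAT", "N_TL_SEC",
               algorithm = "profile_hmm", msa_name = "Tat")
  )
}

#' SMOTE oversampling of the minority class on binary features
#'
#' Synthetic minority rows are built by interpolating a minority row toward
#' one of its k nearest minority neighbours (Hamming distance) and rounding
#' at 0.5 (ties round to 1), keeping the feature space binary. Majority rows
#' are untouched; output classes are balanced.
#'
#' @param features Binary feature matrix (rows = records).
#' @param labels Binary vector (1 = positive) aligned with rows.
#' @param k Number of nearest neighbours considered.
#' @param seed Integer seed.
#' @return List with `features` (augmented matrix) and `labels`.
#' @export
smote_oversample <- function(features, labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == n0) return(list(features = features, labels = labels))
  minority <- if (n1 < n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (n_min < 2) {
    stop("minority class has a single member; disable smote for this task")
  }
  Xmin <- as.matrix(features[labels == minority, , drop = FALSE])
  # pairwise Hamming distances among minority rows
  cross <- tcrossprod(Xmin)
  rs <- rowSums(Xmin)
  ham <- outer(rs, rs, "+") - 2 * cross
  diag(ham) <- Inf
  kk <- min(k, n_min - 1L)
  n_new <- n_maj - n_min
  with_rng(seed, {
    base_idx <- rep_len(seq_len(n_min), n_new)
    syn <- matrix(0, n_new, ncol(Xmin))
    for (s in seq_len(n_new)) {
      i <- base_idx[s]
      nb <- order(ham[i, ])[seq_len(kk)]
      j <- nb[sample.int(kk, 1)]
      lambda <- stats::runif(1)
      val <- Xmin[i, ] + lambda * (Xmin[j, ] - Xmin[i, ])
      syn[s, ] <- as.numeric(val >= 0.5)
    }
    colnames(syn) <- colnames(features)
    rownames(syn) <- sprintf("smote_%d", seq_len(n_new))
    aug <- rbind(as.matrix(features), syn)
    list(features = aug, labels = c(labels, rep(minority, n_new)))
  })
}

task_rows <- function(spec, dataset) {
  fine <- dataset$fine
  if (identical(spec$negative, "rest")) {
    pos <- fine %in% spec$positive
    neg <- !is.na(fine) & !pos
  } else {
    pos <- fine %in% spec$positive
    neg <- fine %in% spec$negative
  }
  if (!any(pos) || !any(neg)) {
    missing_side <- if (!any(pos)) "positive" else "negative"
    stop("model '", spec$name, "': no records on the ", missing_side,
         " side of the task")
  }
  list(rows = which(pos | neg), target = as.integer(pos[pos | neg]))
}

#' Train one lower-level model
#'
#' Random-forest specs: the task's records are featurized (binary gapped
#' n-gram presence), QuiPT-selected at `spec$feature_alpha`, optionally SMOTE
#' balanced, and fitted with a 500-tree probability forest
#' (mtry = floor(sqrt(p)), Gini importance, untuned). Profile-HMM specs: a
#' profile is built from the named signal MSA and training-set log-odds
#' scores define the standardization (mean/sd) used at prediction time.
#'
#' @param spec A [model_spec()].
#' @param dataset Labelled `plastid_dataset` containing both task sides.
#' @param seed Integer seed.
#' @param features Optional precomputed [extract_presence()] matrix for the
#'   whole dataset (rows matched by record id).
#' @param msas Named list of signal MSAs (for `profile_hmm` specs).
#' @param hmm_scores Optional precomputed named numeric vector of raw
#'   log-odds scores per record id (skips rescoring).
#' @return A `trained_model`.
#' @export
train_model <- function(spec, dataset, seed = 1L, features = NULL,
                        msas = NULL, hmm_scores = NULL) {
  tr <- task_rows(spec, dataset)
  if (spec$algorithm == "profile_hmm") {
    if (is.null(msas) || is.null(msas[[spec$msa_name]])) {
      stop("model '", spec$name, "' needs MSA '", spec$msa_name, "'")
    }
    hmm <- build_from_msa(msas[[spec$msa_name]])
    raw <- if (!is.null(hmm_scores)) {
      hmm_scores[dataset$id[tr$rows]]
    } else {
      vapply(dataset$sequence[tr$rows], function(s) score_logodds(hmm, s),
             numeric(1))
    }
    mu <- mean(raw); sdv <- stats::sd(raw)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    model <- structure(list(spec = spec, hmm = hmm, mean = mu, sd = sdv),
                       class = "trained_model")
    return(model)
  }
  if (is.null(features)) features <- extract_presence(dataset)
  X <- features[dataset$id[tr$rows], , drop = FALSE]
  sel <- suppressWarnings(select_features(X, tr$target, spec$feature_alpha))
  Xs <- sel$matrix
  y <- tr$target
  if (ncol(Xs) == 0) {
    # degenerate: no informative pattern; fall back to the empirical rate
    model <- structure(list(spec = spec, patterns = character(0),
                            prior = mean(y)), class = "trained_model")
    return(model)
  }
  Xd <- as.matrix(Xs)
  if (isTRUE(spec$smote)) {
    aug <- smote_oversample(Xd, y, seed = child_seed(seed, spec$name))
    Xd <- aug$features; y <- aug$labels
  }
  fit <- ranger::ranger(
    x = Xd, y = factor(y, levels = c(0, 1)),
    num.trees = 500, mtry = max(1L, floor(sqrt(ncol(Xd)))),
    probability = TRUE, importance = "impurity",
    seed = child_seed(seed, spec$name), num.threads = 1
  )
  structure(list(spec = spec, patterns = colnames(Xd), forest = fit),
            class = "trained_model")
}

#' Positive-class probabilities / standardized scores of a trained model
#'
#' For forests: probability of the positive task side. For HMM models: the
#' z-scored log-odds of the sequence (standardized by the training mean/sd).
#' Feature columns absent from the model's selection contribute zeros.
#'
#' @param model A `trained_model`.
#' @param dataset A `plastid_dataset` to score.
#' @param features Optional precomputed feature matrix for `dataset`.
#' @param hmm_scores Optional precomputed raw log-odds per record id.
#' @return Numeric vector, one value per record.
#' @export
predict_model <- function(model, dataset, features = NULL, hmm_scores = NULL) {
  if (!is.null(model$hmm)) {
    raw <- if (!is.null(hmm_scores)) {
      unname(hmm_scores[dataset$id])
    } else {
      vapply(dataset$sequence, function(s) score_logodds(model$hmm, s),
             numeric(1), USE.NAMES = FALSE)
    }
    return((raw - model$mean) / model$sd)
  }
  if (is.null(model$forest)) {
    return(rep(model$prior, nrow(dataset)))
  }
  if (is.null(features)) features <- extract_presence(dataset)
  have <- intersect(model$patterns, colnames(features))
  X <- matrix(0, nrow(dataset), length(model$patterns),
              dimnames = list(dataset$id, model$patterns))
  if (length(have) > 0) {
    X[, have] <- as.matrix(features[dataset$id, have, drop = FALSE])
  }
  pr <- stats::predict(model$forest, data = X, num.threads = 1)$predictions
  unname(pr[, "1"])
}

#' Count model features embeddable in a sequence motif
#'
#' Among a random-forest model's selected patterns (optionally the `top_k`
#' by Gini importance), counts those whose gapped match window embeds fully
#' in the given motif string.
#'
#' @param model A `trained_model` with a fitted forest.
#' @param motif Amino-acid motif string, e.g. `"DPLG"`.
#' @param top_k Restrict to the k most important patterns (all if NULL).
#' @return Integer count.
#' @export
count_motif_matching_features <- function(model, motif, top_k = NULL) {
  if (is.null(model$forest)) stop("model has no fitted forest with importances")
  pats <- model$patterns
  if (!is.null(top_k)) {
    imp <- ranger::importance(model$forest)
    pats <- names(sort(imp, decreasing = TRUE))[seq_len(min(top_k, length(imp)))]
  }
  sum(vapply(pats, pattern_matches_motif, logical(1), motif = motif))
}

#' Train the naive multiclass baseline forest
#'
#' A single untuned 500-tree probability forest over all classes at once,
#' fitted on the full (unselected) n-gram presence matrix; patterns absent
#' from every training record are dropped (they carry no split information).
#'
#' @param dataset Labelled `plastid_dataset` with >= 2 classes.
#' @param seed Integer seed.
#' @param features Optional precomputed feature matrix.
#' @return A `trained_model` with a `classes` field.
#' @export
train_baseline <- function(dataset, seed = 1L, features = NULL) {
  labelled <- !is.na(dataset$fine)
  ds <- dataset[labelled, , drop = FALSE]
  classes <- intersect(fine_classes(), unique(ds$fine))
  if (length(classes) < 2) stop("baseline needs >= 2 classes")
  if (is.null(features)) features <- extract_presence(ds)
  X <- features[ds$id, , drop = FALSE]
  seen <- Matrix::colSums(X) > 0
  Xd <- as.matrix(X[, seen, drop = FALSE])
  fit <- ranger::ranger(
    x = Xd, y = factor(ds$fine, levels = classes),
    num.trees = 500, mtry = max(1L, floor(sqrt(ncol(Xd)))),
    probability = TRUE, importance = "impurity",
    seed = child_seed(seed, "baseline"), num.threads = 1
  )
  structure(list(spec = list(name = "baseline", algorithm = "random_forest"),
                 patterns = colnames(Xd), forest = fit, classes = classes),
            class = "trained_model")
}

#' Class probabilities of the baseline model
#'
#' @param model Baseline `trained_model` from [train_baseline()].
#' @param dataset A `plastid_dataset`.
#' @param features Optional precomputed feature matrix.
#' @return Matrix (records x classes) of probabilities summing to 1 per row.
#' @export
predict_baseline <- function(model, dataset, features = NULL) {
  if (is.null(features)) features <- extract_presence(dataset)
  have <- intersect(model$patterns, colnames(features))
  X <- matrix(0, nrow(dataset), length(model$patterns),
              dimnames = list(dataset$id, model$patterns))
  X[, have] <- as.matrix(features[dataset$id, have, drop = FALSE])
  pr <- stats::predict(model$forest, data = X, num.threads = 1)$predictions
  pr[, model$classes, drop = FALSE]
}
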