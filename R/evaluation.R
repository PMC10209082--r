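# Repeated stratified cross-validation and the evaluation metrics:
# Cohen's kappa, Hand-Till average one-vs-one multiclass AUC (AU1U), and
# class-specific accuracy (per-class recall).

#' Confusion matrix over the fine classes
#'
#' @param truth,predicted Character vectors of class labels.
#' @param classes Class levels (default: classes present in either vector,
#'   canonical order).
#' @return A k x k count matrix (rows = truth, columns = predicted).
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) {
    classes <- intersect(fine_classes(), union(truth, predicted))
    if (length(classes) == 0) classes <- sort(union(truth, predicted))
  }
  table(factor(truth, levels = classes),
        factor(predicted, levels = classes))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e) with p_o = trace/total
#' and p_e the product-of-margins expectation. The degenerate case p_e = 1
#' (all mass in one row-column pair) is defined as 0 with a warning.
#'
#' @param confusion k x k count matrix (rows = truth, columns = predicted).
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohen_kappa(matrix(c(40, 20, 10, 30), 2))  # 0.4
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  total <- sum(m)
  if (total <= 0) stop("confusion matrix must have positive total")
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate confusion matrix (p_e = 1); kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Hand-Till average one-vs-one multiclass AUC (AU1U)
#'
#' Mean over unordered class pairs (i, j) of (A(i|j) + A(j|i)) / 2, where
#' A(i|j) is the rank-based probability that a class-i example receives a
#' higher predicted probability of class i than a class-j example does; ties
#' are credited 0.5. Pairs involving a class absent from `truth` are
#' skipped.
#'
#' @param probabilities n x k matrix of class probabilities (columns named
#'   by class), rows summing to 1.
#' @param truth Character vector of true class labels (length n).
#' @return AU1U in \[0, 1\].
#' @export
au1u <- function(probabilities, truth) {
  classes <- colnames(probabilities)
  present <- intersect(classes, unique(truth))
  if (length(present) < 2) stop("need >= 2 classes present in truth")
  pair_auc <- function(i, j) {
    # A(i|j): rank i-probabilities of true-i vs true-j examples
    pi_ <- probabilities[truth == i, i]
    pj_ <- probabilities[truth == j, i]
    r <- rank(c(pi_, pj_))
    ni <- length(pi_); nj <- length(pj_)
    (sum(r[seq_len(ni)]) - ni * (ni + 1) / 2) / (ni * nj)
  }
  vals <- c()
  for (a in seq_len(length(present) - 1)) {
    for (b in (a + 1):length(present)) {
      i <- present[a]; j <- present[b]
      vals <- c(vals, (pair_auc(i, j) + pair_auc(j, i)) / 2)
    }
  }
  mean(vals)
}

#' Class-specific accuracies (per-class recall)
#'
#' For each class c: correctly predicted members of c divided by the true
#' members of c. Classes with no true members are NA (missing), never 0.
#'
#' @param confusion k x k count matrix (rows = truth, columns = predicted).
#' @return Named numeric vector of per-class accuracies.
#' @export
class_accuracy <- function(confusion) {
  m <- as.matrix(confusion)
  totals <- rowSums(m)
  acc <- ifelse(totals > 0, diag(m) / totals, NA_real_)
  stats::setNames(acc, rownames(m))
}

# Stratified fold assignment: within each class, shuffled records are dealt
# to folds round-robin, so fold class proportions are within one record of
# the overall proportions.
stratified_folds <- function(fine, folds, seed) {
  assign_f <- integer(length(fine))
  with_rng(seed, {
    for (cls in unique(fine)) {
      idx <- which(fine == cls)
      if (length(idx) < folds) {
        warning("class ", cls, " has fewer members (", length(idx),
                ") than folds (", folds, "); best-effort stratification")
      }
      assign_f[idx] <- (sample(seq_along(idx)) %% folds) + 1L
    }
  })
  assign_f
}

#' Repeated stratified cross-validation of an ensemble (or the baseline)
#'
#' Per repetition a fresh stratified fold assignment is drawn; within each
#' fold iteration the lower models are trained on the k-1 training folds,
#' the higher model on those folds' meta-features, and metrics are computed
#' on the held-out fold. All fold x repetition cells are pooled for the
#' aggregate means and standard deviations.
#'
#' @param config An [ensemble_config()], or the string `"baseline"` for the
#'   naive multiclass forest.
#' @param dataset Labelled `plastid_dataset`.
#' @param folds Number of folds (default 5).
#' @param reps Number of repetitions (default 5).
#' @param seed Integer seed (controls fold assignments and model fits).
#' @param msas Named list of signal MSAs for HMM specs.
#' @param features Optional precomputed feature matrix for `dataset`
#'   (computed once internally otherwise).
#' @return An `evaluation_report`: data.frame `cells` (rep, fold, kappa,
#'   au1u, per-class accuracy), `summary` (means and sds), `confusions`.
#' @export
repeated_stratified_cv <- function(config, dataset, folds = 5L, reps = 5L,
                                   seed = 1L, msas = NULL, features = NULL) {
  if (folds < 2) stop("folds must be >= 2")
  baseline <- identical(config, "baseline")
  if (!baseline) stopifnot(inherits(config, "ensemble_config"))
  ds <- dataset[!is.na(dataset$fine), , drop = FALSE]
  class(ds) <- c("plastid_dataset", "data.frame")
  classes <- intersect(fine_classes(), unique(ds$fine))
  if (is.null(features)) features <- extract_presence(ds)
  # raw HMM scores depend only on the fixed signal MSAs: compute once
  hmm_scores <- NULL
  if (!baseline) {
    hmm_specs <- Filter(function(s) s$algorithm == "profile_hmm",
                        config$lower)
    if (length(hmm_specs) > 0) {
      if (is.null(msas)) stop("ensemble contains HMM specs; msas required")
      hmm_scores <- stats::setNames(lapply(hmm_specs, function(spec) {
        hmm <- build_from_msa(msas[[spec$msa_name]])
        stats::setNames(
          vapply(ds$sequence, function(s) score_logodds(hmm, s), numeric(1),
                 USE.NAMES = FALSE),
          ds$id)
      }), vapply(hmm_specs, `[[`, character(1), "name"))
    }
  }
  cells <- NULL
  confusions <- list()
  for (rep_i in seq_len(reps)) {
    assign_f <- stratified_folds(ds$fine, folds,
                                 child_seed(seed, paste0("rep", rep_i)))
    for (fold_i in seq_len(folds)) {
      tr <- ds[assign_f != fold_i, , drop = FALSE]
      te <- ds[assign_f == fold_i, , drop = FALSE]
      class(tr) <- class(te) <- c("plastid_dataset", "data.frame")
      fit_seed <- child_seed(seed, sprintf("r%df%d", rep_i, fold_i))
      if (baseline) {
        model <- train_baseline(tr, seed = fit_seed, features = features)
        probs <- predict_baseline(model, te, features = features)
      } else {
        ens <- train_stacked(config, tr, seed = fit_seed, msas = msas,
                             features = features, hmm_scores = hmm_scores)
        rep_out <- predict(ens, te, features = features,
                           hmm_scores = hmm_scores)
        probs <- as.matrix(rep_out[, paste0("prob_", ens$classes)])
        colnames(probs) <- ens$classes
      }
      pred <- colnames(probs)[apply(probs, 1, which.max)]
      conf <- confusion_matrix(te$fine, pred, classes = classes)
      acc <- class_accuracy(conf)
      cell <- data.frame(rep = rep_i, fold = fold_i,
                         kappa = cohen_kappa(conf),
                         au1u = au1u(probs, te$fine))
      for (cls in classes) cell[[paste0("acc_", cls)]] <- acc[[cls]]
      cells <- rbind(cells, cell)
      confusions[[sprintf("rep%d_fold%d", rep_i, fold_i)]] <- conf
    }
  }
  metric_cols <- setdiff(names(cells), c("rep", "fold"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(cells[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(cells[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL
  )
  structure(list(cells = cells, summary = summary, confusions = confusions,
                 config = if (baseline) "baseline" else config,
                 folds = folds, reps = reps),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", x$reps, "x", x$folds, "repeated stratified CV\n")
  k <- x$summary[x$summary$metric == "kappa", ]
  a <- x$summary[x$summary$metric == "au1u", ]
  cat(sprintf("  mean kappa %.3f (sd %.3f), mean AU1U %.3f (sd %.3f)\n",
              k$mean, k$sd, a$mean, a$sd))
  invisible(x)
}

report_mean <- function(report, metric = "kappa") {
  report$summary$mean[report$summary$metric == metric]
}

#' Select the best configuration by mean CV kappa
#'
#' Argmax of mean kappa over the reports; exact ties are broken by fewer
#' lower-level models, then by report order.
#'
#' @param reports List of `evaluation_report`s (each carrying its config).
#' @return The winning config (an `ensemble_config` or `"baseline"`).
#' @export
select_best <- function(reports) {
  if (length(reports) == 0) stop("no reports supplied")
  kappas <- vapply(reports, report_mean, numeric(1))
  n_lower <- vapply(reports, function(r) {
    if (identical(r$config, "baseline")) 1L else length(r$config$lower)
  }, integer(1))
  ord <- order(-kappas, n_lower, seq_along(reports))
  reports[[ord[1]]]$config
}
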