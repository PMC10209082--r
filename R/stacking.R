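# Stacked ensembles: lower-level models feed a higher-level aggregator,
# optionally with conditionally restricted routing (expert rules that mask
# some models for records failing a guard model's decision).

#' Default conditional routing rules
#'
#' One expert rule: records the Nuclear guard calls plastid-encoded
#' (probability of nuclear strictly below 0.5; ties keep models active) are
#' not processed by the nuclear-specific models.
#'
#' @return List of routing rules (`guard`, `when`, `inactive`).
#' @export
default_routing_rules <- function() {
  list(list(
    guard = "Nuclear", when = "negative",
    inactive = c("N_E_vs_N_TM", "N_S_vs_other_nuclear", "Nuclear_membrane",
                 "Sec", "Tat")
  ))
}

#' Configuration of a stacked ensemble
#'
#' An ensemble is a pair (S, G): a set S of lower-level models and an
#' aggregation function G which is itself a predictive model (model
#' stacking). The final prediction is G applied to the lower models' outputs.
#'
#' @param lower List of [model_spec()]s (the set S).
#' @param higher `"random_forest"` or `"multinomial_log_linear"` (G).
#' @param conditional Use conditionally restricted routing.
#' @param routing_rules Routing rules (default [default_routing_rules()]
#'   when `conditional`); each rule: `guard` (model name), `when`
#'   (`"positive"`/`"negative"` guard outcome), `inactive` (model names
#'   masked when the rule fires).
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(lower = default_registry(),
                            higher = c("random_forest",
                                       "multinomial_log_linear"),
                            conditional = FALSE, routing_rules = NULL) {
  higher <- match.arg(higher)
  names(lower) <- vapply(lower, function(s) s$name, character(1))
  if (anyDuplicated(names(lower))) stop("duplicate lower model names")
  if (conditional && is.null(routing_rules)) {
    routing_rules <- default_routing_rules()
  }
  if (!conditional) routing_rules <- list()
  for (rule in routing_rules) {
    if (!rule$guard %in% names(lower)) {
      stop("routing rule guard '", rule$guard, "' is not a lower model")
    }
    if (rule$guard %in% rule$inactive) {
      stop("guard '", rule$guard, "' cannot be guarded by itself")
    }
    if (!all(rule$inactive %in% names(lower))) {
      stop("routing rule references unknown model(s)")
    }
  }
  if (length(routing_rules) > 1) {
    edges <- do.call(rbind, lapply(routing_rules, function(r) {
      cbind(r$guard, r$inactive)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g)) stop("cyclic guard structure in routing rules")
  }
  structure(list(lower = lower, higher = higher, conditional = conditional,
                 routing_rules = routing_rules),
            class = "ensemble_config")
}

#' Active-model mask from routing rules
#'
#' @param rules Routing rules (see [ensemble_config()]).
#' @param guard_outputs Named list mapping guard model name to its
#'   positive-side probability vector over the records.
#' @param model_names Names of all lower models.
#' @param n_records Number of records.
#' @return Logical matrix (records x models); TRUE = active. With no rules,
#'   all TRUE.
#' @export
apply_routing <- function(rules, guard_outputs, model_names, n_records) {
  mask <- matrix(TRUE, n_records, length(model_names),
                 dimnames = list(NULL, model_names))
  for (rule in rules) {
    p <- guard_outputs[[rule$guard]]
    if (is.null(p)) stop("no guard output for '", rule$guard, "'")
    fires <- if (rule$when == "negative") p < 0.5 else p > 0.5
    mask[fires, rule$inactive] <- FALSE
  }
  mask
}

maskable_models <- function(config) {
  unique(unlist(lapply(config$routing_rules, function(r) r$inactive)))
}

#' Meta-feature matrix from trained lower models
#'
#' One column per lower model (positive-class probability for forests,
#' standardized log-odds for HMM scorers). Under conditional routing, masked
#' cells are set to 0 and a companion `mask_<model>` indicator column is 1
#' for the masked records.
#'
#' @param models Named list of `trained_model`s.
#' @param dataset A `plastid_dataset`.
#' @param config The `ensemble_config` (for routing).
#' @param features,hmm_scores Optional precomputed features / raw HMM scores
#'   (named list per HMM model).
#' @return Numeric matrix of meta-features.
#' @export
build_meta_features <- function(models, dataset, config,
                                features = NULL, hmm_scores = NULL) {
  if (is.null(features)) features <- extract_presence(dataset)
  outs <- vapply(names(models), function(nm) {
    predict_model(models[[nm]], dataset, features = features,
                  hmm_scores = hmm_scores[[nm]])
  }, numeric(nrow(dataset)))
  outs <- matrix(outs, nrow = nrow(dataset),
                 dimnames = list(dataset$id, names(models)))
  maskable <- maskable_models(config)
  if (length(config$routing_rules) > 0) {
    guards <- unique(vapply(config$routing_rules, `[[`, character(1), "guard"))
    guard_outputs <- stats::setNames(
      lapply(guards, function(g) outs[, g]), guards)
    mask <- apply_routing(config$routing_rules, guard_outputs,
                          names(models), nrow(dataset))
    outs[!mask] <- 0
    mask_cols <- matrix(as.numeric(!mask[, maskable, drop = FALSE]),
                        nrow = nrow(dataset),
                        dimnames = list(dataset$id,
                                        paste0("mask_", maskable)))
    outs <- cbind(outs, mask_cols)
  }
  outs
}

#' Train a stacked ensemble
#'
#' Lower models are trained on the full training data; the higher-level
#' model is trained on meta-features computed on that same training data
#' (in-sample stacking; set `out_of_fold = TRUE` for out-of-fold
#' meta-features instead). The higher model is a 500-tree probability forest
#' or a multinomial log-linear model with a tiny L2 ridge (decay 1e-6).
#'
#' @param config An [ensemble_config()].
#' @param dataset Labelled `plastid_dataset`.
#' @param seed Integer seed.
#' @param msas Named list of signal MSAs for the HMM specs.
#' @param features,hmm_scores Optional precomputed features / raw HMM score
#'   vectors (named list per HMM model name, each a named vector by id).
#' @param envelope_submodel Train the optional N_E OM/IM sub-model (needs
#'   `side` labels on N_E records).
#' @param out_of_fold Use 5-fold out-of-fold lower-model predictions as the
#'   higher model's training meta-features (default FALSE).
#' @return A `stacked_ensemble`.
#' @export
train_stacked <- function(config, dataset, seed = 1L, msas = NULL,
                          features = NULL, hmm_scores = NULL,
                          envelope_submodel = FALSE, out_of_fold = FALSE) {
  stopifnot(inherits(config, "ensemble_config"))
  labelled <- !is.na(dataset$fine)
  ds <- dataset[labelled, , drop = FALSE]
  class(ds) <- c("plastid_dataset", "data.frame")
  classes <- intersect(fine_classes(), unique(ds$fine))
  if (length(classes) < length(fine_classes())) {
    warning("absent fine class(es) dropped from the output space: ",
            paste(setdiff(fine_classes(), classes), collapse = ", "))
  }
  if (is.null(features)) features <- extract_presence(ds)
  models <- stats::setNames(lapply(config$lower, function(spec) {
    train_model(spec, ds, seed = seed, features = features, msas = msas,
                hmm_scores = hmm_scores[[spec$name]])
  }), names(config$lower))
  meta <- if (out_of_fold) {
    oof_meta_features(config, ds, seed, msas, features, hmm_scores)
  } else {
    build_meta_features(models, ds, config, features, hmm_scores)
  }
  y <- factor(ds$fine, levels = classes)
  higher <- fit_higher(config$higher, meta, y, seed)
  env_model <- NULL
  if (envelope_submodel) {
    env_model <- train_envelope_submodel(ds, seed, features)
  }
  structure(list(config = config, models = models, higher = higher,
                 classes = classes, meta_columns = colnames(meta),
                 envelope_submodel = env_model),
            class = "stacked_ensemble")
}

fit_higher <- function(type, meta, y, seed) {
  if (type == "random_forest") {
    fit <- ranger::ranger(
      x = meta, y = y, num.trees = 500,
      mtry = max(1L, floor(sqrt(ncol(meta)))),
      probability = TRUE, seed = child_seed(seed, "higher"),
      num.threads = 1
    )
    list(type = type, fit = fit)
  } else {
    df <- data.frame(meta, check.names = FALSE)
    df$.y <- y
    fit <- nnet::multinom(.y ~ ., data = df, decay = 1e-6, trace = FALSE,
                          maxit = 500, MaxNWts = 5000)
    list(type = type, fit = fit, levels = levels(y))
  }
}

predict_higher <- function(higher, meta, classes) {
  if (higher$type == "random_forest") {
    pr <- stats::predict(higher$fit, data = meta,
                         num.threads = 1)$predictions
    pr[, classes, drop = FALSE]
  } else {
    pr <- stats::predict(higher$fit, newdata = data.frame(meta, check.names = FALSE),
                         type = "probs")
    if (is.null(dim(pr))) {  # two-class multinom returns P(second level)
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- higher$levels
    }
    pr[, classes, drop = FALSE]
  }
}

# Out-of-fold meta-features: lower models refit per internal fold so the
# higher model never sees in-sample lower-model predictions.
oof_meta_features <- function(config, ds, seed, msas, features, hmm_scores,
                              folds = 5L) {
  assign_f <- stratified_folds(ds$fine, folds, child_seed(seed, "oof"))
  meta <- NULL
  for (f in sort(unique(assign_f))) {
    tr_idx <- which(assign_f != f); te_idx <- which(assign_f == f)
    tr <- ds[tr_idx, , drop = FALSE]; te <- ds[te_idx, , drop = FALSE]
    class(tr) <- class(te) <- c("plastid_dataset", "data.frame")
    models <- stats::setNames(lapply(config$lower, function(spec) {
      train_model(spec, tr, seed = seed, features = features, msas = msas,
                  hmm_scores = hmm_scores[[spec$name]])
    }), names(config$lower))
    mf <- build_meta_features(models, te, config, features, hmm_scores)
    meta <- rbind(meta, mf)
  }
  meta[ds$id, , drop = FALSE]
}

train_envelope_submodel <- function(ds, seed, features) {
  ne <- ds[!is.na(ds$fine) & ds$fine == "N_E" & !is.na(ds$side), ,
           drop = FALSE]
  if (nrow(ne) < 4 || length(unique(ne$side)) < 2) {
    warning("not enough sided N_E records; envelope sub-model skipped")
    return(NULL)
  }
  X <- features[ne$id, , drop = FALSE]
  y <- as.integer(ne$side == "IM")
  sel <- suppressWarnings(select_features(X, y, alpha = 0.05))
  Xd <- as.matrix(if (ncol(sel$matrix) > 0) sel$matrix else X[, Matrix::colSums(X) > 0, drop = FALSE])
  fit <- ranger::ranger(
    x = Xd, y = factor(ne$side, levels = c("IM", "OM")),
    num.trees = 500, mtry = max(1L, floor(sqrt(ncol(Xd)))),
    probability = TRUE, seed = child_seed(seed, "envelope"), num.threads = 1
  )
  list(patterns = colnames(Xd), forest = fit)
}

#' Predict with a stacked ensemble
#'
#' Per record: probabilities over the fine classes, the argmax fine class
#' (ties broken by canonical class order), the derived origin and
#' generalized localization, the import pathway for thylakoid-lumen calls,
#' and — when the envelope sub-model is attached and the call is N_E — an
#' additional OM/IM side call with its probability.
#'
#' @param object A `stacked_ensemble`.
#' @param dataset A `plastid_dataset` (labels not required).
#' @param features Optional precomputed feature matrix.
#' @param hmm_scores Optional precomputed raw HMM scores (named list).
#' @param ... Unused.
#' @return A data.frame report, one row per record.
#' @export
predict.stacked_ensemble <- function(object, dataset, features = NULL,
                                     hmm_scores = NULL, ...) {
  if (is.null(features)) features <- extract_presence(dataset)
  meta <- build_meta_features(object$models, dataset, object$config,
                              features, hmm_scores)
  meta <- meta[, object$meta_columns, drop = FALSE]
  probs <- predict_higher(object$higher, meta, object$classes)
  fine <- object$classes[apply(probs, 1, which.max)]
  mg <- map_generalized(fine)
  pathway <- ifelse(fine == "N_TL_SEC", "Sec",
                    ifelse(fine == "N_TL_TAT", "Tat", NA_character_))
  out <- data.frame(id = dataset$id, fine = fine, stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob_", object$classes)
  out <- cbind(out, probs)
  out$origin <- mg$origin
  out$localization <- mg$generalized
  out$pathway <- pathway
  out$envelope_side <- NA_character_
  out$envelope_side_prob <- NA_real_
  sub <- object$envelope_submodel
  if (!is.null(sub) && any(fine == "N_E")) {
    idx <- which(fine == "N_E")
    have <- intersect(sub$patterns, colnames(features))
    X <- matrix(0, length(idx), length(sub$patterns),
                dimnames = list(dataset$id[idx], sub$patterns))
    X[, have] <- as.matrix(features[dataset$id[idx], have, drop = FALSE])
    pr <- stats::predict(sub$forest, data = X, num.threads = 1)$predictions
    side <- colnames(pr)[apply(pr, 1, which.max)]
    out$envelope_side[idx] <- side
    out$envelope_side_prob[idx] <- pr[cbind(seq_along(idx),
                                            apply(pr, 1, which.max))]
  }
  rownames(out) <- NULL
  out
}

#' Enumerate lower-level model sets from a slot grammar
#'
#' The grammar is a list of slots; each slot is a list of choices and each
#' choice is a character vector of model names (possibly empty). The result
#' is the Cartesian product of one choice per slot, each combination
#' flattened to the union of its names, deduplicated.
#'
#' @param grammar List of slots (lists of character vectors).
#' @return List of unique character vectors (model sets).
#' @export
enumerate_model_sets <- function(grammar) {
  if (length(grammar) == 0) stop("empty grammar")
  for (slot in grammar) {
    if (length(slot) == 0) stop("empty slot in grammar")
  }
  idx <- expand.grid(lapply(grammar, seq_along))
  sets <- lapply(seq_len(nrow(idx)), function(r) {
    sort(unique(unlist(lapply(seq_along(grammar), function(s) {
      grammar[[s]][[idx[r, s]]]
    }))))
  })
  unique(sets)
}

#' Cross model sets with ensemble and higher-level model types
#'
#' Every lower-level model set combines with the two ensemble types (plain /
#' conditionally restricted) and the two higher-level model types (random
#' forest / multinomial log-linear), multiplying the count by 4.
#'
#' @param sets List of model sets from [enumerate_model_sets()], or a single
#'   integer count of sets.
#' @return If `sets` is a count: the total number of ensemble
#'   configurations. Otherwise a data.frame grid with columns `set_index`,
#'   `conditional`, `higher`.
#' @export
ensemble_grid <- function(sets) {
  if (is.numeric(sets) && length(sets) == 1) {
    return(as.integer(sets) * 2L * 2L)
  }
  expand.grid(
    set_index = seq_along(sets),
    conditional = c(FALSE, TRUE),
    higher = c("random_forest", "multinomial_log_linear"),
    stringsAsFactors = FALSE
  )
}
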