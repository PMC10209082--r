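small_dataset <- function(n = 8, seed = 31) {
  generate_dataset(generator_config(n_per_class = n, seed = seed))
}

test_msas <- function(seed = 91) {
  list(Sec = generate_signal_msa("Sec", 30, seed),
       Tat = generate_signal_msa("Tat", 30, seed + 1))
}

test_that("the default registry encodes the eight-model architecture", {
  reg <- default_registry()
  expect_length(reg, 8)
  names(reg) <- vapply(reg, function(s) s$name, character(1))
  expect_setequal(reg$Nuclear$positive,
                  c("N_E", "N_TM", "N_S", "N_TL_SEC", "N_TL_TAT"))
  expect_setequal(reg$Membrane$positive, c("N_E", "N_TM", "P_IM", "P_TM"))
  expect_identical(reg$Plastid_membrane$positive, "P_IM")
  expect_identical(reg$Plastid_membrane$negative, "P_TM")
  expect_identical(reg$Sec$algorithm, "profile_hmm")
  expect_identical(reg$Tat$algorithm, "profile_hmm")
  expect_error(model_spec("bad", "N_S", "N_S"), "disjoint")
  expect_error(model_spec("bad", "N_S", algorithm = "profile_hmm"), "MSA")
})

test_that("SMOTE balances classes without touching majority rows", {
  set.seed(8)
  X <- matrix(rbinom(15 * 8, 1, 0.5), 15, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- c(rep(1, 5), rep(0, 10))
  aug <- smote_oversample(X, y, seed = 4)
  expect_identical(as.integer(table(aug$labels)), c(10L, 10L))
  expect_equal(aug$features[6:15, ], X[6:15, ], ignore_attr = TRUE)
  expect_true(all(aug$features %in% c(0, 1)))
  expect_identical(smote_oversample(X, y, seed = 4), aug)
  # synthetic rows interpolate between identical points exactly
  Xi <- rbind(X[1, ], X[1, ], X[6:15, ])
  a2 <- smote_oversample(Xi, c(1, 1, rep(0, 10)), seed = 1)
  syn <- a2$features[13:20, , drop = FALSE]
  expect_true(all(apply(syn, 1, function(r) all(r == X[1, ]))))
  # balanced input is a no-op
  expect_identical(smote_oversample(X[1:10, ], rep(c(1, 0), each = 5),
                                    seed = 1)$features, X[1:10, ])
  expect_error(smote_oversample(X, c(1, rep(0, 14)), seed = 1), "single")
})

test_that("forest training separates a separable task deterministically", {
  ds <- small_dataset(5)
  X <- extract_presence(ds)
  spec <- model_spec("Nuclear", c("N_E", "N_TM", "N_S", "N_TL_SEC",
                                  "N_TL_TAT"), "rest")
  m1 <- train_model(spec, ds, seed = 2, features = X)
  p1 <- predict_model(m1, ds, features = X)
  expect_true(all(p1 >= 0 & p1 <= 1))
  truth <- as.integer(startsWith(ds$fine, "N_"))
  expect_identical(as.integer(p1 > 0.5), truth)  # training-set separation
  m2 <- train_model(spec, ds, seed = 2, features = X)
  expect_identical(predict_model(m2, ds, features = X), p1)
  # one-sided data is refused with the missing side named
  one_sided <- ds[startsWith(ds$fine, "P_"), ]
  class(one_sided) <- c("plastid_dataset", "data.frame")
  expect_error(train_model(spec, one_sided, features = X), "positive")
})

test_that("fold-local selection scores unseen records without leakage", {
  ds <- small_dataset(6)
  X <- extract_presence(ds)
  half <- ds[seq(1, nrow(ds), by = 2), ]
  rest <- ds[seq(2, nrow(ds), by = 2), ]
  class(half) <- class(rest) <- c("plastid_dataset", "data.frame")
  spec <- model_spec("Membrane", c("N_E", "N_TM", "P_IM", "P_TM"), "rest")
  m <- train_model(spec, half, seed = 3, features = X)
  # features recomputed independently for the held-out half: any selected
  # pattern absent there scores 0, never errors
  p <- predict_model(m, rest, features = extract_presence(rest))
  expect_length(p, nrow(rest))
  expect_false(anyNA(p))
})

test_that("HMM models score standardized log-odds", {
  ds <- small_dataset(6)
  spec <- model_spec("Tat", "N_TL_TAT", "N_TL_SEC",
                     algorithm = "profile_hmm", msa_name = "Tat")
  m <- train_model(spec, ds, seed = 1, msas = test_msas())
  z <- predict_model(m, ds)
  task <- ds$fine %in% c("N_TL_TAT", "N_TL_SEC")
  expect_equal(mean(z[task]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z[task]), 1, tolerance = 1e-9)
  expect_gt(mean(z[ds$fine == "N_TL_TAT"]), mean(z[ds$fine == "N_TL_SEC"]))
})

test_that("motif-matching counts embeddable gapped patterns", {
  ds <- small_dataset(5)
  X <- extract_presence(ds)
  spec <- model_spec("Nuclear_membrane", c("N_E", "N_TM"),
                     c("N_S", "N_TL_SEC", "N_TL_TAT"))
  m <- train_model(spec, ds, seed = 4, features = X)
  for (pat in c("DP_G", "PLG", "D_LG", "D__G")) {
    expect_true(pattern_matches_motif(pat, "DPLG"), label = pat)
  }
  expect_false(pattern_matches_motif("AA", "DPLG"))
  n_all <- count_motif_matching_features(m, "DPLG")
  n_top <- count_motif_matching_features(m, "DPLG", top_k = 50)
  expect_lte(n_top, n_all)
  expect_lte(n_top, 50)
})

test_that("the baseline forest yields proper 8-class probabilities", {
  ds <- small_dataset(5)
  X <- extract_presence(ds)
  bl <- train_baseline(ds, seed = 9, features = X)
  pr <- predict_baseline(bl, ds, features = X)
  expect_identical(dim(pr), c(nrow(ds), 8L))
  expect_equal(unname(rowSums(pr)), rep(1, nrow(ds)), tolerance = 1e-9)
  bl2 <- train_baseline(ds, seed = 9, features = X)
  expect_identical(predict_baseline(bl2, ds, features = X), pr)
  single <- ds[ds$fine == "N_S", ]
  class(single) <- c("plastid_dataset", "data.frame")
  expect_error(train_baseline(single, features = X), ">= 2 classes")
})

test_that("imbalance sinks the baseline's rare class but not the ensemble", {
  counts <- stats::setNames(c(20L, 40L, 50L, 6L, 10L, 30L, 120L, 60L),
                            fine_classes())
  tr <- generate_dataset(generator_config(n_per_class = counts, seed = 21))
  te <- generate_dataset(generator_config(n_per_class = 25, seed = 22))
  msas <- list(Sec = generate_signal_msa("Sec", 50, 31),
               Tat = generate_signal_msa("Tat", 50, 32))
  Xtr <- extract_presence(tr)
  Xte <- extract_presence(te)
  bl <- train_baseline(tr, seed = 5, features = Xtr)
  pb <- predict_baseline(bl, te, features = Xte)
  pred_b <- colnames(pb)[apply(pb, 1, which.max)]
  ens <- train_stacked(ensemble_config(), tr, seed = 5, msas = msas,
                       features = Xtr)
  pred_s <- predict(ens, te, features = Xte)$fine
  acc_b <- class_accuracy(confusion_matrix(te$fine, pred_b))
  acc_s <- class_accuracy(confusion_matrix(te$fine, pred_s))
  rare <- "N_TL_SEC"
  expect_lt(acc_b[rare], acc_s[rare])
  expect_lt(cohen_kappa(confusion_matrix(te$fine, pred_b)),
            cohen_kappa(confusion_matrix(te$fine, pred_s)))
})
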