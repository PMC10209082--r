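stack_dataset <- function(n = 8, seed = 61) {
  generate_dataset(generator_config(n_per_class = n, seed = seed))
}

stack_msas <- function(seed = 71) {
  list(Sec = generate_signal_msa("Sec", 30, seed),
       Tat = generate_signal_msa("Tat", 30, seed + 1))
}

test_that("config validation catches broken routing", {
  expect_error(
    ensemble_config(conditional = TRUE, routing_rules = list(
      list(guard = "Nuclear", when = "negative", inactive = "Nuclear"))),
    "itself")
  expect_error(
    ensemble_config(conditional = TRUE, routing_rules = list(
      list(guard = "NotAModel", when = "negative", inactive = "Sec"))),
    "not a lower model")
  expect_error(
    ensemble_config(conditional = TRUE, routing_rules = list(
      list(guard = "Nuclear", when = "negative", inactive = "Membrane"),
      list(guard = "Membrane", when = "positive", inactive = "Nuclear"))),
    "cyclic")
})

test_that("routing masks follow the guard with ties staying active", {
  rules <- default_routing_rules()
  model_names <- vapply(default_registry(), `[[`, character(1), "name")
  guard <- list(Nuclear = c(0.9, 0.1, 0.5))
  mask <- apply_routing(rules, guard, model_names, 3)
  expect_true(all(mask[1, ]))                      # confidently nuclear
  expect_false(any(mask[2, rules[[1]]$inactive]))  # plastid: masked
  expect_true(all(mask[3, ]))                      # exactly 0.5: active
  # unconditional: all active
  mask0 <- apply_routing(list(), list(), model_names, 4)
  expect_true(all(mask0))
})

test_that("meta-features have one column per model plus mask indicators", {
  ds <- stack_dataset(6)
  X <- extract_presence(ds)
  msas <- stack_msas()
  cfg <- ensemble_config()
  ens <- train_stacked(cfg, ds, seed = 3, msas = msas, features = X)
  meta <- build_meta_features(ens$models, ds, cfg, features = X)
  expect_identical(ncol(meta), 8L)
  # HMM columns are standardized on their training task
  task <- ds$fine %in% c("N_TL_SEC", "N_TL_TAT")
  expect_equal(mean(meta[task, "Tat"]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(meta[task, "Tat"]), 1, tolerance = 1e-9)
  cfg_c <- ensemble_config(conditional = TRUE)
  ens_c <- train_stacked(cfg_c, ds, seed = 3, msas = msas, features = X)
  meta_c <- build_meta_features(ens_c$models, ds, cfg_c, features = X)
  masked <- plastidstack:::maskable_models(cfg_c)
  expect_identical(ncol(meta_c), 8L + length(masked))
  # masked cells are zero wherever the mask indicator fires
  for (mm in masked) {
    fired <- meta_c[, paste0("mask_", mm)] == 1
    expect_true(all(meta_c[fired, mm] == 0))
  }
  # routing changes neither the record count nor the class space
  out_u <- predict(ens, ds, features = X)
  out_c <- predict(ens_c, ds, features = X)
  expect_identical(nrow(out_c), nrow(ds))
  expect_identical(colnames(out_c), colnames(out_u))
  expect_true(all(out_c$fine %in% fine_classes()))
})

test_that("out-of-fold stacking trains and predicts coherently", {
  ds <- stack_dataset(6)
  X <- extract_presence(ds)
  ens <- train_stacked(ensemble_config(), ds, seed = 9, msas = stack_msas(),
                       features = X, out_of_fold = TRUE)
  out <- predict(ens, ds, features = X)
  probs <- as.matrix(out[, paste0("prob_", ens$classes)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(ds)), tolerance = 1e-9)
})

test_that("stacked predictions are coherent and deterministic", {
  ds <- stack_dataset(8)
  X <- extract_presence(ds)
  msas <- stack_msas()
  ens <- train_stacked(ensemble_config(), ds, seed = 5, msas = msas,
                       features = X, envelope_submodel = TRUE)
  rep1 <- predict(ens, ds, features = X)
  probs <- as.matrix(rep1[, paste0("prob_", ens$classes)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(ds)), tolerance = 1e-9)
  # derived fields follow the argmax fine class
  ptm <- rep1[rep1$fine == "P_TM", ][1, ]
  expect_identical(ptm$origin, "plastid")
  expect_identical(ptm$localization, "thylakoid_membrane")
  expect_true(is.na(ptm$pathway))
  expect_true(is.na(ptm$envelope_side))
  if (any(rep1$fine == "N_TL_TAT")) {
    expect_identical(unique(rep1$pathway[rep1$fine == "N_TL_TAT"]), "Tat")
  }
  # envelope sub-model fires exactly on N_E calls
  ne <- rep1$fine == "N_E"
  expect_true(all(rep1$envelope_side[ne] %in% c("IM", "OM")))
  expect_true(all(is.na(rep1$envelope_side[!ne])))
  # retraining with the same seed reproduces every probability
  ens2 <- train_stacked(ensemble_config(), ds, seed = 5, msas = msas,
                        features = X, envelope_submodel = TRUE)
  expect_identical(predict(ens2, ds, features = X), rep1)
})

test_that("the multinomial higher model tracks a dominant lower model", {
  # two-class task: a single Nuclear lower model feeds a log-linear G;
  # the stack's ranking must reproduce the lower model's own ranking
  ds <- stack_dataset(10)
  keep <- ds$fine %in% c("N_S", "P_S")
  ds2 <- ds[keep, ]
  class(ds2) <- c("plastid_dataset", "data.frame")
  X <- extract_presence(ds2)
  cfg <- ensemble_config(
    lower = list(model_spec("Nuclear", "N_S", "P_S")),
    higher = "multinomial_log_linear")
  expect_warning(ens <- train_stacked(cfg, ds2, seed = 6, features = X),
                 "absent")
  lower_p <- predict_model(ens$models$Nuclear, ds2, features = X)
  stack_p <- predict(ens, ds2, features = X)$prob_N_S
  expect_identical(order(lower_p), order(stack_p))
})

test_that("model-set enumeration multiplies slot choices and dedups", {
  slot_sec_tat <- list("Sec", "Tat", c("Sec", "Tat"))
  slot_tl <- list(character(0), "N_TL", "TL")
  expect_length(enumerate_model_sets(list(slot_sec_tat)), 3)
  expect_length(enumerate_model_sets(list(slot_tl)), 3)
  sets <- enumerate_model_sets(list(list("base"), slot_sec_tat, slot_tl))
  expect_length(sets, 9)
  expect_true(all(vapply(sets, function(s) "base" %in% s, logical(1))))
  # duplicate-producing slots collapse
  dup <- enumerate_model_sets(list(list("a", "a"), list("b")))
  expect_length(dup, 1)
  expect_error(enumerate_model_sets(list(list())), "empty slot")
})

test_that("every model set crosses with 2 ensemble x 2 higher types", {
  sets <- enumerate_model_sets(list(list("Sec", "Tat", c("Sec", "Tat"))))
  grid <- ensemble_grid(sets)
  expect_identical(nrow(grid), 12L)  # 3 sets x 4
  expect_identical(ensemble_grid(5L), 20L)
})
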