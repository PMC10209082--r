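test_that("kappa follows its closed form and symmetry properties", {
  expect_identical(cohen_kappa(diag(c(5, 3, 2))), 1)
  expect_equal(cohen_kappa(matrix(c(40, 20, 10, 30), 2)), 0.4)
  # invariance under simultaneous row/column permutation
  set.seed(2)
  m <- matrix(rpois(16, 5), 4)
  p <- sample(4)
  expect_equal(cohen_kappa(m[p, p]), cohen_kappa(m))
  # uniform random assignment: zero expectation
  set.seed(3)
  truth <- sample(3, 10000, TRUE)
  pred <- sample(3, 10000, TRUE)
  expect_lt(abs(cohen_kappa(table(truth, pred))), 0.03)
  expect_warning(k <- cohen_kappa(matrix(c(10, 0, 0, 0), 2)), "degenerate")
  expect_identical(k, 0)
})

test_that("AU1U reproduces the printed two-class case and its bounds", {
  pA <- c(0.9, 0.8, 0.3, 0.1)
  probs <- cbind(A = pA, B = 1 - pA)
  expect_equal(au1u(probs, c("A", "B", "A", "B")), 0.75)
  perfect <- cbind(A = c(1, 0), B = c(0, 1))
  expect_identical(au1u(perfect, c("A", "B")), 1)
  # probabilities independent of the truth: 0.5 in expectation
  set.seed(4)
  p <- runif(4000)
  expect_lt(abs(au1u(cbind(A = p, B = 1 - p),
                     sample(c("A", "B"), 4000, TRUE)) - 0.5), 0.05)
  expect_error(au1u(perfect, c("A", "A")), ">= 2 classes")
})

test_that("AU1U equals binary AUC when k = 2", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    truth <- sample(c("A", "B"), n, TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("A", "B")
    p <- runif(n)
    ours <- au1u(cbind(A = p, B = 1 - p), truth)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = truth, predictor = p, levels = c("B", "A"),
      direction = "<")))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("class accuracy is per-class recall with NA for absent classes", {
  m <- diag(c(4, 6, 1))
  expect_true(all(class_accuracy(m) == 1))
  m2 <- matrix(c(8, 0, 2, 10), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(class_accuracy(m2)["a"]), 0.8)
  m3 <- rbind(c(3, 0), c(0, 0))
  rownames(m3) <- colnames(m3) <- c("a", "b")
  expect_true(is.na(class_accuracy(m3)["b"]))
})

test_that("stratified folds balance classes within one record", {
  fine <- rep(fine_classes(), times = c(10, 10, 11, 9, 10, 12, 10, 10))
  f <- plastidstack:::stratified_folds(fine, 5, seed = 9)
  for (cls in fine_classes()) {
    per_fold <- table(factor(f[fine == cls], levels = 1:5))
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("repeated CV produces folds x reps cells, reproducibly", {
  ds <- generate_dataset(generator_config(n_per_class = 9, seed = 41))
  msas <- list(Sec = generate_signal_msa("Sec", 30, 51),
               Tat = generate_signal_msa("Tat", 30, 52))
  X <- extract_presence(ds)
  r1 <- repeated_stratified_cv(ensemble_config(), ds, folds = 3, reps = 2,
                               seed = 13, msas = msas, features = X)
  expect_identical(nrow(r1$cells), 6L)
  expect_true(all(r1$cells$kappa >= -1 & r1$cells$kappa <= 1))
  expect_true(all(r1$cells$au1u >= 0 & r1$cells$au1u <= 1))
  r2 <- repeated_stratified_cv(ensemble_config(), ds, folds = 3, reps = 2,
                               seed = 13, msas = msas, features = X)
  expect_identical(r1$cells, r2$cells)
  expect_error(repeated_stratified_cv(ensemble_config(), ds, folds = 1,
                                      seed = 1, msas = msas, features = X),
               "folds")
})

test_that("kappa-argmax selection breaks ties toward smaller ensembles", {
  mk_report <- function(kappa, n_lower) {
    structure(list(
      summary = data.frame(metric = "kappa", mean = kappa, sd = 0),
      config = ensemble_config(lower = default_registry()[seq_len(n_lower)],
                               higher = "random_forest")),
      class = "evaluation_report")
  }
  r1 <- mk_report(0.86, 8)
  r2 <- mk_report(0.88, 8)
  expect_identical(select_best(list(r1)), r1$config)
  expect_identical(select_best(list(r1, r2)), r2$config)
  r3 <- mk_report(0.88, 7)
  expect_identical(select_best(list(r2, r3)), r3$config)
})
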