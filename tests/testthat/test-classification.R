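test_that("linear SVM separates a linearly separable set perfectly", {
  set <- separable_set()
  model <- train_classifier(set, hyperparameter_set("svm_linear"), seed = 1)
  pr <- predict(model, set$spectra)
  expect_identical(pr$label, set$class)
  expect_true(all(pr$score[set$class == "malignant"] > 0.5))
  expect_true(all(pr$score[set$class == "benign"] < 0.5))
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})

test_that("every classifier kind trains, scores in [0,1], and is seeded", {
  set <- separable_set(n_per_class = 15, bands = 8)
  hps <- list(
    hyperparameter_set("svm_linear"),
    hyperparameter_set("svm_rbf", gamma = 0.5),
    hyperparameter_set("svm_sigmoid", slope = 0.1),
    hyperparameter_set("rf", n_trees = 50),
    hyperparameter_set("ann", neurons = c(4, 4, 3, 2)))
  for (hp in hps) {
    m1 <- train_classifier(set, hp, seed = 5)
    m2 <- train_classifier(set, hp, seed = 5)
    p1 <- predict(m1, set$spectra)
    p2 <- predict(m2, set$spectra)
    expect_identical(p1, p2)  # determinism under a fixed seed
    expect_true(all(p1$score >= 0 & p1$score <= 1))
    expect_gte(roc_auc(p1$score, set$class == "malignant"), 0.9)
  }
})

test_that("a single tree memorizes a two-sample training set", {
  wl <- seq(450, 950, length.out = 6)
  set <- labeled_spectra(rbind(rep(0, 6), rep(1, 6)),
                         c("benign", "malignant"), c("P1", "P2"),
                         c("I1", "I2"), wl)
  model <- train_classifier(set, hyperparameter_set("rf", n_trees = 1),
                            seed = 3)
  pr <- predict(model, set$spectra)
  expect_identical(pr$label, c("benign", "malignant"))
})

test_that("prediction enforces its contracts", {
  set <- separable_set(n_per_class = 10, bands = 8)
  model <- train_classifier(set, hyperparameter_set("svm_linear"), seed = 1)
  expect_error(predict(model, matrix(0, 2, 5)),
               class = "hsderm_contract_error")
  # empty input -> empty output
  out <- predict(model, matrix(numeric(0), 0, 8))
  expect_identical(nrow(out), 0L)
  # duplicated rows give identical outputs
  pr <- predict(model, set$spectra[c(1, 1), ])
  expect_identical(pr$label[1], pr$label[2])
  expect_identical(pr$score[1], pr$score[2])

  one_class <- subset_labeled(set, set$class == "benign")
  expect_error(train_classifier(one_class, hyperparameter_set("rf"), 1),
               class = "hsderm_contract_error")
})

test_that("GA improves on (or matches) default hyperparameters and is seeded", {
  sets <- noisy_split_set()
  cfg <- ga_config(population = 10, generations = 4, seed = 13)
  r1 <- ga_optimize("svm_rbf", sets$train, sets$val, cfg)
  r2 <- ga_optimize("svm_rbf", sets$train, sets$val, cfg)
  expect_identical(r1$best_hp, r2$best_hp)
  expect_identical(r1$history, r2$history)
  expect_gte(r1$best_auc, r1$default_auc)
  # best-so-far fitness is non-decreasing across generations
  expect_true(all(diff(r1$history) >= 0))
})

test_that("GA equals exhaustive search on an enumerable toy space", {
  sets <- noisy_split_set(n_per_class = 20, seed = 17)
  seed <- 21
  # oracle: enumerate every candidate tree count
  enumerate_auc <- function(nt) {
    m <- train_classifier(sets$train, hyperparameter_set("rf", n_trees = nt),
                          seed = seed)
    roc_auc(predict(m, sets$val$spectra[sets$val$class != "skin", ])$score,
            sets$val$class[sets$val$class != "skin"] == "malignant")
  }
  best_exhaustive <- max(vapply(1:8, enumerate_auc, numeric(1)))
  res <- ga_optimize("rf", sets$train, sets$val,
                     ga_config(population = 16, generations = 5, seed = seed,
                               bounds = list(n_trees = c(1, 8))))
  expect_equal(res$best_auc, best_exhaustive, tolerance = 1e-12)
})

test_that("GA rejects patient leakage and collapses to a point space", {
  sets <- noisy_split_set()
  leaky <- sets$train
  expect_error(ga_optimize("svm_linear", leaky, leaky,
                           ga_config(population = 4, generations = 1)),
               class = "hsderm_contract_error")
  # search space collapsed to one point returns that point
  res <- ga_optimize("rf", sets$train, sets$val,
                     ga_config(population = 4, generations = 2, seed = 1,
                               bounds = list(n_trees = c(7, 7))))
  expect_identical(res$best_hp$n_trees, 7L)
})
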