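# Balanced random forest: bootstrap balance, tree structure invariants,
# prediction semantics, BA/MCC, grid search, trials and serialization.

test_that("balanced bootstrap equalizes classes", {
  y <- c(rep(TRUE, 4), rep(FALSE, 100))
  idx <- balancedBootstrap(y, seed = 1)
  expect_length(idx, 8)
  expect_equal(sum(y[idx]), 4)
  # minority drawn with replacement, majority without
  expect_lte(length(unique(idx[!y[idx]])), 4)
  expect_equal(anyDuplicated(idx[!y[idx]]), 0)
  # already balanced input: majority side is a permutation subset
  y2 <- rep(c(TRUE, FALSE), each = 50)
  idx2 <- balancedBootstrap(y2, seed = 2)
  expect_length(idx2, 100)
  expect_equal(anyDuplicated(idx2[!y2[idx2]]), 0)
  expect_identical(balancedBootstrap(y, seed = 7),
                   balancedBootstrap(y, seed = 7))
  expect_error(balancedBootstrap(rep(TRUE, 10)), "both classes")
})

test_that("confusion statistics handle degenerate predictors", {
  perfect <- evaluatePredictions(c(0.9, 0.9, 0.1), c(TRUE, TRUE, FALSE))
  expect_equal(perfect$ba, 1); expect_equal(perfect$mcc, 1)
  allpos <- evaluatePredictions(rep(1, 100), c(rep(TRUE, 5), rep(FALSE, 95)))
  expect_equal(allpos$ba, 0.5); expect_equal(allpos$mcc, 0)
  expect_error(evaluatePredictions(numeric(0), logical(0)))
})

test_that("BA/MCC agree with a naive recomputation on random predictions", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    prob <- runif(n); lab <- runif(n) < 0.3
    ev <- evaluatePredictions(prob, lab)
    pred <- prob >= 0.5
    tp <- sum(pred & lab); fn <- sum(!pred & lab)
    tn <- sum(!pred & !lab); fp <- sum(pred & !lab)
    expect_equal(ev$tp + ev$fn + ev$tn + ev$fp, n)
    tpr <- if (tp + fn) tp / (tp + fn) else 0
    tnr <- if (tn + fp) tn / (tn + fp) else 0
    expect_equal(ev$ba, (tpr + tnr) / 2)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(ev$mcc, if (den == 0) 0 else (tp * tn - fp * fn) / den,
                 tolerance = 1e-12)
  }
})

test_that("ensemble prediction is the mean of reached leaf values", {
  vocab_n <- 3
  one <- make_ensemble(list(stump_tree(1, v_off = 0.2, v_on = 0.8)), vocab_n)
  expect_equal(unname(predictProba(one, matrix(c(1, 0, 0), 1))), 0.8)
  expect_equal(unname(predictProba(one, matrix(c(0, 1, 1), 1))), 0.2)
  two <- make_ensemble(list(stump_tree(1, 0.2, 0.2),
                            stump_tree(2, 0.8, 0.8)), vocab_n)
  expect_equal(unname(predictProba(two, matrix(c(1, 0, 0), 1))), 0.5)
  zeros <- make_ensemble(list(leaf_tree(0), leaf_tree(0)), vocab_n)
  expect_equal(unname(predictProba(zeros, matrix(0, 1, 3))), 0)
})

test_that("trees conserve coverage and balance their samples", {
  set.seed(3)
  n <- 80; p <- 20
  X <- Matrix::Matrix(matrix(rbinom(n * p, 1, 0.3), n, p) > 0, sparse = TRUE)
  y <- c(rep(TRUE, 10), rep(FALSE, 70))
  vocab <- new("FeatureVocabulary", ids = sprintf("e%02d", 1:p))
  ens <- trainBRF(X, y, vocab, seed = 5)
  expect_equal(numTrees(ens), 100)
  for (tr in ens@trees[1:10]) {
    expect_equal(tr$coverage[1], 20)                      # 2 x minority
    inner <- which(!tr$is_leaf)
    expect_equal(tr$coverage[inner],
                 tr$coverage[tr$left[inner]] + tr$coverage[tr$right[inner]])
    leaves <- tr$is_leaf
    expect_true(all(tr$value[leaves] >= 0 & tr$value[leaves] <= 1))
    # root value is the class fraction of an exactly balanced sample
    expect_equal(tr$value[1], 0.5)
  }
})

test_that("separable data give perfect accuracy, shuffled labels chance", {
  set.seed(17)
  n1 <- 20; n0 <- 120; p <- 30
  X <- rbind(cbind(matrix(1, n1, 3), matrix(rbinom(n1 * (p - 3), 1, 0.2),
                                            n1)),
             cbind(matrix(0, n0, 3), matrix(rbinom(n0 * (p - 3), 1, 0.2),
                                            n0)))
  X <- Matrix::Matrix(X > 0, sparse = TRUE)
  rownames(X) <- paste0("c", seq_len(n1 + n0))
  y <- c(rep(TRUE, n1), rep(FALSE, n0))
  vocab <- new("FeatureVocabulary", ids = sprintf("e%02d", 1:p))
  ens <- trainBRF(X, y, vocab, seed = 2)
  ev <- evaluatePredictions(predictProba(ens, X), y)
  expect_equal(ev$ba, 1.0)
  # permutation null: accuracy collapses to chance
  bas <- vapply(1:10, function(s) {
    ys <- sample(y)
    half <- sample(length(ys), length(ys) / 2)
    e <- trainBRF(X[half, ], ys[half], vocab, seed = s)
    evaluatePredictions(predictProba(e, X[-half, ]), ys[-half])$ba
  }, numeric(1))
  expect_lt(abs(mean(bas) - 0.5), 0.07)
})

test_that("grid search selects by internal CV and retrains on all data", {
  set.seed(23)
  n <- 60; p <- 12
  X <- Matrix::Matrix(matrix(rbinom(n * p, 1, 0.4), n, p) > 0, sparse = TRUE)
  y <- c(rep(TRUE, 20), rep(FALSE, 40))
  X[y, 1] <- TRUE; X[!y, 1] <- FALSE     # make it learnable
  vocab <- new("FeatureVocabulary", ids = sprintf("e%02d", 1:p))
  grid <- expand.grid(n_estimators = c(10L, 20L), min_samples_split = 2L,
                      min_samples_leaf = c(1L, 2L))
  ens <- trainBRF(X, y, vocab, grid = grid, cv_folds = 5, seed = 4)
  expect_equal(nrow(ens@cv), nrow(grid))
  expect_true(all(c("mcc", "ba") %in% colnames(ens@cv)))
  best <- ens@cv[order(-ens@cv$mcc, -ens@cv$ba, ens@cv$n_estimators), ][1, ]
  expect_equal(ens@hyperparams$n_estimators, best$n_estimators)
  # a one-point grid skips the search entirely
  direct <- trainBRF(X, y, vocab, grid = grid[1, ], seed = 4)
  expect_equal(nrow(direct@cv), 0)
})

test_that("trials summarize stratified splits; identical pairs cross-predict natively", {
  lib <- small_library()
  pd <- curate_pair(lib, "pair1")
  ids <- pairCompounds(pd)$id
  catalog <- featureCatalog(libraryMols(lib)[ids])
  res <- runTrials(pd, catalog, n_trials = 2, base_seed = 42)
  expect_length(res$trials, 2)
  expect_equal(res$summary$metric, c("BA", "MCC"))
  expect_true(all(res$summary$sd >= 0))
  lab <- pairLabels(pd)
  tr <- res$trials[[1]]
  expect_equal(sum(lab[tr$train_ids]), sum(lab[tr$test_ids]), tolerance = 1)
  # single trial reports zero standard deviation
  one <- runTrials(pd, catalog, n_trials = 1, base_seed = 42)
  expect_equal(one$summary$sd, c(0, 0))
  # cross prediction against the same pair equals native evaluation
  cross_self <- crossPredict(res, catalog, pd)
  # the cross evaluation covers all compounds, native only the test half;
  # both must be near-perfect on the separable synthetic system
  expect_gt(cross_self$summary$mean[1], 0.9)
})

test_that("ensembles survive a JSON round trip", {
  ens <- make_ensemble(list(stump_tree(2, 0.25, 0.75), leaf_tree(0.5)), 4)
  path <- tempfile(fileext = ".json")
  writeEnsembleJSON(ens, path)
  back <- readEnsembleJSON(path)
  X <- matrix(rbinom(20, 1, 0.5), 5, 4)
  expect_equal(predictProba(back, X), predictProba(ens, X))
  expect_identical(featureIds(back@vocabulary), featureIds(ens@vocabulary))
})
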