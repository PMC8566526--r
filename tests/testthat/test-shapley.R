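# Shapley explanations: base values, the classic axioms (efficiency,
# dummy, symmetry, linearity), agreement between the path-dependent
# explainer and brute-force coalition enumeration, and the present/absent
# partition.

test_that("tree expected value is the coverage-weighted leaf mean", {
  expect_equal(treeExpectedValue(leaf_tree(0.7)), 0.7)
  expect_equal(treeExpectedValue(stump_tree(1, 0.2, 0.8, 50, 50)), 0.5)
  expect_equal(treeExpectedValue(stump_tree(1, 0.2, 0.8, 90, 10)),
               0.9 * 0.2 + 0.1 * 0.8)
  bad <- leaf_tree(0.5, coverage = 0)
  expect_error(treeExpectedValue(bad), "coverage")
})

test_that("a depth-1 split attributes the full leaf gap to its feature", {
  ens <- make_ensemble(list(stump_tree(1, v_off = 0.2, v_on = 0.8)), 3)
  es <- explainCompounds(ens, Matrix::Matrix(c(1, 0, 0), 1, 3, sparse = TRUE))
  expect_equal(as.numeric(svMatrix(es)[1, ]), c(0.3, 0, 0))
  expect_equal(baseValue(ens), 0.5)
  expect_equal(unname(predictions(es)), 0.8)
  # instance with the feature off gets the mirrored attribution
  es0 <- explainCompounds(ens, Matrix::Matrix(0, 1, 3, sparse = TRUE))
  expect_equal(as.numeric(svMatrix(es0)[1, ]), c(-0.3, 0, 0))
})

test_that("a single-leaf tree explains nothing", {
  ens <- make_ensemble(list(leaf_tree(0.7)), 2)
  es <- explainCompounds(ens, Matrix::Matrix(c(1, 1), 1, 2, sparse = TRUE))
  expect_true(all(svMatrix(es) == 0))
  expect_equal(es@base, 0.7)
})

test_that("duplicating a tree leaves attributions unchanged (linearity)", {
  t1 <- stump_tree(2, 0.3, 0.9, 40, 60)
  one <- make_ensemble(list(t1), 3)
  two <- make_ensemble(list(t1, t1), 3)
  x <- Matrix::Matrix(c(0, 1, 0), 1, 3, sparse = TRUE)
  expect_equal(as.numeric(svMatrix(explainCompounds(one, x))),
               as.numeric(svMatrix(explainCompounds(two, x))))
})

test_that("features unused by the trees have zero Shapley value (dummy)", {
  ens <- make_ensemble(list(stump_tree(1, 0.2, 0.8)), 5)
  x <- Matrix::Matrix(c(1, 1, 1, 1, 1), 1, 5, sparse = TRUE)
  sv <- as.numeric(svMatrix(explainCompounds(ens, x)))
  expect_equal(sv[2:5], rep(0, 4))
  bf <- shapBruteForce(ens, c(1, 1, 1, 1, 1), features = c(1, 3))
  expect_equal(unname(bf$sv["3"]), 0)
})

test_that("structurally interchangeable features get equal values (symmetry)", {
  # f1 and f2 play identical roles: value 1 iff both are on
  tr <- tree_node_frame(
    node_id = 1:5,
    is_leaf = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    feature = c(1L, NA, 2L, NA, NA),
    left = c(2L, NA, 4L, NA, NA), right = c(3L, NA, 5L, NA, NA),
    value = c(NA, 0, NA, 0, 1),
    coverage = c(100, 50, 50, 25, 25))
  ens <- make_ensemble(list(tr), 2)
  bf <- shapBruteForce(ens, c(1, 1))
  expect_equal(unname(bf$sv["1"]), unname(bf$sv["2"]), tolerance = 1e-12)
  es <- explainCompounds(ens, Matrix::Matrix(c(1, 1), 1, 2, sparse = TRUE))
  expect_equal(svMatrix(es)[1, 1], svMatrix(es)[1, 2], tolerance = 1e-12)
})

test_that("explainer agrees with the oracle on trained forests", {
  set.seed(31)
  n <- 50; p <- 10
  X <- Matrix::Matrix(matrix(rbinom(n * p, 1, 0.5), n, p) > 0, sparse = TRUE)
  y <- as.logical(rbinom(n, 1, 0.4))
  y[1:3] <- TRUE; y[4:6] <- FALSE
  vocab <- new("FeatureVocabulary", ids = sprintf("e%02d", 1:p))
  ens <- trainBRF(X, y, vocab,
                  grid = data.frame(n_estimators = 5L, min_samples_split = 2L,
                                    min_samples_leaf = 1L), seed = 8)
  Xi <- matrix(rbinom(5 * p, 1, 0.5), 5, p)
  es <- explainCompounds(ens, Matrix::Matrix(Xi > 0, sparse = TRUE))
  for (i in 1:5) {
    bf <- shapBruteForce(ens, Xi[i, ])
    expect_equal(as.numeric(svMatrix(es)[i, as.integer(names(bf$sv))]),
                 unname(bf$sv), tolerance = 1e-9)
  }
})

test_that("the oracle refuses more than 15 features", {
  ens <- make_ensemble(list(stump_tree(1, 0.2, 0.8)), 20)
  expect_error(shapBruteForce(ens, rbinom(20, 1, 0.5), features = 1:16),
               "15")
})

test_that("present/absent partition reconstructs the prediction", {
  ens <- make_ensemble(list(stump_tree(1, 0.2, 0.8),
                            stump_tree(2, 0.6, 0.4)), 4)
  X <- Matrix::Matrix(rbind(c(1, 0, 1, 0), c(0, 1, 0, 0)), sparse = TRUE)
  rownames(X) <- c("a", "b")
  es <- explainCompounds(ens, X)
  part <- partitionSV(es)
  expect_equal(part$present_sum + part$absent_sum + part$base,
               part$prediction, tolerance = 1e-12)
  # compound a: tree 1 credits +0.3 to present f1, tree 2 credits +0.1 to
  # absent f2; the two-tree mean gives 0.15 present and 0.05 absent
  expect_equal(part$present_sum[1], 0.15, tolerance = 1e-12)
  expect_equal(part$absent_sum[1], 0.05, tolerance = 1e-12)
})

test_that("malformed coverages are rejected", {
  tr <- stump_tree(1, 0.2, 0.8)
  tr$coverage <- c(0, 0, 0)
  ens <- make_ensemble(list(tr), 2)
  expect_error(explainCompounds(ens,
    Matrix::Matrix(c(1, 0), 1, 2, sparse = TRUE)))
})
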