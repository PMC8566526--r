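# Signature analysis: the N/M rank scheme, per-compound prioritized counts,
# atom coloring, contribution partitions, the absence control and motif
# prevalence.

# small hand-built explanation set: three correctly predicted DT compounds
# over six vocabulary positions
hand_explanations <- function(base = 0.4) {
  sv <- Matrix::sparseMatrix(
    i = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
    j = c(1, 2, 3, 1, 4, 2, 2, 5, 1),
    x = c(0.30, 0.20, 0.05, 0.25, 0.22, 0.01, 0.15, 0.10, 0.02),
    dims = c(3, 6), dimnames = list(c("A", "B", "C"), NULL))
  on <- Matrix::sparseMatrix(
    i = rep(1:3, each = 3), j = c(1, 2, 3, 1, 4, 2, 2, 5, 1),
    dims = c(3, 6), dimnames = list(c("A", "B", "C"), NULL))
  new("ExplanationSet", sv = sv, base = base,
      prediction = base + Matrix::rowSums(sv),
      on = as(on, "nMatrix"),
      vocabulary = new("FeatureVocabulary", ids = sprintf("e%d", 1:6)))
}

test_that("the N/M rank scheme matches hand enumeration", {
  es <- hand_explanations()
  labels <- c(A = TRUE, B = TRUE, C = TRUE)
  prio <- extractPrioritized(es, labels, N = 2, M = 2)
  tab <- prioritizedTable(prio)
  # top-2 sets are {f1,f2}, {f1,f4}, {f2,f5}: f1 and f2 occur twice each
  expect_setequal(tab$position, c(1, 2))
  expect_equal(tab$count, c(2, 2))
  # occurrence ties resolved by total Shapley value: f1 (0.57) before f2
  expect_equal(tab$position, c(1, 2))
})

test_that("rank scheme truncates gracefully and ignores compound order", {
  es <- hand_explanations()
  labels <- c(A = TRUE, B = TRUE, C = TRUE)
  # N beyond the per-compound feature count pre-selects whole present sets;
  # M beyond the pooled uniques returns all of them
  prio <- extractPrioritized(es, labels, N = 10, M = 50)
  expect_setequal(prioritizedTable(prio)$position, 1:5)
  perm <- c("C", "A", "B")
  es_perm <- new("ExplanationSet", sv = es@sv[perm, ], base = es@base,
                 prediction = stats::setNames(es@prediction, c("A", "B", "C"))[perm],
                 on = es@on[perm, ], vocabulary = es@vocabulary)
  expect_identical(prioritizedTable(extractPrioritized(es_perm, labels, 2, 2)),
                   prioritizedTable(extractPrioritized(es, labels, 2, 2)))
  expect_error(extractPrioritized(es, labels, N = 0, M = 2))
})

test_that("prioritized counts intersect fingerprints with the feature set", {
  es <- hand_explanations()
  labels <- c(A = TRUE, B = TRUE, C = TRUE)
  prio <- extractPrioritized(es, labels, N = 2, M = 2)
  X <- es@on
  cnt <- countPrioritized(X, prio)
  expect_equal(unname(cnt$counts), c(2, 2, 2))   # all contain f1 and f2? no:
  # A has {1,2,3}: both; B has {1,4,2}: both; C has {2,5,1}: both
  expect_equal(sum(cnt$histogram), 3)
  disjoint <- Matrix::sparseMatrix(i = 1, j = 6, dims = c(1, 6))
  expect_equal(unname(countPrioritized(disjoint, prio)$counts), 0)
})

test_that("atom coloring counts features covering each atom", {
  envs <- list(ids = c("ea", "eb"),
               occurrences = list(
                 ea = list(list(atoms = c(1L, 2L), bonds = 1L)),
                 eb = list(list(atoms = c(2L, 3L), bonds = 2L))))
  vocab <- new("FeatureVocabulary", ids = c("ea", "eb", "ec"))
  col <- colorAtoms(envs, 1:3, vocab)
  expect_equal(col$counts, c(1L, 2L, 1L))
  expect_equal(col$atoms, 1:3)
  expect_equal(col$n_features_present, 2)
  none <- colorAtoms(envs, 3, vocab)        # feature absent in the compound
  expect_true(all(none$counts == 0))
})

test_that("present/absent distributions degenerate correctly", {
  # one correct DT, one correct ST
  sv <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(0.3, -0.3),
                             dims = c(2, 2),
                             dimnames = list(c("dt", "st"), NULL))
  on <- Matrix::sparseMatrix(i = 1, j = 1, dims = c(2, 2),
                             dimnames = list(c("dt", "st"), NULL))
  es <- new("ExplanationSet", sv = sv, base = 0.5,
            prediction = c(0.8, 0.2), on = as(on, "nMatrix"),
            vocabulary = new("FeatureVocabulary", ids = c("e1", "e2")))
  g <- globalPresentAbsent(es, c(dt = TRUE, st = FALSE))
  dtp <- g[g$class == "DT" & g$status == "present", ]
  expect_equal(dtp$min, dtp$median)
  expect_equal(dtp$median, dtp$max)
  expect_equal(dtp$median, 0.3)
  # all-zero Shapley values at base 0.5: the ST compound is predicted DT,
  # so the ST class drops out with a warning and all DT statistics are zero
  es0 <- new("ExplanationSet", sv = sv * 0, base = 0.5,
             prediction = c(0.5, 0.5), on = as(on, "nMatrix"),
             vocabulary = new("FeatureVocabulary", ids = c("e1", "e2")))
  expect_warning(g0 <- globalPresentAbsent(es0, c(dt = TRUE, st = FALSE)),
                 "ST")
  expect_true(all(g0[, c("min", "median", "max")] == 0))
})

test_that("contribution partitions split motif, other and absent features", {
  mols <- parseSmiles(c(tol = "Cc1ccccc1", eth = "CCO"))
  catalog <- featureCatalog(mols)
  vocab <- buildVocabulary(catalog)
  X <- fingerprintMatrix(catalog, vocab)
  env_tol <- catalog$tol
  ring_ch <- env_tol$ids[vapply(env_tol$ids, function(id) {
    occ <- env_tol$occurrences[[id]]
    length(occ) == 5 && all(vapply(occ, function(o)
      length(o$atoms) == 1, logical(1)))
  }, logical(1))][1]                       # aromatic C-H radius-0 (5 centers)
  methyl <- env_tol$ids[vapply(env_tol$ids, function(id) {
    occ <- env_tol$occurrences[[id]]
    length(occ) == 1 && identical(occ[[1]]$atoms, 1L)
  }, logical(1))][1]                       # methyl radius-0
  f_ring <- featurePositions(vocab, ring_ch)
  f_me <- featurePositions(vocab, methyl)
  f_abs <- featurePositions(vocab, setdiff(catalog$eth$ids, env_tol$ids)[1])
  ens <- make_ensemble(list(stump_tree(f_ring, 0.3, 0.7),
                            stump_tree(f_me, 0.4, 0.6),
                            stump_tree(f_abs, 0.45, 0.55)),
                       vocabularySize(vocab), ids = featureIds(vocab))
  es <- explainCompounds(ens, X)
  part <- partitionContributions(es, catalog, mols, "c1ccccc1")
  tol_row <- part[part$compound_id == "tol", ]
  i <- match("tol", explainedIds(es))
  expect_equal(tol_row$motif_sum, as.numeric(svMatrix(es)[i, f_ring]))
  expect_equal(tol_row$other_present_sum, as.numeric(svMatrix(es)[i, f_me]))
  expect_equal(tol_row$absent_sum, as.numeric(svMatrix(es)[i, f_abs]))
  expect_equal(tol_row$motif_sum + tol_row$other_present_sum +
                 tol_row$absent_sum + tol_row$base, tol_row$prediction,
               tolerance = 1e-12)
  # a compound without the motif has zero motif contribution
  eth_row <- part[part$compound_id == "eth", ]
  expect_equal(eth_row$motif_sum, 0)
})

test_that("the absence control extracts the features whose absence drives ST", {
  ens <- make_ensemble(list(stump_tree(1, 0.1, 0.9),
                            stump_tree(2, 0.45, 0.55)), 4)
  X <- Matrix::Matrix(matrix(0, 2, 4), sparse = TRUE)
  rownames(X) <- c("s1", "s2")
  es <- explainCompounds(ens, as(X > 0.5, "nMatrix"))
  labels <- c(s1 = FALSE, s2 = FALSE)
  asig <- absenceSignature(es, labels, N = 1, M = 2)
  expect_equal(prioritizedTable(asig)$position[1], 1)  # the decisive absence
  expect_error(absenceSignature(es, c(s1 = TRUE, s2 = TRUE), 1, 2),
               "correctly predicted")
})

test_that("motif prevalence counts substructure matches per class", {
  mols <- parseSmiles(c(a = "Cc1ccccc1", b = "c1ccccc1", c = "CCO",
                        d = "CCN"))
  labels <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  prev <- motifPrevalence(mols, "c1ccccc1", labels)
  expect_equal(prev$matched[prev$class == "DT"], 2)
  expect_equal(prev$fraction[prev$class == "DT"], 1)
  expect_equal(prev$matched[prev$class == "ST"], 0)
  none <- motifPrevalence(mols, "c1ccncc1", labels)
  expect_true(all(none$matched == 0))
  # self-match: a compound used as its own query counts itself
  self <- motifPrevalence(mols["a"], "Cc1ccccc1", labels["a"])
  expect_equal(self$matched[1], 1)
})

test_that("synthetic prevalence tracks planting and contamination rates", {
  lib <- small_library()
  cp <- compoundTable(lib)
  sub <- cp[cp$pair_id == "pair1", ]
  labels <- stats::setNames(sub$intended_role == "DT", sub$id)
  prev <- motifPrevalence(libraryMols(lib)[sub$id],
                          lib@config@motif_smiles_pair1, labels)
  dt_frac <- prev$fraction[prev$class == "DT" & prev$subset == "all"]
  st_frac <- prev$fraction[prev$class == "ST" & prev$subset == "all"]
  expect_gt(dt_frac, 0.2); expect_lt(dt_frac, 0.8)  # planting rate 0.5
  expect_lt(st_frac, 0.1)                           # contamination 0.02
})
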