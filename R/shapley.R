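## Exact per-compound Shapley values for balanced random forest predictions,
## in units of predicted DT probability: the path-dependent polynomial-time
## tree explainer (C++ backend), a brute-force coalition-enumeration oracle
## for verification, and the present/absent partition of attributions.

#' Expected value (base value) of a single tree
#'
#' The coverage-weighted mean of leaf values, i.e. the model output expected
#' for a training compound before observing any feature.
#'
#' @param tree a tree node table (see [TreeEnsemble-class]).
#' @return numeric scalar.
#' @export
treeExpectedValue <- function(tree) {
  if (tree$coverage[1] <= 0) stop("zero coverage at tree root")
  leaves <- tree$is_leaf
  sum(tree$value[leaves] * tree$coverage[leaves]) / sum(tree$coverage[leaves])
}

#' @describeIn treeExpectedValue ensemble base value: mean over trees
#' @param ensemble a [TreeEnsemble-class]
#' @export
baseValue <- function(ensemble) {
  stopifnot(is(ensemble, "TreeEnsemble"))
  mean(vapply(ensemble@trees, treeExpectedValue, numeric(1)))
}

#' Per-compound Shapley explanations
#'
#' @slot sv sparse matrix (compounds x vocabulary positions) of Shapley
#'   values; positions never used by any tree are exactly zero (dummy
#'   axiom) and stored as structural zeros.
#' @slot base the ensemble base value.
#' @slot prediction predicted DT probability per compound.
#' @slot on the binary fingerprint matrix the explanations refer to.
#' @slot vocabulary the [FeatureVocabulary-class].
#' @export
setClass("ExplanationSet",
  representation(sv = "Matrix", base = "numeric", prediction = "numeric",
                 on = "Matrix", vocabulary = "FeatureVocabulary"),
  validity = function(object) {
    if (nrow(object@sv) != length(object@prediction))
      return("one prediction per compound required")
    if (!identical(dim(object@sv), dim(object@on)))
      return("sv and fingerprint dimensions differ")
    TRUE
  })

setMethod("show", "ExplanationSet", function(object) {
  cat("ExplanationSet:", nrow(object@sv), "compounds,",
      ncol(object@sv), "features; base value",
      signif(object@base, 6), "\n")
})

#' @describeIn ExplanationSet Shapley-value matrix accessor
#' @param x an `ExplanationSet`
#' @export
svMatrix <- function(x) x@sv

#' @describeIn ExplanationSet predicted DT probabilities
#' @export
predictions <- function(x) x@prediction

#' @describeIn ExplanationSet compound identifiers
#' @export
explainedIds <- function(x) rownames(x@sv)

.used_features <- function(ensemble) {
  sort(unique(unlist(lapply(ensemble@trees, function(tr)
    tr$feature[!tr$is_leaf]))))
}

.tree_for_cpp <- function(tree, compact) {
  feature <- ifelse(tree$is_leaf, -1L,
                    as.integer(compact[as.character(tree$feature)]) - 1L)
  list(feature = as.integer(feature),
       left = as.integer(ifelse(tree$is_leaf, -1L, tree$left)) - 1L,
       right = as.integer(ifelse(tree$is_leaf, -1L, tree$right)) - 1L,
       value = as.numeric(tree$value),
       cover = as.numeric(tree$coverage))
}

#' Exact Shapley values via the path-dependent tree explainer
#'
#' Computes, for every compound, the exact Shapley value of every vocabulary
#' position (present or absent) with respect to the ensemble's predicted DT
#' probability, using the polynomial-time path-dependent algorithm in which
#' conditional expectations are defined by per-node training coverages. The
#' efficiency identity `base + sum(sv) = prediction` is asserted at run time
#' for every compound.
#'
#' @param ensemble a [TreeEnsemble-class].
#' @param X binary fingerprint matrix over the ensemble's vocabulary
#'   (rownames are compound ids).
#' @param tol tolerance of the run-time efficiency assertion.
#' @return an [ExplanationSet-class].
#' @export
explainCompounds <- function(ensemble, X, tol = 1e-9) {
  stopifnot(is(ensemble, "TreeEnsemble"))
  if (is.null(dim(X))) X <- Matrix::Matrix(X, nrow = 1, sparse = TRUE)
  stopifnot(ncol(X) == vocabularySize(ensemble@vocabulary))
  used <- .used_features(ensemble)
  compact <- stats::setNames(seq_along(used), used)
  trees <- lapply(ensemble@trees, .tree_for_cpp, compact = compact)
  Xu <- as.matrix(X[, used, drop = FALSE]) * 1L
  storage.mode(Xu) <- "integer"
  phi <- shap_path_dependent_cpp(trees, Xu)
  base <- baseValue(ensemble)
  pred <- unname(predictProba(ensemble, X))
  err <- abs(base + rowSums(phi) - pred)
  if (any(err > tol))
    stop("efficiency violated: max |base + sum(sv) - prediction| = ",
         format(max(err)))
  sv <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(phi)), length(used)),
    j = rep(used, each = nrow(phi)),
    x = as.numeric(phi),
    dims = dim(X), dimnames = list(rownames(X), NULL))
  new("ExplanationSet", sv = Matrix::drop0(sv), base = base,
      prediction = pred, on = X, vocabulary = ensemble@vocabulary)
}

#' Present/absent partition of Shapley values
#'
#' Splits each compound's Shapley values into the sum over features present
#' in the compound (fingerprint bit on) and the sum over absent features;
#' by efficiency, `present_sum + absent_sum + base = prediction`.
#'
#' @param explanations an [ExplanationSet-class].
#' @return data.frame: `compound_id`, `present_sum`, `absent_sum`, `base`,
#'   `prediction`.
#' @export
partitionSV <- function(explanations) {
  stopifnot(is(explanations, "ExplanationSet"))
  sv <- explanations@sv
  on <- explanations@on
  total <- Matrix::rowSums(sv)
  present <- Matrix::rowSums(sv * on)
  data.frame(compound_id = rownames(sv),
             present_sum = present,
             absent_sum = total - present,
             base = explanations@base,
             prediction = explanations@prediction,
             stringsAsFactors = FALSE)
}

## ---- brute-force oracle ---------------------------------------------------

## conditional-expectation game value of one tree for every coalition mask
## over `used` (vocabulary positions): members of the coalition follow the
## instance, non-members are averaged over children by coverage
.tree_value_all_masks <- function(tree, x, used) {
  nmask <- bitwShiftL(1L, length(used))
  masks <- 0:(nmask - 1)
  eval_node <- function(j) {
    if (tree$is_leaf[j]) return(rep(tree$value[j], nmask))
    vl <- eval_node(tree$left[j])
    vr <- eval_node(tree$right[j])
    k <- match(tree$feature[j], used)
    mix <- (tree$coverage[tree$left[j]] * vl +
            tree$coverage[tree$right[j]] * vr) / tree$coverage[j]
    if (is.na(k)) return(mix)  # feature outside the analysed subset
    inst <- if (x[tree$feature[j]] >= 1) vr else vl
    sel <- bitwAnd(masks, bitwShiftL(1L, k - 1L)) > 0
    ifelse(sel, inst, mix)
  }
  eval_node(1L)
}

#' Brute-force Shapley values by coalition enumeration
#'
#' Computes Shapley values from the defining sum over all feature
#' coalitions, with the coalition value given by coverage-weighted tree
#' descent (members of the coalition follow the instance, non-members are
#' averaged over children). Permutation weights use exact integer
#' factorials. This oracle is exponential in the number of features used by
#' the trees and refuses more than 15; it exists to verify the
#' path-dependent explainer, not to replace it.
#'
#' @param model a [TreeEnsemble-class] or a single tree node table.
#' @param x binary instance vector over the vocabulary positions.
#' @param features optional vector of vocabulary positions to analyse;
#'   defaults to all features used by the model's trees.
#' @return list: `sv` (named by vocabulary position), `base`, `prediction`.
#' @export
shapBruteForce <- function(model, x, features = NULL) {
  trees <- if (is(model, "TreeEnsemble")) model@trees else list(model)
  used_all <- sort(unique(unlist(lapply(trees, function(tr)
    tr$feature[!tr$is_leaf]))))
  used <- if (is.null(features)) used_all else sort(unique(features))
  if (length(used) > 15)
    stop("brute-force enumeration limited to 15 features; got ",
         length(used))
  f_n <- length(used)
  nmask <- bitwShiftL(1L, f_n)
  masks <- 0:(nmask - 1)
  popcount <- vapply(masks, function(m) sum(bitwAnd(m,
    bitwShiftL(1L, 0:(max(f_n, 1) - 1))) > 0), integer(1))
  fact <- c(1, cumprod(seq_len(max(f_n, 1))))   # fact[k+1] = k!
  w_of_size <- fact[pmin(popcount, f_n) + 1] *
    fact[pmax(f_n - popcount - 1, 0) + 1] / fact[f_n + 1]
  phi <- stats::setNames(numeric(f_n), used)
  base <- 0; pred <- 0
  for (tr in trees) {
    v <- .tree_value_all_masks(tr, x, used)
    base <- base + v[1]
    pred <- pred + v[nmask]
    for (k in seq_len(f_n)) {
      bit <- bitwShiftL(1L, k - 1L)
      s_wo <- masks[bitwAnd(masks, bit) == 0]
      phi[k] <- phi[k] + sum(w_of_size[s_wo + 1] *
                             (v[bitwOr(s_wo, bit) + 1] - v[s_wo + 1]))
    }
  }
  list(sv = phi / length(trees), base = base / length(trees),
       prediction = pred / length(trees))
}
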