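## Balanced random forest on binary fingerprints: each tree is trained on an
## exactly class-balanced bootstrap (minority drawn with replacement at its
## own size, majority under-sampled without replacement), trees are grown by
## CART/Gini with thresholds fixed at 0.5, and every node records the number
## of balanced-sample compounds reaching it (the coverage used by the
## path-dependent Shapley explainer).

#' Tree ensemble of a balanced random forest
#'
#' @slot trees list of node tables; each a data.frame with columns
#'   `node_id`, `is_leaf`, `feature` (vocabulary position of the split, NA in
#'   leaves), `left`, `right` (child node ids; left = feature absent),
#'   `value` (fraction of DT samples in the node), `coverage` (balanced-
#'   sample count reaching the node).
#' @slot vocabulary the [FeatureVocabulary-class] the model was trained on.
#' @slot hyperparams list: `n_estimators`, `min_samples_split`,
#'   `min_samples_leaf`, `mtry`.
#' @slot seed integer seed the forest was grown from.
#' @slot cv data.frame of internal cross-validation results (empty when the
#'   grid had a single point).
#' @export
setClass("TreeEnsemble",
  representation(trees = "list", vocabulary = "FeatureVocabulary",
                 hyperparams = "list", seed = "integer", cv = "data.frame"),
  validity = function(object) {
    for (tr in object@trees) {
      lv <- tr$value[tr$is_leaf]
      if (any(is.na(lv)) || any(lv < 0 | lv > 1))
        return("leaf values outside [0,1]")
      inner <- which(!tr$is_leaf)
      if (length(inner)) {
        bad <- abs(tr$coverage[inner] -
                   (tr$coverage[tr$left[inner]] + tr$coverage[tr$right[inner]]))
        if (any(bad > 0)) return("coverage not conserved at an internal node")
      }
    }
    TRUE
  })

setMethod("show", "TreeEnsemble", function(object) {
  cat("TreeEnsemble:", length(object@trees), "trees over",
      vocabularySize(object@vocabulary), "features\n  hyperparameters:",
      paste(names(object@hyperparams), unlist(object@hyperparams),
            sep = "=", collapse = ", "), "\n")
})

#' @describeIn TreeEnsemble number of trees
#' @param x a `TreeEnsemble`
#' @export
numTrees <- function(x) length(x@trees)

#' Exactly class-balanced bootstrap indices
#'
#' Draws a per-tree training sample with equal class counts: the minority
#' class is drawn with replacement at its own size and the majority class is
#' under-sampled without replacement to that size.
#'
#' @param labels logical vector (`TRUE` = positive/DT class).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside forest growth).
#' @return integer vector of row indices (length `2 * min(class sizes)`).
#' @export
balancedBootstrap <- function(labels, seed = NULL) {
  stopifnot(is.logical(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  draw <- function() {
    m <- min(n1, n0)
    minority <- which(labels == (n1 <= n0))
    majority <- which(labels != (n1 <= n0))
    c(minority[sample.int(length(minority), m, replace = TRUE)],
      majority[sample.int(length(majority), m, replace = FALSE)])
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

## ---- tree induction -------------------------------------------------------

## Grow one CART tree on a 0/1 feature matrix with Gini impurity.
## Split search follows the usual random-forest rule: inspect mtry randomly
## chosen features and, if none yields a valid split, keep inspecting more
## features in random order until one does (or none is left).
.grow_tree <- function(X, y, min_samples_split, min_samples_leaf, mtry) {
  nodes <- list()
  next_id <- 2L
  stack <- list(list(rows = seq_len(nrow(X)), id = 1L))
  while (length(stack)) {
    task <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rows <- task$rows
    n <- length(rows); n1 <- sum(y[rows])
    make_leaf <- function() {
      nodes[[task$id]] <<- data.frame(
        node_id = task$id, is_leaf = TRUE, feature = NA_integer_,
        left = NA_integer_, right = NA_integer_, value = n1 / n, coverage = n)
    }
    if (n < min_samples_split || n1 == 0 || n1 == n) { make_leaf(); next }
    perm <- sample.int(ncol(X))
    best <- NULL
    for (start in seq(1, ncol(X), by = mtry)) {
      block <- perm[start:min(start + mtry - 1, ncol(X))]
      Xb <- X[rows, block, drop = FALSE]
      n_on <- colSums(Xb)
      n_on1 <- if (n1 > 0) colSums(Xb[y[rows], , drop = FALSE]) else 0
      n_off <- n - n_on; n_off1 <- n1 - n_on1
      valid <- n_on >= min_samples_leaf & n_off >= min_samples_leaf
      if (!any(valid)) next
      g_on <- 1 - (n_on1 / pmax(n_on, 1))^2 - ((n_on - n_on1) / pmax(n_on, 1))^2
      g_off <- 1 - (n_off1 / pmax(n_off, 1))^2 -
               ((n_off - n_off1) / pmax(n_off, 1))^2
      g_parent <- 1 - (n1 / n)^2 - ((n - n1) / n)^2
      gain <- g_parent - (n_on * g_on + n_off * g_off) / n
      gain[!valid] <- -Inf
      if (max(gain) <= 1e-12) next
      cand <- block[gain > max(gain) - 1e-12 & valid]
      best <- min(cand)   # deterministic tie-break: smallest position
      break
    }
    if (is.null(best)) { make_leaf(); next }
    col <- X[rows, best]
    left_id <- next_id
    right_id <- next_id + 1L
    next_id <- next_id + 2L
    nodes[[task$id]] <- data.frame(
      node_id = task$id, is_leaf = FALSE, feature = best,
      left = left_id, right = right_id, value = n1 / n, coverage = n)
    stack[[length(stack) + 1]] <- list(rows = rows[col == 0], id = left_id)
    stack[[length(stack) + 1]] <- list(rows = rows[col == 1], id = right_id)
  }
  do.call(rbind, nodes)
}

.fit_forest <- function(X, y, n_estimators, min_samples_split,
                        min_samples_leaf, mtry, seed) {
  .with_seed(seed, {
    lapply(seq_len(n_estimators), function(t) {
      idx <- balancedBootstrap(y)
      Xb <- as.matrix(X[idx, , drop = FALSE]) * 1
      .grow_tree(Xb, y[idx], min_samples_split, min_samples_leaf, mtry)
    })
  })
}

.route_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  stack <- list(list(node = 1L, rows = seq_len(nrow(X))))
  while (length(stack)) {
    e <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(e$rows) == 0) next
    nd <- tree[e$node, ]
    if (nd$is_leaf) { out[e$rows] <- nd$value; next }
    col <- as.numeric(X[e$rows, nd$feature])
    stack[[length(stack) + 1]] <- list(node = nd$left, rows = e$rows[col == 0])
    stack[[length(stack) + 1]] <- list(node = nd$right, rows = e$rows[col == 1])
  }
  out
}

#' Predicted DT probability of a tree ensemble
#'
#' The ensemble probability is the mean over trees of the DT fraction in the
#' leaf each compound reaches; the class label is DT when the probability is
#' at least 0.5.
#'
#' @param ensemble a [TreeEnsemble-class].
#' @param X binary feature matrix (rows = compounds) over the ensemble's
#'   vocabulary.
#' @return numeric vector of probabilities in `[0, 1]`, named by rownames.
#' @export
predictProba <- function(ensemble, X) {
  stopifnot(is(ensemble, "TreeEnsemble"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == vocabularySize(ensemble@vocabulary))
  acc <- numeric(nrow(X))
  for (tr in ensemble@trees) acc <- acc + .route_tree(tr, X)
  stats::setNames(acc / length(ensemble@trees), rownames(X))
}

## ---- evaluation -----------------------------------------------------------

#' Balanced accuracy and MCC from confusion counts
#'
#' `BA = (TPR + TNR) / 2` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention `MCC = 0` whenever a factor of the denominator is zero.
#'
#' @param tp,fn,tn,fp confusion-matrix cells.
#' @return named list: `tp`, `fn`, `tn`, `fp`, `ba`, `mcc`.
#' @export
confusionStats <- function(tp, fn, tn, fp) {
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  ba <- (tpr + tnr) / 2
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(tp = tp, fn = fn, tn = tn, fp = fp, ba = ba, mcc = mcc)
}

#' Evaluate DT/ST predictions
#'
#' @param prob predicted DT probabilities.
#' @param labels logical vector (`TRUE` = DT).
#' @param threshold decision threshold (default 0.5; predictions at the
#'   threshold count as DT).
#' @return as [confusionStats()].
#' @export
evaluatePredictions <- function(prob, labels, threshold = 0.5) {
  stopifnot(length(prob) == length(labels), length(prob) > 0)
  pred <- prob >= threshold
  confusionStats(tp = sum(pred & labels), fn = sum(!pred & labels),
                 tn = sum(!pred & !labels), fp = sum(pred & !labels))
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("stratified ", k, "-fold split impossible: a class has only ",
           length(idx), " samples")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Default hyperparameter grid
#'
#' The full grid searched by internal cross-validation: number of trees
#' 25/50/100/200/400, minimum samples to split 2/3/5/10, minimum samples per
#' leaf 1/2/5/10.
#' @return data.frame of grid points.
#' @export
brfDefaultGrid <- function() {
  expand.grid(n_estimators = c(25L, 50L, 100L, 200L, 400L),
              min_samples_split = c(2L, 3L, 5L, 10L),
              min_samples_leaf = c(1L, 2L, 5L, 10L))
}

#' Train a balanced random forest
#'
#' When the hyperparameter grid has more than one point, the best point is
#' chosen by stratified internal cross-validation on the training set
#' (highest mean MCC; ties broken by mean BA, then by the smallest number of
#' trees); the final model is then retrained on the complete training set.
#'
#' @param X binary feature matrix (compounds x vocabulary positions).
#' @param y logical labels (`TRUE` = DT).
#' @param vocab the [FeatureVocabulary-class] behind `X`'s columns.
#' @param grid data.frame with columns `n_estimators`, `min_samples_split`,
#'   `min_samples_leaf`; defaults to a single moderate point. Use
#'   [brfDefaultGrid()] for the full search.
#' @param cv_folds folds of the internal cross-validation (default 10).
#' @param mtry features inspected per split (default `sqrt(ncol(X))`).
#' @param seed integer seed; all bootstraps, fold assignments and split
#'   searches derive from it.
#' @return a [TreeEnsemble-class].
#' @export
trainBRF <- function(X, y, vocab, grid = data.frame(n_estimators = 100L,
                       min_samples_split = 2L, min_samples_leaf = 1L),
                     cv_folds = 10L, mtry = NULL, seed = 1L) {
  stopifnot(nrow(X) == length(y), is.logical(y))
  stopifnot(is(vocab, "FeatureVocabulary"),
            ncol(X) == vocabularySize(vocab))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  cv_out <- data.frame()
  pick <- grid[1, , drop = FALSE]
  if (nrow(grid) > 1) {
    fold <- .with_seed(.child_seed(seed, 999), .stratified_folds(y, cv_folds))
    scores <- lapply(seq_len(nrow(grid)), function(g) {
      mccs <- bas <- numeric(cv_folds)
      for (k in seq_len(cv_folds)) {
        tr <- fold != k
        forest <- .fit_forest(X[tr, , drop = FALSE], y[tr],
                              grid$n_estimators[g], grid$min_samples_split[g],
                              grid$min_samples_leaf[g], mtry,
                              .child_seed(seed, g * 100 + k))
        acc <- numeric(sum(!tr))
        for (t in forest) acc <- acc + .route_tree(t, X[!tr, , drop = FALSE])
        ev <- evaluatePredictions(acc / length(forest), y[!tr])
        mccs[k] <- ev$mcc; bas[k] <- ev$ba
      }
      c(mcc = mean(mccs), ba = mean(bas))
    })
    cv_out <- cbind(grid, do.call(rbind, scores))
    ord <- order(-cv_out$mcc, -cv_out$ba, cv_out$n_estimators,
                 cv_out$min_samples_split, cv_out$min_samples_leaf)
    pick <- grid[ord[1], , drop = FALSE]
  }
  trees <- .fit_forest(X, y, pick$n_estimators, pick$min_samples_split,
                       pick$min_samples_leaf, mtry, .child_seed(seed, 1))
  new("TreeEnsemble", trees = trees, vocabulary = vocab,
      hyperparams = list(n_estimators = pick$n_estimators,
                         min_samples_split = pick$min_samples_split,
                         min_samples_leaf = pick$min_samples_leaf,
                         mtry = mtry),
      seed = as.integer(seed), cv = cv_out)
}

## ---- trials ---------------------------------------------------------------

#' Repeated-trial evaluation of a target pair
#'
#' Runs `n_trials` independent trials: a stratified random train/test split
#' of the pair's DT and ST compounds, vocabulary construction from the
#' training compounds, balanced random forest training, and evaluation on
#' the held-out compounds. Accuracy is summarized as mean and standard
#' deviation of BA and MCC over trials.
#'
#' @param pair a [PairDataset-class].
#' @param catalog a [featureCatalog()] covering the pair's compounds.
#' @param n_trials number of trials (default 10).
#' @param split_fraction fraction of each class assigned to training
#'   (default 0.5, an even split).
#' @param grid,cv_folds,mtry passed to [trainBRF()].
#' @param base_seed integer; trial `t` derives its seed from
#'   `(base_seed, t)`.
#' @param vocab_scope `"train"` (default) builds the vocabulary from
#'   training compounds only; `"all"` uses all compounds of the pair.
#' @return list with `trials` (per trial: `ensemble`, `vocab`, `train_ids`,
#'   `test_ids`, `eval` on the test set) and `summary` (data.frame of
#'   mean/sd BA and MCC).
#' @export
runTrials <- function(pair, catalog, n_trials = 10, split_fraction = 0.5,
                      grid = data.frame(n_estimators = 100L,
                        min_samples_split = 2L, min_samples_leaf = 1L),
                      cv_folds = 10L, mtry = NULL, base_seed = 1L,
                      vocab_scope = c("train", "all")) {
  stopifnot(is(pair, "PairDataset"))
  vocab_scope <- match.arg(vocab_scope)
  labels <- pairLabels(pair)
  ids <- names(labels)
  stopifnot(all(ids %in% names(catalog)))
  if (sum(labels) < 2 || sum(!labels) < 2) stop("degenerate pair dataset")
  trials <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    seed_t <- .child_seed(base_seed, t)
    split <- .with_seed(seed_t, {
      tr <- logical(length(ids))
      for (cls in c(TRUE, FALSE)) {
        idx <- which(labels == cls)
        n_tr <- round(length(idx) * split_fraction)
        tr[idx[sample.int(length(idx), n_tr)]] <- TRUE
      }
      tr
    })
    train_ids <- ids[split]; test_ids <- ids[!split]
    if (sum(labels[test_ids]) == 0 || sum(labels[train_ids]) == 0)
      stop("split left a side without DT compounds")
    vocab <- buildVocabulary(catalog,
      if (vocab_scope == "train") train_ids else ids)
    X_tr <- fingerprintMatrix(catalog, vocab, train_ids)
    X_te <- fingerprintMatrix(catalog, vocab, test_ids)
    ens <- trainBRF(X_tr, unname(labels[train_ids]), vocab, grid = grid,
                    cv_folds = cv_folds, mtry = mtry, seed = seed_t)
    ev <- evaluatePredictions(predictProba(ens, X_te),
                              unname(labels[test_ids]))
    trials[[t]] <- list(ensemble = ens, vocab = vocab, train_ids = train_ids,
                        test_ids = test_ids, eval = ev, seed = seed_t)
  }
  list(trials = trials, summary = .trial_summary(lapply(trials, `[[`, "eval")))
}

.trial_summary <- function(evals) {
  ba <- vapply(evals, `[[`, numeric(1), "ba")
  mcc <- vapply(evals, `[[`, numeric(1), "mcc")
  data.frame(metric = c("BA", "MCC"),
             mean = c(mean(ba), mean(mcc)),
             sd = c(if (length(ba) > 1) stats::sd(ba) else 0,
                    if (length(mcc) > 1) stats::sd(mcc) else 0))
}

#' Cross-pair prediction
#'
#' Applies models trained on one target pair to the compounds of another
#' pair: the other pair's compounds are featurized with the model's
#' vocabulary (environments unseen in training are dropped) and evaluated
#' against their own DT/ST labels.
#'
#' @param trials result of [runTrials()] on the source pair.
#' @param catalog a [featureCatalog()] covering the other pair's compounds.
#' @param other a [PairDataset-class]: the pair to predict.
#' @return list with per-trial evaluations and a `summary` data.frame.
#' @export
crossPredict <- function(trials, catalog, other) {
  stopifnot(is(other, "PairDataset"))
  labels <- pairLabels(other)
  evals <- lapply(trials$trials, function(tr) {
    X <- fingerprintMatrix(catalog, tr$vocab, names(labels))
    evaluatePredictions(predictProba(tr$ensemble, X), unname(labels))
  })
  list(evals = evals, summary = .trial_summary(evals))
}

## ---- serialization --------------------------------------------------------

#' Serialize a tree ensemble to JSON
#'
#' Writes the complete tree structure (node ids, split positions, children,
#' leaf values, coverages), hyperparameters, seed, and the vocabulary; this
#' file is the contract consumed by the Shapley explainer and is sufficient
#' to reconstruct the model exactly.
#'
#' @param ensemble a [TreeEnsemble-class].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeEnsembleJSON <- function(ensemble, path) {
  ## leaves carry no split: encode their feature/children as -1
  obj <- list(trees = lapply(ensemble@trees, function(tr) {
                tr <- tr[, c("node_id", "is_leaf", "feature", "left", "right",
                             "value", "coverage")]
                for (col in c("feature", "left", "right"))
                  tr[[col]][is.na(tr[[col]])] <- -1L
                tr
              }),
              vocabulary = ensemble@vocabulary@ids,
              hyperparams = ensemble@hyperparams,
              seed = ensemble@seed)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeEnsembleJSON
#' @param path JSON file written by `writeEnsembleJSON`.
#' @export
readEnsembleJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  trees <- lapply(obj$trees, function(tr) {
    tr <- as.data.frame(tr)
    for (col in c("feature", "left", "right")) {
      v <- as.integer(tr[[col]])
      v[v < 0] <- NA_integer_
      tr[[col]] <- v
    }
    tr$is_leaf <- as.logical(tr$is_leaf)
    tr
  })
  new("TreeEnsemble", trees = trees,
      vocabulary = new("FeatureVocabulary", ids = obj$vocabulary),
      hyperparams = as.list(obj$hyperparams),
      seed = as.integer(obj$seed), cv = data.frame())
}
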