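# Hand-built tree node tables and random tree ensembles used by the
# classifier and Shapley tests.

tree_node_frame <- function(...) {
  df <- data.frame(...)
  stopifnot(all(c("node_id", "is_leaf", "feature", "left", "right", "value",
                  "coverage") %in% colnames(df)))
  df
}

# single leaf with the given value
leaf_tree <- function(value, coverage = 10) {
  tree_node_frame(node_id = 1L, is_leaf = TRUE, feature = NA_integer_,
                  left = NA_integer_, right = NA_integer_, value = value,
                  coverage = coverage)
}

# depth-1 stump: split on `feature`, left = feature off
stump_tree <- function(feature, v_off, v_on, c_off = 50, c_on = 50) {
  tree_node_frame(
    node_id = 1:3,
    is_leaf = c(FALSE, TRUE, TRUE),
    feature = c(feature, NA, NA),
    left = c(2L, NA, NA), right = c(3L, NA, NA),
    value = c((c_off * v_off + c_on * v_on) / (c_off + c_on), v_off, v_on),
    coverage = c(c_off + c_on, c_off, c_on))
}

make_ensemble <- function(trees, n_features,
                          ids = sprintf("env%03d", seq_len(n_features))) {
  new("TreeEnsemble", trees = trees,
      vocabulary = new("FeatureVocabulary", ids = sort(ids)),
      hyperparams = list(n_estimators = length(trees)), seed = 1L,
      cv = data.frame())
}

# random tree with integer coverages conserved at every node; features may
# repeat along a path, which exercises the path bookkeeping of the explainer
random_tree <- function(n_features, max_depth, root_coverage = 64) {
  nodes <- list()
  next_id <- 1L
  build <- function(depth, coverage) {
    id <- next_id; next_id <<- next_id + 1L
    if (depth >= max_depth || coverage < 2 || stats::runif(1) < 0.25) {
      nodes[[id]] <<- data.frame(node_id = id, is_leaf = TRUE,
                                 feature = NA_integer_, left = NA_integer_,
                                 right = NA_integer_,
                                 value = stats::runif(1), coverage = coverage)
      return(id)
    }
    c_left <- sample(seq_len(coverage - 1), 1)
    nodes[[id]] <<- data.frame(node_id = id, is_leaf = FALSE,
                               feature = sample(n_features, 1),
                               left = NA_integer_, right = NA_integer_,
                               value = NA_real_, coverage = coverage)
    l <- build(depth + 1, c_left)
    r <- build(depth + 1, coverage - c_left)
    nodes[[id]]$left <<- l
    nodes[[id]]$right <<- r
    id
  }
  build(0, root_coverage)
  tr <- do.call(rbind, nodes)
  # leaves need values; internal value slots are irrelevant to the explainer
  tr$value[!tr$is_leaf] <- 0
  tr
}
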