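## Global Shapley-value analysis: present/absent contribution distributions,
## the rank-based N/M prioritized-feature extraction scheme, atom-level
## mapping of prioritized features, cumulative contribution partitions, the
## absence-signature control, and motif prevalence statistics.

#' Prioritized feature set
#'
#' Result of the rank-based feature extraction scheme: per correctly
#' predicted compound the `N` present features with the largest Shapley
#' values are pre-selected, pooled across compounds, and the `M` features
#' occurring most frequently are prioritized.
#'
#' @slot table data.frame with one row per prioritized feature, ordered by
#'   rank: `rank`, `position`, `env_id`, `count` (number of compounds whose
#'   top-N set contains the feature), `total_sv`.
#' @slot N,M the scheme parameters.
#' @slot compound_ids the correctly predicted compounds the scheme was run
#'   on.
#' @slot mode `"present"` (DT presence scheme) or `"absent"` (ST absence
#'   control).
#' @export
setClass("PrioritizedFeatureSet",
  representation(table = "data.frame", N = "integer", M = "integer",
                 compound_ids = "character", mode = "character"),
  validity = function(object) {
    if (nrow(object@table) > object@M) return("more than M features")
    if (is.unsorted(rev(object@table$count))) return("counts must be non-increasing")
    TRUE
  })

setMethod("show", "PrioritizedFeatureSet", function(object) {
  cat("PrioritizedFeatureSet (", object@mode, " scheme, N=", object@N,
      ", M=", object@M, "): ", nrow(object@table), " features from ",
      length(object@compound_ids), " compounds\n", sep = "")
})

#' @describeIn PrioritizedFeatureSet vocabulary positions, by rank
#' @param x a `PrioritizedFeatureSet`
#' @export
prioritizedPositions <- function(x) x@table$position

#' @describeIn PrioritizedFeatureSet feature table accessor
#' @export
prioritizedTable <- function(x) x@table

.correct_mask <- function(explanations, labels) {
  ids <- explainedIds(explanations)
  stopifnot(all(ids %in% names(labels)))
  lab <- labels[ids]
  pred_dt <- explanations@prediction >= 0.5
  stats::setNames(pred_dt == lab, ids)
}

#' Global present/absent Shapley-value distributions
#'
#' For every correctly predicted compound, sums Shapley values separately
#' over present and absent features and summarizes the resulting
#' distributions per class (DT/ST) and status (present/absent) by box-plot
#' statistics (min, lower quartile, median, upper quartile, max).
#'
#' @param explanations an [ExplanationSet-class].
#' @param labels named logical vector (`TRUE` = DT) covering the explained
#'   compounds.
#' @return data.frame with columns `class`, `status`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
globalPresentAbsent <- function(explanations, labels) {
  correct <- .correct_mask(explanations, labels)
  part <- partitionSV(explanations)
  part <- part[correct[part$compound_id], , drop = FALSE]
  lab <- labels[part$compound_id]
  out <- list()
  for (cls in c("DT", "ST")) {
    sub <- part[lab == (cls == "DT"), , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("no correctly predicted ", cls, " compounds; class omitted")
      next
    }
    for (status in c("present", "absent")) {
      v <- if (status == "present") sub$present_sum else sub$absent_sum
      fv <- stats::fivenum(v)
      out[[length(out) + 1]] <- data.frame(
        class = cls, status = status, n = length(v), min = fv[1], q1 = fv[2],
        median = fv[3], q3 = fv[4], max = fv[5])
    }
  }
  do.call(rbind, out)
}

#' Per-compound feature counts
#'
#' Number of on-bits per compound and their median; on typical drug-like
#' compounds the median motivates the choice of `N` (about 10% of the median
#' feature count) in the prioritization scheme.
#'
#' @param X binary fingerprint matrix (compounds x positions).
#' @return list: `counts` (named integer vector) and `median`.
#' @export
featureCountDistribution <- function(X) {
  stopifnot(nrow(X) >= 1)
  counts <- Matrix::rowSums(X)
  med <- stats::median(counts)
  message("median feature count ", med, "; N = ", max(1, round(med / 10)),
          " would pre-select ~10% of a typical compound's features")
  list(counts = counts, median = med)
}

.topN_present <- function(sv_row, on_row, N, sign = +1) {
  pos <- if (sign > 0) which(on_row) else which(!on_row)
  v <- sign * sv_row[pos]
  pos <- pos[v > 0]; v <- v[v > 0]
  if (length(pos) == 0) return(integer(0))
  ord <- order(-v, pos)
  pos[ord[seq_len(min(N, length(pos)))]]
}

.rank_scheme <- function(explanations, labels, N, M, class_is_dt, sign,
                         mode) {
  stopifnot(N >= 1, M >= 1)
  correct <- .correct_mask(explanations, labels)
  ids <- explainedIds(explanations)
  lab <- labels[ids]
  use <- which(correct & lab == class_is_dt)
  if (length(use) == 0)
    stop("no correctly predicted ", if (class_is_dt) "DT" else "ST",
         " compounds to extract features from")
  sv <- explanations@sv
  on <- explanations@on
  picks <- lapply(use, function(i)
    .topN_present(as.numeric(sv[i, ]), as.logical(on[i, ]), N, sign))
  pool <- unlist(picks)
  if (length(pool) == 0)
    stop("no features with ", if (sign > 0) "positive" else "negative",
         " Shapley values among the selected compounds")
  count <- table(pool)
  pos <- as.integer(names(count))
  tot <- vapply(pos, function(p) sum(sign * sv[use, p]), numeric(1))
  ord <- order(-as.integer(count), -tot, pos)
  keep <- ord[seq_len(min(M, length(ord)))]
  tab <- data.frame(rank = seq_along(keep), position = pos[keep],
                    env_id = featureIds(explanations@vocabulary, pos[keep]),
                    count = as.integer(count)[keep], total_sv = tot[keep],
                    stringsAsFactors = FALSE)
  new("PrioritizedFeatureSet", table = tab, N = as.integer(N),
      M = as.integer(M), compound_ids = ids[use], mode = mode)
}

#' Rank-based prioritized-feature extraction
#'
#' For each correctly predicted DT compound, pre-selects the `N` present
#' features with the largest positive Shapley values (ties broken by
#' ascending position; compounds with fewer than `N` qualifying features
#' contribute all of them), pools the pre-selections, and prioritizes the
#' `M` features occurring most frequently across compounds (ties broken by
#' total Shapley value, then position).
#'
#' @param explanations an [ExplanationSet-class] covering training and/or
#'   test compounds of a trial.
#' @param labels named logical vector (`TRUE` = DT).
#' @param N number of features pre-selected per compound (default 5).
#' @param M number of prioritized features (default 10).
#' @return a [PrioritizedFeatureSet-class].
#' @export
extractPrioritized <- function(explanations, labels, N = 5, M = 10) {
  .rank_scheme(explanations, labels, N, M, class_is_dt = TRUE, sign = +1,
               mode = "present")
}

#' Absence-signature control
#'
#' Mirror image of [extractPrioritized()] for correctly predicted ST
#' compounds: among features absent from each compound, pre-selects the `N`
#' with the most negative Shapley values (the absences driving the correct
#' ST prediction) and prioritizes the `M` most frequent.
#'
#' @inheritParams extractPrioritized
#' @return a [PrioritizedFeatureSet-class] with mode `"absent"`.
#' @export
absenceSignature <- function(explanations, labels, N = 5, M = 10) {
  .rank_scheme(explanations, labels, N, M, class_is_dt = FALSE, sign = -1,
               mode = "absent")
}

#' Count prioritized features per compound
#'
#' @param X binary fingerprint matrix.
#' @param prioritized a [PrioritizedFeatureSet-class] (or integer positions).
#' @return list: `counts` (named per compound) and `histogram` (table over
#'   `0..M`).
#' @export
countPrioritized <- function(X, prioritized) {
  pos <- if (is(prioritized, "PrioritizedFeatureSet"))
    prioritizedPositions(prioritized) else as.integer(prioritized)
  stopifnot(length(pos) >= 1)
  counts <- Matrix::rowSums(X[, pos, drop = FALSE])
  m <- if (is(prioritized, "PrioritizedFeatureSet")) prioritized@M
       else length(pos)
  list(counts = counts,
       histogram = table(factor(counts, levels = 0:m)))
}

#' Color atoms by prioritized-feature membership
#'
#' For every prioritized feature present in the compound, each atom covered
#' by at least one occurrence of the feature receives one count; the counts
#' drive the usual light-yellow-to-dark-red substructure highlighting and
#' the induced covered substructure.
#'
#' @param envs an [enumerateEnvironments()] result (or a [MolGraph-class] /
#'   SMILES, which will be enumerated).
#' @param prioritized a [PrioritizedFeatureSet-class] or integer positions.
#' @param vocab the [FeatureVocabulary-class] the positions refer to.
#' @return list: `counts` (integer per atom), `atoms` (indices with count
#'   >= 1), `n_features_present` (prioritized features present).
#' @export
colorAtoms <- function(envs, prioritized, vocab) {
  if (!is.list(envs) || is.null(envs$occurrences))
    envs <- enumerateEnvironments(envs)
  pos <- if (is(prioritized, "PrioritizedFeatureSet"))
    prioritizedPositions(prioritized) else as.integer(prioritized)
  ids <- featureIds(vocab, pos)
  n <- max(c(0, unlist(lapply(envs$occurrences, function(occ)
    lapply(occ, `[[`, "atoms")))))
  counts <- integer(n)
  n_present <- 0
  for (id in ids) {
    occ <- envs$occurrences[[id]]
    if (is.null(occ)) next
    n_present <- n_present + 1
    covered <- unique(unlist(lapply(occ, `[[`, "atoms")))
    counts[covered] <- counts[covered] + 1L
  }
  list(counts = counts, atoms = which(counts >= 1),
       n_features_present = n_present)
}

#' Partition a compound's contributions around a motif
#'
#' Splits the Shapley values of one compound into features mapping entirely
#' inside the designated motif substructure (every occurrence's atoms lie in
#' a motif match), other present features, and absent features; the three
#' sums plus the base value reconstruct the prediction.
#'
#' @param explanations an [ExplanationSet-class].
#' @param catalog a [featureCatalog()] covering the compounds.
#' @param mols named list of [MolGraph-class] objects.
#' @param motif_query motif substructure ([MolGraph-class] or SMILES).
#' @param compound_ids compounds to partition (default: all explained).
#' @return data.frame: `compound_id`, `motif_sum`, `other_present_sum`,
#'   `absent_sum`, `base`, `prediction`.
#' @export
partitionContributions <- function(explanations, catalog, mols, motif_query,
                                   compound_ids = NULL) {
  if (is.character(motif_query)) motif_query <- parseSmiles(motif_query)[[1]]
  ids <- explainedIds(explanations)
  if (is.null(compound_ids)) compound_ids <- ids
  stopifnot(all(compound_ids %in% ids),
            all(compound_ids %in% names(catalog)),
            all(compound_ids %in% names(mols)))
  vocab <- explanations@vocabulary
  out <- lapply(compound_ids, function(id) {
    i <- match(id, ids)
    sv_row <- as.numeric(explanations@sv[i, ])
    on_row <- as.logical(explanations@on[i, ])
    maps <- matchSubstructure(mols[[id]], motif_query)
    motif_atoms <- unique(unlist(maps))
    present <- which(on_row)
    motif_feat <- logical(length(present))
    if (length(motif_atoms)) {
      env <- catalog[[id]]
      for (k in seq_along(present)) {
        occ <- env$occurrences[[featureIds(vocab, present[k])]]
        if (!is.null(occ))
          motif_feat[k] <- all(vapply(occ, function(o)
            all(o$atoms %in% motif_atoms), logical(1)))
      }
    }
    tot <- sum(sv_row)
    ms <- sum(sv_row[present[motif_feat]])
    ps <- sum(sv_row[present])
    data.frame(compound_id = id, motif_sum = ms,
               other_present_sum = ps - ms, absent_sum = tot - ps,
               base = explanations@base,
               prediction = unname(explanations@prediction[i]))
  })
  do.call(rbind, out)
}

#' Motif prevalence per class
#'
#' Substructure-match counts and fractions of a motif among DT and ST
#' compounds, optionally also among the correctly predicted subsets.
#'
#' @param mols named list of [MolGraph-class] objects.
#' @param motif_query motif ([MolGraph-class] or SMILES).
#' @param labels named logical vector (`TRUE` = DT) over `names(mols)`.
#' @param correct optional named logical vector of prediction correctness.
#' @return data.frame: `class`, `subset`, `matched`, `total`, `fraction`.
#' @export
motifPrevalence <- function(mols, motif_query, labels, correct = NULL) {
  if (is.character(motif_query)) motif_query <- parseSmiles(motif_query)[[1]]
  ids <- names(mols)
  stopifnot(all(ids %in% names(labels)))
  hit <- vapply(mols, function(m) hasSubstructure(m, motif_query), logical(1))
  lab <- labels[ids]
  rows <- list()
  add <- function(cls, subset, sel) {
    rows[[length(rows) + 1]] <<- data.frame(
      class = cls, subset = subset, matched = sum(hit[sel]),
      total = sum(sel),
      fraction = if (sum(sel)) sum(hit[sel]) / sum(sel) else 0)
  }
  add("DT", "all", lab)
  add("ST", "all", !lab)
  if (!is.null(correct)) {
    corr <- correct[ids]
    add("DT", "correct", lab & corr)
    add("ST", "correct", !lab & corr)
  }
  do.call(rbind, rows)
}

#' Motif recovery by the prioritized feature set
#'
#' For each motif-bearing compound, the fraction of the planted motif's
#' atoms covered by prioritized features present in the compound
#' ([colorAtoms()] cover), together with the fraction of compounds reaching
#' a given coverage level. This quantifies whether the extracted features
#' delineate the motif as a coherent substructure.
#'
#' @param mols named list of [MolGraph-class] objects (motif-bearing,
#'   correctly predicted DT compounds).
#' @param catalog a [featureCatalog()] covering them.
#' @param prioritized a [PrioritizedFeatureSet-class].
#' @param vocab the [FeatureVocabulary-class].
#' @param motif_query the planted motif ([MolGraph-class] or SMILES).
#' @param level coverage level counted as recovered (default 0.8).
#' @return list: `per_compound` data.frame (`compound_id`, `motif_atoms`,
#'   `covered`, `coverage`) and `recovered_fraction`.
#' @export
motifRecovery <- function(mols, catalog, prioritized, vocab, motif_query,
                          level = 0.8) {
  if (is.character(motif_query)) motif_query <- parseSmiles(motif_query)[[1]]
  ids <- names(mols)
  stopifnot(all(ids %in% names(catalog)))
  rows <- lapply(ids, function(id) {
    maps <- matchSubstructure(mols[[id]], motif_query)
    motif_atoms <- unique(unlist(maps))
    if (length(motif_atoms) == 0)
      return(data.frame(compound_id = id, motif_atoms = 0L, covered = 0L,
                        coverage = NA_real_))
    col <- colorAtoms(catalog[[id]], prioritized, vocab)
    cov <- length(intersect(col$atoms, motif_atoms))
    data.frame(compound_id = id, motif_atoms = length(motif_atoms),
               covered = cov, coverage = cov / length(motif_atoms))
  })
  per <- do.call(rbind, rows)
  ok <- per$coverage[!is.na(per$coverage)]
  list(per_compound = per,
       recovered_fraction = if (length(ok)) mean(ok >= level) else NA_real_)
}
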