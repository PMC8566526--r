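## Staged pipeline: synthesize/ingest -> curate -> featurize -> train ->
## explain -> analyze -> report. Every stage consumes only serialized
## outputs of earlier stages (so any stage can be re-run in isolation) and
## every run ends with a manifest listing each artifact with a content hash.

#' Pipeline configuration
#'
#' Single source of truth for a full study run. Either a synthetic
#' configuration (the default) or a raw activity CSV can provide the input
#' data; all seeds are explicit.
#'
#' @param synthetic a [syntheticConfig()], or `NULL` when `activity_csv` is
#'   given.
#' @param activity_csv path to a raw activity table (schema of
#'   [filterRecords()]); used when `synthetic` is `NULL`.
#' @param pairs named list of character(2) target-id pairs.
#' @param motif_queries named list (by pair) of motif SMILES used for
#'   contribution partitions and recovery statistics; defaults to the
#'   planted motifs when running synthetically.
#' @param organism organism required by curation.
#' @param n_trials,split_fraction,grid,cv_folds,vocab_scope see
#'   [runTrials()].
#' @param N,M prioritization parameters (see [extractPrioritized()]).
#' @param base_seed integer master seed.
#' @param interference use the shipped interference catalog (`TRUE`), none
#'   (`FALSE`), or a path to a custom TSV catalog.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           activity_csv = NULL,
                           pairs = list(pair1 = c("T_MAOB", "T_A2AR"),
                                        pair2 = c("T_MAOB", "T_ACHE")),
                           motif_queries = NULL,
                           organism = "Homo sapiens",
                           n_trials = 10, split_fraction = 0.5,
                           grid = data.frame(n_estimators = 100L,
                             min_samples_split = 2L, min_samples_leaf = 1L),
                           cv_folds = 10L, vocab_scope = "train",
                           N = 5, M = 10, base_seed = 1L,
                           interference = TRUE) {
  if (is.null(synthetic) && is.null(activity_csv))
    stop("either a synthetic config or an activity CSV is required")
  if (!is.null(activity_csv) && !file.exists(activity_csv))
    stop("activity_csv does not exist: ", activity_csv)
  if (is.null(motif_queries) && !is.null(synthetic))
    motif_queries <- list(pair1 = synthetic@motif_smiles_pair1,
                          pair2 = synthetic@motif_smiles_pair2)
  structure(list(synthetic = synthetic, activity_csv = activity_csv,
                 pairs = pairs, motif_queries = motif_queries,
                 organism = organism, n_trials = n_trials,
                 split_fraction = split_fraction, grid = grid,
                 cv_folds = cv_folds, vocab_scope = vocab_scope,
                 N = N, M = M, base_seed = as.integer(base_seed),
                 interference = interference),
            class = "PipelineConfig")
}

.interference_catalog <- function(config) {
  if (isTRUE(config$interference)) defaultInterferenceCatalog()
  else if (is.character(config$interference))
    utils::read.csv(config$interference, sep = "\t", stringsAsFactors = FALSE)
  else NULL
}

.read_smi <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(vapply(parts, `[[`, character(1), 1),
                  vapply(parts, `[[`, character(1), 2))
}

.stage_synth <- function(config, outdir) {
  dir <- file.path(outdir, "synth")
  if (!is.null(config$synthetic)) {
    lib <- generateLibrary(config$synthetic)
    writeLibrary(lib, dir)
  } else {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    act <- utils::read.csv(config$activity_csv, stringsAsFactors = FALSE)
    utils::write.csv(act, file.path(dir, "activity.csv"), row.names = FALSE)
    cpd <- act[!duplicated(act$compound_id), c("smiles", "compound_id")]
    writeLines(paste(cpd$smiles, cpd$compound_id, sep = "\t"),
               file.path(dir, "compounds.smi"))
  }
  invisible(dir)
}

.stage_curate <- function(config, outdir) {
  dir <- file.path(outdir, "curate")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  act <- utils::read.csv(file.path(outdir, "synth", "activity.csv"),
                         stringsAsFactors = FALSE)
  truth_path <- file.path(outdir, "synth", "ground_truth.json")
  cohorts <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    cohorts <- split(truth$compounds$id, truth$compounds$pair_id)
  }
  catalog <- .interference_catalog(config)
  for (pr in names(config$pairs)) {
    sub <- if (!is.null(cohorts))
      act[act$compound_id %in% cohorts[[pr]], , drop = FALSE] else act
    cur <- filterRecords(sub, organism = config$organism,
                         interference_catalog = catalog)
    pd <- assignClasses(cur, config$pairs[[pr]], raw_table = sub)
    utils::write.csv(cur[, c("compound_id", "target_id", "p_potency")],
                     file.path(dir, paste0(pr, "_curated.csv")),
                     row.names = FALSE)
    writeLines(paste(names(attr(cur, "drop_log")), attr(cur, "drop_log"),
                     sep = "\t"),
               file.path(dir, paste0(pr, "_drop_log.tsv")))
    jsonlite::write_json(
      list(pair_id = pd@pair_id, compounds = pd@compounds,
           excluded = pd@excluded),
      file.path(dir, paste0(pr, "_dataset.json")),
      dataframe = "columns", auto_unbox = TRUE)
  }
  invisible(dir)
}

.read_pair_dataset <- function(outdir, pr) {
  obj <- jsonlite::read_json(
    file.path(outdir, "curate", paste0(pr, "_dataset.json")),
    simplifyVector = TRUE)
  cp <- as.data.frame(obj$compounds, stringsAsFactors = FALSE)
  cp$target_id <- as.character(cp$target_id)
  new("PairDataset", pair_id = obj$pair_id, compounds = cp,
      excluded = as.character(unlist(obj$excluded)))
}

.stage_featurize <- function(config, outdir) {
  dir <- file.path(outdir, "featurize")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smi <- .read_smi(file.path(outdir, "synth", "compounds.smi"))
  for (pr in names(config$pairs)) {
    pd <- .read_pair_dataset(outdir, pr)
    ids <- pd@compounds$id
    mols <- parseSmiles(smi[ids], ids = ids)
    catalog <- featureCatalog(mols)
    all_ids <- sort(unique(unlist(lapply(catalog, `[[`, "ids"))))
    per_cpd <- lapply(catalog, function(e) match(e$ids, all_ids))
    jsonlite::write_json(list(env_ids = all_ids, compounds = per_cpd),
                         file.path(dir, paste0(pr, "_environments.json")))
    counts <- vapply(catalog, function(e) length(e$ids), integer(1))
    utils::write.csv(data.frame(compound_id = ids, n_features = counts[ids]),
                     file.path(dir, paste0(pr, "_feature_counts.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

.read_catalog_ids <- function(outdir, pr) {
  obj <- jsonlite::read_json(
    file.path(outdir, "featurize", paste0(pr, "_environments.json")),
    simplifyVector = TRUE)
  lapply(obj$compounds, function(ix) list(ids = obj$env_ids[ix]))
}

.stage_train <- function(config, outdir) {
  dir <- file.path(outdir, "train")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- list()
  for (pr in names(config$pairs)) {
    pd <- .read_pair_dataset(outdir, pr)
    catalog <- .read_catalog_ids(outdir, pr)
    runs[[pr]] <- runTrials(pd, catalog, n_trials = config$n_trials,
                            split_fraction = config$split_fraction,
                            grid = config$grid, cv_folds = config$cv_folds,
                            base_seed = .child_seed(config$base_seed,
                                                    match(pr, names(config$pairs))),
                            vocab_scope = config$vocab_scope)
    writeEnsembleJSON(runs[[pr]]$trials[[1]]$ensemble,
                      file.path(dir, paste0(pr, "_trial1_model.json")))
    jsonlite::write_json(
      lapply(runs[[pr]]$trials, function(t)
        list(seed = t$seed, train_ids = t$train_ids, test_ids = t$test_ids)),
      file.path(dir, paste0(pr, "_splits.json")))
  }
  rows <- list()
  for (pr in names(config$pairs)) {
    s <- runs[[pr]]$summary
    rows[[length(rows) + 1]] <- data.frame(
      trained_on = pr, tested_on = pr, task = "native", metric = s$metric,
      mean = s$mean, sd = s$sd)
    for (other in setdiff(names(config$pairs), pr)) {
      cr <- crossPredict(runs[[pr]], .read_catalog_ids(outdir, other),
                         .read_pair_dataset(outdir, other))
      s <- cr$summary
      rows[[length(rows) + 1]] <- data.frame(
        trained_on = pr, tested_on = other, task = "cross",
        metric = s$metric, mean = s$mean, sd = s$sd)
    }
    ev <- lapply(runs[[pr]]$trials, `[[`, "eval")
    utils::write.csv(
      data.frame(trial = seq_along(ev),
                 tp = vapply(ev, `[[`, numeric(1), "tp"),
                 fn = vapply(ev, `[[`, numeric(1), "fn"),
                 tn = vapply(ev, `[[`, numeric(1), "tn"),
                 fp = vapply(ev, `[[`, numeric(1), "fp"),
                 ba = vapply(ev, `[[`, numeric(1), "ba"),
                 mcc = vapply(ev, `[[`, numeric(1), "mcc")),
      file.path(dir, paste0(pr, "_trial_confusions.csv")), row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "accuracy_summary.csv"), row.names = FALSE)
  invisible(dir)
}

.stage_explain <- function(config, outdir) {
  dir <- file.path(outdir, "explain")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pr in names(config$pairs)) {
    ens <- readEnsembleJSON(file.path(outdir, "train",
                                      paste0(pr, "_trial1_model.json")))
    splits <- jsonlite::read_json(file.path(outdir, "train",
                                            paste0(pr, "_splits.json")),
                                  simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
    ids <- c(splits[[1]]$train_ids, splits[[1]]$test_ids)
    catalog <- .read_catalog_ids(outdir, pr)
    X <- fingerprintMatrix(catalog, ens@vocabulary, ids)
    es <- explainCompounds(ens, X)
    part <- partitionSV(es)
    jsonlite::write_json(part, file.path(dir, paste0(pr, "_sv_summary.json")),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    sv <- Matrix::summary(es@sv)   # triplet form: nonzero entries only
    utils::write.csv(
      data.frame(compound_id = rownames(es@sv)[sv$i], position = sv$j,
                 sv = sv$x, present = as.logical(es@on[cbind(sv$i, sv$j)])),
      file.path(dir, paste0(pr, "_sv.csv")), row.names = FALSE)
  }
  invisible(dir)
}

.stage_analyze <- function(config, outdir) {
  dir <- file.path(outdir, "analyze")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smi <- .read_smi(file.path(outdir, "synth", "compounds.smi"))
  for (pr in names(config$pairs)) {
    pd <- .read_pair_dataset(outdir, pr)
    labels <- pairLabels(pd)
    ens <- readEnsembleJSON(file.path(outdir, "train",
                                      paste0(pr, "_trial1_model.json")))
    catalog <- .read_catalog_ids(outdir, pr)
    ids <- names(labels)
    X <- fingerprintMatrix(catalog, ens@vocabulary, ids)
    es <- explainCompounds(ens, X)
    gpa <- globalPresentAbsent(es, labels)
    utils::write.csv(gpa, file.path(dir, paste0(pr, "_present_absent.csv")),
                     row.names = FALSE)
    prio <- extractPrioritized(es, labels, N = config$N, M = config$M)
    utils::write.csv(prioritizedTable(prio),
                     file.path(dir, paste0(pr, "_prioritized.csv")),
                     row.names = FALSE)
    asig <- tryCatch(absenceSignature(es, labels, N = config$N, M = config$M),
                     error = function(e) NULL)
    if (!is.null(asig))
      utils::write.csv(prioritizedTable(asig),
                       file.path(dir, paste0(pr, "_absence_signature.csv")),
                       row.names = FALSE)
    cnt <- countPrioritized(X, prio)
    utils::write.csv(
      data.frame(compound_id = ids, label = ifelse(labels[ids], "DT", "ST"),
                 prioritized_count = as.integer(cnt$counts[ids]),
                 correct = unname(.correct_mask(es, labels)[ids])),
      file.path(dir, paste0(pr, "_prioritized_counts.csv")),
      row.names = FALSE)
    ## atom colorings and motif statistics on correctly predicted DTs
    correct <- .correct_mask(es, labels)
    dts <- ids[labels[ids] & correct[ids]]
    mols <- parseSmiles(smi[dts], ids = dts)
    cat_dt <- featureCatalog(mols)
    colorings <- lapply(cat_dt, colorAtoms, prioritized = prio,
                        vocab = ens@vocabulary)
    jsonlite::write_json(lapply(colorings, `[[`, "counts"),
                         file.path(dir, paste0(pr, "_atom_colorings.json")))
    motif <- config$motif_queries[[pr]]
    if (!is.null(motif)) {
      pc <- partitionContributions(es, cat_dt, mols, motif, dts)
      utils::write.csv(pc,
        file.path(dir, paste0(pr, "_contribution_partition.csv")),
        row.names = FALSE)
      all_mols <- parseSmiles(smi[ids], ids = ids)
      prev <- motifPrevalence(all_mols, motif, labels, correct)
      utils::write.csv(prev, file.path(dir, paste0(pr, "_motif_prevalence.csv")),
                       row.names = FALSE)
      carriers <- dts[vapply(mols[dts], function(m)
        hasSubstructure(m, parseSmiles(motif)[[1]]), logical(1))]
      rec <- motifRecovery(mols[carriers], cat_dt, prio, ens@vocabulary, motif)
      utils::write.csv(rec$per_compound,
        file.path(dir, paste0(pr, "_motif_recovery.csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}

.stage_report <- function(config, outdir) {
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    base_seed = config$base_seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ShapSig")),
    files = data.frame(path = sub(paste0("^", outdir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files)),
                       bytes = file.size(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(file.path(outdir, "manifest.json"))
}

#' Run the full analysis pipeline
#'
#' Executes synthesize/ingest, curation, featurization, training (native
#' and cross predictions), Shapley explanation, and signature analysis,
#' writing each stage's artifacts under `outdir` and finishing with a
#' manifest of content hashes. Stages communicate exclusively through
#' serialized artifacts, so each can be re-run in isolation via
#' [runPipelineStage()].
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory.
#' @return invisibly, the manifest path.
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (stage in c("synth", "curate", "featurize", "train", "explain",
                  "analyze", "report"))
    runPipelineStage(config, outdir, stage)
  invisible(file.path(outdir, "manifest.json"))
}

#' @rdname runPipeline
#' @param stage one of `"synth"`, `"curate"`, `"featurize"`, `"train"`,
#'   `"explain"`, `"analyze"`, `"report"`.
#' @export
runPipelineStage <- function(config, outdir, stage) {
  fn <- switch(stage, synth = .stage_synth, curate = .stage_curate,
               featurize = .stage_featurize, train = .stage_train,
               explain = .stage_explain, analyze = .stage_analyze,
               report = .stage_report,
               stop("unknown stage: ", stage))
  tryCatch(fn(config, outdir),
           error = function(e)
             stop("pipeline stage '", stage, "' failed: ",
                  conditionMessage(e), call. = FALSE))
}
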