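# Shared fixtures. `small_library()` is a reduced synthetic system for unit
# tests; `study_run()` is the full default-scale study (both target pairs,
# 10 trials, native and cross evaluation, trial-1 explanations) shared by
# the acceptance tests. Both are computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_config <- function(seed = 7) {
  syntheticConfig(seed = seed, n_dt_per_pair = 12L, n_st_per_target = 60L,
                  dirty_record_fraction = 0.05)
}

small_library <- function() .memo("small_lib", generateLibrary(small_config()))

pair_targets <- list(pair1 = c("T_MAOB", "T_A2AR"),
                     pair2 = c("T_MAOB", "T_ACHE"))

# curate one pair of a library (the pair's own cohort of compounds)
curate_pair <- function(lib, pair_name) {
  cp <- compoundTable(lib)
  ids <- cp$id[cp$pair_id == pair_name]
  act <- activityTable(lib)
  act <- act[act$compound_id %in% ids, , drop = FALSE]
  cur <- filterRecords(act)
  assignClasses(cur, pair_targets[[pair_name]], raw_table = act)
}

# full default-condition study: the scale and seeds here define the
# synthetic reproduction of the two-target-pair experiment
study_run <- function() .memo("study", {
  cfg <- syntheticConfig(seed = 1L)
  lib <- generateLibrary(cfg)
  out <- list(cfg = cfg, lib = lib, pds = list(), cats = list(),
              trials = list(), cross = list(), expl = list(),
              labels = list(), prior = list())
  for (pr in names(pair_targets)) {
    out$pds[[pr]] <- curate_pair(lib, pr)
    ids <- pairCompounds(out$pds[[pr]])$id
    out$cats[[pr]] <- featureCatalog(libraryMols(lib)[ids])
    out$trials[[pr]] <- runTrials(out$pds[[pr]], out$cats[[pr]],
                                  n_trials = 10, base_seed = 101)
    out$labels[[pr]] <- pairLabels(out$pds[[pr]])
  }
  for (pr in names(pair_targets)) {
    other <- setdiff(names(pair_targets), pr)
    out$cross[[pr]] <- crossPredict(out$trials[[pr]], out$cats[[other]],
                                    out$pds[[other]])
    tr1 <- out$trials[[pr]]$trials[[1]]
    ids <- c(tr1$train_ids, tr1$test_ids)
    X <- fingerprintMatrix(out$cats[[pr]], tr1$vocab, ids)
    out$expl[[pr]] <- explainCompounds(tr1$ensemble, X)
    out$prior[[pr]] <- extractPrioritized(out$expl[[pr]], out$labels[[pr]],
                                          N = 5, M = 10)
  }
  out
})

# motif-bearing DT compounds of a pair that trial 1 predicted correctly
correct_carriers <- function(run, pr) {
  cp <- compoundTable(run$lib)
  es <- run$expl[[pr]]
  ids <- explainedIds(es)
  correct <- (predictions(es) >= 0.5) == run$labels[[pr]][ids]
  carriers <- cp$id[cp$id %in% ids & cp$motif & cp$intended_role == "DT"]
  carriers[correct[match(carriers, ids)]]
}
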