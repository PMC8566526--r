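## Synthetic bioactivity generator: molecule libraries and raw activity
## tables with the statistical structure the downstream analysis assumes --
## two target pairs sharing one pseudo-target, severe DT/ST class imbalance,
## pair-specific planted structural motifs, decoy scaffolds, and records that
## deliberately violate each curation rule.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## deterministic child seeds below 2^31
.child_seed <- function(seed, k) (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647

#' Configuration of the synthetic study system
#'
#' Defines the planted motifs, class sizes, planting and contamination rates
#' and decoy chemistry of the synthetic two-target-pair system. Defaults
#' emulate the shape of a curated ChEMBL extract for two pairs sharing one
#' target: ~60 dual-target (DT) compounds per pair against thousands of
#' single-target (ST) compounds, with the pair motif present in half of the
#' DT compounds and ~2% of ST compounds.
#'
#' @param seed integer seed controlling the whole library.
#' @param motif_smiles_pair1 primary planted motif of pair 1 (default a
#'   caffeine xanthine scaffold).
#' @param motif_smiles_pair2 primary planted motif of pair 2 (default a
#'   2H-chromen-2-one / coumarin scaffold).
#' @param n_dt_per_pair number of DT compounds per pair.
#' @param n_st_per_target number of ST compounds per target within each pair.
#' @param motif_planting_rate fraction of DT compounds carrying the pair
#'   motif; the rest carry the pair's secondary motif.
#' @param st_contamination_rate fraction of ST compounds built like motif
#'   carriers (emulating untested dual-actives in the data).
#' @param decoy_scaffold_count number of decoy ring scaffolds to draw from.
#' @param dirty_record_fraction fraction of activity rows mutated to violate
#'   exactly one curation rule each.
#' @param purine_decoy_rate fraction of ST decoys built on the purine ring,
#'   placing a caffeine-related ring in unrelated structural contexts.
#' @return a `SyntheticConfig` object.
#' @export
syntheticConfig <- function(seed = 1L,
                            motif_smiles_pair1 = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
                            motif_smiles_pair2 = "O=c1ccc2ccccc2o1",
                            n_dt_per_pair = 60L,
                            n_st_per_target = 1500L,
                            motif_planting_rate = 0.5,
                            st_contamination_rate = 0.02,
                            decoy_scaffold_count = 24L,
                            dirty_record_fraction = 0.03,
                            purine_decoy_rate = 0.16) {
  cfg <- new("SyntheticConfig",
             seed = as.integer(seed),
             motif_smiles_pair1 = motif_smiles_pair1,
             motif_smiles_pair2 = motif_smiles_pair2,
             n_dt_per_pair = as.integer(n_dt_per_pair),
             n_st_per_target = as.integer(n_st_per_target),
             motif_planting_rate = motif_planting_rate,
             st_contamination_rate = st_contamination_rate,
             decoy_scaffold_count = as.integer(decoy_scaffold_count),
             dirty_record_fraction = dirty_record_fraction,
             purine_decoy_rate = purine_decoy_rate)
  validObject(cfg)
  cfg
}

#' @rdname syntheticConfig
#' @export
setClass("SyntheticConfig",
  representation(seed = "integer", motif_smiles_pair1 = "character",
                 motif_smiles_pair2 = "character", n_dt_per_pair = "integer",
                 n_st_per_target = "integer", motif_planting_rate = "numeric",
                 st_contamination_rate = "numeric",
                 decoy_scaffold_count = "integer",
                 dirty_record_fraction = "numeric",
                 purine_decoy_rate = "numeric"),
  validity = function(object) {
    rates <- c(object@motif_planting_rate, object@st_contamination_rate,
               object@dirty_record_fraction, object@purine_decoy_rate)
    if (any(rates < 0 | rates > 1)) return("all rates must be in [0, 1]")
    if (object@n_dt_per_pair < 2) return("need at least 2 DT compounds")
    if (object@n_dt_per_pair >= object@n_st_per_target)
      return("class imbalance required: n_dt_per_pair << n_st_per_target")
    ok1 <- tryCatch({parseSmiles(object@motif_smiles_pair1); TRUE},
                    error = function(e) FALSE)
    ok2 <- tryCatch({parseSmiles(object@motif_smiles_pair2); TRUE},
                    error = function(e) FALSE)
    if (!ok1 || !ok2) return("motif SMILES do not parse")
    TRUE
  })

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: seed", object@seed, "\n",
      " DT per pair:", object@n_dt_per_pair,
      "| ST per target:", object@n_st_per_target, "\n",
      " planting", object@motif_planting_rate,
      "| contamination", object@st_contamination_rate,
      "| dirty", object@dirty_record_fraction, "\n")
})

#' Synthetic compound library with ground truth
#'
#' @slot compounds data.frame: `id`, `smiles`, `pair_id`, `intended_role`
#'   (DT / ST_A / ST_B), `final_role` (role after dirty-record injection:
#'   compounds losing a record to a curation trap become `excluded`),
#'   `motif` (carries the pair's primary motif), `construction`
#'   (primary / secondary / decoy).
#' @slot activity data.frame of raw activity records (see
#'   [filterRecords()] for the schema).
#' @slot dirty data.frame sidecar: `row` (index into `activity`) and `rule`
#'   violated by that record.
#' @slot mols named list of parsed [MolGraph-class] objects.
#' @slot config the generating [syntheticConfig()].
#' @export
setClass("SyntheticLibrary",
  representation(compounds = "data.frame", activity = "data.frame",
                 dirty = "data.frame", mols = "list", config = "SyntheticConfig"))

setMethod("show", "SyntheticLibrary", function(object) {
  cat("SyntheticLibrary:", nrow(object@compounds), "compounds,",
      nrow(object@activity), "activity records (",
      nrow(object@dirty), "dirty )\n")
  print(table(object@compounds$pair_id, object@compounds$final_role))
})

#' @describeIn SyntheticLibrary compound table accessor
#' @param x a `SyntheticLibrary`
#' @export
compoundTable <- function(x) x@compounds

#' @describeIn SyntheticLibrary activity table accessor
#' @export
activityTable <- function(x) x@activity

#' @describeIn SyntheticLibrary parsed molecule accessor
#' @export
libraryMols <- function(x) x@mols

## ---- SMILES assembly ------------------------------------------------------

## Character spans of atom tokens (including trailing ring-closure digits) in
## a restricted SMILES grammar: organic-subset atoms, brackets, branches,
## ring closures. Enough for the generator's own scaffold strings.
.smiles_atom_spans <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  spans <- list()
  i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1
      start <- i; i <- j + 1
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1] %in% c("l", "r")) {
      start <- i; i <- i + 2
    } else if (grepl("[A-Za-z]", ch)) {
      start <- i; i <- i + 1
    } else {
      i <- i + 1
      next
    }
    ## ring-closure digits stick to the atom token
    while (i <= n && grepl("[0-9]", chars[i])) i <- i + 1
    spans[[length(spans) + 1]] <- c(start = start, end = i - 1)
  }
  do.call(rbind, spans)
}

## Insert "(frag)" branches after the given atom indices (1-based, SMILES
## appearance order). Processing right-to-left keeps positions valid.
.attach_branches <- function(smiles, sites, frags) {
  spans <- .smiles_atom_spans(smiles)
  ord <- order(sites, decreasing = TRUE)
  out <- smiles
  for (k in ord) {
    pos <- spans[sites[k], "end"]
    out <- paste0(substr(out, 1, pos), "(", frags[k], ")",
                  substring(out, pos + 1))
  }
  out
}

## sites eligible for decoration: ring atoms bearing >= 1 hydrogen, written
## as plain (non-bracket) atom tokens
.decoration_sites <- function(mol, ring_only = TRUE) {
  a <- mol@atoms
  spans <- .smiles_atom_spans(mol@smiles)
  plain <- substring(mol@smiles, spans[, "start"], spans[, "start"]) != "["
  ok <- a$hcount >= 1 & plain
  if (ring_only && any(a$ring)) ok <- ok & a$ring
  which(ok)
}

#' Assemble a decorated compound from a scaffold
#'
#' Attaches fragment SMILES as single-bond branches at randomly chosen
#' hydrogen-bearing ring atoms of the scaffold, and returns the canonical
#' SMILES of the product. With no decorations, the canonical form of the
#' scaffold itself is returned; a scaffold without any attachment point is
#' returned unchanged with a warning.
#'
#' @param scaffold scaffold SMILES.
#' @param decorations character vector of fragment SMILES (possibly empty).
#' @param seed integer seed for site selection.
#' @return a single canonical SMILES string containing the scaffold as a
#'   substructure.
#' @export
assembleCompound <- function(scaffold, decorations, seed = 1L) {
  mol <- parseSmiles(scaffold)[[1]]
  if (length(decorations) == 0) return(canonicalSmiles(scaffold))
  sites <- .decoration_sites(mol)
  if (length(sites) == 0) {
    warning("scaffold has no attachment point; returned unchanged")
    return(scaffold)
  }
  out <- .with_seed(seed, {
    k <- min(length(decorations), length(sites))
    picked <- sites[sample.int(length(sites), k)]
    .attach_branches(scaffold, picked, decorations[seq_len(k)])
  })
  canonicalSmiles(out)
}

.decoy_scaffolds <- c(
  "c1ccccc1",          # benzene
  "c1ccncc1",          # pyridine
  "c1cncnc1",          # pyrimidine
  "C1CCNCC1",          # piperidine
  "C1CNCCN1",          # piperazine
  "C1COCCN1",          # morpholine
  "C1CCCCC1",          # cyclohexane
  "c1ccoc1",           # furan
  "c1ccsc1",           # thiophene
  "c1cc[nH]c1",        # pyrrole
  "c1c[nH]cn1",        # imidazole
  "c1ccc2[nH]ccc2c1",  # indole
  "c1ccc2ccccc2c1",    # naphthalene
  "c1ccc2ncccc2c1",    # quinoline
  "C1CCOC1",           # tetrahydrofuran
  "c1cc[nH]n1",        # pyrazole
  "c1cnco1",           # oxazole
  "c1ccc2[nH]cnc2c1",  # benzimidazole
  "C1CCNC1",           # pyrrolidine
  "c1cnsc1",           # isothiazole
  "O=C1CCCCC1",        # cyclohexanone
  "O=C1CCCN1",         # 2-pyrrolidinone
  "O=C1CCCO1",         # gamma-butyrolactone
  "O=C1C=CC=CN1"       # 2-pyridone
)

.purine_scaffold <- "c1ncc2[nH]cnc2n1"

.fragments <- c("C", "CC", "CCC", "O", "OC", "CO", "N", "F", "Cl",
                "C#N", "C(F)(F)F", "OCC", "C(=O)C", "C(=O)OC",
                "c3ccccc3", "Cc3ccccc3")

## variable aliphatic tails attached directly at the motif's fixed ring
## position: a chain head, optionally capped, built by linear concatenation
.tail_heads <- c("C", "CC", "CCC", "OC", "CO", "OCC", "COC")
.tail_caps <- c("C", "F", "Cl", "O", "C#N")

.sample_tail <- function() {
  head <- .tail_heads[sample.int(length(.tail_heads), 1)]
  if (stats::runif(1) < 0.5)
    paste0(head, .tail_caps[sample.int(length(.tail_caps), 1)])
  else head
}

## secondary motifs: pair-specific scaffolds carried by DT compounds that do
## not carry the primary motif (benzothiazinone / cinnamamide)
.secondary_motifs <- c(pair1 = "O=C1CSc2ccccc2N1",
                       pair2 = "O=C(Nc1ccccc1)C=Cc1ccccc1")

## linker site on a motif: first ring carbon bearing a hydrogen
.linker_site <- function(mol) {
  a <- mol@atoms
  cand <- which(a$ring & a$hcount >= 1 & a$element == "C")
  if (length(cand) == 0) cand <- which(a$hcount >= 1)
  cand[1]
}

## carrier construction: motif + variable aliphatic tail at a fixed ring
## position; every environment centred more than two bonds from the
## attachment atom is identical across carriers, so the motif's interior
## environments form a stable, class-specific feature block
.make_carrier <- function(motif_smiles, site, tail) {
  .attach_branches(motif_smiles, site, tail)
}

.make_decoy <- function(scaffold_mol, n_dec, frags) {
  sites <- .decoration_sites(scaffold_mol)
  if (length(sites) == 0) return(scaffold_mol@smiles)
  n_dec <- min(n_dec, length(sites))
  picked <- sites[sample.int(length(sites), n_dec)]
  .attach_branches(scaffold_mol@smiles,
                   picked, sample(frags, n_dec, replace = TRUE))
}

## ---- dirty records --------------------------------------------------------

.dirty_rules <- c("mw", "relation", "flag", "potency", "confidence",
                  "relationship")

.apply_dirty_rule <- function(row, rule) {
  switch(rule,
    mw = { row$mw <- 1200 },
    relation = { row$standard_relation <- ">" },
    flag = { row$activity_flag <- sample(
      c("inactive", "not active", "inconclusive"), 1) },
    potency = { row$standard_value_nM <- 20000 },
    confidence = { row$target_confidence <- 8L },
    relationship = { row$relationship_type <- "H" })
  row
}

#' Inject curation-rule violations into an activity table
#'
#' Mutates the requested fraction of rows so that each violates exactly one
#' curation rule (molecular weight >= 1000 Da, non-exact relation, inactivity
#' flag, potency worse than 10 uM, confidence below 9, indirect target
#' relationship), cycling uniformly over the six rule types. The mutated row
#' indices and their rules are returned as a ground-truth sidecar.
#'
#' @param table activity-record data.frame (see [filterRecords()] schema).
#' @param fraction fraction of rows to dirty, in `[0, 1]`.
#' @param seed integer seed.
#' @return `list(table =, sidecar =)` where `sidecar` has columns `row` and
#'   `rule`; with `fraction = 0` the table is returned unchanged.
#' @export
injectDirtyRecords <- function(table, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_bad <- round(nrow(table) * fraction)
  if (n_bad == 0)
    return(list(table = table,
                sidecar = data.frame(row = integer(0), rule = character(0))))
  .with_seed(seed, {
    rows <- sample(nrow(table), n_bad)
    rules <- rep_len(.dirty_rules, n_bad)[sample(n_bad)]
    for (k in seq_len(n_bad))
      table[rows[k], ] <- .apply_dirty_rule(table[rows[k], ], rules[k])
    list(table = table, sidecar = data.frame(row = rows, rule = rules))
  })
}

## ---- library generation ---------------------------------------------------

.target_ids <- list(pair1 = c("T_MAOB", "T_A2AR"),
                    pair2 = c("T_MAOB", "T_ACHE"))

#' Generate a synthetic two-pair compound library and activity table
#'
#' Builds, for each of two target pairs sharing one pseudo-target, a small
#' dual-target (DT) class and a large single-target (ST) class. DT compounds
#' carry the pair's primary planted motif at the configured planting rate and
#' a pair-specific secondary motif otherwise; ST compounds are decorated
#' decoy ring systems, a configured fraction of which are built like motif
#' carriers (contamination emulating untested dual-actives). Activity rows
#' use exact Ki/IC50/Kd values between 1 nM and 5 uM so that every clean row
#' survives curation; a configured fraction of rows is then mutated to
#' violate one curation rule each ([injectDirtyRecords()]).
#'
#' @param config a [syntheticConfig()].
#' @return a [SyntheticLibrary-class]; `final_role` in its compound table is
#'   the ground-truth class after the dirty rows are taken into account.
#' @export
generateLibrary <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  n_dt <- config@n_dt_per_pair
  n_st <- config@n_st_per_target
  scaffs <- .decoy_scaffolds[seq_len(min(config@decoy_scaffold_count,
                                         length(.decoy_scaffolds)))]
  scaff_mols <- parseSmiles(c(scaffs, .purine_scaffold),
                            ids = paste0("scf", seq_len(length(scaffs) + 1)))
  motifs <- list(pair1 = config@motif_smiles_pair1,
                 pair2 = config@motif_smiles_pair2)
  motif_mols <- parseSmiles(unlist(motifs), ids = c("m1", "m2"))
  second_mols <- parseSmiles(.secondary_motifs, ids = c("s1", "s2"))
  sites <- list(pair1 = .linker_site(motif_mols$m1),
                pair2 = .linker_site(motif_mols$m2))
  sec_sites <- list(pair1 = .linker_site(second_mols$s1),
                    pair2 = .linker_site(second_mols$s2))

  build_pair <- function(pair) {
    ip <- if (pair == "pair1") 1L else 2L
    motif <- motifs[[pair]]
    secondary <- unname(.secondary_motifs[pair])
    rate <- config@motif_planting_rate
    carrier <- if (rate > 0 && rate * n_dt < 1) {
      warning("motif_planting_rate x n_dt_per_pair < 1; zero motif carriers")
      rep(FALSE, n_dt)
    } else stats::runif(n_dt) < rate
    dt <- data.frame(
      id = sprintf("P%d_DT_%04d", ip, seq_len(n_dt)),
      smiles = vapply(seq_len(n_dt), function(i) {
        if (carrier[i])
          .make_carrier(motif, sites[[pair]], .sample_tail())
        else
          .make_carrier(secondary, sec_sites[[pair]], .sample_tail())
      }, character(1)),
      pair_id = pair, intended_role = "DT",
      motif = carrier,
      construction = ifelse(carrier, "primary", "secondary"),
      stringsAsFactors = FALSE)
    st_one <- function(tag, n) {
      contam <- stats::runif(n) < config@st_contamination_rate
      data.frame(
        id = sprintf("P%d_ST%s_%04d", ip, tag, seq_len(n)),
        smiles = vapply(seq_len(n), function(i) {
          if (contam[i])
            .make_carrier(motif, sites[[pair]], .sample_tail())
          else {
            use_purine <- stats::runif(1) < config@purine_decoy_rate
            scf <- if (use_purine) scaff_mols[[length(scaff_mols)]]
                   else scaff_mols[[sample(length(scaffs), 1)]]
            .make_decoy(scf, sample(1:3, 1), .fragments)
          }
        }, character(1)),
        pair_id = pair, intended_role = paste0("ST_", tag),
        motif = contam,
        construction = ifelse(contam, "primary", "decoy"),
        stringsAsFactors = FALSE)
    }
    rbind(dt, st_one("A", n_st), st_one("B", n_st))
  }

  .with_seed(config@seed, {
    compounds <- rbind(build_pair("pair1"), build_pair("pair2"))
    mols <- parseSmiles(compounds$smiles, ids = compounds$id)
    mw <- vapply(mols, function(m) m@mw, numeric(1))

    ## activity rows: DT -> both targets, ST_A/ST_B -> one target
    act <- do.call(rbind, lapply(seq_len(nrow(compounds)), function(i) {
      cp <- compounds[i, ]
      tg <- .target_ids[[cp$pair_id]]
      targets <- switch(cp$intended_role, DT = tg, ST_A = tg[1], ST_B = tg[2])
      data.frame(
        compound_id = cp$id, smiles = cp$smiles, target_id = targets,
        standard_type = sample(c("Ki", "IC50", "Kd"), length(targets),
                               replace = TRUE),
        standard_relation = "=",
        standard_value_nM = 10^stats::runif(length(targets), 0, log10(5000)),
        activity_flag = "", target_confidence = 9L, relationship_type = "D",
        organism = "Homo sapiens", mw = unname(mw[cp$id]),
        stringsAsFactors = FALSE)
    }))
    rownames(act) <- NULL
    dirty <- injectDirtyRecords(act, config@dirty_record_fraction,
                                seed = .child_seed(config@seed, 1))
    act <- dirty$table

    ## ground-truth roles after dirty injection
    clean <- rep(TRUE, nrow(act)); clean[dirty$sidecar$row] <- FALSE
    clean_by_cpd <- tapply(clean, act$compound_id, all)
    n_rows <- table(act$compound_id)
    compounds$final_role <- as.character(ifelse(
      clean_by_cpd[compounds$id], compounds$intended_role, "excluded"))
    ## an ST compound whose single row is dirty vanishes from curated data
    compounds$final_role[!clean_by_cpd[compounds$id] &
                         n_rows[compounds$id] == 1] <- "dropped"
    new("SyntheticLibrary", compounds = compounds, activity = act,
        dirty = dirty$sidecar, mols = mols, config = config)
  })
}

#' Write a synthetic library to disk
#'
#' Writes compounds as a `.smi` file (SMILES TAB id), the raw activity table
#' as CSV, and the ground truth (compound roles and dirty-record sidecar) as
#' JSON.
#'
#' @param lib a [SyntheticLibrary-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeLibrary <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smi <- file.path(dir, "compounds.smi")
  writeLines(paste(lib@compounds$smiles, lib@compounds$id, sep = "\t"), smi)
  act <- file.path(dir, "activity.csv")
  utils::write.csv(lib@activity, act, row.names = FALSE)
  truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(compounds = lib@compounds, dirty = lib@dirty),
                       truth, dataframe = "rows", auto_unbox = TRUE)
  invisible(c(smi = smi, activity = act, truth = truth))
}
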