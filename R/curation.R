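## ChEMBL-style curation: row-level quality filters, potency transformation,
## assay-interference removal, and per-pair DT/ST class assignment.

.required_cols <- c("compound_id", "smiles", "target_id", "standard_type",
                    "standard_relation", "standard_value_nM", "activity_flag",
                    "target_confidence", "relationship_type", "organism", "mw")

.bad_flags <- c("inactive", "not active", "inconclusive",
                "potential transcription error")

#' Negative decadic logarithm of a molar potency
#'
#' Converts a potency in nM to its negative decadic logarithm on the molar
#' scale, so 100 nM becomes 7.0 and the 10 uM activity threshold becomes 5.0.
#'
#' @param value_nM potency value(s) in nM; must be positive.
#' @return numeric p-potency value(s).
#' @export
toPPotency <- function(value_nM) {
  if (any(!is.finite(value_nM)) || any(value_nM <= 0))
    stop("potency values must be positive and finite")
  -log10(value_nM * 1e-9)
}

#' Default assay-interference pattern catalog
#'
#' Reads the SMARTS catalog of reactive / assay-interfering substructure
#' classes shipped with the package (quinones, rhodanines, azo compounds and
#' related chemotypes). The catalog is a plain two-column TSV (`name`,
#' `smarts`) and can be replaced by any user catalog of the same shape.
#'
#' @return data.frame with columns `name` and `smarts`.
#' @export
defaultInterferenceCatalog <- function() {
  path <- system.file("extdata", "interference_smarts.tsv", package = "ShapSig")
  utils::read.csv(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Flag potential assay-interference compounds
#'
#' Matches molecules against a pluggable SMARTS catalog (OpenBabel SMARTS
#' semantics via ChemmineOB). Unparseable SMILES are skipped with a warning
#' and flagged `NA`.
#'
#' @param smiles character vector of SMILES.
#' @param catalog data.frame with a `smarts` column; defaults to the shipped
#'   catalog. An empty catalog flags nothing.
#' @return logical vector: `TRUE` where any pattern matches.
#' @export
flagInterference <- function(smiles, catalog = defaultInterferenceCatalog()) {
  stopifnot(is.character(smiles))
  out <- rep(FALSE, length(smiles))
  if (length(smiles) == 0 || nrow(catalog) == 0) return(out)
  parseable <- vapply(seq_along(smiles), function(i) {
    !is.null(tryCatch(suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(smiles[i], "x"))),
      error = function(e) NULL))
  }, logical(1))
  if (any(!parseable)) {
    warning(sum(!parseable), " unparseable SMILES skipped by interference filter")
    out[!parseable] <- NA
  }
  idx <- which(parseable)
  if (length(idx)) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(smiles[idx], paste0("m", idx))))
    ## single-heavy-atom molecules carry a reduced atom block that the
    ## OpenBabel SMARTS bridge cannot digest; they cannot match any
    ## multi-atom pattern, so search the others only
    searchable <- vapply(seq_along(sdf), function(i) {
      ab <- ChemmineR::atomblock(sdf[[i]])
      !is.null(dim(ab)) && ncol(ab) >= 3
    }, logical(1))
    hit <- rep(FALSE, length(idx))
    if (any(searchable)) {
      for (p in catalog$smarts) {
        counts <- tryCatch(
          suppressWarnings(ChemmineR::smartsSearchOB(sdf[searchable], p,
                                                     uniqueMatches = TRUE)),
          error = function(e) stop("invalid SMARTS pattern: ", p))
        hit[searchable] <- hit[searchable] | counts > 0
      }
    }
    out[idx] <- hit
  }
  out
}

#' Apply curation rules to a raw activity table
#'
#' Retains only records that satisfy every curation rule: molecular weight
#' below 1000 Da, direct target relationship ("D"), human organism, target
#' confidence 9, standard type Ki/IC50/Kd with exact ("=") relation, no
#' inactivity flag, and potency of at least 10 uM (p-potency >= 5.0) after
#' averaging multiple measurements per compound-target; compounds matching
#' the assay-interference catalog are removed entirely. Drop counts per rule
#' are reported in the `"drop_log"` attribute.
#'
#' @param table raw activity data.frame (schema of [generateLibrary()]
#'   activity tables: `compound_id`, `smiles`, `target_id`, `standard_type`,
#'   `standard_relation`, `standard_value_nM`, `activity_flag`,
#'   `target_confidence`, `relationship_type`, `organism`, `mw`).
#' @param organism organism label required (string match).
#' @param interference_catalog SMARTS catalog passed to [flagInterference()];
#'   `NULL` disables interference filtering.
#' @return data.frame of curated activities (`compound_id`, `target_id`,
#'   `p_potency`, `smiles`), one row per compound-target, with attributes
#'   `"drop_log"` (named integer vector of per-rule drop counts) and
#'   `"straddle"` (compound-target keys whose measurements straddled the
#'   potency threshold before averaging).
#' @export
filterRecords <- function(table, organism = "Homo sapiens",
                          interference_catalog = defaultInterferenceCatalog()) {
  stopifnot(nrow(table) > 0)
  missing_cols <- setdiff(.required_cols, colnames(table))
  if (length(missing_cols))
    stop("activity table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  log <- c()
  keep <- rep(TRUE, nrow(table))
  apply_rule <- function(name, ok) {
    log[[name]] <<- sum(keep & !ok)
    keep <<- keep & ok
  }
  apply_rule("mw_ge_1000", table$mw < 1000)
  apply_rule("relationship_not_D", table$relationship_type == "D")
  apply_rule("organism", table$organism == organism)
  apply_rule("confidence_lt_9", table$target_confidence == 9)
  apply_rule("type", table$standard_type %in% c("Ki", "IC50", "Kd"))
  apply_rule("relation_not_exact", table$standard_relation == "=")
  apply_rule("flagged", !(tolower(table$activity_flag) %in% .bad_flags))
  apply_rule("value_missing", is.finite(table$standard_value_nM) &
                              table$standard_value_nM > 0)
  surv <- table[keep, , drop = FALSE]

  ## aggregate multiple measurements per compound-target by mean p-potency
  straddle <- character(0)
  if (nrow(surv) > 0) {
    p <- toPPotency(surv$standard_value_nM)
    key <- paste(surv$compound_id, surv$target_id, sep = "\r")
    agg <- tapply(p, key, mean)
    rng <- tapply(p, key, function(v) diff(range(v)) > 0 &&
                    min(v) < 5 && max(v) >= 5)
    straddle <- names(rng)[rng]
    if (length(straddle))
      message(length(straddle),
              " compound-target pairs straddle the 10 uM threshold; mean used")
    first <- !duplicated(key)
    out <- data.frame(compound_id = surv$compound_id[first],
                      target_id = surv$target_id[first],
                      p_potency = unname(agg[key[first]]),
                      smiles = surv$smiles[first],
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(compound_id = character(0), target_id = character(0),
                      p_potency = numeric(0), smiles = character(0))
  }
  weak <- out$p_potency < 5.0
  log[["potency_below_10uM"]] <- sum(weak)
  out <- out[!weak, , drop = FALSE]

  if (!is.null(interference_catalog) && nrow(out) > 0) {
    cpd <- !duplicated(out$compound_id)
    bad <- flagInterference(out$smiles[cpd], interference_catalog)
    bad_ids <- out$compound_id[cpd][which(bad)]
    log[["interference"]] <- sum(out$compound_id %in% bad_ids)
    out <- out[!out$compound_id %in% bad_ids, , drop = FALSE]
  } else {
    log[["interference"]] <- 0L
  }
  rownames(out) <- NULL
  attr(out, "drop_log") <- unlist(log)
  attr(out, "straddle") <- sub("\r", ":", straddle)
  out
}

#' Paired DT/ST compound dataset
#'
#' Compounds of one target pair partitioned into dual-target (curated
#' activity against both targets), single-target (curated activity against
#' exactly one target and no recorded activity of any quality against the
#' partner), and excluded compounds (activity against one target plus a
#' non-surviving record against the partner).
#'
#' @slot pair_id character(2): the two target identifiers.
#' @slot compounds data.frame: `id`, `smiles`, `label` (DT/ST), `target_id`
#'   (NA for DT, the single active target for ST).
#' @slot excluded character vector of excluded compound ids.
#' @export
setClass("PairDataset",
  representation(pair_id = "character", compounds = "data.frame",
                 excluded = "character"),
  validity = function(object) {
    if (length(object@pair_id) != 2) return("pair_id must name two targets")
    if (anyDuplicated(object@compounds$id)) return("duplicated compound ids")
    if (!all(object@compounds$label %in% c("DT", "ST")))
      return("labels must be DT or ST")
    TRUE
  })

setMethod("show", "PairDataset", function(object) {
  tab <- table(object@compounds$label)
  cat("PairDataset", paste(object@pair_id, collapse = " / "), ":",
      tab["DT"], "DT,", tab["ST"], "ST,",
      length(object@excluded), "excluded\n")
})

#' @describeIn PairDataset data.frame of compounds with DT/ST labels
#' @param x a `PairDataset`
#' @export
pairCompounds <- function(x) x@compounds

#' @describeIn PairDataset logical DT indicator named by compound id
#' @export
pairLabels <- function(x) {
  stats::setNames(x@compounds$label == "DT", x@compounds$id)
}

#' Assign DT/ST classes for a target pair
#'
#' DT compounds have curated activity against both targets of the pair. ST
#' compounds have curated activity against exactly one target and no
#' recorded activity of any quality against the partner; compounds with a
#' sub-threshold or otherwise non-surviving record against the partner are
#' excluded rather than demoted to ST.
#'
#' @param curated output of [filterRecords()].
#' @param pair character(2) of target ids.
#' @param raw_table optional raw activity table; partner-activity evidence at
#'   any quality level is taken from it (defaults to the curated table only).
#' @param related_targets optional further target ids whose recorded
#'   activity also disqualifies a compound from the ST class.
#' @return a [PairDataset-class].
#' @export
assignClasses <- function(curated, pair, raw_table = NULL,
                          related_targets = NULL) {
  stopifnot(length(pair) == 2)
  cur <- curated[curated$target_id %in% pair, , drop = FALSE]
  ## recorded (any-quality) activity per compound x target
  rec <- curated[, c("compound_id", "target_id")]
  if (!is.null(raw_table))
    rec <- rbind(rec, raw_table[, c("compound_id", "target_id")])
  disqualify <- c(pair, related_targets)
  cur_a <- unique(cur$compound_id[cur$target_id == pair[1]])
  cur_b <- unique(cur$compound_id[cur$target_id == pair[2]])
  dt <- intersect(cur_a, cur_b)
  if (length(dt) == 0)
    warning("no DT compounds for pair ", paste(pair, collapse = "/"))
  rec_by_target <- lapply(stats::setNames(disqualify, disqualify),
                          function(t) unique(rec$compound_id[rec$target_id == t]))
  st_of <- function(own, partner_targets) {
    cand <- setdiff(own, dt)
    evid <- unique(unlist(rec_by_target[partner_targets]))
    list(st = setdiff(cand, evid), excluded = intersect(cand, evid))
  }
  a <- st_of(cur_a, setdiff(disqualify, pair[1]))
  b <- st_of(cur_b, setdiff(disqualify, pair[2]))
  smiles_of <- cur$smiles[match(c(dt, a$st, b$st), cur$compound_id)]
  compounds <- data.frame(
    id = c(dt, a$st, b$st),
    smiles = smiles_of,
    label = c(rep("DT", length(dt)), rep("ST", length(a$st) + length(b$st))),
    target_id = c(rep(NA_character_, length(dt)),
                  rep(pair[1], length(a$st)), rep(pair[2], length(b$st))),
    stringsAsFactors = FALSE)
  new("PairDataset", pair_id = pair, compounds = compounds,
      excluded = unique(c(a$excluded, b$excluded)))
}
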