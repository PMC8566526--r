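## Layered circular atom environments (Morgan, bond radius <= 2), encoded as
## canonical signature strings and mapped to unique vector positions so that
## distinct environments can never share a position (no bit collisions).

#' Feature vocabulary
#'
#' Bijective map between canonical atom-environment identifiers and vector
#' positions. Identifiers are canonical signature strings of layered circular
#' atom environments; positions are `1..size` in lexicographic identifier
#' order, which makes vocabularies reproducible regardless of compound order.
#'
#' @slot ids character vector of environment identifiers, sorted; position of
#'   an identifier is its index in this vector.
#' @export
setClass("FeatureVocabulary", representation(ids = "character"),
  validity = function(object) {
    if (anyDuplicated(object@ids)) return("duplicated environment identifiers")
    if (is.unsorted(object@ids)) return("identifiers must be sorted")
    TRUE
  })

setMethod("show", "FeatureVocabulary", function(object) {
  cat("FeatureVocabulary with", length(object@ids), "atom environments\n")
})

#' @describeIn FeatureVocabulary number of environments
#' @param x a `FeatureVocabulary`
#' @export
vocabularySize <- function(x) length(x@ids)

#' @describeIn FeatureVocabulary identifier of given positions
#' @param positions integer vector of vector positions
#' @export
featureIds <- function(x, positions = seq_along(x@ids)) x@ids[positions]

#' @describeIn FeatureVocabulary positions of given identifiers (NA if unseen)
#' @param ids character vector of environment identifiers
#' @export
featurePositions <- function(x, ids) match(ids, x@ids)

## Radius-0 atom invariant: element, heavy-atom degree, implicit hydrogen
## count, formal charge, ring membership (the standard Morgan atom
## invariants; bond orders enter at radius >= 1 through the bond codes).
.atom_invariants <- function(mol) {
  n <- numAtoms(mol)
  deg <- integer(n)
  b <- mol@bonds
  if (nrow(b) > 0) deg <- tabulate(c(b$from, b$to), nbins = n)
  paste0("(", mol@atoms$element, ";", deg, ";", mol@atoms$hcount, ";",
         mol@atoms$charge, ";", as.integer(mol@atoms$ring), ")")
}

.bond_code <- function(order) {
  code <- as.character(order)
  code[order == 1.5] <- "a"
  code
}

#' Enumerate layered circular atom environments
#'
#' Computes, for every atom and every radius `0..max_radius`, a canonical
#' environment identifier built by iterated neighborhood signatures (sorted
#' over neighbors, hence independent of atom numbering), together with the
#' set of atoms and bonds the environment covers. Environments with an
#' identical atom/bond cover within the molecule are collapsed to a single
#' feature (the lexicographically smallest identifier is kept), matching the
#' usual circular-fingerprint deduplication.
#'
#' @param mol a [MolGraph-class] or a SMILES string.
#' @param max_radius maximum bond radius (default 2).
#' @return a list with elements
#'   \describe{
#'     \item{ids}{character vector of unique environment identifiers}
#'     \item{occurrences}{named list (by identifier) of occurrence lists;
#'       each occurrence has integer vectors `atoms` and `bonds`}
#'     \item{table}{data.frame with one row per (center, radius) environment
#'       before collapsing: `center`, `radius`, `env_id`}
#'   }
#' @export
enumerateEnvironments <- function(mol, max_radius = 2) {
  if (is.character(mol)) mol <- parseSmiles(mol)[[1]]
  stopifnot(is(mol, "MolGraph"), max_radius >= 0)
  n <- numAtoms(mol)
  b <- mol@bonds
  nb <- vector("list", n)       # neighbor atom / bond-row indices
  nbbond <- vector("list", n)
  if (nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      nb[[b$from[k]]] <- c(nb[[b$from[k]]], b$to[k])
      nb[[b$to[k]]] <- c(nb[[b$to[k]]], b$from[k])
      nbbond[[b$from[k]]] <- c(nbbond[[b$from[k]]], k)
      nbbond[[b$to[k]]] <- c(nbbond[[b$to[k]]], k)
    }
  }
  bcode <- .bond_code(b$order)
  ## iterated signatures
  h <- .atom_invariants(mol)
  sigs <- list(h)
  r <- 0
  while (r < max_radius) {
    h2 <- vapply(seq_len(n), function(i) {
      if (length(nb[[i]]) == 0) return(sigs[[r + 1]][i])
      parts <- paste0(bcode[nbbond[[i]]], sigs[[r + 1]][nb[[i]]])
      paste0(sigs[[r + 1]][i], "[", paste(sort(parts), collapse = ","), "]")
    }, character(1))
    sigs[[r + 2]] <- h2
    r <- r + 1
  }
  ## covers via BFS distances
  dist_from <- function(center) {
    d <- rep(NA_integer_, n)
    d[center] <- 0L
    frontier <- center
    depth <- 0L
    while (length(frontier) && depth < max_radius) {
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[is.na(d[nxt])]
      d[nxt] <- depth + 1L
      frontier <- nxt
      depth <- depth + 1L
    }
    d
  }
  centers <- integer(0); radii <- integer(0); env_ids <- character(0)
  covers <- list()
  for (i in seq_len(n)) {
    d <- dist_from(i)
    for (rr in 0:max_radius) {
      atoms <- which(!is.na(d) & d <= rr)
      if (rr == 0) {
        bonds <- integer(0)
      } else {
        du <- d[b$from]; dv <- d[b$to]
        bonds <- which(!is.na(du) & !is.na(dv) &
                       pmin(du, dv) <= rr - 1L & pmax(du, dv) <= rr)
      }
      centers <- c(centers, i); radii <- c(radii, rr)
      env_ids <- c(env_ids, paste0("r", rr, ":", sigs[[rr + 1]][i]))
      covers[[length(covers) + 1]] <- list(atoms = sort(atoms),
                                           bonds = sort(bonds))
    }
  }
  tab <- data.frame(center = centers, radius = radii, env_id = env_ids,
                    stringsAsFactors = FALSE)
  ## collapse identical covers to one feature (lexicographically smallest id)
  cover_key <- vapply(covers, function(cv)
    paste(paste(cv$atoms, collapse = ","), paste(cv$bonds, collapse = ","),
          sep = "|"), character(1))
  canon <- vapply(split(env_ids, cover_key), min, character(1))
  final_id <- unname(canon[cover_key])
  occurrences <- list()
  ids <- sort(unique(final_id))
  for (id in ids) {
    occ_idx <- which(final_id == id)
    occ_keys <- cover_key[occ_idx]
    occ_idx <- occ_idx[!duplicated(occ_keys)]
    occurrences[[id]] <- covers[occ_idx]
  }
  list(ids = ids, occurrences = occurrences, table = tab)
}

#' Enumerate environments for a set of molecules
#'
#' Convenience wrapper around [enumerateEnvironments()] caching per-compound
#' results; the catalog is the input to vocabulary construction and
#' fingerprint generation, so parsing and enumeration happen once per
#' compound no matter how many trials reuse it.
#'
#' @param mols named list of [MolGraph-class] objects (see [parseSmiles()]).
#' @param max_radius maximum bond radius.
#' @return named list of [enumerateEnvironments()] results.
#' @export
featureCatalog <- function(mols, max_radius = 2) {
  stopifnot(is.list(mols), length(mols) >= 1, !is.null(names(mols)))
  lapply(mols, enumerateEnvironments, max_radius = max_radius)
}

#' Build a collision-free feature vocabulary
#'
#' Every environment identifier observed in the given compounds receives one
#' unique vector position; positions are assigned in sorted identifier order
#' so the vocabulary depends only on the set of observed environments.
#'
#' @param catalog a [featureCatalog()] (or a list with per-compound `$ids`).
#' @param compound_ids optional subset of compounds (e.g. the training set
#'   only) whose environments enter the vocabulary.
#' @return a [FeatureVocabulary-class].
#' @export
buildVocabulary <- function(catalog, compound_ids = NULL) {
  stopifnot(length(catalog) >= 1)
  if (!is.null(compound_ids)) {
    stopifnot(all(compound_ids %in% names(catalog)))
    catalog <- catalog[compound_ids]
  }
  ids <- sort(unique(unlist(lapply(catalog, `[[`, "ids"), use.names = FALSE)))
  new("FeatureVocabulary", ids = ids)
}

#' Binary fingerprints over a vocabulary
#'
#' Encodes compounds as rows of a sparse binary matrix over the vocabulary's
#' vector positions. Environments absent from the vocabulary (e.g. in
#' compounds of another target pair) are dropped; the number of dropped
#' environments per compound is returned in the `"unseen"` attribute.
#'
#' @param catalog a [featureCatalog()].
#' @param vocab a [FeatureVocabulary-class].
#' @param compound_ids optional subset/order of compounds to encode.
#' @return a `Matrix::ngCMatrix` (compounds x positions) with an `"unseen"`
#'   attribute (integer vector of dropped-environment counts per compound).
#' @export
fingerprintMatrix <- function(catalog, vocab, compound_ids = NULL) {
  stopifnot(is(vocab, "FeatureVocabulary"))
  if (is.null(compound_ids)) compound_ids <- names(catalog)
  stopifnot(all(compound_ids %in% names(catalog)))
  ii <- integer(0); jj <- integer(0)
  unseen <- stats::setNames(integer(length(compound_ids)), compound_ids)
  for (k in seq_along(compound_ids)) {
    ids <- catalog[[compound_ids[k]]]$ids
    pos <- featurePositions(vocab, ids)
    unseen[k] <- sum(is.na(pos))
    pos <- pos[!is.na(pos)]
    ii <- c(ii, rep(k, length(pos)))
    jj <- c(jj, pos)
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj,
                            dims = c(length(compound_ids), vocabularySize(vocab)),
                            dimnames = list(compound_ids, NULL))
  m <- as(m, "nMatrix")
  attr(m, "unseen") <- unseen
  m
}

#' Map a feature back to atoms and bonds
#'
#' Returns every occurrence of an environment identifier in a compound, i.e.
#' the atom and bond sets it covers (occurrences with identical cover are
#' collapsed). An identifier that does not occur yields an empty list.
#'
#' @param mol a [MolGraph-class], SMILES string, or a cached
#'   [enumerateEnvironments()] result.
#' @param env_id environment identifier string.
#' @return list of occurrences, each `list(atoms =, bonds =)`.
#' @export
mapFeatureToAtoms <- function(mol, env_id) {
  env <- if (is.list(mol) && !is.null(mol$occurrences)) mol
         else enumerateEnvironments(mol)
  occ <- env$occurrences[[env_id]]
  if (is.null(occ)) list() else occ
}
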