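#' @import methods
#' @importFrom stats median quantile rbinom runif sd setNames fivenum
#' @importFrom utils head read.csv write.csv
#' @useDynLib ShapSig, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Molecular graph
#'
#' Light-weight connectivity-level representation of a molecule: a table of
#' heavy atoms (element, formal charge, ring membership, aromaticity) and a
#' table of bonds (endpoint indices and bond order, with aromatic bonds coded
#' as order 1.5). Atom indices follow the order of first appearance in the
#' SMILES string the molecule was parsed from. Hydrogens are implicit.
#'
#' @slot smiles SMILES string the graph was parsed from.
#' @slot atoms `data.frame` with columns `element`, `charge`, `hcount`
#'   (implicit hydrogens), `ring`, `aromatic`, one row per heavy atom.
#' @slot bonds `data.frame` with columns `from`, `to`, `order`.
#' @slot mw molecular weight in Dalton (implicit hydrogens included).
#' @export
setClass("MolGraph",
  representation(smiles = "character", atoms = "data.frame",
                 bonds = "data.frame", mw = "numeric"),
  validity = function(object) {
    n <- nrow(object@atoms)
    b <- object@bonds
    if (nrow(b) > 0 && (any(b$from < 1) || any(b$to < 1) ||
        any(b$from > n) || any(b$to > n)))
      return("bond endpoints outside atom range")
    if (nrow(b) > 0 && any(b$from == b$to))
      return("self-bond")
    TRUE
  })

setMethod("show", "MolGraph", function(object) {
  cat("MolGraph:", object@smiles, "\n ", nrow(object@atoms), "heavy atoms,",
      nrow(object@bonds), "bonds, MW", round(object@mw, 1), "Da\n")
})

#' @describeIn MolGraph number of heavy atoms
#' @param x,object a `MolGraph`
#' @export
numAtoms <- function(x) nrow(x@atoms)

#' @describeIn MolGraph atom table accessor
#' @export
atomTable <- function(x) x@atoms

#' @describeIn MolGraph bond table accessor
#' @export
bondTable <- function(x) x@bonds

## MDL ctab charge codes -> formal charges
.mdl_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

## standard valences of the organic subset; hypervalent S/P pick the smallest
## standard valence that accommodates the kekulized bond-order sum
.std_valence <- list(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
                     S = c(2, 4, 6), Cl = 1, Br = 1, I = 1, Se = c(2, 4, 6),
                     As = c(3, 5))

.implicit_h <- function(element, charge, bos_kek) {
  v <- .std_valence[[element]]
  if (is.null(v)) return(0L)
  if (element %in% c("N", "P", "O", "S", "Se")) v <- v + charge
  else v <- v - abs(charge)
  v <- v[v >= bos_kek]
  if (length(v) == 0) return(0L)
  as.integer(max(0, min(v) - bos_kek))
}

.sdf_to_molgraph <- function(sdf, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  charge <- rep(0L, n)
  if (!is.null(dim(ab)) && ncol(ab) >= 5) {
    code <- as.character(ab[, 5])
    code[!code %in% names(.mdl_charge)] <- "0"
    charge <- unname(.mdl_charge[code])
  }
  bb <- ChemmineR::bondblock(sdf)
  bonds <- data.frame(from = integer(0), to = integer(0), order = numeric(0))
  if (!is.null(dim(bb)) && ncol(bb) >= 3 && nrow(bb) > 0) {
    bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                        order = as.numeric(bb[, 3]))
    bonds <- bonds[bonds$from >= 1 & bonds$to >= 1, , drop = FALSE]
  }
  ## implicit hydrogens from kekulized bond orders (before aromatic remap)
  hcount <- integer(n)
  for (i in seq_len(n)) {
    bos <- if (nrow(bonds)) sum(bonds$order[bonds$from == i | bonds$to == i]) else 0
    hcount[i] <- .implicit_h(elements[i], charge[i], round(bos))
  }
  ring <- rep(FALSE, n)
  aromatic_atom <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    rr <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                   error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    ring_atoms <- lapply(rr$RINGS, function(rg) as.integer(sub("^.*_", "", rg)))
    if (length(ring_atoms)) {
      ring[unique(unlist(ring_atoms))] <- TRUE
      arom <- rr$AROMATIC
      for (k in seq_along(ring_atoms)) {
        if (isTRUE(arom[[k]])) {
          idx <- ring_atoms[[k]]
          aromatic_atom[idx] <- TRUE
          m <- cbind(idx, c(idx[-1], idx[1]))
          key <- paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
          hit <- paste(pmin(bonds$from, bonds$to),
                       pmax(bonds$from, bonds$to)) %in% key
          bonds$order[hit] <- 1.5
        }
      }
    }
  }
  atoms <- data.frame(element = elements, charge = charge, hcount = hcount,
                      ring = ring, aromatic = aromatic_atom,
                      stringsAsFactors = FALSE)
  mw <- tryCatch(as.numeric(ChemmineR::MW(sdf)), error = function(e) NA_real_)
  new("MolGraph", smiles = smiles, atoms = atoms, bonds = bonds, mw = mw)
}

#' Parse SMILES strings into molecular graphs
#'
#' Parses one or more SMILES via OpenBabel (ChemmineOB) and derives
#' connectivity, formal charges, ring membership and aromaticity
#' (ring perception by [ChemmineR::rings()]). Atom order follows the order
#' of appearance in the input SMILES.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional compound identifiers; defaults to `names(smiles)` or
#'   `mol1 ... molN`.
#' @return named list of [MolGraph-class] objects.
#' @examples
#' \donttest{
#' mols <- parseSmiles(c(ethanol = "CCO"))
#' numAtoms(mols$ethanol)
#' }
#' @export
parseSmiles <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  named <- stats::setNames(smiles, ids)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(named)),
                     error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) != length(smiles)) {
    ## one or more inputs failed to parse: isolate offenders one at a time
    bad <- character(0)
    out <- vector("list", length(smiles))
    for (i in seq_along(smiles)) {
      s1 <- tryCatch(suppressWarnings(
        ChemmineR::smiles2sdf(named[i])), error = function(e) NULL)
      if (is.null(s1)) bad <- c(bad, smiles[i])
      else out[[i]] <- .sdf_to_molgraph(s1[[1]], smiles[[i]])
    }
    if (length(bad))
      stop("unparseable SMILES: ", paste(bad, collapse = ", "))
    names(out) <- ids
    return(out)
  }
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    out[[i]] <- .sdf_to_molgraph(sdfset[[i]], smiles[[i]])
  }
  names(out) <- ids
  out
}

#' Canonicalize SMILES strings
#'
#' Round-trips SMILES through OpenBabel's canonical SMILES writer, so that
#' identical molecules written differently map to one string.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, same length.
#' @export
canonicalSmiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  out <- ChemmineOB::convertFormat(
    "SMI", "CAN", source = paste0(paste(smiles, collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(lines) != length(smiles))
    stop("canonicalization failed for at least one SMILES")
  unname(vapply(lines, function(s) strsplit(s, "[\t ]")[[1]][1], character(1)))
}

.element_codes <- function(...) {
  all_el <- unique(unlist(list(...)))
  stats::setNames(seq_along(all_el), all_el)
}

.mol_igraph <- function(mol, element_code, order_code) {
  g <- igraph::make_empty_graph(n = numAtoms(mol), directed = FALSE)
  b <- mol@bonds
  if (nrow(b) > 0)
    g <- igraph::add_edges(g, rbind(b$from, b$to))
  igraph::V(g)$color <- as.integer(element_code[mol@atoms$element])
  if (nrow(b) > 0)
    igraph::E(g)$color <- as.integer(order_code[as.character(b$order)])
  g
}

#' Substructure matching with atom maps
#'
#' Finds all embeddings of a query molecular graph inside a target molecule
#' using VF2 subgraph monomorphism (igraph) with element-labelled atoms and
#' order-labelled bonds. Aromatic bonds (order 1.5) only match aromatic
#' bonds, so kekulized and aromatic forms must come through the same parser
#' (which this package's [parseSmiles()] guarantees).
#'
#' @param target a [MolGraph-class] (or SMILES string) to search in.
#' @param query a [MolGraph-class] (or SMILES string) to search for.
#' @param unique_sets if `TRUE` (default), embeddings mapping to the same set
#'   of target atoms are collapsed to one.
#' @return list of integer vectors; element `k` of each vector is the target
#'   atom matched to query atom `k`. Empty list when there is no match.
#' @export
matchSubstructure <- function(target, query, unique_sets = TRUE) {
  if (is.character(target)) target <- parseSmiles(target)[[1]]
  if (is.character(query)) query <- parseSmiles(query)[[1]]
  el <- .element_codes(target@atoms$element, query@atoms$element)
  oc <- .element_codes(as.character(target@bonds$order),
                       as.character(query@bonds$order))
  gt <- .mol_igraph(target, el, oc)
  gq <- .mol_igraph(query, el, oc)
  if (numAtoms(query) > numAtoms(target)) return(list())
  maps <- igraph::subgraph_isomorphisms(gq, gt, method = "vf2")
  maps <- lapply(maps, as.integer)
  if (unique_sets && length(maps)) {
    key <- vapply(maps, function(m) paste(sort(m), collapse = ","), character(1))
    maps <- maps[!duplicated(key)]
  }
  maps
}

#' Test whether a molecule contains a substructure
#'
#' @inheritParams matchSubstructure
#' @return logical scalar.
#' @export
hasSubstructure <- function(target, query) {
  length(matchSubstructure(target, query, unique_sets = TRUE)) > 0
}
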