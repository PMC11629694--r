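# Fixed 75-dimensional atom feature layout (Duvenaud-style neural
# fingerprint lineage): the blocks below are pinned so that feature
# indices are stable across releases.
.ELEMENT_LIST <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "other")            # 44
.HYBRID_LIST <- c("SP", "SP2", "SP3", "SP3D", "SP3D2") # 5

#' Atom feature layout
#'
#' Names of the 75 per-atom feature slots, in order: one-hot element over a
#' fixed 44-symbol list (unknown elements map to the reserved "other"
#' slot), one-hot heavy-atom degree 0-10, one-hot implicit valence
#' (implicit hydrogen count) 0-6, formal charge, radical-electron count,
#' one-hot hybridization (SP, SP2, SP3, SP3D, SP3D2), an aromaticity flag,
#' and one-hot total hydrogen count 0-4.
#'
#' @return character vector of length 75.
#' @export
atomFeatureLayout <- function() {
  c(paste0("element_", .ELEMENT_LIST),
    paste0("degree_", 0:10),
    paste0("implicit_valence_", 0:6),
    "formal_charge", "radical_electrons",
    paste0("hybridization_", .HYBRID_LIST),
    "aromatic",
    paste0("total_h_", 0:4))
}

.atomFeatureRow <- function(element, degree, n_h, charge, hybrid, aromatic) {
  v <- numeric(75)
  ei <- match(element, .ELEMENT_LIST)
  if (is.na(ei)) ei <- length(.ELEMENT_LIST)      # reserved "other" slot
  v[ei] <- 1
  v[44 + min(degree, 10L) + 1L] <- 1
  v[55 + min(n_h, 6L) + 1L] <- 1                  # implicit valence block
  v[63] <- charge
  v[64] <- 0                                      # radical electrons
  v[64 + match(hybrid, .HYBRID_LIST)] <- 1
  v[70] <- as.numeric(aromatic)
  v[70 + min(n_h, 4L) + 1L] <- 1                  # total-H block
  v
}

#' Per-atom feature vectors of a molecule
#'
#' Computes the fixed-layout 75-dimensional feature vector for every heavy
#' atom of a molecule: atom identity, bonding environment (degree, implicit
#' valence, hydrogenation) and electronic state (formal charge,
#' hybridization, aromaticity).  See [atomFeatureLayout()] for slot order.
#'
#' @param smiles a single SMILES string.
#' @param canonicalize canonicalize first (default TRUE); tables ingested
#'   with [readLnpTable()] are already canonical, so pipeline code skips
#'   the extra conversion.  The feature multiset is invariant either way.
#' @return numeric matrix, one row per heavy atom, 75 columns.
#' @examples
#' dim(atomFeatures("CCO"))   # 3 x 75
#' @export
atomFeatures <- function(smiles, canonicalize = TRUE) {
  mol <- .parseMol(if (canonicalize) canonicalizeSmiles(smiles) else smiles)
  a <- mol$atoms
  feats <- t(vapply(seq_len(nrow(a)), function(i) {
    .atomFeatureRow(a$element[i], a$degree[i], a$n_h[i], a$charge[i],
                    .hybridization(a$sybyl[i], a$degree[i], a$n_h[i]),
                    a$aromatic[i])
  }, numeric(75)))
  colnames(feats) <- atomFeatureLayout()
  feats
}

#' Build a hydrogen-suppressed molecular graph
#'
#' Converts a SMILES string into a [MolGraph-class]: one node per heavy
#' atom, one undirected edge per covalent bond, hydrogens suppressed
#' (their count is carried in the node features instead).  Disconnected
#' fragments, e.g. counter-ions of salts, are kept as separate components
#' of a single graph.
#'
#' @param smiles a single SMILES string.
#' @param largestFragment if TRUE, restrict to the fragment with the most
#'   heavy atoms (ties broken by first occurrence).  Default FALSE.
#' @param canonicalize canonicalize first (default TRUE); skip for
#'   already-canonical input.
#' @return a [MolGraph-class] object.
#' @examples
#' g <- buildMolGraph("c1ccccc1")
#' degrees(g)   # all 2
#' @export
buildMolGraph <- function(smiles, largestFragment = FALSE,
                          canonicalize = TRUE) {
  canon <- if (canonicalize) canonicalizeSmiles(smiles) else smiles
  mol <- .parseMol(canon)
  adj <- mol$adjacency
  a <- mol$atoms

  if (largestFragment && nrow(a) > 1L) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    adj <- adj[keep, keep, drop = FALSE]
    a <- a[keep, , drop = FALSE]
    a$degree <- as.integer(rowSums(adj))
  }

  feats <- t(vapply(seq_len(nrow(a)), function(i) {
    .atomFeatureRow(a$element[i], a$degree[i], a$n_h[i], a$charge[i],
                    .hybridization(a$sybyl[i], a$degree[i], a$n_h[i]),
                    a$aromatic[i])
  }, numeric(75)))
  colnames(feats) <- atomFeatureLayout()

  new("MolGraph", nodeFeatures = feats, adjacency = adj,
      degrees = as.integer(rowSums(adj)), atomSymbols = a$element,
      smiles = canon)
}

# Deterministic integer hashing for circular-substructure identifiers.
# Polynomial rolling hash over an integer sequence, kept inside 2^31 so
# the arithmetic is exact in doubles on every platform.
.hashSeq <- function(x) {
  h <- 16777619
  for (v in x) h <- (h * 31 + (v %% 2147483647) + 1) %% 2147483647
  h
}

.BOND_CODE <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 4, "am" = 5,
                "du" = 6, "un" = 7, "nc" = 8)

#' Count-based circular fingerprint
#'
#' Morgan-style circular fingerprint: for every heavy atom, the
#' substructures obtained by drawing circles of radius 0..\code{radius}
#' around it are assigned deterministic integer identifiers by iterative
#' neighborhood hashing; each occurrence is folded into
#' \code{identifier mod bins} and the counts accumulated, so repeating
#' substructures (ubiquitous in lipid tails) contribute their multiplicity
#' rather than a single bit.  A radius is counted for an atom only when
#' the corresponding neighborhood exists, i.e. some atom lies at exactly
#' that topological distance.
#'
#' @param smiles a single SMILES string.
#' @param radius maximum circle radius (default 2).
#' @param bins folded vector length (default 2048).
#' @param canonicalize canonicalize first (default TRUE); skip for
#'   already-canonical input (counts are invariant either way).
#' @return integer count vector of length \code{bins}.
#' @examples
#' sum(circularFingerprint("C"))    # 1: a single radius-0 environment
#' sum(circularFingerprint("CC"))   # 4: two atoms x radii {0, 1}
#' @export
circularFingerprint <- function(smiles, radius = 2L, bins = 2048L,
                                canonicalize = TRUE) {
  stopifnot(radius >= 0L, bins >= 1L)
  mol <- .parseMol(if (canonicalize) canonicalizeSmiles(smiles) else smiles)
  ids <- .environmentIdentifiers(mol, radius)
  counts <- integer(bins)
  for (id in ids) {
    b <- (id %% bins) + 1L
    counts[b] <- counts[b] + 1L
  }
  counts
}

# All circular-environment identifiers of a parsed molecule, one entry per
# (atom, realizable radius) pair.  Shared by the fingerprint and by the
# descriptor registry's environment-histogram block.
.environmentIdentifiers <- function(mol, radius) {
  a <- mol$atoms
  n <- nrow(a)
  adj <- mol$adjacency

  # invariant initial identifier per atom
  id0 <- vapply(seq_len(n), function(i) {
    .hashSeq(c(match(a$element[i], .ELEMENT_LIST, nomatch = 44L),
               a$degree[i], a$n_h[i], round(a$charge[i]),
               as.integer(a$aromatic[i])))
  }, numeric(1))

  bond_code <- matrix(0, n, n)
  if (nrow(mol$bonds)) {
    code <- .BOND_CODE[mol$bonds$type]
    code[is.na(code)] <- 9
    bond_code[cbind(mol$bonds$a1, mol$bonds$a2)] <- code
    bond_code[cbind(mol$bonds$a2, mol$bonds$a1)] <- code
  }

  neighbors <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  ids <- list(id0)
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      prev <- ids[[r]]
      ids[[r + 1L]] <- vapply(seq_len(n), function(i) {
        nb <- neighbors[[i]]
        if (length(nb) == 0L) return(NA_real_)
        pairs <- cbind(bond_code[i, nb], prev[nb])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        .hashSeq(c(r, prev[i], as.vector(t(pairs))))
      }, numeric(1))
    }
  }

  # realizable radii: atom i contributes radius r iff some atom sits at
  # topological distance exactly r from i
  dist <- .bfsDistances(adj)
  out <- numeric(0)
  for (i in seq_len(n)) {
    ecc <- max(dist[i, is.finite(dist[i, ])])
    for (r in 0:min(radius, ecc)) out <- c(out, ids[[r + 1L]][i])
  }
  out
}

# All-pairs shortest path lengths by repeated BFS (unweighted); Inf across
# disconnected fragments.
.bfsDistances <- function(adj) {
  n <- nrow(adj)
  neighbors <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(neighbors[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}
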