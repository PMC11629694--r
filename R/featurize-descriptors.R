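# The pinned expert-descriptor registry.  Descriptor sets drift across
# cheminformatics backend versions, so the 200 names are frozen as a
# versioned config asset (inst/extdata/expert_descriptor_registry_v1.txt)
# and regenerated here for validation: the two must agree exactly.

.OB_PROPS <- c("HBA1", "HBA2", "HBD", "logP", "MR", "TPSA", "nF")
.GRAPH_PROPS <- c(
  "HeavyAtomCount", "TotalHCount", "NumRingBonds", "NumRingAtoms",
  "CyclomaticNumber", "NumComponents", "FormalChargeSum", "NumPosCharged",
  "NumNegCharged", "NumAromaticAtoms", "FractionAromatic", "FractionCSP3",
  "NumRotatableBonds", "MeanDegree", "MaxDegree", "GraphDiameter",
  "WienerIndex", "MeanAtomicMass", "MolWt", "NumHeteroatoms",
  "TerminalAtomCount", "BranchAtomCount")
.COUNT_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                     "Si", "Se", "Na", "K", "Li", "Mg", "Ca", "Zn", "Fe",
                     "other")
.BOND_PAIRS <- c("C_C", "C_N", "C_O", "C_S", "C_P", "N_O", "N_N", "N_P",
                 "O_P", "O_S", "C_X", "other_pair")
.N_ENV_BINS <- 98L

#' The pinned 200-descriptor registry
#'
#' Ordered names of the 200 physicochemical and structural descriptors
#' that make up the expert representation: OpenBabel properties (logP,
#' molar refractivity, TPSA, hydrogen-bond donor/acceptor counts, fluorine
#' count), global graph/topology descriptors (ring, rotatable-bond,
#' charge, aromaticity, Wiener-index, molecular-weight terms), element /
#' degree / hydrogen-count / hybridization / bond-type histograms,
#' bonded-element-pair counts, adjacency-spectrum and Moreau-Broto
#' autocorrelation terms, and a 98-bin histogram of hashed radius-1 atom
#' environments.
#'
#' @return character vector of exactly 200 descriptor names.
#' @export
descriptorRegistry <- function() {
  c(.OB_PROPS,
    .GRAPH_PROPS,
    paste0("Count_", .COUNT_ELEMENTS),
    paste0("DegreeCount_", 0:6),
    paste0("HCount_", 0:4),
    paste0("HybridCount_", .HYBRID_LIST),
    paste0("BondCount_", c("single", "double", "triple", "aromatic",
                           "amide")),
    paste0("PairCount_", .BOND_PAIRS),
    paste0("AdjEig", 1:3), "LaplacianEig2",
    paste0("ATS", rep(1:5, times = 3), "_",
           rep(c("mass", "charge", "en"), each = 5)),
    sprintf("EnvHash1_%03d", seq_len(.N_ENV_BINS) - 1L))
}

#' Expert physicochemical descriptor vector
#'
#' Computes the pinned, ordered 200-descriptor representation of a
#' molecule (see [descriptorRegistry()] for the composition).  Values are
#' deterministic per canonical SMILES; any non-finite value is replaced by
#' 0 with a warning.
#'
#' @param smiles a single SMILES string.
#' @param registry ordered descriptor-name list; must be exactly the 200
#'   names of [descriptorRegistry()] (subsets/reorderings of it are
#'   rejected at startup rather than silently producing a different
#'   representation).
#' @param canonicalize canonicalize first (default TRUE); skip for
#'   already-canonical input.
#' @return named numeric vector of length 200.
#' @examples
#' d <- expertDescriptors("CCO")
#' d["MolWt"]
#' @export
expertDescriptors <- function(smiles, registry = descriptorRegistry(),
                              canonicalize = TRUE) {
  known <- descriptorRegistry()
  if (!identical(as.character(registry), known)) {
    bad <- setdiff(registry, known)
    stop("descriptor registry mismatch",
         if (length(bad)) paste0("; unresolvable name(s): ",
                                 paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  canon <- if (canonicalize) canonicalizeSmiles(smiles) else smiles
  mol <- .parseMol(canon)
  v <- c(.obDescriptors(canon), .graphDescriptors(mol),
         .histogramDescriptors(mol), .spectralDescriptors(mol),
         .autocorrDescriptors(mol), .envHashDescriptors(mol))
  v <- v[known]
  if (any(!is.finite(v))) {
    warning(sum(!is.finite(v)), " non-finite descriptor value(s) set to 0",
            call. = FALSE)
    v[!is.finite(v)] <- 0
  }
  v
}

.obDescriptors <- function(canon) {
  obmol <- ChemmineOB::forEachMol("SMILES", canon, identity)
  p <- suppressWarnings(ChemmineOB::prop_OB(obmol))
  out <- vapply(.OB_PROPS, function(nm) {
    x <- suppressWarnings(as.numeric(p[[nm]][1]))
    if (length(x) == 0L) NA_real_ else x
  }, numeric(1))
  names(out) <- .OB_PROPS
  out
}

.graphDescriptors <- function(mol) {
  a <- mol$atoms
  n <- nrow(a)
  adj <- mol$adjacency
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  n_edges <- sum(adj) / 2
  bridges <- if (n_edges > 0) igraph::bridges(g) else integer(0)
  ring_bonds <- n_edges - length(bridges)
  ring_atoms <- if (ring_bonds > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    nb <- if (length(bridges)) el[-as.integer(bridges), , drop = FALSE] else el
    length(unique(as.vector(nb)))
  } else 0
  d <- .bfsDistances(adj)
  finite_d <- d[is.finite(d) & d > 0]
  hyb <- vapply(seq_len(n), function(i)
    .hybridization(a$sybyl[i], a$degree[i], a$n_h[i]), character(1))
  is_c <- a$element == "C"
  mass <- .ATOMIC_MASS[a$element]
  mass[is.na(mass)] <- 0
  rot <- 0
  if (nrow(mol$bonds)) {
    bridge_pairs <- if (length(bridges)) {
      el <- igraph::as_edgelist(g, names = FALSE)
      el[as.integer(bridges), , drop = FALSE]
    } else matrix(integer(0), 0, 2)
    if (nrow(bridge_pairs)) {
      deg <- a$degree
      single <- mol$bonds$type == "1"
      key <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
                   pmax(mol$bonds$a1, mol$bonds$a2))
      bkey <- paste(pmin(bridge_pairs[, 1], bridge_pairs[, 2]),
                    pmax(bridge_pairs[, 1], bridge_pairs[, 2]))
      ok <- single & key %in% bkey &
        deg[mol$bonds$a1] > 1 & deg[mol$bonds$a2] > 1
      rot <- sum(ok)
    }
  }
  c(HeavyAtomCount = n,
    TotalHCount = sum(a$n_h),
    NumRingBonds = ring_bonds,
    NumRingAtoms = ring_atoms,
    CyclomaticNumber = n_edges - n + comp$no,
    NumComponents = comp$no,
    FormalChargeSum = sum(a$charge),
    NumPosCharged = sum(a$charge > 0),
    NumNegCharged = sum(a$charge < 0),
    NumAromaticAtoms = sum(a$aromatic),
    FractionAromatic = mean(a$aromatic),
    FractionCSP3 = if (any(is_c)) mean(hyb[is_c] == "SP3") else 0,
    NumRotatableBonds = rot,
    MeanDegree = mean(a$degree),
    MaxDegree = max(a$degree),
    GraphDiameter = if (length(finite_d)) max(finite_d) else 0,
    WienerIndex = sum(finite_d) / 2,
    MeanAtomicMass = mean(mass),
    MolWt = sum(mass) + sum(a$n_h) * .ATOMIC_MASS[["H"]],
    NumHeteroatoms = sum(!is_c),
    TerminalAtomCount = sum(a$degree == 1),
    BranchAtomCount = sum(a$degree >= 3))
}

.histogramDescriptors <- function(mol) {
  a <- mol$atoms
  el <- ifelse(a$element %in% .COUNT_ELEMENTS, a$element, "other")
  elc <- vapply(.COUNT_ELEMENTS, function(e) sum(el == e), numeric(1))
  names(elc) <- paste0("Count_", .COUNT_ELEMENTS)
  degc <- vapply(0:6, function(k) sum(pmin(a$degree, 6L) == k), numeric(1))
  names(degc) <- paste0("DegreeCount_", 0:6)
  hc <- vapply(0:4, function(k) sum(pmin(a$n_h, 4L) == k), numeric(1))
  names(hc) <- paste0("HCount_", 0:4)
  hyb <- vapply(seq_len(nrow(a)), function(i)
    .hybridization(a$sybyl[i], a$degree[i], a$n_h[i]), character(1))
  hybc <- vapply(.HYBRID_LIST, function(h) sum(hyb == h), numeric(1))
  names(hybc) <- paste0("HybridCount_", .HYBRID_LIST)
  bt <- mol$bonds$type
  bc <- c(single = sum(bt == "1"), double = sum(bt == "2"),
          triple = sum(bt == "3"), aromatic = sum(bt == "ar"),
          amide = sum(bt == "am"))
  names(bc) <- paste0("BondCount_", names(bc))
  halogens <- c("F", "Cl", "Br", "I")
  pairc <- stats::setNames(numeric(length(.BOND_PAIRS)),
                           paste0("PairCount_", .BOND_PAIRS))
  if (nrow(mol$bonds)) {
    e1 <- a$element[mol$bonds$a1]; e2 <- a$element[mol$bonds$a2]
    for (i in seq_along(e1)) {
      pr <- sort(c(e1[i], e2[i]))
      key <- paste0(pr[1], "_", pr[2])
      key <- if (key %in% .BOND_PAIRS) key
             else if (pr[1] == "C" && pr[2] %in% halogens) "C_X"
             else if (pr[2] == "C" && pr[1] %in% halogens) "C_X"
             else "other_pair"
      pairc[paste0("PairCount_", key)] <- pairc[paste0("PairCount_", key)] + 1
    }
  }
  c(elc, degc, hc, hybc, bc, pairc)
}

.spectralDescriptors <- function(mol) {
  adj <- mol$adjacency
  n <- nrow(adj)
  ev <- if (n > 1) sort(eigen(adj, symmetric = TRUE,
                              only.values = TRUE)$values,
                        decreasing = TRUE) else 0
  top3 <- c(ev, 0, 0, 0)[1:3]
  lap <- diag(rowSums(adj), n) - adj
  lev <- sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  l2 <- if (n > 1) lev[2] else 0
  stats::setNames(c(top3, l2), c(paste0("AdjEig", 1:3), "LaplacianEig2"))
}

.autocorrDescriptors <- function(mol) {
  a <- mol$atoms
  d <- .bfsDistances(mol$adjacency)
  mass <- .ATOMIC_MASS[a$element]; mass[is.na(mass)] <- 0
  en <- .PAULING_EN[a$element]; en[is.na(en)] <- 2.0
  props <- list(mass = mass, charge = a$charge, en = en)
  out <- numeric(0)
  for (pn in names(props)) {
    p <- props[[pn]]
    for (k in 1:5) {
      sel <- is.finite(d) & d == k
      val <- sum(outer(p, p)[sel]) / 2
      out[paste0("ATS", k, "_", pn)] <- val
    }
  }
  out
}

.envHashDescriptors <- function(mol) {
  ids <- .environmentIdentifiers(mol, radius = 1L)
  counts <- numeric(.N_ENV_BINS)
  for (id in ids) {
    b <- (id %% .N_ENV_BINS) + 1
    counts[b] <- counts[b] + 1
  }
  stats::setNames(counts, sprintf("EnvHash1_%03d", seq_len(.N_ENV_BINS) - 1L))
}
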