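# Internal molecule parsing layer.
#
# All SMILES interpretation is delegated to OpenBabel (through ChemmineOB);
# this file only reshapes OpenBabel's MOL2 output into the heavy-atom tables
# the featurizers consume.  MOL2 is used because it carries, per atom, the
# SYBYL atom type (hybridization + aromaticity) and, in its UNITY_ATOM_ATTR
# block, formal charges -- none of which survive in a kekulized SDF.

# Standard atomic weights (CIAAW 2021, abridged), used for the
# molecular-weight and mass-autocorrelation descriptors.
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Se = 78.971, Br = 79.904, I = 126.904, Li = 6.94
)

# Pauling electronegativities for the autocorrelation descriptors;
# elements not listed fall back to 2.0.
.PAULING_EN <- c(
  H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
  Na = 0.93, Mg = 1.31, Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16,
  K = 0.82, Ca = 1.00, Fe = 1.83, Zn = 1.65, Se = 2.55, Br = 2.96,
  I = 2.66, Li = 0.98
)

.mol2Convert <- function(smiles, addH = TRUE) {
  opts <- if (addH) data.frame(names = "h", args = "") else NULL
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "MOL2", smiles, options = opts))
  if (!nzchar(out) || !grepl("@<TRIPOS>ATOM", out, fixed = TRUE)) {
    stop("SMILES could not be parsed: '", smiles, "'", call. = FALSE)
  }
  out
}

.mol2Section <- function(lines, tag) {
  start <- which(lines == paste0("@<TRIPOS>", tag))
  if (length(start) == 0L) return(character(0))
  start <- start[1L] + 1L
  markers <- grep("^@<TRIPOS>", lines)
  stop_at <- markers[markers >= start]
  end <- if (length(stop_at)) stop_at[1L] - 1L else length(lines)
  if (end < start) return(character(0))
  lines[start:end]
}

# Parse one SMILES into heavy-atom tables.  Returns a list with
#   atoms:  data.frame(element, sybyl, charge, aromatic, n_h, degree)
#   bonds:  data.frame(a1, a2, type) over heavy atoms (1-based indices)
#   adjacency: dense symmetric 0/1 matrix over heavy atoms
.parseMol <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  txt <- .mol2Convert(smiles, addH = TRUE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]

  atom_lines <- .mol2Section(lines, "ATOM")
  bond_lines <- .mol2Section(lines, "BOND")
  attr_lines <- .mol2Section(lines, "UNITY_ATOM_ATTR")

  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  sybyl <- vapply(af, `[[`, character(1), 6L)
  element <- sub("\\..*$", "", sybyl)

  n_all <- length(element)
  charge <- numeric(n_all)
  if (length(attr_lines)) {
    i <- 1L
    while (i <= length(attr_lines)) {
      head <- as.integer(strsplit(trimws(attr_lines[i]), "[[:space:]]+")[[1]])
      atom_id <- head[1L]; n_attr <- head[2L]
      for (j in seq_len(n_attr)) {
        kv <- strsplit(trimws(attr_lines[i + j]), "[[:space:]]+")[[1]]
        if (kv[1L] == "charge") charge[atom_id] <- as.numeric(kv[2L])
      }
      i <- i + 1L + n_attr
    }
  }

  if (length(bond_lines)) {
    bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
    b1 <- vapply(bf, function(x) as.integer(x[2L]), integer(1))
    b2 <- vapply(bf, function(x) as.integer(x[3L]), integer(1))
    btype <- vapply(bf, `[[`, character(1), 4L)
  } else {
    b1 <- b2 <- integer(0); btype <- character(0)
  }

  heavy <- which(element != "H")
  if (length(heavy) == 0L) {
    stop("SMILES '", smiles, "' has no heavy atom", call. = FALSE)
  }
  idx <- integer(n_all); idx[heavy] <- seq_along(heavy)

  is_h1 <- element[b1] == "H"; is_h2 <- element[b2] == "H"
  n_h <- integer(length(heavy))
  hh <- b1[is_h2 & !is_h1]; n_h_tab <- table(factor(idx[hh], seq_along(heavy)))
  hh2 <- b2[is_h1 & !is_h2]
  n_h <- as.integer(n_h_tab) +
    as.integer(table(factor(idx[hh2], seq_along(heavy))))

  keep <- !is_h1 & !is_h2
  bonds <- data.frame(a1 = idx[b1[keep]], a2 = idx[b2[keep]],
                      type = btype[keep], stringsAsFactors = FALSE)

  n <- length(heavy)
  adj <- matrix(0, n, n)
  if (nrow(bonds)) {
    adj[cbind(bonds$a1, bonds$a2)] <- 1
    adj[cbind(bonds$a2, bonds$a1)] <- 1
  }

  aromatic <- grepl("\\.ar$", sybyl[heavy])
  if (nrow(bonds)) {
    ar <- bonds$type == "ar"
    aromatic[unique(c(bonds$a1[ar], bonds$a2[ar]))] <- TRUE
  }

  atoms <- data.frame(
    element = element[heavy],
    sybyl = sybyl[heavy],
    charge = charge[heavy],
    aromatic = aromatic,
    n_h = n_h,
    degree = as.integer(rowSums(adj)),
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, bonds = bonds, adjacency = adj)
}

# Hybridization class from the SYBYL atom type.  Returns one of
# "SP", "SP2", "SP3", "SP3D", "SP3D2".
.hybridization <- function(sybyl, degree, n_h) {
  suffix <- sub("^[^.]*\\.?", "", sybyl)
  total <- degree + n_h
  if (suffix == "1") return("SP")
  if (suffix %in% c("2", "ar", "am", "pl3", "co2", "cat")) return("SP2")
  if (total >= 6) return("SP3D2")
  if (total == 5) return("SP3D")
  "SP3"
}
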