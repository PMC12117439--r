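# Molecular descriptors: circular fingerprints and Tanimoto similarity,
# atom-contribution log P, normalized synthetic-accessibility score, and
# coordination-environment patterns.

# deterministic 31-bit string hash (polynomial, modulus 2^31-1)
str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Circular substructure fingerprint
#'
#' Radius-2 circular (Morgan-type) fingerprint folded to a fixed-length bit
#' vector.  Atom environments are hashed from element, degree, charge,
#' hydrogen count and incident bond codes, then iteratively extended over
#' bond-neighbor pairs.  All similarity thresholds in the package are
#' defined relative to this fingerprint specification.
#'
#' @param mol a molecule (`tml_mol`) or SMILES string.
#' @param radius environment radius (default 2).
#' @param nbits fingerprint length (default 2048).
#' @return logical vector of length `nbits`.
#' @export
morgan_fingerprint <- function(mol, radius = 2L, nbits = 2048L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  n <- mol_natoms(mol)
  bond_code <- function(bidx, at) {
    if (mol$bonds$dative[bidx] == 1L) {
      if (mol$bonds$a1[bidx] == at) "D>" else "D<"
    } else as.character(mol$bonds$order[bidx])
  }
  codes <- vapply(seq_len(n), function(i) {
    bc <- sort(vapply(mol_bonds_of(mol, i), bond_code, "", at = i))
    str_hash(paste(mol$atoms$element[i], length(bc), mol$atoms$charge[i],
                   mol_hcount(mol, i), paste(bc, collapse = ","), sep = "|"))
  }, 0L)
  all_codes <- codes
  for (r in seq_len(radius)) {
    codes <- vapply(seq_len(n), function(i) {
      bidx <- mol_bonds_of(mol, i)
      nb <- ifelse(mol$bonds$a1[bidx] == i, mol$bonds$a2[bidx], mol$bonds$a1[bidx])
      pairs <- sort(vapply(seq_along(bidx), function(k)
        paste0(bond_code(bidx[k], i), ":", codes[nb[k]]), ""))
      str_hash(paste(r, codes[i], paste(pairs, collapse = ";"), sep = "#"))
    }, 0L)
    all_codes <- c(all_codes, codes)
  }
  bits <- rep(FALSE, nbits)
  bits[(unique(all_codes) %% nbits) + 1L] <- TRUE
  bits
}

#' Tanimoto similarity between two fingerprints
#'
#' |a AND b| / |a OR b|; symmetric, in [0, 1], and 1 for identical non-empty
#' fingerprints.  Two empty fingerprints compare as 0 with a warning.
#'
#' @param a,b logical fingerprint vectors of equal length.
#' @return numeric similarity.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  u <- sum(a | b)
  if (u == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / u
}

# ---- log P ------------------------------------------------------------------

# reduced Wildman-Crippen-style atom contribution table; values chosen to
# reproduce the qualitative hydrophobicity ordering of common fragments
LOGP_CONTRIB <- list(
  C_hydrophobic = 0.14,   # carbon with only C/H neighbors, saturated
  C_unsat       = 0.29,   # carbon in a multiple bond, only C/H neighbors
  C_polar       = 0.02,   # carbon bonded to at least one heteroatom
  N_sat         = -1.02,  # amine-type nitrogen
  N_unsat       = -0.25,  # imine/nitrile nitrogen
  O_hydroxyl    = -0.40,
  O_other       = -0.20,
  F             = 0.42, Cl = 0.65, Br = 0.86, I = 1.05,
  S             = 0.65, P = 0.86, B = 0.10,
  H_on_C        = 0.123,
  H_on_N        = -0.60,
  H_on_O        = -0.45,
  H_other       = 0.0,
  charge_pen    = -0.25   # per unit of absolute formal charge
)

#' Octanol-water partition coefficient (atom-contribution estimate)
#'
#' Crippen-type additive log P over a reduced atom-type table: each heavy
#' atom contributes according to its element and bonding environment, each
#' hydrogen according to the atom it sits on.  A pure function of the
#' molecular graph; conformer-independent and deterministic.
#'
#' @param mol free-ligand molecule (`tml_mol`), [anchored_ligand()] (its free
#'   ligand graph is used) or SMILES string.
#' @return numeric log P estimate.
#' @export
log_p <- function(mol) {
  if (inherits(mol, "anchored_ligand")) mol <- mol$mol
  if (is.character(mol)) mol <- parse_smiles(mol)
  ct <- LOGP_CONTRIB
  total <- 0
  for (i in seq_len(mol_natoms(mol))) {
    el <- mol$atoms$element[i]
    if (el %in% PLACEHOLDER_ELEMENTS)
      stop("log P is defined for free ligands; strip placeholders first")
    nb <- mol_neighbors(mol, i)
    nb_el <- mol$atoms$element[nb]
    bidx <- mol_bonds_of(mol, i)
    has_multi <- any(mol$bonds$order[bidx] > 1L)
    h <- mol_hcount(mol, i)
    contrib <- switch(el,
      C = if (any(!nb_el %in% c("C", "H"))) ct$C_polar
          else if (has_multi) ct$C_unsat else ct$C_hydrophobic,
      N = if (has_multi) ct$N_unsat else ct$N_sat,
      O = if (h > 0L) ct$O_hydroxyl else ct$O_other,
      F = ct$F, Cl = ct$Cl, Br = ct$Br, I = ct$I,
      S = ct$S, P = ct$P, B = ct$B, H = ct$H_other,
      stop("log P: no contribution defined for atom type '", el, "'"))
    hc <- switch(el, C = ct$H_on_C, N = ct$H_on_N, O = ct$H_on_O, ct$H_other)
    total <- total + contrib + h * hc + abs(mol$atoms$charge[i]) * ct$charge_pen
  }
  total
}

# ---- synthetic accessibility ------------------------------------------------

# reference fragment-frequency table built from the package's own fixture
# enumeration (free ligands, radius-2 environments); memoized
.sa_env <- new.env(parent = emptyenv())

sa_reference_table <- function() {
  if (!is.null(.sa_env$table)) return(.sa_env$table)
  counts <- new.env(parent = emptyenv())
  for (mode in 1:2) {
    for (rec in enumerate_fixtures(mode)) {
      for (code in atom_env_codes(rec$ligand$mol, radius = 2L)) {
        key <- as.character(code)
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  .sa_env$table <- as.list(counts)
  .sa_env$table
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# radius-r environment codes of every heavy atom
atom_env_codes <- function(mol, radius = 2L) {
  n <- mol_natoms(mol)
  bond_code <- function(bidx, at) as.character(mol$bonds$order[bidx])
  codes <- vapply(seq_len(n), function(i) {
    str_hash(paste(mol$atoms$element[i], length(mol_bonds_of(mol, i)),
                   mol$atoms$charge[i], sep = "|"))
  }, 0L)
  for (r in seq_len(radius)) {
    codes <- vapply(seq_len(n), function(i) {
      bidx <- mol_bonds_of(mol, i)
      nb <- ifelse(mol$bonds$a1[bidx] == i, mol$bonds$a2[bidx], mol$bonds$a1[bidx])
      pairs <- sort(vapply(seq_along(bidx), function(k)
        paste0(bond_code(bidx[k], i), ":", codes[nb[k]]), ""))
      str_hash(paste(r, codes[i], paste(pairs, collapse = ";"), sep = "#"))
    }, 0L)
  }
  heavy <- which(mol$atoms$element != "H")
  codes[heavy]
}

#' Raw synthetic-accessibility score on the 1-10 scale
#'
#' Fragment-contribution score in the style of Ertl and Schuffenhauer:
#' common radius-2 atom environments (scored against a reference corpus
#' frequency table) lower the score, while ring complexity (fused systems,
#' macrocycles) and molecular size raise it.  1 = easiest to synthesize,
#' 10 = hardest.
#'
#' @param mol free ligand (`tml_mol`, [anchored_ligand()] or SMILES).
#' @param reference fragment-frequency table; defaults to the internal
#'   corpus-derived table.  Passing `NULL` raises a configuration error.
#' @return numeric raw score in [1, 10].
#' @export
sa_score_raw <- function(mol, reference = sa_reference_table()) {
  if (is.null(reference))
    stop("configuration error: no fragment-score table available for the SA score")
  if (inherits(mol, "anchored_ligand")) mol <- mol$mol
  if (is.character(mol)) mol <- parse_smiles(mol)
  codes <- atom_env_codes(mol, radius = 2L)
  freq <- vapply(codes, function(code)
    reference[[as.character(code)]] %||% 0L, 0L)
  frag <- mean(log2(1 + freq))           # typically 0 (rare) .. ~9 (common)
  rings <- find_rings(mol)
  nring <- length(rings)
  ring_atoms <- unlist(rings)
  fused_atoms <- sum(table(ring_atoms) > 1L)
  macro <- sum(vapply(rings, length, 0L) > 8L)
  heavy <- length(mol_heavy_atoms(mol))
  size_pen <- heavy^1.005 - heavy
  complexity <- 0.6 * nring + 1.2 * log2(1 + fused_atoms) + 2 * macro + size_pen
  raw <- 5.5 - 0.75 * frag + 0.9 * complexity
  min(max(raw, 1), 10)
}

#' Normalized synthetic-accessibility score
#'
#' Maps the raw 1-10 score s to (10 - s) / 9, giving a score in [0, 1] where
#' 0 is hardest and 1 easiest to synthesize.
#'
#' @inheritParams sa_score_raw
#' @return numeric in [0, 1].
#' @export
sa_score <- function(mol, reference = sa_reference_table()) {
  sa_normalize(sa_score_raw(mol, reference))
}

sa_normalize <- function(raw) (10 - raw) / 9

# ---- coordination environment ----------------------------------------------

#' Coordination-environment pattern of an anchored ligand
#'
#' Per anchor: the anchor element followed by the bracketed, sorted heavy
#' neighbor elements, e.g. `N([C][C])` for pyridine-type imines or
#' `P([C][C][C])` for phosphines.  For kappa-2 ligands both anchor patterns
#' are concatenated in sorted order.
#'
#' @param ligand an [anchored_ligand()].
#' @return pattern string.
#' @export
coordination_environment <- function(ligand) {
  stopifnot(inherits(ligand, "anchored_ligand"))
  pat <- vapply(ligand$anchors, function(i) {
    nb <- mol_neighbors(ligand$mol, i)
    nb_el <- sort(ligand$mol$atoms$element[nb])
    nb_el <- nb_el[nb_el != "H"]
    paste0(ligand$mol$atoms$element[i],
           "(", paste0("[", nb_el, "]", collapse = ""), ")")
  }, "")
  paste(sort(pat), collapse = "")
}
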