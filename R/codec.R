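#' Construct an anchored ligand
#'
#' An anchored ligand is a neutral ligand molecular graph together with its
#' metal-coordination mode: which atoms bind the metal (the anchors), the
#' formal metal-ligand bond order of each anchor (1 or 2), and the denticity
#' (kappa-1 = monodentate, kappa-2 = bidentate).  It is the unit record of
#' every corpus in this package.
#'
#' @param smiles SMILES of the free ligand (Kekulé dialect; divalent carbene
#'   carbons written with explicit H count, e.g. `[CH2]`).
#' @param anchors integer vector of anchor atom indices (in the atom order of
#'   `smiles`); length 1 for kappa-1, 2 for kappa-2.
#' @param bond_orders integer vector of per-anchor formal metal-bond orders,
#'   each 1 (dative) or 2 (formal double bond, e.g. carbenes).
#' @param denticity 1 or 2.
#' @return an object of class `anchored_ligand`.
#' @export
anchored_ligand <- function(smiles, anchors, bond_orders, denticity = length(anchors)) {
  mol <- if (inherits(smiles, "tml_mol")) smiles else parse_smiles(smiles)
  anchors <- as.integer(anchors)
  bond_orders <- as.integer(bond_orders)
  denticity <- as.integer(denticity)
  if (!denticity %in% c(1L, 2L))
    stop("denticity must be 1 or 2")
  if (length(anchors) != denticity)
    stop("length(anchors) must equal denticity")
  if (length(bond_orders) != denticity)
    stop("length(bond_orders) must equal denticity")
  if (!all(bond_orders %in% c(1L, 2L)))
    stop("bond orders must be 1 or 2")
  if (any(anchors < 1L | anchors > mol_natoms(mol)))
    stop("anchor index out of range")
  if (anyDuplicated(anchors))
    stop("anchor atoms must be distinct")
  if (any(mol$atoms$element[anchors] %in% PLACEHOLDER_ELEMENTS))
    stop("placeholder elements (Li/Be/Ir) cannot be ligand atoms")
  if (any(mol$atoms$element %in% PLACEHOLDER_ELEMENTS))
    stop("placeholder elements (Li/Be/Ir) cannot appear in the ligand graph")
  if (mol_formal_charge(mol) != 0L)
    stop("charge error: ligand net formal charge must be 0, got ",
         mol_formal_charge(mol))
  if (!mol_is_connected(mol))
    stop("ligand graph must be connected")
  # adjacent kappa-2 anchors are legal only for the haptic (eta-2) case:
  # both anchors order 1 sharing a multiple bond whose pi electrons donate
  haptic <- FALSE
  if (denticity == 2L) {
    bidx <- mol_bond_between(mol, anchors[1], anchors[2])
    if (length(bidx)) {
      ok_pi <- mol$bonds$order[bidx] >= 2L && all(bond_orders == 1L) &&
        mol$bonds$dative[bidx] == 0L
      if (!ok_pi)
        stop("adjacency error: kappa-2 anchor atoms must be non-adjacent ",
             "(except eta-2 pi coordination of a multiple bond)")
      haptic <- TRUE
    }
  }
  # every anchor must support its declared metal bond on top of its valence
  for (k in seq_along(anchors)) {
    if (haptic) break
    i <- anchors[k]
    el <- mol$atoms$element[i]
    used <- mol_bond_valence(mol, i) + mol_hcount(mol, i) + bond_orders[k]
    vals <- allowed_valences(el, mol$atoms$charge[i])
    if (bond_orders[k] == 1L) {
      # dative donation costs no valence but needs a lone pair: saturated
      # atoms of elements without one (C, B) cannot anchor datively
      if (mol_bond_valence(mol, i) + mol_hcount(mol, i) >= max(vals) &&
          mol$atoms$charge[i] >= 0L &&
          !el %in% c("N", "O", "S", "P", "F", "Cl", "Br", "I"))
        stop("valence error: anchor atom ", i, " (", el,
             ") has no capacity for a dative bond")
    } else {
      if (used > max(vals))
        stop("valence error: anchor atom ", i, " (", el,
             ") cannot support a formal double bond to the metal")
    }
  }
  # order-2 anchors must carry an explicit H count (the divalent resonance
  # form), so stripping the metal later cannot create phantom hydrogens
  for (k in which(bond_orders == 2L)) {
    i <- anchors[k]
    if (is.na(mol$atoms$hcount[i])) {
      # an unannotated order-2 anchor is read as the divalent resonance
      # form: freeze H at the tetravalent implicit count minus the two
      # electrons engaged in the metal double bond
      mol$atoms$hcount[i] <- max(mol_hcount(mol, i) - 2L, 0L)
    }
  }
  # canonical anchor order: by canonical atom rank
  rk <- canon_ranks(mol)
  ord <- order(rk[anchors])
  structure(list(mol = mol, anchors = anchors[ord],
                 bond_orders = bond_orders[ord], denticity = denticity,
                 haptic = haptic),
            class = "anchored_ligand")
}

#' @export
print.anchored_ligand <- function(x, ...) {
  cat("<anchored_ligand> kappa-", x$denticity, "\n", sep = "")
  cat("  free ligand: ", as.character(canonical_smiles(x$mol)), "\n", sep = "")
  cat("  anchors: ", paste(x$anchors, collapse = ", "),
      " (", paste(x$mol$atoms$element[x$anchors], collapse = ", "), ")",
      "  orders: ", paste(x$bond_orders, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Encode an anchored ligand as a metal-anchored SMILES string
#'
#' Serializes the coordination mode into the placeholder grammar: a kappa-1
#' order-1 anchor becomes a dative bond to `[Li]`; a kappa-1 order-2 anchor
#' (carbene/silylene type) a formal double bond to `[Be]`; a kappa-2 ligand
#' forms a metallacycle around `[Ir]`, with any order-2 anchor routed through
#' a `[Be]` bridge (`anchor=[Be]->[Ir]`) to keep valences legal.  The dative
#' arrows of the grammar are serialized with the ASCII tokens `->` / `<-`
#' (unicode arrows are accepted on input everywhere).
#'
#' @param ligand an [anchored_ligand()].
#' @return a canonical anchored-SMILES string with attribute `mode`.
#' @export
encode_anchored <- function(ligand) {
  stopifnot(inherits(ligand, "anchored_ligand"))
  mol <- ligand$mol
  if (ligand$denticity == 1L) {
    i <- ligand$anchors[1]
    if (ligand$bond_orders[1] == 1L) {
      mol <- mol_add_atom(mol, "Li", 0L, 0L)
      mol <- mol_add_bond(mol, i, mol_natoms(mol), 1L, 1L)
    } else {
      mol <- mol_add_atom(mol, "Be", 0L, 0L)
      mol <- mol_add_bond(mol, i, mol_natoms(mol), 2L, 0L)
    }
  } else {
    if (isTRUE(ligand$haptic)) {
      # eta-2 pi coordination: the shared multiple bond donates its pi
      # electrons, leaving the sigma framework inside the metallacycle
      bidx <- mol_bond_between(mol, ligand$anchors[1], ligand$anchors[2])
      mol$bonds$order[bidx] <- mol$bonds$order[bidx] - 1L
    }
    mol <- mol_add_atom(mol, "Ir", 0L, 0L)
    ir <- mol_natoms(mol)
    for (k in seq_len(2L)) {
      i <- ligand$anchors[k]
      if (ligand$bond_orders[k] == 1L) {
        mol <- mol_add_bond(mol, i, ir, 1L, 1L)
      } else {
        mol <- mol_add_atom(mol, "Be", 0L, 0L)
        be <- mol_natoms(mol)
        mol <- mol_add_bond(mol, i, be, 2L, 0L)
        mol <- mol_add_bond(mol, be, ir, 1L, 1L)
      }
    }
  }
  vc <- mol_valence_ok(mol)
  if (!vc$ok)
    stop("valence error: placeholder attachment overflows atom(s) ",
         paste(vc$bad_atoms, collapse = ", "))
  out <- as.character(canonical_smiles(mol))
  attr(out, "mode") <- ligand$denticity
  class(out) <- "anchored_smiles"
  out
}

#' @export
print.anchored_smiles <- function(x, ...) {
  cat(unclass(x), " (kappa-", attr(x, "mode"), ")\n", sep = "")
  invisible(x)
}

# classify the placeholder pattern of a parsed anchored molecule; errors with
# informative grammar messages.  Returns list(anchors, orders, denticity,
# placeholder_atoms) with indices in the anchored molecule.
classify_anchor_pattern <- function(mol) {
  ph <- which(mol$atoms$element %in% PLACEHOLDER_ELEMENTS)
  if (!length(ph))
    stop("missing-anchor error: no placeholder atom ([Li]/[Be]/[Ir]) present")
  el <- mol$atoms$element[ph]
  b <- mol$bonds

  bonds_of <- function(i) mol_bonds_of(mol, i)
  is_dative_in <- function(bidx, i) b$dative[bidx] == 1L & b$a2[bidx] == i
  other <- function(bidx, i) ifelse(b$a1[bidx] == i, b$a2[bidx], b$a1[bidx])

  n_li <- sum(el == "Li"); n_be <- sum(el == "Be"); n_ir <- sum(el == "Ir")

  if (n_ir == 0L) {
    if (length(ph) != 1L)
      stop("grammar error: multiple placeholders without an [Ir] center")
    i <- ph
    bi <- bonds_of(i)
    if (length(bi) != 1L)
      stop("grammar error: kappa-1 placeholder must have exactly one bond")
    j <- other(bi, i)
    if (mol$atoms$element[j] %in% PLACEHOLDER_ELEMENTS)
      stop("grammar error: placeholder bonded to placeholder")
    if (el == "Li") {
      if (!is_dative_in(bi, i))
        stop("grammar error: [Li] must accept a dative bond")
      list(anchors = j, orders = 1L, denticity = 1L, placeholder_atoms = i)
    } else if (el == "Be") {
      if (b$dative[bi] != 0L || b$order[bi] != 2L)
        stop("grammar error: terminal [Be] must carry a formal double bond")
      list(anchors = j, orders = 2L, denticity = 1L, placeholder_atoms = i)
    } else stop("grammar error: unexpected placeholder pattern")
  } else {
    if (n_ir != 1L) stop("grammar error: more than one [Ir] center")
    if (n_li != 0L) stop("grammar error: [Li] cannot appear with [Ir]")
    if (n_be > 2L) stop("grammar error: more than two [Be] bridges")
    ir <- ph[el == "Ir"]
    bi <- bonds_of(ir)
    if (length(bi) != 2L || !all(is_dative_in(bi, ir)))
      stop("grammar error: [Ir] must accept exactly two dative bonds")
    donors <- other(bi, ir)
    anchors <- integer(0); orders <- integer(0)
    for (d in donors) {
      if (mol$atoms$element[d] == "Be") {
        bd <- setdiff(bonds_of(d), bi)
        if (length(bd) != 1L || b$dative[bd] != 0L || b$order[bd] != 2L)
          stop("grammar error: [Be] bridge must carry one formal double bond")
        a <- other(bd, d)
        if (mol$atoms$element[a] %in% PLACEHOLDER_ELEMENTS)
          stop("grammar error: placeholder bonded to placeholder")
        anchors <- c(anchors, a); orders <- c(orders, 2L)
      } else if (mol$atoms$element[d] %in% PLACEHOLDER_ELEMENTS) {
        stop("grammar error: placeholder donating to [Ir]")
      } else {
        anchors <- c(anchors, d); orders <- c(orders, 1L)
      }
    }
    n_be_used <- sum(orders == 2L)
    if (n_be_used != n_be)
      stop("grammar error: dangling [Be] not bridging to [Ir]")
    if (anchors[1] == anchors[2])
      stop("grammar error: kappa-2 anchors must be two distinct atoms")
    list(anchors = anchors, orders = orders, denticity = 2L,
         placeholder_atoms = c(ir, ph[el == "Be"]))
  }
}

#' Decode a metal-anchored SMILES string into an anchored ligand
#'
#' Removes the placeholder atoms and their bonds, recovering the free ligand
#' together with anchors, formal metal-bond orders and denticity.  Carbene
#' anchors (order 2) are restored to the neutral divalent resonance form:
#' the anchor carbon keeps the hydrogen count it had in the anchored string,
#' so stripping the metal never creates a pentavalent carbon.
#'
#' @param s anchored-SMILES string (ASCII `->`/`<-` or unicode arrows).
#' @return an [anchored_ligand()].
#' @export
decode_anchored <- function(s) {
  mol <- parse_smiles(as.character(s))
  if (!mol_is_connected(mol))
    stop("grammar error: anchored SMILES must be a single connected fragment")
  pat <- classify_anchor_pattern(mol)
  # freeze the hydrogen count of order-2 anchors before stripping the metal
  for (k in which(pat$orders == 2L)) {
    i <- pat$anchors[k]
    mol$atoms$hcount[i] <- mol_hcount(mol, i)
  }
  free <- mol_delete_atoms(mol, pat$placeholder_atoms)
  map <- attr(free, "index_map")
  anchors <- map[pat$anchors]
  if (pat$denticity == 2L) {
    d <- mol_distance(free, anchors[1], anchors[2])
    if (is.infinite(d))
      stop("validity error: kappa-2 anchors lie in disconnected parts")
    if (d == 1L) {
      # adjacent anchors: eta-2 haptic coordination; restore the pi bond
      # the two dative bonds were drawn from
      if (!all(pat$orders == 1L))
        stop("adjacency error: adjacent kappa-2 anchors with a formal ",
             "double metal bond are not a valid coordination mode")
      bidx <- mol_bond_between(free, anchors[1], anchors[2])
      for (i in anchors) free$atoms$hcount[i] <- mol_hcount(free, i) - 1L
      free$bonds$order[bidx] <- free$bonds$order[bidx] + 1L
    }
  }
  vc <- mol_valence_ok(free)
  if (!vc$ok)
    stop("validity error: decoded ligand violates valence rules at atom(s) ",
         paste(vc$bad_atoms, collapse = ", "))
  if (mol_formal_charge(free) != 0L)
    stop("charge error: decoded ligand is not neutral")
  anchored_ligand(free, anchors, pat$orders, pat$denticity)
}

#' Canonicalize an anchored SMILES string
#'
#' Idempotent: any two spellings of the same anchored ligand graph map to a
#' single representative string.
#'
#' @param s anchored-SMILES string.
#' @return canonical anchored-SMILES string.
#' @export
canonicalize_anchored <- function(s) {
  mol <- parse_smiles(as.character(s))
  out <- as.character(canonical_smiles(mol))
  ph <- mol$atoms$element[mol$atoms$element %in% PLACEHOLDER_ELEMENTS]
  attr(out, "mode") <- if ("Ir" %in% ph) 2L else if (length(ph)) 1L else NA_integer_
  class(out) <- "anchored_smiles"
  out
}

#' Generator-side validity check for anchored SMILES strings
#'
#' Used to score raw generated strings: a string is valid for a mode iff it
#' parses and its placeholder pattern matches that mode's grammar (exactly
#' one `[Li]`/`[Be]` for kappa-1; one `[Ir]` metallacycle with up to two
#' `[Be]` bridges for kappa-2).  Never throws: failures are reported as
#' `valid = FALSE` plus a reason.
#'
#' @param s character string.
#' @param mode 1 or 2 (the declared denticity).
#' @return list with elements `valid` (logical) and `reason` (character).
#' @export
check_anchor_validity <- function(s, mode) {
  mode <- as.integer(mode)
  res <- tryCatch({
    lig <- decode_anchored(s)
    if (lig$denticity == mode) list(valid = TRUE, reason = "ok")
    else list(valid = FALSE,
              reason = sprintf("kappa-%d pattern under kappa-%d mode",
                               lig$denticity, mode))
  }, error = function(e) list(valid = FALSE, reason = conditionMessage(e)))
  res
}

# structural equality of two anchored ligands: identical free-ligand graphs
# (canonical string), denticity, and anchors at equivalent positions with
# equal bond orders
anchored_equal <- function(a, b) {
  if (a$denticity != b$denticity) return(FALSE)
  ca <- as.character(canonical_smiles(a$mol))
  cb <- as.character(canonical_smiles(b$mol))
  if (!identical(ca, cb)) return(FALSE)
  rka <- canon_ranks(a$mol, symmetry = TRUE)
  rkb <- canon_ranks(b$mol, symmetry = TRUE)
  key <- function(l, rk) paste(rk[l$anchors], l$bond_orders, sep = ":", collapse = ";")
  identical(key(a, rka), key(b, rkb))
}
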