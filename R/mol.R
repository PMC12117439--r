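#' @keywords internal
"_PACKAGE"

# Internal molecular-graph container used throughout the package.
#
# Atoms: element symbol, formal charge, hcount (NA = implicit, filled from
# standard valences; an integer = explicit, as written in a bracket atom).
# Bonds: a1, a2 (atom indices), order in {1,2,3}, dative flag (0 = covalent;
# 1 = dative with a1 the donor and a2 the acceptor).  A dative bond
# contributes 0 to the donor's valence and 1 to the acceptor's, mirroring the
# lone-pair donation it represents.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
PLACEHOLDER_ELEMENTS <- c("Li", "Be", "Ir")

# standard valence alternatives for neutral atoms
STD_VALENCE <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L,
  Li = 1L, Be = 2L, Ir = 8L
)

# atoms/bonds are plain lists of parallel vectors (column access only):
# profiling showed data.frame row growth dominating decode time
mol_new <- function() {
  structure(list(
    atoms = list(element = character(), charge = integer(),
                 hcount = integer()),
    bonds = list(a1 = integer(), a2 = integer(), order = integer(),
                 dative = integer())
  ), class = "tml_mol")
}

mol_add_atom <- function(mol, element, charge = 0L, hcount = NA_integer_) {
  a <- mol$atoms
  a$element <- c(a$element, element)
  a$charge <- c(a$charge, as.integer(charge))
  a$hcount <- c(a$hcount, as.integer(hcount))
  mol$atoms <- a
  mol
}

mol_add_bond <- function(mol, a1, a2, order = 1L, dative = 0L) {
  if (a1 == a2) stop("self-bond on atom ", a1)
  if (mol_has_bond(mol, a1, a2)) stop("duplicate bond ", a1, "-", a2)
  b <- mol$bonds
  b$a1 <- c(b$a1, as.integer(a1))
  b$a2 <- c(b$a2, as.integer(a2))
  b$order <- c(b$order, as.integer(order))
  b$dative <- c(b$dative, as.integer(dative))
  mol$bonds <- b
  mol
}

mol_nbonds <- function(mol) length(mol$bonds$a1)

mol_has_bond <- function(mol, a1, a2) {
  any((mol$bonds$a1 == a1 & mol$bonds$a2 == a2) |
      (mol$bonds$a1 == a2 & mol$bonds$a2 == a1))
}

mol_natoms <- function(mol) length(mol$atoms$element)

mol_neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

mol_bonds_of <- function(mol, i) {
  which(mol$bonds$a1 == i | mol$bonds$a2 == i)
}

mol_bond_between <- function(mol, a1, a2) {
  which((mol$bonds$a1 == a1 & mol$bonds$a2 == a2) |
        (mol$bonds$a1 == a2 & mol$bonds$a2 == a1))
}

# valence used at atom i by its bonds (dative: donor side contributes 0)
mol_bond_valence <- function(mol, i) {
  b <- mol$bonds
  rows <- which(b$a1 == i | b$a2 == i)
  if (!length(rows)) return(0L)
  v <- 0L
  for (r in rows) {
    if (b$dative[r] == 1L && b$a1[r] == i) next  # donor: no valence cost
    v <- v + b$order[r]
  }
  v
}

allowed_valences <- function(element, charge = 0L) {
  base <- STD_VALENCE[[element]]
  if (is.null(base)) return(integer(0))
  if (charge != 0L && element %in% c("C", "N", "O", "P", "S", "B")) {
    # charged atoms shift their valence; anions are additionally allowed the
    # raised alternative so that erroneously charged hypervalent records
    # (e.g. anionic pentavalent P) still parse and can be filtered out
    base <- sort(unique(c(base + charge, base - charge)))
    base <- base[base >= 0L]
  }
  base
}

# implicit H count; explicit hcount wins, non-organic-subset atoms get 0
mol_hcount <- function(mol, i) {
  h <- mol$atoms$hcount[i]
  if (!is.na(h)) return(h)
  el <- mol$atoms$element[i]
  if (!el %in% ORGANIC_SUBSET) return(0L)
  used <- mol_bond_valence(mol, i)
  vals <- allowed_valences(el, mol$atoms$charge[i])
  fit <- vals[vals >= used]
  if (!length(fit)) return(0L)
  min(fit) - used
}

# total valence check: every atom's bonds + hydrogens must fit an allowed
# valence of its element/charge
mol_valence_ok <- function(mol) {
  bad <- integer(0)
  for (i in seq_len(mol_natoms(mol))) {
    el <- mol$atoms$element[i]
    vals <- allowed_valences(el, mol$atoms$charge[i])
    if (!length(vals)) { bad <- c(bad, i); next }
    tot <- mol_bond_valence(mol, i) + mol_hcount(mol, i)
    if (el == "Ir") { if (tot > max(vals)) bad <- c(bad, i); next }
    if (!tot %in% vals && tot > max(vals)) bad <- c(bad, i)
  }
  list(ok = !length(bad), bad_atoms = bad)
}

mol_formal_charge <- function(mol) sum(mol$atoms$charge)

mol_heavy_atoms <- function(mol, exclude_placeholders = TRUE) {
  el <- mol$atoms$element
  keep <- el != "H"
  if (exclude_placeholders) keep <- keep & !el %in% PLACEHOLDER_ELEMENTS
  which(keep)
}

# connected components over atoms
mol_fragments <- function(mol) {
  n <- mol_natoms(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      a <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[a] != 0L) next
      comp[a] <- cur
      stack <- c(stack, mol_neighbors(mol, a))
    }
  }
  comp
}

mol_is_connected <- function(mol) {
  n <- mol_natoms(mol)
  n <= 1L || all(mol_fragments(mol) == 1L)
}

# delete atoms (and incident bonds), remapping indices; returns new mol with
# attr "index_map" old -> new (NA for removed)
mol_delete_atoms <- function(mol, idx) {
  n <- mol_natoms(mol)
  keep <- setdiff(seq_len(n), idx)
  map <- rep(NA_integer_, n)
  map[keep] <- seq_along(keep)
  out <- mol
  out$atoms <- lapply(mol$atoms, `[`, keep)
  b <- mol$bonds
  bkeep <- !(b$a1 %in% idx | b$a2 %in% idx)
  b <- lapply(b, `[`, bkeep)
  b$a1 <- map[b$a1]
  b$a2 <- map[b$a2]
  out$bonds <- b
  attr(out, "index_map") <- map
  out
}

# induced subgraph on atom set `idx` (bonds among them only);
# attr "index_map" maps old -> new
mol_subgraph <- function(mol, idx) {
  mol_delete_atoms(mol, setdiff(seq_len(mol_natoms(mol)), idx))
}

# shortest path length between two atoms (bond count), Inf if disconnected
mol_distance <- function(mol, from, to) {
  if (from == to) return(0L)
  dist <- rep(NA_integer_, mol_natoms(mol))
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    a <- queue[[1]]
    queue <- queue[-1]
    for (nb in mol_neighbors(mol, a)) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[a] + 1L
        if (nb == to) return(dist[nb])
        queue <- c(queue, nb)
      }
    }
  }
  Inf
}

# molecular formula-ish summary, used in a few reports
mol_element_counts <- function(mol, heavy_only = TRUE) {
  el <- mol$atoms$element
  if (heavy_only) el <- el[el != "H"]
  table(el)
}
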