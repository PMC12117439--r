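# Canonical atom ranking by iterative invariant refinement (Morgan/CANGEN
# style).  Initial invariants: element, degree, charge, total H count and the
# multiset of incident bond codes (order + dative role).  Refinement folds in
# sorted neighbor ranks until the partition stabilizes; remaining ties are
# broken one class at a time followed by re-refinement.  Tied atoms that
# survive refinement are treated as symmetry-equivalent, which holds for the
# ligand chemistry this package generates.

canon_ranks <- function(mol, symmetry = FALSE) {
  n <- mol_natoms(mol)
  if (n == 1L) return(1L)

  bond_code <- function(bidx, at) {
    if (mol$bonds$dative[bidx] == 1L) {
      if (mol$bonds$a1[bidx] == at) "D>" else "D<"
    } else as.character(mol$bonds$order[bidx])
  }

  inv <- vapply(seq_len(n), function(i) {
    codes <- sort(vapply(mol_bonds_of(mol, i), bond_code, "", at = i))
    paste(mol$atoms$element[i], length(codes), mol$atoms$charge[i],
          mol_hcount(mol, i), paste(codes, collapse = ","), sep = "|")
  }, "")
  ranks <- match(inv, sort(unique(inv)))

  refine <- function(ranks) {
    repeat {
      sig <- vapply(seq_len(n), function(i) {
        bidx <- mol_bonds_of(mol, i)
        nb <- ifelse(mol$bonds$a1[bidx] == i, mol$bonds$a2[bidx], mol$bonds$a1[bidx])
        codes <- vapply(seq_along(bidx), function(k)
          sprintf("%05d%s", ranks[nb[k]], bond_code(bidx[k], i)), "")
        paste0(sprintf("%05d", ranks[i]), "/", paste(sort(codes), collapse = ";"))
      }, "")
      new_ranks <- match(sig, sort(unique(sig)))
      if (identical(new_ranks, ranks)) return(ranks)
      ranks <- new_ranks
    }
  }

  ranks <- refine(ranks)
  if (symmetry) return(ranks)  # refinement-only ranks = symmetry classes
  # tie-breaking: split the lowest tied class and re-refine
  repeat {
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1L])
    if (!length(tied)) break
    cls <- which(ranks == min(tied))
    pick <- cls[1L]
    ranks <- ranks * 2L
    ranks[pick] <- ranks[pick] - 1L
    ranks <- match(ranks, sort(unique(ranks)))
    ranks <- refine(ranks)
  }
  ranks
}

# canonical SMILES: rank-driven deterministic traversal
canonical_smiles <- function(mol) {
  write_smiles(mol, ranks = canon_ranks(mol))
}
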