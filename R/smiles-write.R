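# SMILES writer.  Emits Kekulé SMILES in the package dialect (ASCII dative
# tokens, bracket atoms for placeholders / explicit-H atoms / charges).
# With `ranks` supplied the traversal is fully determined by them, which is
# how canonical output is produced; without, input atom order is used, which
# keeps atom order stable for downstream coordinate mapping.

write_smiles <- function(mol, ranks = NULL) {
  n <- mol_natoms(mol)
  if (!n) stop("empty molecule")
  if (is.null(ranks)) ranks <- seq_len(n)

  frag_id <- mol_fragments(mol)
  nfrag <- max(frag_id)

  ring_digit <- 0L
  pieces <- character(nfrag)
  emit_order <- integer(0)

  atom_token <- function(i) {
    el <- mol$atoms$element[i]
    ch <- mol$atoms$charge[i]
    hc <- mol$atoms$hcount[i]
    # normalize: an explicit H count equal to the implicit one is dropped
    if (!is.na(hc) && el %in% ORGANIC_SUBSET && ch == 0L) {
      tmp <- mol
      tmp$atoms$hcount[i] <- NA_integer_
      if (mol_hcount(tmp, i) == hc) hc <- NA_integer_
    }
    plain <- el %in% ORGANIC_SUBSET && ch == 0L && is.na(hc)
    if (plain) return(el)
    h <- if (is.na(hc)) mol_hcount(mol, i) else hc
    hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    cstr <- ""
    if (ch > 0L) cstr <- if (ch == 1L) "+" else paste0("+", ch)
    if (ch < 0L) cstr <- if (ch == -1L) "-" else paste0("-", abs(ch))
    paste0("[", el, hstr, cstr, "]")
  }

  bond_token <- function(bidx, from) {
    if (mol$bonds$dative[bidx] == 1L)
      return(if (mol$bonds$a1[bidx] == from) "->" else "<-")
    switch(mol$bonds$order[bidx], "", "=", "#")
  }

  for (f in seq_len(nfrag)) {
    atoms_f <- which(frag_id == f)
    root <- atoms_f[which.min(ranks[atoms_f])]
    visited <- rep(FALSE, n)
    closure_at <- vector("list", n)   # atom -> list of (digit, bond token)
    opened <- new.env(parent = emptyenv())

    # first pass: recursive DFS in rank order fixing tree edges and ring
    # closures (each non-tree bond becomes exactly one digit pair)
    dfs_children <- vector("list", n)
    used_bond <- rep(FALSE, mol_nbonds(mol))
    dfs1 <- function(a) {
      visited[a] <<- TRUE
      nbs <- mol_bonds_of(mol, a)
      nb_atoms <- ifelse(mol$bonds$a1[nbs] == a, mol$bonds$a2[nbs], mol$bonds$a1[nbs])
      ord <- order(ranks[nb_atoms])
      nbs <- nbs[ord]; nb_atoms <- nb_atoms[ord]
      for (k in seq_along(nbs)) {
        if (used_bond[nbs[k]]) next
        if (visited[nb_atoms[k]]) {
          used_bond[nbs[k]] <<- TRUE
          ring_digit <<- ring_digit + 1L
          dig <- if (ring_digit <= 9L) as.character(ring_digit) else
            sprintf("%%%02d", ring_digit)
          # open at the earlier-visited atom (carrying the bond token),
          # close with a bare digit at the current atom
          closure_at[[nb_atoms[k]]] <<- c(closure_at[[nb_atoms[k]]],
            list(list(digit = dig, token = bond_token(nbs[k], nb_atoms[k]))))
          closure_at[[a]] <<- c(closure_at[[a]],
            list(list(digit = dig, token = "")))
        } else {
          used_bond[nbs[k]] <<- TRUE
          dfs_children[[a]] <<- c(dfs_children[[a]],
                                  list(list(atom = nb_atoms[k], bond = nbs[k])))
          dfs1(nb_atoms[k])
        }
      }
    }
    dfs1(root)

    write_atom <- function(a, in_bond) {
      out <- if (is.na(in_bond)) "" else {
        p <- if (mol$bonds$a1[in_bond] == a) mol$bonds$a2[in_bond] else mol$bonds$a1[in_bond]
        bond_token(in_bond, p)
      }
      out <- paste0(out, atom_token(a))
      emit_order <<- c(emit_order, a)
      for (cl in closure_at[[a]]) out <- paste0(out, cl$token, cl$digit)
      kids <- dfs_children[[a]]
      if (length(kids)) {
        kids <- kids[order(vapply(kids, function(k) ranks[k$atom], numeric(1)))]
        for (k in seq_along(kids)) {
          sub <- write_atom(kids[[k]]$atom, kids[[k]]$bond)
          if (k < length(kids)) sub <- paste0("(", sub, ")")
          out <- paste0(out, sub)
        }
      }
      out
    }
    pieces[f] <- write_atom(root, NA_integer_)
  }

  ord <- order(pieces)
  out <- paste(pieces[ord], collapse = ".")
  attr(out, "atom_order") <- emit_order
  out
}
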