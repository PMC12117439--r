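# Ring perception: smallest set of smallest rings, found per ring bond via
# BFS for the shortest cycle through that bond.  Adequate for the ligand
# chemistry handled here (small mono- and fused bicyclic systems).

# all bonds that lie on some cycle (bridges removed by DFS low-link)
ring_bonds <- function(mol) {
  n <- mol_natoms(mol)
  nb <- lapply(seq_len(n), function(i) mol_bonds_of(mol, i))
  disc <- rep(0L, n); low <- rep(0L, n); timer <- 0L
  is_bridge <- rep(FALSE, mol_nbonds(mol))
  dfs <- function(a, via) {
    timer <<- timer + 1L
    disc[a] <<- low[a] <<- timer
    for (bidx in nb[[a]]) {
      if (!is.na(via) && bidx == via) next
      b <- if (mol$bonds$a1[bidx] == a) mol$bonds$a2[bidx] else mol$bonds$a1[bidx]
      if (disc[b] == 0L) {
        dfs(b, bidx)
        low[a] <<- min(low[a], low[b])
        if (low[b] > disc[a]) is_bridge[bidx] <<- TRUE
      } else {
        low[a] <<- min(low[a], disc[b])
      }
    }
  }
  for (s in seq_len(n)) if (disc[s] == 0L) dfs(s, NA_integer_)
  which(!is_bridge)
}

# list of rings, each an integer vector of atom indices in ring order
find_rings <- function(mol) {
  rb <- ring_bonds(mol)
  if (!length(rb)) return(list())
  rings <- list()
  seen <- character(0)
  for (bidx in rb) {
    u <- mol$bonds$a1[bidx]; v <- mol$bonds$a2[bidx]
    # shortest u..v path avoiding this bond
    n <- mol_natoms(mol)
    prev <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
    dist[u] <- 0L; queue <- u
    while (length(queue) && is.na(dist[v])) {
      a <- queue[[1]]; queue <- queue[-1]
      for (b2 in mol_bonds_of(mol, a)) {
        if (b2 == bidx) next
        b <- if (mol$bonds$a1[b2] == a) mol$bonds$a2[b2] else mol$bonds$a1[b2]
        if (is.na(dist[b])) {
          dist[b] <- dist[a] + 1L; prev[b] <- a
          queue <- c(queue, b)
        }
      }
    }
    if (is.na(dist[v])) next
    path <- v
    while (path[1] != u) path <- c(prev[path[1]], path)
    key <- paste(sort(path), collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
  }
  # keep smallest rings: drop any ring whose atom set contains another ring's
  keep <- rep(TRUE, length(rings))
  for (i in seq_along(rings)) for (j in seq_along(rings)) {
    if (i != j && keep[i] && keep[j] &&
        length(rings[[j]]) < length(rings[[i]]) &&
        all(rings[[j]] %in% rings[[i]])) keep[i] <- FALSE
  }
  rings[keep]
}
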