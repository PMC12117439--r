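# Independent oracles used by the tests.  These deliberately avoid the
# package's canonicalization / decomposition machinery so they can serve as
# cross-checks for it.

# molecule accessors via exported decode (tests treat molecules as opaque
# otherwise); a tiny adjacency view for the oracles
oracle_graph <- function(lig) {
  mol <- lig$mol
  n <- length(mol$atoms$element)
  adj <- matrix(0L, n, n)
  for (k in seq_along(mol$bonds$a1)) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    code <- mol$bonds$order[k] + 10L * mol$bonds$dative[k]
    adj[i, j] <- code
    adj[j, i] <- if (mol$bonds$dative[k] == 1L) code + 100L else code
  }
  list(n = n, el = mol$atoms$element, ch = mol$atoms$charge,
       hc = vapply(seq_len(n), function(i) tmligen:::mol_hcount(mol, i), 0L),
       adj = adj)
}

# backtracking graph isomorphism with anchor correspondence
graphs_isomorphic <- function(liga, ligb) {
  ga <- oracle_graph(liga); gb <- oracle_graph(ligb)
  if (ga$n != gb$n) return(FALSE)
  if (liga$denticity != ligb$denticity) return(FALSE)
  anch_a <- rep(0L, ga$n); anch_a[liga$anchors] <- liga$bond_orders
  anch_b <- rep(0L, gb$n); anch_b[ligb$anchors] <- ligb$bond_orders
  n <- ga$n
  used <- rep(FALSE, n)
  map <- rep(NA_integer_, n)
  compat <- function(i, j) {
    ga$el[i] == gb$el[j] && ga$ch[i] == gb$ch[j] && ga$hc[i] == gb$hc[j] &&
      anch_a[i] == anch_b[j] &&
      sum(ga$adj[i, ] > 0) == sum(gb$adj[j, ] > 0)
  }
  bt <- function(i) {
    if (i > n) return(TRUE)
    for (j in which(!used)) {
      if (!compat(i, j)) next
      ok <- TRUE
      for (i2 in seq_len(i - 1L)) {
        if (ga$adj[i, i2] != gb$adj[j, map[i2]]) { ok <- FALSE; break }
      }
      if (!ok) next
      used[j] <<- TRUE; map[i] <<- j
      if (bt(i + 1L)) return(TRUE)
      used[j] <<- FALSE; map[i] <<- NA_integer_
    }
    FALSE
  }
  bt(1L)
}

# brute-force enumeration of all simple cycles up to the molecule size
# (DFS from every atom), reduced to the set of minimal cycles; used to check
# ring perception on molecules <= 20 atoms
enumerate_simple_cycles <- function(lig_or_mol) {
  mol <- if (!is.null(lig_or_mol$mol)) lig_or_mol$mol else lig_or_mol
  n <- length(mol$atoms$element)
  nbrs <- lapply(seq_len(n), function(i)
    c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i]))
  cycles <- list()
  seen <- character(0)
  path <- integer(0)
  dfs <- function(start, v) {
    path <<- c(path, v)
    for (w in nbrs[[v]]) {
      if (w == start && length(path) >= 3L) {
        key <- paste(sort(path), collapse = ",")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- sort(path)
        }
      } else if (!w %in% path && w > start) {
        dfs(start, w)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  cycles
}

# oracle check of the smallest-ring perception: every perceived ring is a
# genuine simple cycle; every cycle bond is covered; and for each cycle bond
# the smallest perceived ring through it has the length of the shortest
# brute-force cycle through it
ring_perception_consistent <- function(mol) {
  all_cycles <- enumerate_simple_cycles(mol)
  got <- lapply(tmligen:::find_rings(mol), sort)
  keys <- vapply(all_cycles, paste, "", collapse = ",")
  if (!all(vapply(got, paste, "", collapse = ",") %in% keys)) return(FALSE)
  nb <- length(mol$bonds$a1)
  for (k in seq_len(nb)) {
    u <- mol$bonds$a1[k]; v <- mol$bonds$a2[k]
    inc <- function(set) u %in% set && v %in% set
    cyc_lens <- vapply(all_cycles[vapply(all_cycles, inc, TRUE)], length, 0L)
    got_lens <- vapply(got[vapply(got, inc, TRUE)], length, 0L)
    if (!length(cyc_lens)) {
      if (length(got_lens)) return(FALSE)
      next
    }
    if (!length(got_lens)) return(FALSE)
    if (min(got_lens) != min(cyc_lens)) return(FALSE)
  }
  TRUE
}

# brute-force Tanimoto from raw bit vectors
tanimoto_brute <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (k in seq_along(a)) {
    if (a[k] && b[k]) inter <- inter + 1L
    if (a[k] || b[k]) uni <- uni + 1L
  }
  if (uni == 0L) 0 else inter / uni
}

# brute-force diversity statistics by explicit double loops
diversity_brute <- function(smiles_vec) {
  fps <- lapply(smiles_vec, function(s)
    morgan_fingerprint(decode_anchored(s)$mol))
  n <- length(fps)
  s_pairs <- c(); s_sq <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tc <- tanimoto_brute(fps[[i]], fps[[j]])
    s_sq <- s_sq + tc^2
    if (j > i) s_pairs <- c(s_pairs, tc)
  }
  list(avg_tanimoto = mean(s_pairs), intdiv2 = 1 - sqrt(s_sq / n^2))
}
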