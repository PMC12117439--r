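# Junction-tree decomposition of molecular graphs and the fragment token
# serialization the generative model is trained on.
#
# Clusters are simple rings (rings sharing >= 3 atoms merged), non-ring
# bonds, and singleton atoms wherever an atom belongs to >= 3 clusters.
# Cluster-graph edges connect clusters sharing atoms; the junction tree is
# a maximum-spanning tree over shared-atom counts with deterministic
# label-based tie-breaking.  Placeholder atoms and dative bonds live inside
# clusters like ordinary atoms and bonds, which is what makes metal
# coordination learnable by the model.

#' Junction-tree decomposition of a molecule
#'
#' @param mol molecule (`tml_mol`), anchored-SMILES string, or
#'   [anchored_ligand()] (decomposed with its placeholders attached).
#' @return object of class `junction_tree`: list of clusters (each with
#'   `atoms`, `kind`, `label`, `slot_of` mapping molecule atom -> label slot),
#'   `edges` (data.frame from, to), and `root` cluster index.
#' @export
tree_decompose <- function(mol) {
  if (inherits(mol, "anchored_ligand")) mol <- parse_smiles(encode_anchored(mol))
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (!mol_is_connected(mol)) stop("tree_decompose requires a connected molecule")
  n <- mol_natoms(mol)

  rings <- find_rings(mol)
  # merge rings sharing >= 3 atoms (bridged systems) into one cluster
  if (length(rings) > 1L) {
    repeat {
      merged <- FALSE
      for (i in seq_along(rings)) {
        for (j in seq_along(rings)) {
          if (j <= i) next
          if (length(intersect(rings[[i]], rings[[j]])) >= 3L) {
            rings[[i]] <- union(rings[[i]], rings[[j]])
            rings[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  ring_sets <- lapply(rings, sort)

  in_ring_bond <- rep(FALSE, mol_nbonds(mol))
  for (rs in ring_sets) {
    hit <- mol$bonds$a1 %in% rs & mol$bonds$a2 %in% rs
    in_ring_bond <- in_ring_bond | hit
  }
  clusters <- c(
    lapply(ring_sets, function(a) list(atoms = a, kind = "ring")),
    lapply(which(!in_ring_bond), function(b)
      list(atoms = sort(c(mol$bonds$a1[b], mol$bonds$a2[b])), kind = "bond"))
  )
  if (!length(clusters) && n == 1L)
    clusters <- list(list(atoms = 1L, kind = "atom"))

  # singleton clusters for atoms in >= 3 clusters
  membership <- lapply(seq_len(n), function(i)
    which(vapply(clusters, function(cl) i %in% cl$atoms, TRUE)))
  for (i in seq_len(n)) {
    if (length(membership[[i]]) >= 3L)
      clusters[[length(clusters) + 1L]] <- list(atoms = i, kind = "atom")
  }

  # labels and slot maps
  for (k in seq_along(clusters)) {
    lab <- cluster_label(mol, clusters[[k]]$atoms)
    clusters[[k]]$label <- lab$label
    clusters[[k]]$slot_of <- lab$slot_of
  }

  # cluster graph: edges between clusters sharing atoms, weight = #shared
  nc <- length(clusters)
  cand <- data.frame(i = integer(), j = integer(), w = integer())
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (j <= i) next
    w <- length(intersect(clusters[[i]]$atoms, clusters[[j]]$atoms))
    if (w > 0L) cand <- rbind(cand, data.frame(i = i, j = j, w = w))
  }
  edges <- data.frame(from = integer(), to = integer())
  if (nc > 1L) {
    # singleton-atom clusters bind their incident clusters tightly
    kindw <- vapply(clusters, function(cl) if (cl$kind == "atom") 10L else 0L, 0L)
    cand$wt <- cand$w + pmax(kindw[cand$i], kindw[cand$j])
    key <- paste(vapply(cand$i, function(k) clusters[[k]]$label, ""),
                 vapply(cand$j, function(k) clusters[[k]]$label, ""))
    cand <- cand[order(-cand$wt, key), , drop = FALSE]
    comp <- seq_len(nc)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (r in seq_len(nrow(cand))) {
      ri <- find(cand$i[r]); rj <- find(cand$j[r])
      if (ri != rj) {
        comp[ri] <- rj
        edges <- rbind(edges, data.frame(from = cand$i[r], to = cand$j[r]))
      }
    }
    roots <- unique(vapply(seq_len(nc), find, 0L))
    if (length(roots) != 1L)
      stop("cluster graph is disconnected; decomposition failed")
  }

  root <- pick_root(mol, clusters)
  structure(list(mol = mol, clusters = clusters, edges = edges, root = root),
            class = "junction_tree")
}

# label = canonical SMILES of the induced fragment; slot_of maps molecule
# atom index -> position in the label's atom order
cluster_label <- function(mol, atoms) {
  frag <- mol_subgraph(mol, atoms)
  map <- attr(frag, "index_map")     # old -> new
  # hydrogens are not part of cluster identity: recompute within fragment
  org <- frag$atoms$element %in% ORGANIC_SUBSET
  frag$atoms$hcount[org] <- NA_integer_
  smi <- canonical_smiles(frag)
  emit <- attr(smi, "atom_order")    # emission position -> frag index
  slot_of <- rep(NA_integer_, mol_natoms(mol))
  for (pos in seq_along(emit)) {
    old <- which(map == emit[pos])
    slot_of[old] <- pos
  }
  list(label = as.character(smi), slot_of = slot_of)
}

# root: the cluster holding the highest-priority placeholder, else the
# lexicographically smallest label (deterministic)
pick_root <- function(mol, clusters) {
  pri <- c(Ir = 3L, Li = 2L, Be = 1L)
  best <- 0L; best_p <- -1L; best_lab <- ""
  for (k in seq_along(clusters)) {
    els <- mol$atoms$element[clusters[[k]]$atoms]
    p <- max(c(pri[els], 0L), na.rm = TRUE)
    lab <- clusters[[k]]$label
    if (p > best_p || (p == best_p && (best == 0L || lab < best_lab))) {
      best <- k; best_p <- p; best_lab <- lab
    }
  }
  best
}

#' Audit a junction tree against its molecule
#'
#' Checks the structural invariants: atom cover, bond cover, connectivity and
#' acyclicity of the cluster tree.
#'
#' @param jt a `junction_tree`.
#' @return list of logical checks.
#' @export
jtree_audit <- function(jt) {
  mol <- jt$mol
  atoms_cov <- sort(unique(unlist(lapply(jt$clusters, `[[`, "atoms"))))
  cover_atoms <- identical(atoms_cov, seq_len(mol_natoms(mol)))
  cover_bonds <- all(vapply(seq_len(mol_nbonds(mol)), function(b) {
    any(vapply(jt$clusters, function(cl)
      mol$bonds$a1[b] %in% cl$atoms && mol$bonds$a2[b] %in% cl$atoms, TRUE))
  }, TRUE))
  nc <- length(jt$clusters)
  acyclic <- nrow(jt$edges) == nc - 1L
  # connectivity via union-find over edges
  comp <- seq_len(nc)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (nrow(jt$edges)) for (r in seq_len(nrow(jt$edges)))
    comp[find(jt$edges$from[r])] <- find(jt$edges$to[r])
  connected <- length(unique(vapply(seq_len(nc), find, 0L))) == 1L
  list(cover_atoms = cover_atoms, cover_bonds = cover_bonds,
       connected = connected, acyclic = acyclic,
       ok = cover_atoms && cover_bonds && connected && acyclic)
}

# ---- serialization ----------------------------------------------------------

# DFS token stream: "R|<label>" root, "D|<label>|<pslots>|<cslots>" child
# attachment (slots comma-separated, aligned), "U" pop, "E" end.
jtree_serialize <- function(jt) {
  nc <- length(jt$clusters)
  adj <- vector("list", nc)
  if (nrow(jt$edges)) for (r in seq_len(nrow(jt$edges))) {
    adj[[jt$edges$from[r]]] <- c(adj[[jt$edges$from[r]]], jt$edges$to[r])
    adj[[jt$edges$to[r]]] <- c(adj[[jt$edges$to[r]]], jt$edges$from[r])
  }
  tokens <- character(0)
  visit <- function(k, parent) {
    if (is.na(parent)) {
      tokens <<- c(tokens, paste0("R|", jt$clusters[[k]]$label))
    } else {
      shared <- intersect(jt$clusters[[parent]]$atoms, jt$clusters[[k]]$atoms)
      ps <- jt$clusters[[parent]]$slot_of[shared]
      cs <- jt$clusters[[k]]$slot_of[shared]
      ord <- order(ps)
      tokens <<- c(tokens, paste0("D|", jt$clusters[[k]]$label, "|",
                                  paste(ps[ord], collapse = ","), "|",
                                  paste(cs[ord], collapse = ",")))
    }
    kids <- setdiff(adj[[k]], parent)
    if (length(kids)) {
      keys <- vapply(kids, function(j) {
        shared <- intersect(jt$clusters[[k]]$atoms, jt$clusters[[j]]$atoms)
        sprintf("%04d|%s", min(jt$clusters[[k]]$slot_of[shared]),
                jt$clusters[[j]]$label)
      }, "")
      kids <- kids[order(keys)]
      for (j in kids) {
        visit(j, k)
        tokens <<- c(tokens, "U")
      }
    }
  }
  visit(jt$root, NA_integer_)
  c(tokens, "E")
}

# ---- assembly ---------------------------------------------------------------

# incremental assembly state for decoding token streams back into molecules;
# used both for exact reconstruction and for masked sampling
assembly_new <- function() {
  list(mol = mol_new(), stack = list(), done = FALSE)
}

parse_token <- function(tok) {
  parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
  if (parts[1] == "R") list(type = "R", label = parts[2])
  else if (parts[1] == "D")
    list(type = "D", label = parts[2],
         ps = as.integer(strsplit(parts[3], ",")[[1]]),
         cs = as.integer(strsplit(parts[4], ",")[[1]]))
  else if (parts[1] == "U") list(type = "U")
  else if (parts[1] == "E") list(type = "E")
  else stop("bad token: ", tok)
}

# fragment cache: label -> list(mol, natoms) in emission order
.frag_cache <- new.env(parent = emptyenv())

# labels are canonical strings, so atom appearance order in the label equals
# the emission (slot) order used by cluster_label: re-parsing gives the
# fragment directly in slot order
fragment_of_label <- function(label) {
  hit <- .frag_cache[[label]]
  if (!is.null(hit)) return(hit)
  frag <- parse_smiles(label)
  .frag_cache[[label]] <- frag
  frag
}

# try to apply one token; returns updated state or (on chemistry/grammar
# violation) NULL
assembly_step <- function(st, tok) {
  t <- parse_token(tok)
  if (t$type == "E") {
    if (length(st$stack) != 1L || st$done) return(NULL)
    st$done <- TRUE
    return(st)
  }
  if (t$type == "U") {
    if (length(st$stack) <= 1L) return(NULL)
    st$stack <- st$stack[-length(st$stack)]
    return(st)
  }
  if (t$type == "R") {
    if (length(st$stack)) return(NULL)
    frag <- fragment_of_label(t$label)
    st$mol <- frag
    st$stack <- list(list(label = t$label, atoms = seq_len(mol_natoms(frag))))
    return(st)
  }
  # DOWN
  if (!length(st$stack)) return(NULL)
  top <- st$stack[[length(st$stack)]]
  frag <- fragment_of_label(t$label)
  nf <- mol_natoms(frag)
  if (any(t$ps > length(top$atoms)) || any(t$ps < 1L)) return(NULL)
  if (any(t$cs > nf) || any(t$cs < 1L)) return(NULL)
  if (length(t$ps) != length(t$cs) || !length(t$ps)) return(NULL)
  tgt <- top$atoms[t$ps]
  # shared atoms must agree in element and charge
  for (k in seq_along(t$cs)) {
    if (st$mol$atoms$element[tgt[k]] != frag$atoms$element[t$cs[k]]) return(NULL)
    if (st$mol$atoms$charge[tgt[k]] != frag$atoms$charge[t$cs[k]]) return(NULL)
  }
  mol <- st$mol
  new_idx <- rep(NA_integer_, nf)
  new_idx[t$cs] <- tgt
  for (a in seq_len(nf)) {
    if (!is.na(new_idx[a])) next
    mol <- mol_add_atom(mol, frag$atoms$element[a], frag$atoms$charge[a],
                        frag$atoms$hcount[a])
    new_idx[a] <- mol_natoms(mol)
  }
  for (b in seq_len(mol_nbonds(frag))) {
    u <- new_idx[frag$bonds$a1[b]]; v <- new_idx[frag$bonds$a2[b]]
    ex <- mol_bond_between(mol, u, v)
    if (length(ex)) {
      # both shared: the bond already exists and must match
      if (mol$bonds$order[ex] != frag$bonds$order[b] ||
          mol$bonds$dative[ex] != frag$bonds$dative[b]) return(NULL)
      next
    }
    mol <- tryCatch(mol_add_bond(mol, u, v, frag$bonds$order[b],
                                 frag$bonds$dative[b]),
                    error = function(e) NULL)
    if (is.null(mol)) return(NULL)
  }
  # valence feasibility on the merged atoms
  for (a in unique(tgt)) {
    el <- mol$atoms$element[a]
    vals <- allowed_valences(el, mol$atoms$charge[a])
    if (!length(vals)) return(NULL)
    if (mol_bond_valence(mol, a) > max(vals)) return(NULL)
  }
  st$mol <- mol
  st$stack <- c(st$stack, list(list(label = t$label, atoms = new_idx)))
  st
}

# full decode: token stream -> molecule (NULL if infeasible)
assemble_tokens <- function(tokens) {
  st <- assembly_new()
  for (tok in tokens) {
    st <- assembly_step(st, tok)
    if (is.null(st)) return(NULL)
  }
  if (!st$done) return(NULL)
  vc <- mol_valence_ok(st$mol)
  if (!vc$ok) return(NULL)
  st$mol
}
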