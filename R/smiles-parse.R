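# SMILES subset parser.
#
# Supported dialect: Kekulé SMILES over H/B/C/N/O/F/P/S/Cl/Br/I plus bracket
# atoms (element, explicit H count, formal charge), branches, ring-bond
# closures (1-9 and %nn), multi-fragment '.', bond orders -/=/# and the
# dative-bond tokens "->" / "<-" (unicode arrows accepted on input).
# Aromatic (lowercase) atoms and bonds are rejected: the package reads and
# writes kekulized structures only.

parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("SMILES must be a single character string")
  s <- gsub("→", "->", text, fixed = TRUE)
  s <- gsub("←", "<-", s, fixed = TRUE)
  s <- gsub("\\s+", "", s)
  if (!nchar(s)) stop("empty SMILES")

  mol <- mol_new()
  prev <- NA_integer_          # previous atom index
  stack <- integer(0)          # branch stack
  pend_order <- NA_integer_    # pending bond order
  pend_dat <- 0L               # 0 none, +1 prev donates, -1 next donates
  rings <- list()              # digit -> list(atom, order, dat)

  i <- 1L
  n <- nchar(s)
  two_el <- c("Cl", "Br")

  take_bond <- function() {
    spec <- !is.na(pend_order) || pend_dat != 0L
    o <- if (is.na(pend_order)) 1L else pend_order
    d <- pend_dat
    pend_order <<- NA_integer_
    pend_dat <<- 0L
    list(order = o, dat = d, spec = spec)
  }

  add_atom_here <- function(element, charge, hcount) {
    mol <<- mol_add_atom(mol, element, charge, hcount)
    idx <- mol_natoms(mol)
    if (!is.na(prev)) {
      b <- take_bond()
      if (b$dat == -1L) {
        mol <<- mol_add_bond(mol, idx, prev, 1L, 1L)
      } else if (b$dat == 1L) {
        mol <<- mol_add_bond(mol, prev, idx, 1L, 1L)
      } else {
        mol <<- mol_add_bond(mol, prev, idx, b$order, 0L)
      }
    } else {
      # leading bond token before first atom of a fragment is invalid
      if (!is.na(pend_order) || pend_dat != 0L)
        stop("bond token with no preceding atom at position ", i)
    }
    prev <<- idx
  }

  close_ring <- function(digit) {
    b <- take_bond()
    key <- as.character(digit)
    if (is.na(prev)) stop("ring-closure digit with no preceding atom")
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, order_spec = b$spec,
                            order_val = b$order, dat = b$dat)
    } else {
      op <- rings[[key]]
      rings[[key]] <<- NULL
      a_open <- op$atom
      a_close <- prev
      if (a_open == a_close) stop("ring closure to same atom")
      # reconcile bond specs given at either site
      order <- 1L; dat <- 0L
      open_spec <- op$order_spec
      close_spec <- b$spec
      if (open_spec && close_spec) {
        if (op$order_val != b$order) stop("conflicting ring-bond orders for digit ", key)
        # arrows: open-site arrow is relative to opening atom, close-site to
        # closing atom; "A->1 ... B<-1" both mean A donates to B
        if (op$dat != 0L || b$dat != 0L) {
          if (op$dat != 0L && b$dat != 0L && op$dat != -b$dat)
            stop("conflicting dative ring-bond direction for digit ", key)
          dat <- if (op$dat != 0L) op$dat else -b$dat
        }
        order <- op$order_val
      } else if (open_spec) {
        order <- op$order_val; dat <- op$dat
      } else if (close_spec) {
        order <- b$order; dat <- -b$dat
      }
      if (dat == 1L) {        # opening atom donates to closing atom
        mol <<- mol_add_bond(mol, a_open, a_close, 1L, 1L)
      } else if (dat == -1L) {
        mol <<- mol_add_bond(mol, a_close, a_open, 1L, 1L)
      } else {
        mol <<- mol_add_bond(mol, a_open, a_close, order, 0L)
      }
    }
  }

  while (i <= n) {
    ch <- substr(s, i, i)
    ch2 <- if (i < n) substr(s, i, i + 1L) else ""

    if (ch2 == "->") { pend_dat <- 1L; pend_order <- 1L; i <- i + 2L; next }
    if (ch2 == "<-") { pend_dat <- -1L; pend_order <- 1L; i <- i + 2L; next }
    if (ch == "-") { pend_order <- 1L; i <- i + 1L; next }
    if (ch == "=") { pend_order <- 2L; i <- i + 1L; next }
    if (ch == "#") { pend_order <- 3L; i <- i + 1L; next }
    if (ch == ":") stop("aromatic bonds not supported; supply a Kekulé SMILES")
    if (ch %in% c("/", "\\")) { i <- i + 1L; next }  # E/Z marks ignored
    if (ch == "(") {
      if (is.na(prev)) stop("branch open with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (!length(stack)) stop("unmatched ')'")
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch == ".") {
      if (!is.na(pend_order) || pend_dat != 0L) stop("bond token before '.'")
      prev <- NA_integer_; i <- i + 1L; next
    }
    if (grepl("^[0-9]$", ch)) { close_ring(ch); i <- i + 1L; next }
    if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure")
      dd <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", dd)) stop("malformed %nn ring closure")
      close_ring(dd); i <- i + 3L; next
    }
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0L) stop("unclosed bracket atom")
      body <- substr(s, i + 1L, i + j - 2L)
      at <- parse_bracket_atom(body)
      add_atom_here(at$element, at$charge, at$hcount)
      i <- i + j; next
    }
    if (ch2 %in% two_el) {
      add_atom_here(ch2, 0L, NA_integer_); i <- i + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom_here(ch, 0L, NA_integer_); i <- i + 1L; next
    }
    if (grepl("^[bcnops]$", ch))
      stop("aromatic atoms not supported; supply a Kekulé SMILES")
    stop("unexpected character '", ch, "' at position ", i)
  }

  if (length(stack)) stop("unmatched '('")
  if (length(rings)) stop("unclosed ring bond(s): ", paste(names(rings), collapse = ", "))
  if (!is.na(pend_order) || pend_dat != 0L) stop("dangling bond token at end of SMILES")
  if (!mol_natoms(mol)) stop("no atoms in SMILES")
  vc <- mol_valence_ok(mol)
  if (!vc$ok)
    stop("valence violation at atom(s) ",
         paste(vc$bad_atoms, collapse = ", "), " (",
         paste(mol$atoms$element[vc$bad_atoms], collapse = ", "), ")")
  mol
}

parse_bracket_atom <- function(body) {
  m <- regexec("^([0-9]*)([A-Z][a-z]?)(@{0,2})(H([0-9]*))?((\\+{1,2}|-{1,2})([0-9]*)?)?$",
               body)
  g <- regmatches(body, m)[[1]]
  if (!length(g)) stop("malformed bracket atom [", body, "]")
  if (nchar(g[2])) stop("isotope labels not supported in [", body, "]")
  element <- g[3]
  if (!element %in% c(ORGANIC_SUBSET, PLACEHOLDER_ELEMENTS, "H"))
    stop("unsupported element '", element, "' in bracket atom")
  hcount <- 0L
  if (nchar(g[5])) hcount <- if (nchar(g[6])) as.integer(g[6]) else 1L
  charge <- 0L
  if (nchar(g[7])) {
    sign <- if (substr(g[7], 1L, 1L) == "+") 1L else -1L
    mag <- if (nchar(g[9])) as.integer(g[9]) else nchar(g[8])
    charge <- sign * mag
  }
  list(element = element, charge = charge, hcount = hcount)
}
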