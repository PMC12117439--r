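# Fixture ligand generator.
#
# Combinatorially assembles valid anchored ligands from scaffold families
# representative of experimentally derived ligand libraries (imine/pyridine
# N donors, phosphines, amines, carbenes, carbonyl/thiocarbonyl, chelating
# N,N / P,P / N,P and carbene chelates) crossed with common substituents.
# Templates are written directly in the anchored grammar and decoded, so
# every fixture is codec-audited at birth.  Chemistry is restricted to
# H/C/N/O/F/P/S/Cl so downstream descriptors stay well-behaved.

FIXTURE_SUBSTITUENTS <- c(H = "", Me = "C", F = "F", CF3 = "C(F)(F)F",
                          OMe = "OC", Ph = "C8=CC=CC=C8", NH2 = "N",
                          iPr = "C(C)C")

# each template: anchored-SMILES string with {a}/{b}/{c} slots; slots is the
# number of slots; subs optionally restricts the substituent alphabet
fixture_templates <- function(mode) {
  k1 <- list(
    list(t = "C1=C({a})C=C({b})C=N1->[Li]", slots = 2),          # pyridines
    list(t = "N({a})({b})({c})->[Li]", slots = 3, no_h = TRUE),  # amines
    list(t = "P({a})({b})({c})->[Li]", slots = 3, no_h = TRUE),  # phosphines
    list(t = "C({a})({b})=N({c})->[Li]", slots = 3),             # imines
    list(t = "C(=[Be])(N(C){a})N(C){b}", slots = 2),             # carbenes
    list(t = "C({a})({b})=O->[Li]", slots = 2, no_h = TRUE),     # ketones
    list(t = "C({a})({b})=S->[Li]", slots = 2, no_h = TRUE),     # thioketones
    list(t = "C({a})#N->[Li]", slots = 1)                        # nitriles
  )
  k2 <- list(
    list(t = "N1({a})CCN({b})->[Ir]<-1", slots = 2),             # diamines
    list(t = "P1({a})({b})CCP({c})({d})->[Ir]<-1", slots = 4, no_h = TRUE),
    list(t = "N1({a})({b})CCP(C)({c})->[Ir]<-1", slots = 3, no_h = TRUE),
    list(t = "C({a})(=N({b})->[Ir]<-1)C({c})=N1C", slots = 3),   # diimines
    list(t = "C(=[Be]->[Ir]<-1)(N(C){a})CCN1{b}", slots = 2)     # carbene-N
  )
  if (mode == 1L) k1 else if (mode == 2L) k2 else c(k1, k2)
}

fill_template <- function(template, subs) {
  out <- template
  slot_names <- c("a", "b", "c", "d")
  for (k in seq_along(subs)) {
    frag <- FIXTURE_SUBSTITUENTS[[subs[k]]]
    rep <- if (nzchar(frag)) paste0("(", frag, ")") else ""
    # slots already written as ({a}) in templates: replace the wrapped form
    out <- sub(paste0("({", slot_names[k], "})"), rep, out, fixed = TRUE)
    out <- sub(paste0("{", slot_names[k], "}"), frag, out, fixed = TRUE)
  }
  out
}

# full deterministic enumeration for a mode, memoized per session
.fixture_cache <- new.env(parent = emptyenv())

enumerate_fixtures <- function(mode) {
  key <- paste0("mode", mode)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  subs_all <- names(FIXTURE_SUBSTITUENTS)
  out_smiles <- character(0)
  for (tmpl in fixture_templates(mode)) {
    alphabet <- if (isTRUE(tmpl$no_h)) setdiff(subs_all, "H") else subs_all
    # bound the grid: 2 slots -> full cross; >2 slots -> vary the first two,
    # cycle the rest to keep enumeration compact
    if (tmpl$slots <= 2) {
      grid <- expand.grid(rep(list(alphabet), tmpl$slots),
                          stringsAsFactors = FALSE)
    } else {
      grid <- expand.grid(alphabet, alphabet, stringsAsFactors = FALSE)
      extra <- matrix(alphabet[1 + (seq_len(nrow(grid)) +
                                    seq_len(tmpl$slots - 2)[1]) %%
                               length(alphabet)],
                      nrow = nrow(grid), ncol = tmpl$slots - 2)
      grid <- cbind(grid, as.data.frame(extra, stringsAsFactors = FALSE))
    }
    for (r in seq_len(nrow(grid))) {
      s <- fill_template(tmpl$t, as.character(grid[r, ]))
      out_smiles <- c(out_smiles, s)
    }
  }
  # decode, validate, filter and deduplicate on canonical anchored SMILES
  records <- list()
  seen <- character(0)
  idx <- 0L
  for (s in out_smiles) {
    rec <- tryCatch(corpus_record(s, id = "tmp", source = "fixture"),
                    error = function(e) NULL)
    if (is.null(rec)) next
    if (rec$anchored_smiles %in% seen) next
    lig <- rec$ligand
    if (lig$denticity != (if (mode == 3L) lig$denticity else mode)) next
    if (length(mol_heavy_atoms(lig$mol)) < 4L) next
    if (lig$denticity == 2L && isTRUE(lig$haptic)) next
    seen <- c(seen, rec$anchored_smiles)
    idx <- idx + 1L
    records[[idx]] <- rec
  }
  # stable order independent of template order quirks
  ord <- order(vapply(records, `[[`, "", "anchored_smiles"))
  records <- records[ord]
  .fixture_cache[[key]] <- records
  records
}

#' Generate fixture ligand corpora
#'
#' Deterministic per seed: the full combinatorial space is enumerated,
#' deduplicated on canonical anchored SMILES, and `n` records are drawn
#' without replacement.  In mixed mode the draw is stratified to a roughly
#' 1:1 kappa-1:kappa-2 ratio.  Every output passes the training filters and
#' round-trips through the codec.
#'
#' @param n number of records.
#' @param mode 1, 2, or "mixed".
#' @param seed integer seed.
#' @return list of corpus records with ids `fix-<mode>-<k>`.
#' @export
generate_fixtures <- function(n, mode = 1L, seed = 1L) {
  if (n < 1L) stop("n must be at least 1")
  mixed <- identical(mode, "mixed") || identical(mode, 3L)
  if (mixed) {
    n1 <- floor(n / 2); n2 <- n - n1
    r1 <- generate_fixtures(n1, 1L, seed)
    r2 <- generate_fixtures(n2, 2L, seed + 1L)
    out <- c(r1, r2)
    for (k in seq_along(out)) out[[k]]$id <- sprintf("fix-mixed-%04d", k)
    return(out)
  }
  mode <- as.integer(mode)
  pool <- enumerate_fixtures(mode)
  if (n > length(pool))
    stop("n exceeds the enumerable fixture space for kappa-", mode,
         " (maximum ", length(pool), ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  take <- sample(length(pool), n)
  out <- pool[take]
  for (k in seq_along(out))
    out[[k]]$id <- sprintf("fix-k%d-%04d", mode, k)
  out
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
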