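test_that("acyclic molecules decompose into bond clusters", {
  jt <- tree_decompose("CC")
  expect_identical(length(jt$clusters), 1L)
  expect_identical(jt$clusters[[1]]$kind, "bond")
  # neopentane: four C-C bond clusters + the quaternary-atom singleton
  jt2 <- tree_decompose("CC(C)(C)C")
  kinds <- vapply(jt2$clusters, `[[`, "", "kind")
  expect_identical(sum(kinds == "bond"), 4L)
  expect_identical(sum(kinds == "atom"), 1L)
  expect_true(jtree_audit(jt2)$ok)
})

test_that("benzene is a single ring cluster", {
  jt <- tree_decompose("C1=CC=CC=C1")
  expect_identical(length(jt$clusters), 1L)
  expect_identical(jt$clusters[[1]]$kind, "ring")
})

test_that("placeholders and dative bonds live inside ordinary clusters", {
  jt <- tree_decompose("C1N->[Ir]<-NC1")
  expect_true(jtree_audit(jt)$ok)
  root_atoms <- jt$clusters[[jt$root]]$atoms
  els <- jt$mol$atoms$element[root_atoms]
  expect_true("Ir" %in% els)
})

test_that("the decomposition audit passes on every fixture", {
  recs <- generate_fixtures(100, "mixed", seed = 51)
  for (r in recs) {
    a <- jtree_audit(tree_decompose(r$anchored_smiles))
    expect_true(a$ok)
  }
})

test_that("ring perception matches brute-force cycle enumeration (<= 20 atoms)", {
  cases <- c("C1=CC=CC=C1", "C1CC1", "C1CCC2(CC1)CCCC2",   # spiro
             "C1CC2CCC1C2",                                # bridged
             "C1=CC=C(C=C1)C2=CC=CC=N2",                   # biaryl
             "C1CCCCCCCCC1")                               # macrocycle
  for (s in cases) {
    mol <- tmligen:::parse_smiles(s)
    if (tmligen:::mol_natoms(mol) > 20) next
    expect_true(ring_perception_consistent(mol))
  }
})

test_that("bridged ring systems merge into one cluster (>= 3 shared atoms)", {
  # norbornane: two fused 5-rings sharing 3 atoms -> one merged cluster
  jt <- tree_decompose("C1CC2CCC1C2")
  kinds <- vapply(jt$clusters, `[[`, "", "kind")
  expect_identical(sum(kinds == "ring"), 1L)
  expect_true(jtree_audit(jt)$ok)
})

test_that("serialization round-trips through assembly for all fixtures", {
  recs <- generate_fixtures(60, "mixed", seed = 52)
  for (r in recs) {
    jt <- tree_decompose(r$anchored_smiles)
    toks <- tmligen:::jtree_serialize(jt)
    m2 <- tmligen:::assemble_tokens(toks)
    expect_false(is.null(m2))
    expect_identical(as.character(tmligen:::canonical_smiles(m2)),
                     as.character(tmligen:::canonical_smiles(jt$mol)))
  }
})

test_that("decomposition is deterministic", {
  s <- "C1=CC=CC(CC(C)N)=N1->[Li]"
  t1 <- tmligen:::jtree_serialize(tree_decompose(s))
  t2 <- tmligen:::jtree_serialize(tree_decompose(s))
  expect_identical(t1, t2)
})
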