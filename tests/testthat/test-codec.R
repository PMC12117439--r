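test_that("the reference coordination modes encode to their known strings", {
  en_k1 <- encode_anchored(anchored_ligand("NCCN", 1, 1))
  expect_identical(as.character(en_k1),
                   as.character(canonicalize_anchored("NCCN->[Li]")))
  en_k2 <- encode_anchored(anchored_ligand("NCCN", c(1, 4), c(1, 1)))
  expect_identical(as.character(en_k2),
                   as.character(canonicalize_anchored("C1N->[Ir]<-NC1")))
  eta2 <- encode_anchored(anchored_ligand("C=C", c(1, 2), c(1, 1)))
  expect_identical(as.character(eta2),
                   as.character(canonicalize_anchored("C1->[Ir]<-C1")))
  # unicode arrows are accepted on input
  expect_identical(as.character(canonicalize_anchored("NCCN→[Li]")),
                   as.character(en_k1))
})

test_that("a methylidene carbene encodes through the =[Be] form and keeps 2 H", {
  carbene <- anchored_ligand("[CH2]", 1, 2)
  s <- encode_anchored(carbene)
  expect_match(as.character(s), "[Be]", fixed = TRUE)
  expect_match(as.character(s), "=", fixed = TRUE)
  back <- decode_anchored(s)
  expect_identical(back$bond_orders, 2L)
  expect_identical(back$denticity, 1L)
  expect_identical(tmligen:::mol_hcount(back$mol, back$anchors[1]), 2L)
})

test_that("mixed-order kappa-2 ligands route order-2 anchors through [Be] bridges", {
  d_form <- anchored_ligand("[C](CCN)N(C)C", anchors = c(1, 4),
                            bond_orders = c(2, 1))
  s <- as.character(encode_anchored(d_form))
  expect_identical(lengths(regmatches(s, gregexpr("\\[Be\\]", s))), 1L)
  expect_identical(lengths(regmatches(s, gregexpr("\\[Ir\\]", s))), 1L)
  e_form <- anchored_ligand("[C](N(C)C)CC[C]N(C)C", anchors = c(1, 7),
                            bond_orders = c(2, 2))
  s2 <- as.character(encode_anchored(e_form))
  expect_identical(lengths(regmatches(s2, gregexpr("\\[Be\\]", s2))), 2L)
})

test_that("decoding inverts the printed encodings", {
  lig <- decode_anchored("NCCN->[Li]")
  expect_identical(lig$denticity, 1L)
  expect_identical(lig$bond_orders, 1L)
  expect_identical(lig$mol$atoms$element[lig$anchors], "N")
  lig2 <- decode_anchored("C1N->[Ir]<-NC1")
  expect_identical(lig2$denticity, 2L)
  expect_identical(lig2$bond_orders, c(1L, 1L))
  expect_setequal(lig2$mol$atoms$element[lig2$anchors], "N")
})

test_that("codec errors are specific and informative", {
  expect_error(decode_anchored("CCN"), "missing-anchor")
  expect_error(anchored_ligand("[NH3+]CC[O-]", 1, 1), NA)  # net neutral is fine
  expect_error(anchored_ligand("[NH3+]CCO", 1, 1), "charge error")
  expect_error(anchored_ligand("NN", c(1, 2), c(1, 1)), "adjacency error")
  expect_error(anchored_ligand("CC(C)(C)C", 2, 2), "valence error")
  expect_error(decode_anchored("NCCN->[Li].[Li]"), "connected")
})

test_that("generator-side validity matches the declared grammar", {
  expect_true(check_anchor_validity("NCCN->[Li]", 1)$valid)
  expect_false(check_anchor_validity("NCCN->[Li].[Li]", 1)$valid)
  res <- check_anchor_validity("C1N->[Ir]<-NC1", 1)
  expect_false(res$valid)
  expect_match(res$reason, "kappa-2 pattern under kappa-1")
  expect_true(check_anchor_validity("C1N->[Ir]<-NC1", 2)$valid)
  expect_false(check_anchor_validity("not a smiles ((", 1)$valid)
})

test_that("canonicalization is idempotent and decode-invariant on fixtures", {
  recs <- generate_fixtures(40, "mixed", seed = 21)
  for (r in recs) {
    s <- r$anchored_smiles
    c1 <- as.character(canonicalize_anchored(s))
    expect_identical(as.character(canonicalize_anchored(c1)), c1)
    d1 <- decode_anchored(s)
    d2 <- decode_anchored(c1)
    expect_true(tmligen:::anchored_equal(d1, d2))
  }
})

test_that("atom-order permutations collapse to one canonical string", {
  set.seed(42)
  recs <- generate_fixtures(15, "mixed", seed = 22)
  for (r in recs) {
    mol <- tmligen:::parse_smiles(r$anchored_smiles)
    ref <- as.character(tmligen:::canonical_smiles(mol))
    for (k in 1:5) {
      p <- sample(tmligen:::mol_natoms(mol))
      m2 <- mol
      m2$atoms <- lapply(mol$atoms, `[`, order(p))
      m2$bonds$a1 <- p[mol$bonds$a1]
      m2$bonds$a2 <- p[mol$bonds$a2]
      expect_identical(as.character(tmligen:::canonical_smiles(m2)), ref)
    }
  }
})

test_that("no placeholder element survives decoding as a ligand atom", {
  recs <- generate_fixtures(60, "mixed", seed = 23)
  for (r in recs) {
    lig <- decode_anchored(r$anchored_smiles)
    expect_false(any(lig$mol$atoms$element %in% c("Li", "Be", "Ir")))
  }
})

test_that("encoder output always passes the generator-side validity check", {
  recs <- generate_fixtures(60, "mixed", seed = 24)
  for (r in recs) {
    lig <- r$ligand
    expect_true(check_anchor_validity(encode_anchored(lig), lig$denticity)$valid)
  }
})
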