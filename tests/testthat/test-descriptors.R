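test_that("tanimoto is a similarity: symmetry, range, identity", {
  recs <- generate_fixtures(10, 1, seed = 41)
  fps <- lapply(recs, function(r) morgan_fingerprint(r$ligand$mol))
  for (i in 1:5) {
    a <- fps[[2 * i - 1]]; b <- fps[[2 * i]]
    tc <- tanimoto(a, b)
    expect_identical(tc, tanimoto(b, a))
    expect_gte(tc, 0); expect_lte(tc, 1)
    expect_identical(tanimoto(a, a), 1)
  }
  expect_identical(tanimoto(rep(TRUE, 8), rep(c(FALSE, TRUE), 4) & FALSE), 0)
  expect_warning(tanimoto(rep(FALSE, 8), rep(FALSE, 8)), "empty")
})

test_that("tanimoto agrees exactly with a bit-by-bit brute-force count", {
  recs <- generate_fixtures(20, "mixed", seed = 42)
  set.seed(1)
  for (k in 1:10) {
    ij <- sample(20, 2)
    a <- morgan_fingerprint(recs[[ij[1]]]$ligand$mol)
    b <- morgan_fingerprint(recs[[ij[2]]]$ligand$mol)
    expect_identical(tanimoto(a, b), tanimoto_brute(a, b))
  }
})

test_that("identical molecules give identical fingerprints regardless of spelling", {
  a <- morgan_fingerprint("N(CC)CCO")
  b <- morgan_fingerprint(tmligen:::parse_smiles("OCCN(C)C"))  # different molecule
  c2 <- morgan_fingerprint("OCCN(CC)")
  expect_identical(a, c2)
  expect_false(identical(a, b))
})

test_that("log P rises with a phenyl and falls when NH2 replaces it", {
  base <- "P(C)(C)C"
  with_ph <- "P(C)(C)CC8=CC=CC=C8"
  with_nh2 <- "P(C)(C)CN"
  expect_gt(log_p(with_ph), log_p(base))
  expect_lt(log_p(with_nh2), log_p(with_ph))
  expect_identical(log_p("OCCN"), log_p("OCCN"))
})

test_that("log P is conformer-independent and errors on uncovered atoms", {
  lig <- decode_anchored("P(C)(C)(C)->[Li]")
  expect_identical(log_p(lig), log_p(lig$mol))
  expect_error(log_p(tmligen:::parse_smiles("[Li]")), "free ligand")
})

test_that("the SA normalization maps the raw endpoints to 0 and 1", {
  expect_identical(tmligen:::sa_normalize(10), 0)
  expect_identical(tmligen:::sa_normalize(1), 1)
})

test_that("simple molecules score as easier to make than fused polycycles", {
  expect_gt(sa_score("CC"), sa_score("C1CC2CCC1C3CCC(C2)C3"))
  expect_gt(sa_score_raw("C1CC2CCC1C3CCC(C2)C3"), sa_score_raw("CC"))
  expect_error(sa_score("CC", reference = NULL), "configuration error")
})

test_that("coordination environment patterns follow the anchor-and-neighbors rule", {
  expect_identical(coordination_environment(decode_anchored("C1=CC=CC=N1->[Li]")),
                   "N([C][C])")
  expect_identical(coordination_environment(decode_anchored("P(C)(C)(C)->[Li]")),
                   "P([C][C][C])")
  expect_identical(coordination_environment(anchored_ligand("[C-]#[O+]", 1, 1)),
                   "C([O])")
  expect_identical(coordination_environment(decode_anchored("C1N->[Ir]<-NC1")),
                   "N([C])N([C])")
})
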