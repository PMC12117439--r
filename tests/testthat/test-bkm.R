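test_that("a bare anchor with only H neighbors sits below its substituted analogue", {
  nh3ish <- decode_anchored("N(C)->[Li]")        # methylamine: one C
  bulky <- decode_anchored("N(C(C)(C)C)->[Li]")  # tert-butylamine
  v1 <- bk_m(nh3ish)
  v2 <- bk_m(bulky)
  expect_gt(v1, 0)
  expect_gt(v2, v1)
})

test_that("grid integration matches the Monte-Carlo estimate on a fixture", {
  lig <- decode_anchored("P(C)(C)(C)->[Li]")
  g <- bk_m(lig, method = "grid")
  m <- bk_m(lig, method = "mc", mc_points = 2e5)
  expect_lt(abs(g - m) / g, 0.02)
})

test_that("near-anchor substitution grows the descriptor (ortho effect)", {
  plain <- decode_anchored("C1=CC=CC=N1->[Li]")
  ortho <- decode_anchored("C1=CC=CC(C(C)C)=N1->[Li]")
  expect_gt(bk_m(ortho), bk_m(plain))
})

test_that("kappa-2 ligands accumulate bulk over both probes", {
  en <- decode_anchored("C1N->[Ir]<-NC1")
  en_k1 <- decode_anchored("NCCN->[Li]")
  expect_gt(bk_m(en), bk_m(en_k1))
})

test_that("bk_m is deterministic for a fixed conformer", {
  lig <- decode_anchored("N(C)(C)CCO->[Li]")
  expect_identical(bk_m(lig), bk_m(lig))
})
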