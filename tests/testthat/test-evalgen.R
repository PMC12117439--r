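test_that("novelty is zero when the generated set equals the training set", {
  tr <- generate_fixtures(20, 1, seed = 71)
  gen <- vapply(tr, `[[`, "", "anchored_smiles")
  rep <- funnel_metrics(gen, tr, mode = 1)
  expect_identical(rep$novel_pct, 0)
  expect_identical(rep$valid_pct, 100)
})

test_that("an all-distinct, all-valid, all-new toy set scores 100/100/100", {
  tr <- list(corpus_record("N(C)(C)(C)->[Li]", "t1"))
  gen <- c("P(C)(C)(C)->[Li]", "C1=CC=CC=N1->[Li]", "N(CC)(C)(C)->[Li]")
  rep <- funnel_metrics(gen, tr, mode = 1)
  expect_identical(rep$valid_pct, 100)
  expect_identical(rep$unique_pct, 100)
  expect_identical(rep$novel_pct, 100)
})

test_that("repeats among the valid lower uniqueness by exact count", {
  tr <- list(corpus_record("N(C)(C)(C)->[Li]", "t1"))
  gen <- c(rep("P(C)(C)(C)->[Li]", 4),
           "C1=CC=CC=N1->[Li]", "N(CC)(C)(C)->[Li]", "OCCN->[Li]",
           "C(C)(C)=S->[Li]", "C(C)#N->[Li]", "N(C)(C)CCO->[Li]")
  rep <- funnel_metrics(gen, tr, mode = 1)
  expect_identical(unname(rep$counts["valid"]), 10L)
  expect_identical(rep$unique_pct, 70)
})

test_that("the funnel is monotone and permutation-invariant", {
  tr <- generate_fixtures(30, 1, seed = 72)
  gen <- c(vapply(tr[1:10], `[[`, "", "anchored_smiles"),
           "P(CC)(CC)(CC)->[Li]", "garbage((", "C1N->[Ir]<-NC1")
  r1 <- funnel_metrics(gen, tr, mode = 1)
  expect_true(r1$counts["valid"] >= r1$counts["unique"])
  expect_true(r1$counts["unique"] >= r1$counts["novel"])
  set.seed(2)
  r2 <- funnel_metrics(sample(gen), tr, mode = 1)
  expect_identical(r1$counts, r2$counts)
})

test_that("diversity has its closed-form values on degenerate pairs", {
  # two copies of one molecule: avg TC 1, IntDiv2 0
  d <- diversity(c("P(C)(C)(C)->[Li]", "P(C)(C)(C)->[Li]"))
  expect_equal(d$avg_tanimoto, 1)
  expect_equal(d$intdiv2, 0)
  # two molecules with disjoint fingerprints: IntDiv2 = 1 - sqrt(0.5)
  fpa <- morgan_fingerprint("N(C)(C)C")
  fpb <- morgan_fingerprint("P(F)(F)F")
  expect_identical(tanimoto(fpa, fpb), 0)
  d2 <- diversity(c("CN(C)(C)->[Li]", "FP(F)(F)->[Li]"))
  expect_equal(d2$avg_tanimoto, 0)
  expect_equal(d2$intdiv2, 1 - sqrt(0.5))
  expect_error(diversity("P(C)(C)(C)->[Li]"), "at least 2")
})

test_that("diversity equals the brute-force double-loop oracle", {
  recs <- generate_fixtures(20, "mixed", seed = 73)
  smiles <- vapply(recs, `[[`, "", "anchored_smiles")
  got <- diversity(smiles)
  want <- diversity_brute(smiles)
  expect_equal(got$avg_tanimoto, want$avg_tanimoto)
  expect_equal(got$intdiv2, want$intdiv2)
})

test_that("distribution histograms are normalized and reproducible", {
  recs <- generate_fixtures(30, "mixed", seed = 74)
  smiles <- vapply(recs, `[[`, "", "anchored_smiles")
  rep1 <- distribution_report(smiles)
  expect_equal(sum(rep1$heteroatoms), 1)
  expect_equal(sum(rep1$coordination), 1)
  expect_equal(sum(rep1$size), 1)
  rep2 <- distribution_report(smiles)
  expect_identical(rep1$mean_size, rep2$mean_size)
  # pyridine-only set: coordination is a point mass
  pyr <- distribution_report(rep("C1=CC=CC=N1->[Li]", 3))
  expect_identical(names(pyr$coordination), "N([C][C])")
  expect_equal(unname(pyr$coordination), 1)
})

test_that("the drug-like subset removes flagged elements, monotonically", {
  set <- c("P(C)(C)(C)->[Li]",           # P: excluded by default
           "C1=CC=CC=N1->[Li]",          # retained
           "ClCCN->[Li]")                # Cl: only under the extended list
  sub_default <- drug_like_subset(set)
  expect_false("P(C)(C)(C)->[Li]" %in% sub_default)
  expect_true("C1=CC=CC=N1->[Li]" %in% sub_default)
  expect_true("ClCCN->[Li]" %in% sub_default)
  sub_ext <- drug_like_subset(set, exclude = c("B", "Si", "P", "As", "Se",
                                               "I", "Cl", "Br"))
  expect_true(all(sub_ext %in% sub_default))
  expect_false("ClCCN->[Li]" %in% sub_ext)
})
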