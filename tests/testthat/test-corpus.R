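test_that("training filters reject undersized and misdeclared ligands", {
  small <- corpus_record("N(C)(C)(C)->[Li]", "tiny")   # 4 heavy atoms: kept
  tiny <- corpus_record("C(N)#N->[Li]", "3heavy")      # 3 heavy atoms
  k2 <- corpus_record("C1N->[Ir]<-NC1", "en")
  out <- apply_training_filters(list(small, tiny, k2), mode = 1)
  expect_identical(out$report$input_count, 3L)
  expect_identical(out$report$kept_count, 1L)
  expect_identical(unname(out$report$rejection_counts["size"]), 1L)
  expect_identical(unname(out$report$rejection_counts["denticity"]), 1L)
})

test_that("kappa-2 ligands with adjacent (haptic) anchors are filtered out", {
  eta2 <- corpus_record("CC1->[Ir]<-C1CC", "eta")
  ok <- corpus_record("N1(C)CCN(C)->[Ir]<-1", "en")
  out <- apply_training_filters(list(eta2, ok), mode = 2)
  expect_identical(out$report$kept_count, 1L)
  expect_identical(unname(out$report$rejection_counts["adjacency"]), 1L)
})

test_that("high-valent anionic atoms are detected and removed", {
  # anionic pentavalent phosphorus: 5 explicit bonds with a negative charge
  bad <- tmligen:::parse_smiles("C[P-](C)(C)(C)C")
  expect_true(tmligen:::has_high_valent_anion(bad))
  okmol <- tmligen:::parse_smiles("CP(C)C")
  expect_false(tmligen:::has_high_valent_anion(okmol))
  # carbonyl-style [C-]#[O+] is fine: 3 <= lowest C valence
  expect_false(tmligen:::has_high_valent_anion(tmligen:::parse_smiles("[C-]#[O+]")))
})

test_that("filters are order-independent and conserve counts", {
  recs <- generate_fixtures(60, "mixed", seed = 31)
  out1 <- apply_training_filters(recs, mode = 1)
  set.seed(1)
  out2 <- apply_training_filters(sample(recs), mode = 1)
  ids1 <- sort(vapply(out1$records, `[[`, "", "id"))
  ids2 <- sort(vapply(out2$records, `[[`, "", "id"))
  expect_identical(ids1, ids2)
  rep <- out1$report
  expect_identical(rep$kept_count + sum(rep$rejection_counts), rep$input_count)
})

test_that("fixture generation is deterministic, distinct, and codec-clean", {
  a <- generate_fixtures(10, 1, seed = 7)
  b <- generate_fixtures(10, 1, seed = 7)
  expect_identical(vapply(a, `[[`, "", "anchored_smiles"),
                   vapply(b, `[[`, "", "anchored_smiles"))
  big <- generate_fixtures(100, "mixed", seed = 8)
  smiles <- vapply(big, `[[`, "", "anchored_smiles")
  expect_identical(anyDuplicated(smiles), 0L)
  for (r in big[seq(1, 100, by = 7)]) {
    back <- decode_anchored(r$anchored_smiles)
    expect_true(tmligen:::anchored_equal(back, r$ligand))
  }
})

test_that("mixed-mode fixtures hold a roughly 1:1 denticity ratio", {
  mx <- generate_fixtures(400, "mixed", seed = 9)
  frac1 <- mean(vapply(mx, function(r) r$ligand$denticity, 0L) == 1L)
  expect_gte(frac1, 0.45)
  expect_lte(frac1, 0.55)
})

test_that("requesting more fixtures than the space holds names the maximum", {
  expect_error(generate_fixtures(10000, 1, seed = 1), "maximum")
})

test_that("corpus CSV round-trips losslessly and tolerates bad records", {
  recs <- generate_fixtures(25, "mixed", seed = 33)
  path <- tempfile(fileext = ".csv")
  write_corpus(recs, path)
  back <- read_corpus(path)
  expect_identical(nrow(back$errors), 0L)
  expect_identical(vapply(back$records, `[[`, "", "anchored_smiles"),
                   vapply(recs, `[[`, "", "anchored_smiles"))
  # inject a malformed line: other records unaffected, error carries line no.
  lines <- readLines(path)
  lines <- append(lines, "bad-id,not A smiles ((,1,1,1,fixture", after = 3)
  writeLines(lines, path)
  back2 <- read_corpus(path)
  expect_identical(length(back2$records), length(recs))
  expect_identical(nrow(back2$errors), 1L)
})

test_that("alternate CSV dialects are ingested via column mapping", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# ligand export, custom dialect",
               "name,anchored_smiles",
               "lig1,NCCN->[Li]",
               "lig2,P(C)(C)(C)->[Li]",
               "lig3,C1N->[Ir]<-NC1"), path)
  got <- read_corpus(path, col_map = c(id = "name", smiles = "anchored_smiles"))
  expect_identical(length(got$records), 3L)
  expect_identical(got$records[[1]]$id, "lig1")
})
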