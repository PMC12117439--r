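test_that("vocabulary construction is monotone and closed over training data", {
  recs <- generate_fixtures(30, 1, seed = 61)
  vocA <- build_vocabulary(recs[1:15])
  vocAB <- build_vocabulary(recs)
  expect_true(all(vocA$labels %in% vocAB$labels))
  expect_identical(tmligen:::vocabulary_coverage(vocAB, recs), 1)
  expect_error(build_vocabulary(list()), "empty corpus")
})

test_that("a benzene-containing corpus yields the ring label", {
  rec <- corpus_record("N(->[Li])(C)C8=CC=CC=C8", "anilineish")
  voc <- build_vocabulary(list(rec))
  expect_true(any(grepl("^C1=CC=CC=C1$|^C=1C=CC=CC1$", voc$labels)))
})

test_that("training reduces the loss and keeps the KL term non-negative", {
  m <- shared_model_k1()
  h <- m$history
  expect_lt(mean(tail(h$loss, 10)), mean(head(h$loss, 10)))
  expect_true(all(h$kl >= 0))
  expect_true(all(is.finite(h$loss)))
})

test_that("training is deterministic under a fixed seed", {
  recs <- generate_fixtures(20, 1, seed = 62)
  cfg <- jtvae_config(epochs = 25)
  m1 <- jtvae_train(recs, cfg, seed = 5)
  m2 <- jtvae_train(recs, cfg, seed = 5)
  expect_identical(m1$history, m2$history)
  m3 <- jtvae_train(recs, cfg, seed = 6)
  expect_false(identical(m1$history$loss, m3$history$loss))
})

test_that("an overfit model reconstructs most of its training set", {
  m <- shared_model_k1()
  recs <- shared_model_k1_corpus()
  match <- vapply(recs, function(r) jtvae_reconstruct(m, r)$match, TRUE)
  expect_gte(mean(match), 0.8)
})

test_that("the latent mean of a molecule is reproducible", {
  m <- shared_model_k1()
  recs <- shared_model_k1_corpus()
  z1 <- tmligen:::encode_mu(m, recs[1])
  z2 <- tmligen:::encode_mu(m, recs[1])
  expect_identical(z1, z2)
})

test_that("sampling honors seeds and the trivial n = 0 case", {
  m <- shared_model_k1()
  expect_identical(jtvae_sample(m, 0), character(0))
  s1 <- jtvae_sample(m, 20, seed = 4)
  s2 <- jtvae_sample(m, 20, seed = 4)
  expect_identical(as.character(s1), as.character(s2))
  s3 <- jtvae_sample(m, 20, seed = 5)
  expect_false(identical(as.character(s1), as.character(s3)))
})

test_that("every sampled string parses as a chemically valid molecule", {
  m <- shared_model_k1()
  s <- jtvae_sample(m, 50, seed = 6)
  for (x in s) expect_error(tmligen:::parse_smiles(x), NA)
})

test_that("latent interpolation decodes to parseable strings throughout", {
  m <- shared_model_k1()
  recs <- shared_model_k1_corpus()
  za <- as.numeric(tmligen:::encode_mu(m, recs[1]))
  zb <- as.numeric(tmligen:::encode_mu(m, recs[25]))
  for (t in seq(0, 1, by = 0.2)) {
    dec <- tmligen:::decode_z(m, (1 - t) * za + t * zb, mode = "greedy")
    expect_false(is.null(dec))
    expect_error(tmligen:::parse_smiles(dec$smiles), NA)
  }
})

test_that("checkpoints reload to an identical model", {
  m <- shared_model_k1()
  d <- tempfile()
  jtvae_save(m, d)
  m2 <- jtvae_load(d)
  expect_identical(m$params, m2$params)
  expect_identical(m$vocab$tokens, m2$vocab$tokens)
  s1 <- jtvae_sample(m, 5, seed = 7)
  s2 <- jtvae_sample(m2, 5, seed = 7)
  expect_identical(as.character(s1), as.character(s2))
})
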