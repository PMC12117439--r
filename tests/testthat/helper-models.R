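# Shared fixtures and trained models, cached on disk for the test session so
# expensive training runs once regardless of test-file execution order.

test_cache_dir <- function() {
  d <- file.path(tempdir(), "tmligen-test-cache")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

shared_corpus <- function(mode, n = 120L) {
  generate_fixtures(n, mode, seed = 100L + mode)
}

# a kappa-1 model overfit on a small corpus; used for reconstruction,
# sampling and interpolation tests
shared_model_k1 <- function() {
  path <- file.path(test_cache_dir(), "model-k1")
  if (dir.exists(path)) return(jtvae_load(path))
  recs <- generate_fixtures(50L, 1L, seed = 105L)
  m <- jtvae_train(recs, jtvae_config(epochs = 150L), seed = 11L)
  jtvae_save(m, path)
  saveRDS(recs, file.path(path, "corpus.rds"))
  m
}

shared_model_k1_corpus <- function() {
  shared_model_k1()
  readRDS(file.path(test_cache_dir(), "model-k1", "corpus.rds"))
}

# conditional model on cheap synthetic labels (log P and heavy-atom count)
shared_conditional <- function() {
  path <- file.path(test_cache_dir(), "model-cond.rds")
  if (file.exists(path)) return(readRDS(path))
  recs <- generate_fixtures(150L, 1L, seed = 107L)
  lab <- lapply(recs, function(r) {
    r$y <- c(logP = log_p(r$ligand),
             size = length(tmligen:::mol_heavy_atoms(r$ligand$mol)))
    r
  })
  m <- train_conditional(lab[1:110], jtvae_config(epochs = 150L), seed = 13L)
  out <- list(model = m, train = lab[1:110], test = lab[111:150])
  saveRDS(out, path)
  out
}
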