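test_that("isolation forest recovers planted outliers at 1% contamination", {
  set.seed(81)
  X <- cbind(stats::rnorm(1000), stats::rnorm(1000))
  planted <- cbind(stats::rnorm(10, 8), stats::rnorm(10, 8))
  labs <- lapply(seq_len(1010), function(i)
    list(y = rbind(X, planted)[i, ]))
  hits <- 0L
  for (sd in 1:10) {
    ex <- exclude_outliers(labs, 0.01, seed = sd)
    if (all(1001:1010 %in% ex$removed)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("outlier exclusion validates its inputs and the zero limit", {
  labs <- lapply(1:200, function(i) list(y = c(i %% 7, i %% 5)))
  expect_error(exclude_outliers(labs, 0.5), "contamination")
  expect_error(exclude_outliers(labs, 0), "contamination")
  expect_error(exclude_outliers(labs[1:50], 0.01), "at least 100")
  # contamination small enough that floor(c * n) == 0: nothing removed
  ex <- exclude_outliers(labs, 0.004, seed = 1)
  expect_identical(length(ex$records), 200L)
})

test_that("the conditional property head recovers synthetic labels (held out)", {
  sh <- shared_conditional()
  mu <- tmligen:::encode_mu(sh$model, sh$test)
  yh <- predict_properties(sh$model, mu)
  y <- t(vapply(sh$test, `[[`, numeric(2), "y"))
  expect_gte(stats::cor(yh[, 1], y[, 1], method = "spearman"), 0.8)
  expect_gte(stats::cor(yh[, 2], y[, 2], method = "spearman"), 0.8)
})

test_that("property-head residuals on the training ligands center near zero", {
  sh <- shared_conditional()
  mu <- tmligen:::encode_mu(sh$model, sh$train)
  yh <- predict_properties(sh$model, mu)
  y <- t(vapply(sh$train, `[[`, numeric(2), "y"))
  res <- (yh - y) / matrix(apply(y, 2, stats::sd), nrow(y), 2, byrow = TRUE)
  expect_lt(abs(mean(res[, 1])), 0.25)
  expect_lt(abs(mean(res[, 2])), 0.25)
})

test_that("degenerate property variance is rejected at training time", {
  recs <- generate_fixtures(20, 1, seed = 83)
  lab <- lapply(recs, function(r) { r$y <- c(a = 1, b = stats::runif(1)); r })
  expect_error(train_conditional(lab, jtvae_config(epochs = 2)),
               "degenerate property variance")
})

test_that("compass directions are eight distinct unit vectors", {
  dirs <- lapply(paste0("D", 1:8), compass_direction)
  for (d in dirs) expect_equal(sqrt(sum(d^2)), 1)
  expect_identical(anyDuplicated(vapply(dirs, paste, "", collapse = ",")), 0L)
  expect_error(compass_direction("D9"), "unknown direction")
})

test_that("region sampling respects the decile and center definitions", {
  sh <- shared_conditional()
  lab <- sh$train
  r1 <- sample_prompts(lab, "R1", 5, seed = 1)
  r3 <- sample_prompts(lab, "R3", 5, seed = 1)
  ce <- sample_prompts(lab, "C", 5, seed = 1)
  y1 <- function(set) vapply(set, function(r) r$y[[1]], 0)
  expect_gte(min(y1(r1)), max(y1(ce)))
  expect_lte(max(y1(r3)), min(y1(r1)))
  expect_error(sample_prompts(lab, "R1", 10000, seed = 1), "reduce k")
  # all-identical labels: C succeeds, R regions fail informatively
  flat <- lapply(lab[1:110], function(r) { r$y <- c(a = 1, b = 1); r })
  expect_error(sample_prompts(flat, "C", 2, seed = 1), "degenerate")
  expect_error(sample_prompts(flat, "R1", 2, seed = 1), "undefined")
})

test_that("a constant property head converges immediately", {
  sh <- shared_conditional()
  m <- sh$model
  m$params$Wp1[] <- 0; m$params$Wp2[] <- 0   # flat objective everywhere
  traj <- latent_optimize(m, sh$train[[1]], "D1")
  expect_identical(length(traj$steps), 1L)
  expect_identical(traj$termination, "converged")
})

test_that("trajectory invariants hold: gate, monotone objective, prompt at step 0", {
  sh <- shared_conditional()
  traj <- latent_optimize(sh$model, sh$train[[3]], "D3",
                          tc_threshold = 0.2, max_steps = 25)
  expect_identical(traj$steps[[1]]$smiles,
                   as.character(canonicalize_anchored(sh$train[[3]]$anchored_smiles)))
  tcs <- vapply(traj$steps, `[[`, 0, "tc")
  expect_true(all(tcs[-1] >= 0.2))
  gs <- vapply(traj$steps, `[[`, 0, "g")
  expect_true(all(diff(gs) >= 0))
})

test_that("verification applies the strict single- and dual-objective rules", {
  mk <- function(dir, y0, y1) {
    traj <- structure(list(direction = compass_direction(dir),
                           steps = list(list(smiles = "A"), list(smiles = "B"))),
                      class = "opt_trajectory")
    oracle <- function(s) if (s == "A") y0 else y1
    verify_trajectory(traj, oracle)
  }
  expect_true(mk("D1", c(0, 0), c(1, -5))$verified)     # y2 ignored for D1
  expect_false(mk("D1", c(0, 0), c(0, 3))$verified)     # tie on y1: unverified
  expect_false(mk("D5", c(0, 0), c(1, -1))$verified)    # dual needs both
  expect_true(mk("D7", c(0, 0), c(2, -1))$verified)     # +y1, -y2
  expect_false(mk("D3", c(0, 0), c(1, 0))$verified)     # wrong sense
  # oracle failure is reported, not raised
  traj <- structure(list(direction = compass_direction("D1"),
                         steps = list(list(smiles = "A"), list(smiles = "B"))),
                    class = "opt_trajectory")
  v <- verify_trajectory(traj, function(s) stop("boom"))
  expect_false(v$verified)
  expect_match(v$reason, "oracle failure")
})

test_that("verification of a stored trajectory is idempotent", {
  sh <- shared_conditional()
  oracle <- function(s) { l <- decode_anchored(s)
    c(log_p(l), length(tmligen:::mol_heavy_atoms(l$mol))) }
  traj <- latent_optimize(sh$model, sh$train[[5]], "D3", max_steps = 15)
  v1 <- verify_trajectory(traj, oracle)
  v2 <- verify_trajectory(traj, oracle)
  expect_identical(v1, v2)
})

test_that("the campaign report funnel is monotone with a correct longest-D", {
  sh <- shared_conditional()
  oracle <- function(s) { l <- decode_anchored(s)
    c(log_p(l), length(tmligen:::mol_heavy_atoms(l$mol))) }
  res <- run_campaign(sh$model, sh$train, regions = "C",
                      directions = c("D1", "D3"), k = 3,
                      tc_threshold = 0.2, oracle = oracle, seed = 2,
                      max_steps = 15)
  rep <- conditional_report(res, sh$model, sh$train)
  expect_identical(nrow(rep), 1L)
  pcts <- unlist(rep[1, c("similar_pct", "valid_pct", "unique_pct",
                          "novel_pct", "verified_pct")])
  expect_true(all(pcts >= 0 & pcts <= 100, na.rm = TRUE))
  # longest direction against a brute-force recomputation
  lens <- vapply(res, function(x)
    tmligen:::trajectory_length(x$trajectory, sh$model$prop_stats), 0)
  expect_identical(rep$longest_direction, res[[which.max(lens)]]$direction)
  # single fully successful trajectory: all stages 100
  best <- res[vapply(res, function(x)
    isTRUE(x$verification$verified) && length(x$trajectory$steps) > 1, TRUE)]
  if (length(best)) {
    rep1 <- conditional_report(best[1], sh$model, sh$train)
    expect_identical(unname(unlist(rep1[1, c("similar_pct", "valid_pct",
                                             "unique_pct", "novel_pct",
                                             "verified_pct")])),
                     rep(100, 5))
  }
})
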