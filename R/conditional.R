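# Conditional generation machinery: property labeling, isolation-forest
# outlier exclusion, prompt sampling from property-space regions, compass
# directions, latent-space gradient optimization with Tanimoto gating, and
# post-hoc verification against a property oracle.

# ---- isolation forest -------------------------------------------------------

# hand-rolled isolation forest (random axis-aligned splits on subsamples,
# anomaly score from normalized mean path length)
iforest_fit <- function(X, ntrees = 100L, psi = 256L, seed = 1L) {
  X <- as.matrix(X)
  psi <- min(psi, nrow(X))
  hmax <- ceiling(log2(psi))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  build <- function(idx, depth) {
    if (depth >= hmax || length(idx) <= 1L)
      return(list(leaf = TRUE, size = length(idx)))
    q <- sample.int(ncol(X), 1L)
    rng <- range(X[idx, q])
    if (rng[1] == rng[2]) return(list(leaf = TRUE, size = length(idx)))
    p <- stats::runif(1, rng[1], rng[2])
    left <- idx[X[idx, q] < p]
    right <- idx[X[idx, q] >= p]
    list(leaf = FALSE, q = q, p = p,
         l = build(left, depth + 1L), r = build(right, depth + 1L))
  }
  trees <- lapply(seq_len(ntrees), function(k)
    build(sample.int(nrow(X), psi), 0L))
  structure(list(trees = trees, psi = psi), class = "iforest")
}

# average path length of an unsuccessful BST search (Liu et al. c(n))
iforest_c <- function(n) {
  if (n <= 1L) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

iforest_score <- function(forest, X) {
  X <- as.matrix(X)
  path <- function(tree, x, depth) {
    if (tree$leaf) return(depth + iforest_c(tree$size))
    if (x[tree$q] < tree$p) path(tree$l, x, depth + 1)
    else path(tree$r, x, depth + 1)
  }
  h <- vapply(seq_len(nrow(X)), function(i)
    mean(vapply(forest$trees, path, 0, x = X[i, ], depth = 0)), 0)
  2^(-h / iforest_c(forest$psi))
}

#' Exclude property-space outliers with an isolation forest
#'
#' Removes the `floor(contamination * n)` records with the highest anomaly
#' score in the two-dimensional property space.
#'
#' @param labeled list of labeled records (see [label_records()]).
#' @param contamination fraction to remove, in (0, 0.1].
#' @param seed integer seed.
#' @return list(records = kept records, removed = indices removed).
#' @export
exclude_outliers <- function(labeled, contamination, seed = 1L) {
  if (length(labeled) < 100L)
    stop("outlier exclusion needs at least 100 records")
  if (!is.numeric(contamination) || contamination <= 0 || contamination > 0.1)
    stop("contamination must lie in (0, 0.1]")
  Y <- t(vapply(labeled, `[[`, numeric(2), "y"))
  k <- floor(contamination * length(labeled))
  if (k == 0L) return(list(records = labeled, removed = integer(0)))
  sc <- iforest_score(iforest_fit(Y, seed = seed), Y)
  removed <- order(sc, decreasing = TRUE)[seq_len(k)]
  list(records = labeled[-removed], removed = sort(removed))
}

# ---- labeling ---------------------------------------------------------------

#' Attach property labels to corpus records
#'
#' Either from a table (columns `id`, `y1`, `y2` — e.g. externally computed
#' HOMO-LUMO gap and metal charge) or computed internally with the free
#' ligand properties log P and Bk_M.
#'
#' @param records corpus records.
#' @param table optional data.frame with columns id, y1, y2.
#' @param properties when `table` is NULL, names of the two internal
#'   properties (any two of "logP", "BkM").
#' @param bk_cfg Bk_M probe config used for internal labeling.
#' @return list of labeled records, each with a named numeric `y` of length 2.
#' @export
label_records <- function(records, table = NULL,
                          properties = c("logP", "BkM"),
                          bk_cfg = bk_m_config(grid = 0.35)) {
  if (!is.null(table)) {
    if (!all(c("id", "y1", "y2") %in% names(table)))
      stop("label table needs columns id, y1, y2")
    idx <- match(vapply(records, `[[`, "", "id"), table$id)
    if (anyNA(idx)) stop("label table misses ids: ",
                         paste(vapply(records[is.na(idx)], `[[`, "", "id"),
                               collapse = ", "))
    out <- lapply(seq_along(records), function(k) {
      r <- records[[k]]
      r$y <- c(y1 = table$y1[idx[k]], y2 = table$y2[idx[k]])
      r
    })
  } else {
    if ("BkM" %in% properties)
      embed_prewarm(lapply(records, function(r) r$ligand$mol))
    out <- lapply(records, function(r) {
      r$y <- c(y1 = internal_property(r$ligand, properties[1], bk_cfg),
               y2 = internal_property(r$ligand, properties[2], bk_cfg))
      names(r$y) <- properties
      r
    })
  }
  if (any(!is.finite(unlist(lapply(out, `[[`, "y")))))
    stop("labels contain non-finite values")
  out
}

# memoized per canonical string + property
.prop_cache <- new.env(parent = emptyenv())

internal_property <- function(ligand, property, bk_cfg) {
  key <- paste0(property, "\r", encode_anchored(ligand))
  hit <- .prop_cache[[key]]
  if (!is.null(hit)) return(hit)
  v <- switch(property,
    logP = log_p(ligand),
    BkM = bk_m(ligand, cfg = bk_cfg),
    stop("unknown internal property: ", property))
  .prop_cache[[key]] <- v
  v
}

#' Property oracle over free ligands
#'
#' Returns a function mapping an anchored-SMILES string (or anchored ligand)
#' to the named (log P, Bk_M) vector; used for post-hoc verification of
#' free-ligand optimization campaigns.
#'
#' @param bk_cfg Bk_M probe configuration.
#' @export
oracle_free_ligand <- function(bk_cfg = bk_m_config(grid = 0.35)) {
  function(lig) {
    if (is.character(lig)) lig <- decode_anchored(lig)
    c(logP = internal_property(lig, "logP", bk_cfg),
      BkM = internal_property(lig, "BkM", bk_cfg))
  }
}

#' Property oracle from an external label table
#'
#' For properties computed outside the package (e.g. DFT HOMO-LUMO gap and
#' metal partial charge), verification looks the decoded ligand up by its
#' canonical anchored SMILES.
#'
#' @param table data.frame with columns smiles, y1, y2.
#' @export
oracle_from_table <- function(table) {
  key <- vapply(table$smiles, function(s)
    as.character(canonicalize_anchored(s)), "")
  function(lig) {
    s <- if (is.character(lig)) as.character(canonicalize_anchored(lig))
         else as.character(encode_anchored(lig))
    i <- match(s, key)
    if (is.na(i)) stop("oracle failure: ligand not in property table")
    c(y1 = table$y1[i], y2 = table$y2[i])
  }
}

# ---- conditional training ---------------------------------------------------

#' Train a conditional model (VAE + property head)
#'
#' @param labeled labeled records from [label_records()] (outlier-cleaned).
#' @param config from [jtvae_config()].
#' @param seed integer seed.
#' @return `jtvae_model` with a property head and label statistics.
#' @export
train_conditional <- function(labeled, config = jtvae_config(), seed = 1L) {
  Y <- t(vapply(labeled, `[[`, numeric(2), "y"))
  model <- jtvae_train(labeled, config, seed = seed, labels = Y)
  model$prop_names <- names(labeled[[1]]$y)
  model
}

#' Predict properties from latent points
#'
#' @param model conditional `jtvae_model`.
#' @param z latent vector or matrix (rows = points).
#' @param normalized return z-scored values instead of original units.
#' @return matrix of predicted properties.
#' @export
predict_properties <- function(model, z, normalized = FALSE) {
  if (is.null(model$prop_stats)) stop("model has no property head")
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  p <- model$params
  hp <- pmax(z %*% t(p$Wp1) + matrix(p$bp1, nrow(z), length(p$bp1), byrow = TRUE), 0)
  yh <- hp %*% t(p$Wp2) + matrix(p$bp2, nrow(z), 2, byrow = TRUE)
  if (!normalized)
    yh <- sweep(sweep(yh, 2, model$prop_stats$sd, "*"), 2,
                model$prop_stats$mean, "+")
  colnames(yh) <- model$prop_names
  yh
}

# gradient of (direction . normalized prediction) with respect to z
objective_grad <- function(model, z, dir) {
  p <- model$params
  a1 <- as.numeric(p$Wp1 %*% z + p$bp1)
  back <- as.numeric(t(p$Wp2) %*% dir) * (a1 > 0)
  as.numeric(t(p$Wp1) %*% back)
}

objective_value <- function(model, z, dir) {
  sum(predict_properties(model, z, normalized = TRUE) * dir)
}

# ---- regions and directions -------------------------------------------------

#' The eight compass directions in normalized property space
#'
#' D1 = max y1, D2 = max y2, D3 = min y1, D4 = min y2; D5-D8 are the
#' diagonals (max/min of y1 +/- y2), scaled to unit norm.
#'
#' @param id "D1".."D8" (or 1..8).
#' @return unit-norm numeric vector of length 2.
#' @export
compass_direction <- function(id) {
  if (is.numeric(id)) id <- paste0("D", id)
  s <- 1 / sqrt(2)
  dirs <- list(D1 = c(1, 0), D2 = c(0, 1), D3 = c(-1, 0), D4 = c(0, -1),
               D5 = c(s, s), D6 = c(-s, -s), D7 = c(s, -s), D8 = c(-s, s))
  d <- dirs[[id]]
  if (is.null(d)) stop("unknown direction: ", id)
  d
}

#' Sample optimization prompts from property-space regions
#'
#' R1/R2: top decile of y1/y2; R3/R4: bottom decile of y1/y2; C: both
#' properties within 0.5 standard deviations of their means.
#'
#' @param labeled labeled records.
#' @param region one of "R1", "R2", "R3", "R4", "C".
#' @param k number of prompts (sampled without replacement).
#' @param seed integer seed.
#' @export
sample_prompts <- function(labeled, region, k, seed = 1L) {
  Y <- t(vapply(labeled, `[[`, numeric(2), "y"))
  idx <- switch(region,
    R1 = which(Y[, 1] >= stats::quantile(Y[, 1], 0.9)),
    R2 = which(Y[, 2] >= stats::quantile(Y[, 2], 0.9)),
    R3 = which(Y[, 1] <= stats::quantile(Y[, 1], 0.1)),
    R4 = which(Y[, 2] <= stats::quantile(Y[, 2], 0.1)),
    C = {
      m <- colMeans(Y); s <- apply(Y, 2, stats::sd)
      if (any(s < 1e-12))
        stop("region C undefined: degenerate property variance")
      which(abs(Y[, 1] - m[1]) <= 0.5 * s[1] & abs(Y[, 2] - m[2]) <= 0.5 * s[2])
    },
    stop("unknown region: ", region))
  if (region != "C" && length(unique(Y[, if (region %in% c("R2", "R4")) 2 else 1])) == 1L)
    stop("region ", region, " undefined: all labels identical")
  if (length(idx) < k)
    stop("region ", region, " holds only ", length(idx),
         " records; reduce k to at most that")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  labeled[sample(idx, k)]
}

# ---- optimization -----------------------------------------------------------

#' Directional optimization of a ligand prompt in latent space
#'
#' Gradient ascent on the projection of the (normalized) predicted
#' properties onto a compass direction.  Each candidate step is decoded and
#' gated on the Tanimoto similarity of its free ligand to the prompt: steps
#' below the threshold are rejected with the step size halved.  Accepted
#' steps are recorded with their decoded string, predicted properties and
#' similarity; the predicted objective is non-decreasing over accepted steps
#' by construction.
#'
#' @param model conditional `jtvae_model`.
#' @param prompt a (labeled) corpus record.
#' @param direction "D1".."D8" or a unit vector of length 2.
#' @param tc_threshold minimum Tanimoto similarity to the prompt (the
#'   reference thresholds are 0.20 for kappa-1 and 0.15 for kappa-2 models).
#' @param step0 initial step size in latent units.
#' @param max_steps maximum accepted steps.
#' @param max_retries step halvings before giving up on a step.
#' @param tol convergence tolerance on the predicted objective.
#' @return object of class `opt_trajectory`.
#' @export
latent_optimize <- function(model, prompt, direction, tc_threshold = 0.2,
                            step0 = 0.1, max_steps = 80L, max_retries = 6L,
                            tol = 1e-4) {
  dir_id <- if (is.character(direction)) direction else NA_character_
  dir <- if (is.character(direction)) compass_direction(direction) else direction
  z <- as.numeric(encode_mu(model, list(prompt)))
  fp0 <- morgan_fingerprint(prompt$ligand$mol)
  g <- objective_value(model, z, dir)
  steps <- list(list(z = z, smiles = as.character(
    canonicalize_anchored(prompt$anchored_smiles)),
    yhat = as.numeric(predict_properties(model, z)), tc = 1, g = g))
  reason <- "max_steps"
  for (it in seq_len(max_steps)) {
    grad <- objective_grad(model, z, dir)
    gn <- sqrt(sum(grad^2))
    if (gn < 1e-12) { reason <- "converged"; break }
    alpha <- step0
    accepted <- FALSE
    for (try in seq_len(max_retries)) {
      z2 <- z + alpha * grad / gn
      dec <- decode_z(model, z2, mode = "greedy")
      if (!is.null(dec)) {
        lig <- tryCatch(decode_anchored(dec$smiles), error = function(e) NULL)
        if (!is.null(lig)) {
          tc <- tanimoto(fp0, morgan_fingerprint(lig$mol))
          g2 <- objective_value(model, z2, dir)
          if (tc >= tc_threshold && g2 >= g) {
            conv <- abs(g2 - g) < tol
            z <- z2; g <- g2; accepted <- TRUE
            # a latent move that decodes to the same ligand advances the
            # walk without adding a trajectory step
            if (dec$smiles != steps[[length(steps)]]$smiles)
              steps[[length(steps) + 1L]] <- list(
                z = z, smiles = dec$smiles,
                yhat = as.numeric(predict_properties(model, z)), tc = tc, g = g)
            if (conv) reason <- "converged"
            break
          }
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) { reason <- "similarity_exhausted"; break }
    if (reason == "converged") break
  }
  structure(list(prompt = prompt, direction = dir, direction_id = dir_id,
                 steps = steps, termination = reason), class = "opt_trajectory")
}

#' @export
print.opt_trajectory <- function(x, ...) {
  cat("<opt_trajectory> ", x$direction_id %||% "custom", ", ",
      length(x$steps), " step(s), terminated: ", x$termination, "\n", sep = "")
  cat("  prompt: ", x$steps[[1]]$smiles, "\n", sep = "")
  cat("  final:  ", x$steps[[length(x$steps)]]$smiles, "\n", sep = "")
  invisible(x)
}

#' Verify an optimization trajectory against a property oracle
#'
#' Recomputes both properties for the prompt and the final decoded ligand
#' and requires every property with a nonzero direction component to move
#' strictly in the requested sense (ties count as unverified).
#'
#' @param trajectory an `opt_trajectory`.
#' @param oracle function(anchored smiles or ligand) -> numeric length 2.
#' @return list(verified, delta, reason).
#' @export
verify_trajectory <- function(trajectory, oracle) {
  final <- trajectory$steps[[length(trajectory$steps)]]$smiles
  start <- trajectory$steps[[1]]$smiles
  res <- tryCatch({
    y0 <- oracle(start)
    y1 <- oracle(final)
    delta <- y1 - y0
    d <- trajectory$direction
    ok <- TRUE
    for (k in 1:2) {
      if (abs(d[k]) > 1e-12 && !(sign(delta[k]) == sign(d[k]) && delta[k] != 0))
        ok <- FALSE
    }
    list(verified = ok, delta = delta, reason = if (ok) "ok" else "direction not satisfied")
  }, error = function(e)
    list(verified = FALSE, delta = c(NA_real_, NA_real_),
         reason = paste("oracle failure:", conditionMessage(e))))
  res
}

# normalized property-space path length of a trajectory
trajectory_length <- function(trajectory, prop_stats) {
  ys <- t(vapply(trajectory$steps, `[[`, numeric(2), "yhat"))
  yn <- sweep(sweep(ys, 2, prop_stats$mean), 2, prop_stats$sd, "/")
  if (nrow(yn) < 2L) return(0)
  sum(sqrt(rowSums(diff(yn)^2)))
}

# ---- campaign ---------------------------------------------------------------

#' Run a conditional optimization campaign
#'
#' For every sampled prompt and every requested direction, runs
#' [latent_optimize()] and verifies the outcome with the oracle.
#'
#' @param model conditional model.
#' @param labeled labeled training records (prompt source).
#' @param regions character vector of region ids.
#' @param directions character vector of direction ids.
#' @param k prompts per region.
#' @param tc_threshold similarity threshold.
#' @param oracle property oracle for verification.
#' @param seed integer seed.
#' @param ... passed to [latent_optimize()].
#' @return list of result entries (region, direction, trajectory, verification).
#' @export
run_campaign <- function(model, labeled, regions = c("R1", "R2", "R3", "R4", "C"),
                         directions = paste0("D", 1:8), k = 5L,
                         tc_threshold = 0.2, oracle = oracle_free_ligand(),
                         seed = 1L, ...) {
  results <- list()
  for (rg in regions) {
    prompts <- sample_prompts(labeled, rg, k, seed = seed + str_hash(rg) %% 1000L)
    for (p in prompts) for (d in directions) {
      traj <- latent_optimize(model, p, d, tc_threshold = tc_threshold, ...)
      ver <- verify_trajectory(traj, oracle)
      results[[length(results) + 1L]] <- list(
        region = rg, direction = d, prompt_id = p$id,
        trajectory = traj, verification = ver)
    }
  }
  results
}

#' Funnel report of a conditional campaign
#'
#' Per region: percentage similar (the optimizer moved at least one step
#' within the similarity gate), valid among similar, unique among
#' similar-and-valid, novel among similar-valid-unique (relative to the
#' training set), verified among the rest, and the direction of the longest
#' trajectory in normalized property space.
#'
#' @param results from [run_campaign()].
#' @param model the conditional model (for label statistics).
#' @param training training records for novelty.
#' @return data.frame, one row per region.
#' @export
conditional_report <- function(results, model, training) {
  train_canon <- unique(vapply(training, function(r)
    as.character(canonicalize_anchored(r$anchored_smiles)), ""))
  regions <- unique(vapply(results, `[[`, "", "region"))
  rows <- lapply(regions, function(rg) {
    rs <- Filter(function(x) x$region == rg, results)
    n <- length(rs)
    final <- vapply(rs, function(x)
      x$trajectory$steps[[length(x$trajectory$steps)]]$smiles, "")
    similar <- vapply(rs, function(x) length(x$trajectory$steps) > 1L, TRUE)
    mode <- decode_anchored(rs[[1]]$trajectory$steps[[1]]$smiles)$denticity
    valid <- similar & vapply(final, function(s)
      check_anchor_validity(s, mode)$valid, TRUE)
    uniq <- valid & !duplicated(final)
    novel <- uniq & !final %in% train_canon
    verified <- novel & vapply(rs, function(x) isTRUE(x$verification$verified), TRUE)
    lens <- vapply(rs, function(x)
      trajectory_length(x$trajectory, model$prop_stats), 0)
    pct <- function(a, b) if (sum(b) == 0) NA_real_ else 100 * sum(a) / sum(b)
    data.frame(region = rg,
               n = n,
               similar_pct = 100 * mean(similar),
               valid_pct = pct(valid, similar),
               unique_pct = pct(uniq, valid),
               novel_pct = pct(novel, uniq),
               verified_pct = pct(verified, novel),
               longest_direction = rs[[which.max(lens)]]$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
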