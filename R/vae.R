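# Junction-tree variational autoencoder.
#
# Architecture (all sizes configurable): molecules are serialized as
# junction-tree DFS token streams.  The encoder maps tree features (token
# counts) and graph features (composition, bond and ring counts, folded
# circular fingerprint) through linear Gaussian heads to a split latent
# z = (z_tree, z_graph).  The decoder is a latent-conditioned recurrent
# network over the token stream; fragment-by-fragment assembly with
# feasibility masking enforces chemical validity of everything it emits.
# An optional property head (small MLP on z) makes the model conditional
# and differentiable with respect to the latent point.  Training minimizes
# reconstruction cross-entropy + KL regularization (+ property MSE), with
# hand-written backpropagation and Adam.

#' Model configuration
#'
#' @param hidden decoder recurrent state size.
#' @param embed token embedding size.
#' @param latent_tree,latent_graph latent dimensions (default 28 + 28).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param kl_weight final KL weight.
#' @param kl_warmup epochs over which the KL weight ramps from 0.
#' @param prop_weight weight of the property regression loss.
#' @param prop_hidden property-head hidden width.
#' @param max_tokens decoding length cap.
#' @param batch minibatch size (0 = full batch).
#' @export
jtvae_config <- function(hidden = 64L, embed = 24L, latent_tree = 28L,
                         latent_graph = 28L, epochs = 120L, lr = 5e-3,
                         kl_weight = 0.005, kl_warmup = 20L,
                         prop_weight = 1.0, prop_hidden = 24L,
                         max_tokens = 80L, batch = 0L) {
  as.list(environment())
}

# ---- vocabulary -------------------------------------------------------------

#' Build the cluster vocabulary and token inventory from training records
#'
#' @param records list of corpus records.
#' @return object of class `jt_vocabulary`: cluster labels with counts, the
#'   decoder token inventory, and per-record token sequences.
#' @export
build_vocabulary <- function(records) {
  if (!length(records)) stop("empty corpus: cannot build a vocabulary")
  seqs <- lapply(records, function(r)
    jtree_serialize(tree_decompose(r$anchored_smiles)))
  tokens <- sort(unique(unlist(seqs)))
  labels <- sort(unique(unlist(lapply(seqs, function(s) {
    p <- lapply(s, parse_token)
    unlist(lapply(p, function(t) if (t$type %in% c("R", "D")) t$label else NULL))
  }))))
  label_counts <- table(unlist(lapply(seqs, function(s) {
    p <- lapply(s, parse_token)
    unlist(lapply(p, function(t) if (t$type %in% c("R", "D")) t$label else NULL))
  })))
  structure(list(tokens = tokens, labels = labels,
                 label_counts = label_counts[labels], sequences = seqs),
            class = "jt_vocabulary")
}

# fraction of a held-out record set whose tokens are covered
vocabulary_coverage <- function(vocab, records) {
  seqs <- lapply(records, function(r)
    jtree_serialize(tree_decompose(r$anchored_smiles)))
  mean(vapply(seqs, function(s) all(s %in% vocab$tokens), TRUE))
}

# ---- features ---------------------------------------------------------------

FEATURE_ELEMENTS <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I",
                      "Li", "Be", "Ir")

tree_features <- function(tokens, vocab) {
  v <- as.numeric(table(factor(tokens, levels = vocab$tokens)))
  c(v, log1p(length(tokens))) / 4
}

graph_features <- function(mol) {
  el <- as.numeric(table(factor(mol$atoms$element, levels = FEATURE_ELEMENTS)))
  bo <- as.numeric(table(factor(mol$bonds$order, levels = 1:3)))
  dat <- sum(mol$bonds$dative)
  nring <- length(find_rings(mol))
  heavy <- length(mol_heavy_atoms(mol))
  htot <- sum(vapply(seq_len(mol_natoms(mol)), function(i) mol_hcount(mol, i), 0L))
  fp <- as.numeric(morgan_fingerprint(mol, radius = 2L, nbits = 64L))
  c(el / 4, bo / 4, dat, nring, heavy / 10, htot / 10, fp)
}

# ---- parameters -------------------------------------------------------------

init_params <- function(cfg, vocab, dt, dg, with_prop = FALSE) {
  V <- length(vocab$tokens)
  Zt <- cfg$latent_tree; Zg <- cfg$latent_graph; Z <- Zt + Zg
  H <- cfg$hidden; E <- cfg$embed
  g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))),
                               nr, nc)
  p <- list(
    Wmu_t = g(Zt, dt), bmu_t = numeric(Zt),
    Wlv_t = g(Zt, dt) * 0.1, blv_t = rep(-2, Zt),
    Wmu_g = g(Zg, dg), bmu_g = numeric(Zg),
    Wlv_g = g(Zg, dg) * 0.1, blv_g = rep(-2, Zg),
    Emb = g(V + 1L, E),
    Wx = g(H, E), Wz = g(H, Z), Wh = g(H, H) * 0.5, bh = numeric(H),
    U = g(V, H), bu = numeric(V)
  )
  if (with_prop) {
    P <- cfg$prop_hidden
    p$Wp1 <- g(P, Z); p$bp1 <- numeric(P)
    p$Wp2 <- g(2L, P); p$bp2 <- numeric(2L)
  }
  p
}

zeros_like <- function(p) lapply(p, function(x) if (is.matrix(x)) 0 * x else 0 * x)

# ---- forward / backward -----------------------------------------------------

encode_mu <- function(model, records) {
  feats <- model_features(model, records)
  mu_t <- feats$xt %*% t(model$params$Wmu_t) +
    matrix(model$params$bmu_t, nrow(feats$xt), length(model$params$bmu_t), byrow = TRUE)
  mu_g <- feats$xg %*% t(model$params$Wmu_g) +
    matrix(model$params$bmu_g, nrow(feats$xg), length(model$params$bmu_g), byrow = TRUE)
  cbind(mu_t, mu_g)
}

model_features <- function(model, records) {
  vocab <- model$vocab
  seqs <- lapply(records, function(r)
    jtree_serialize(tree_decompose(r$anchored_smiles)))
  xt <- t(vapply(seqs, tree_features, numeric(length(vocab$tokens) + 1L),
                 vocab = vocab))
  xg <- t(vapply(records, function(r)
    graph_features(parse_smiles(r$anchored_smiles)),
    numeric(length(graph_features(parse_smiles(records[[1]]$anchored_smiles))))))
  list(xt = xt, xg = xg, seqs = seqs)
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# one full forward+backward pass over a batch; returns loss pieces and grads
vae_step <- function(params, cfg, ids_in, ids_out, mask, xt, xg, eps,
                     beta, y = NULL, prop_weight = 0) {
  B <- nrow(ids_in); T <- ncol(ids_in)
  V <- nrow(params$U); H <- cfg$hidden
  Zt <- cfg$latent_tree; Zg <- cfg$latent_graph; Z <- Zt + Zg

  rowrep <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

  mu_t <- xt %*% t(params$Wmu_t) + rowrep(params$bmu_t, B)
  lv_t <- xt %*% t(params$Wlv_t) + rowrep(params$blv_t, B)
  mu_g <- xg %*% t(params$Wmu_g) + rowrep(params$bmu_g, B)
  lv_g <- xg %*% t(params$Wlv_g) + rowrep(params$blv_g, B)
  lv_t <- pmin(pmax(lv_t, -8), 2); lv_g <- pmin(pmax(lv_g, -8), 2)
  mu <- cbind(mu_t, mu_g); lv <- cbind(lv_t, lv_g)
  z <- mu + exp(lv / 2) * eps

  # decoder forward
  hs <- vector("list", T + 1L)
  hs[[1]] <- matrix(0, B, H)
  ps <- vector("list", T)
  zWz <- z %*% t(params$Wz)
  ce <- 0
  for (t in seq_len(T)) {
    e_t <- params$Emb[ids_in[, t], , drop = FALSE]
    pre <- e_t %*% t(params$Wx) + zWz + hs[[t]] %*% t(params$Wh) + rowrep(params$bh, B)
    h <- tanh(pre)
    hs[[t + 1L]] <- h
    logits <- h %*% t(params$U) + rowrep(params$bu, B)
    p <- softmax_rows(logits)
    ps[[t]] <- p
    idx <- cbind(seq_len(B), ids_out[, t])
    ce <- ce - sum(log(pmax(p[idx], 1e-12)) * mask[, t])
  }
  kl <- 0.5 * sum((mu^2 + exp(lv) - 1 - lv))

  # property head
  mse <- 0; yhat <- NULL; hp <- NULL
  if (!is.null(y) && prop_weight > 0) {
    a1 <- z %*% t(params$Wp1) + rowrep(params$bp1, B)
    hp <- pmax(a1, 0)
    yhat <- hp %*% t(params$Wp2) + rowrep(params$bp2, B)
    mse <- sum((yhat - y)^2)
  }
  loss <- (ce + beta * kl + prop_weight * mse) / B

  # ---- backward ----
  gr <- zeros_like(params)
  dz <- matrix(0, B, Z)
  dh_next <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    p <- ps[[t]]
    dlog <- p * mask[, t]
    idx <- cbind(seq_len(B), ids_out[, t])
    dlog[idx] <- dlog[idx] - mask[, t]
    h <- hs[[t + 1L]]
    gr$U <- gr$U + t(dlog) %*% h
    gr$bu <- gr$bu + colSums(dlog)
    dh <- dlog %*% params$U + dh_next
    dpre <- dh * (1 - h^2)
    e_t <- params$Emb[ids_in[, t], , drop = FALSE]
    gr$Wx <- gr$Wx + t(dpre) %*% e_t
    gr$Wz <- gr$Wz + t(dpre) %*% z
    gr$Wh <- gr$Wh + t(dpre) %*% hs[[t]]
    gr$bh <- gr$bh + colSums(dpre)
    dE <- dpre %*% params$Wx
    for (b in seq_len(B)) {
      r <- ids_in[b, t]
      gr$Emb[r, ] <- gr$Emb[r, ] + dE[b, ]
    }
    dz <- dz + dpre %*% params$Wz
    dh_next <- dpre %*% params$Wh
  }
  if (!is.null(y) && prop_weight > 0) {
    dyhat <- prop_weight * 2 * (yhat - y)
    gr$Wp2 <- t(dyhat) %*% hp
    gr$bp2 <- colSums(dyhat)
    dhp <- dyhat %*% params$Wp2
    da1 <- dhp * (hp > 0)
    gr$Wp1 <- t(da1) %*% z
    gr$bp1 <- colSums(da1)
    dz <- dz + da1 %*% params$Wp1
  }
  dmu <- dz + beta * mu
  dlv <- dz * eps * 0.5 * exp(lv / 2) + beta * 0.5 * (exp(lv) - 1)
  tsel <- seq_len(Zt); gsel <- Zt + seq_len(Zg)
  gr$Wmu_t <- t(dmu[, tsel, drop = FALSE]) %*% xt
  gr$bmu_t <- colSums(dmu[, tsel, drop = FALSE])
  gr$Wlv_t <- t(dlv[, tsel, drop = FALSE]) %*% xt
  gr$blv_t <- colSums(dlv[, tsel, drop = FALSE])
  gr$Wmu_g <- t(dmu[, gsel, drop = FALSE]) %*% xg
  gr$bmu_g <- colSums(dmu[, gsel, drop = FALSE])
  gr$Wlv_g <- t(dlv[, gsel, drop = FALSE]) %*% xg
  gr$blv_g <- colSums(dlv[, gsel, drop = FALSE])
  gr <- lapply(gr, function(gm) gm / B)

  list(loss = loss, ce = ce / B, kl = kl / B, mse = mse / B, grads = gr)
}

# ---- training ---------------------------------------------------------------

#' Train a junction-tree VAE
#'
#' @param records training corpus records (pass them through
#'   [apply_training_filters()] first).
#' @param config from [jtvae_config()].
#' @param seed integer seed controlling initialization and sampling noise.
#' @param labels optional numeric matrix (n x 2) of property labels for
#'   conditional training; z-normalized internally.
#' @param verbose print per-epoch metrics.
#' @return object of class `jtvae_model` with the vocabulary, parameters,
#'   config and per-epoch metric history.
#' @export
jtvae_train <- function(records, config = jtvae_config(), seed = 1L,
                        labels = NULL, verbose = FALSE) {
  if (!length(records)) stop("empty corpus")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  vocab <- build_vocabulary(records)
  V <- length(vocab$tokens)
  tok2id <- stats::setNames(seq_len(V), vocab$tokens)
  seqs_id <- lapply(vocab$sequences, function(s) unname(tok2id[s]))
  B <- length(records)
  T <- max(vapply(seqs_id, length, 0L))
  BOS <- V + 1L
  ids_out <- matrix(1L, B, T); ids_in <- matrix(BOS, B, T)
  mask <- matrix(0, B, T)
  for (b in seq_len(B)) {
    s <- seqs_id[[b]]
    ids_out[b, seq_along(s)] <- s
    if (length(s) > 1L) ids_in[b, 2:length(s)] <- s[-length(s)]
    mask[b, seq_along(s)] <- 1
  }

  model <- structure(list(vocab = vocab, config = config, seed = seed),
                     class = "jtvae_model")
  feats <- model_features(model, records)
  xt <- feats$xt; xg <- feats$xg
  dt <- ncol(xt); dg <- ncol(xg)

  y <- NULL; prop_stats <- NULL
  with_prop <- !is.null(labels)
  if (with_prop) {
    labels <- as.matrix(labels)
    if (ncol(labels) != 2L) stop("labels must have two columns")
    if (any(!is.finite(labels))) stop("labels must be finite")
    sds <- apply(labels, 2, stats::sd)
    if (any(sds < 1e-9)) stop("degenerate property variance")
    prop_stats <- list(mean = colMeans(labels), sd = sds)
    y <- sweep(sweep(labels, 2, prop_stats$mean), 2, prop_stats$sd, "/")
  }

  params <- init_params(config, vocab, dt, dg, with_prop = with_prop)
  mstate <- zeros_like(params); vstate <- zeros_like(params)
  t_adam <- 0
  history <- data.frame(epoch = integer(), loss = numeric(), ce = numeric(),
                        kl = numeric(), mse = numeric(), beta = numeric())
  Z <- config$latent_tree + config$latent_graph
  for (ep in seq_len(config$epochs)) {
    beta <- config$kl_weight * min(1, ep / max(1, config$kl_warmup))
    eps <- matrix(stats::rnorm(B * Z), B, Z)
    st <- vae_step(params, config, ids_in, ids_out, mask, xt, xg, eps, beta,
                   y = y, prop_weight = if (with_prop) config$prop_weight else 0)
    t_adam <- t_adam + 1
    b1 <- 0.9; b2 <- 0.999; lr <- config$lr
    for (nm in names(params)) {
      gnm <- st$grads[[nm]]
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gnm
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gnm^2
      mhat <- mstate[[nm]] / (1 - b1^t_adam)
      vhat <- vstate[[nm]] / (1 - b2^t_adam)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = st$loss,
                                         ce = st$ce, kl = st$kl,
                                         mse = st$mse, beta = beta))
    if (!is.finite(st$loss)) stop("divergent loss at epoch ", ep)
    if (verbose && (ep %% 20L == 0L || ep == 1L))
      message(sprintf("epoch %d loss %.4f ce %.4f kl %.2f mse %.4f",
                      ep, st$loss, st$ce, st$kl, st$mse))
  }
  model$params <- params
  model$history <- history
  model$prop_stats <- prop_stats
  model$tok2id <- tok2id
  model <- attach_token_meta(model)
  model
}

#' Save / load a trained model
#'
#' The checkpoint directory holds the parameters (RDS) and the config and
#' vocabulary as JSON, so a reloaded model is byte-identical.
#' @param model a `jtvae_model`.
#' @param dir checkpoint directory.
#' @export
jtvae_save <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(model$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  writeLines(model$vocab$tokens, file.path(dir, "tokens.txt"))
  invisible(dir)
}

#' @rdname jtvae_save
#' @export
jtvae_load <- function(dir) readRDS(file.path(dir, "model.rds"))
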