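# Decoding from latent space: feasibility-masked fragment-by-fragment
# assembly, unconditional sampling, and reconstruction.

# cheap compatibility cache: can token `tok` (a D-token) attach to a cluster
# with label `plab`?  (slot range + element/charge match; valence is checked
# by the actual assembly step)
.compat_cache <- new.env(parent = emptyenv())

token_compatible <- function(plab, tok, meta) {
  pf <- fragment_of_label(plab)
  cf <- fragment_of_label(meta$label)
  max(meta$ps) <= mol_natoms(pf) && max(meta$cs) <= mol_natoms(cf) &&
    all(pf$atoms$element[meta$ps] == cf$atoms$element[meta$cs]) &&
    all(pf$atoms$charge[meta$ps] == cf$atoms$charge[meta$cs])
}

# logical vector over the whole token inventory: which D-tokens can attach
# under a parent cluster with label `plab`; cached per (model vocab, label)
compat_vector <- function(model, plab) {
  key <- paste0(model$vocab_id %||% "", "\r", plab)
  hit <- .compat_cache[[key]]
  if (!is.null(hit)) return(hit)
  meta <- model$token_meta
  v <- vapply(seq_along(meta), function(k) {
    m <- meta[[k]]
    if (m$type != "D") return(FALSE)
    token_compatible(plab, model$vocab$tokens[k], m)
  }, TRUE)
  .compat_cache[[key]] <- v
  v
}

attach_token_meta <- function(model) {
  model$token_meta <- lapply(model$vocab$tokens, parse_token)
  model$token_type <- vapply(model$token_meta, `[[`, "", "type")
  model$vocab_id <- str_hash(paste(model$vocab$tokens, collapse = "\r"))
  model
}

# decode one latent vector into a molecule via the trained decoder
# mode "greedy": argmax with fallback; "sample": softmax sampling (uses the
# current RNG stream)
decode_z <- function(model, z, mode = c("greedy", "sample"),
                     temperature = 1.0) {
  mode <- match.arg(mode)
  p <- model$params
  cfg <- model$config
  V <- length(model$vocab$tokens)
  if (is.null(model$token_meta)) model <- attach_token_meta(model)
  ttype <- model$token_type
  H <- cfg$hidden
  h <- matrix(0, 1, H)
  zr <- matrix(z, 1)
  zWz <- zr %*% t(p$Wz)
  prev_id <- V + 1L   # BOS
  st <- assembly_new()
  tokens <- character(0)

  for (step in seq_len(cfg$max_tokens)) {
    pre <- p$Emb[prev_id, , drop = FALSE] %*% t(p$Wx) + zWz +
      h %*% t(p$Wh) + matrix(p$bh, 1)
    h <- tanh(pre)
    logits <- as.numeric(h %*% t(p$U) + p$bu)
    # structural mask
    depth <- length(st$stack)
    feas <- (ttype == "R" & depth == 0L) |
            (ttype == "E" & depth == 1L) |
            (ttype == "U" & depth > 1L)
    if (depth >= 1L)
      feas <- feas | compat_vector(model, st$stack[[depth]]$label)
    if (!any(feas)) return(NULL)
    logits[!feas] <- -Inf
    chosen <- NA_integer_
    if (mode == "greedy") {
      ord <- order(logits, decreasing = TRUE)
      for (k in ord) {
        if (!is.finite(logits[k])) break
        st2 <- assembly_step(st, model$vocab$tokens[k])
        if (!is.null(st2)) { chosen <- k; st <- st2; break }
      }
    } else {
      ll <- logits / temperature
      repeat {
        if (!any(is.finite(ll))) break
        pr <- exp(ll - max(ll, na.rm = TRUE))
        pr[!is.finite(pr)] <- 0
        k <- sample.int(V, 1L, prob = pr)
        st2 <- assembly_step(st, model$vocab$tokens[k])
        if (!is.null(st2)) { chosen <- k; st <- st2; break }
        ll[k] <- -Inf
      }
    }
    if (is.na(chosen)) return(NULL)
    tokens <- c(tokens, model$vocab$tokens[chosen])
    prev_id <- chosen
    if (st$done) {
      vc <- mol_valence_ok(st$mol)
      if (!vc$ok) return(NULL)
      return(list(mol = st$mol, tokens = tokens,
                  smiles = as.character(canonical_smiles(st$mol))))
    }
  }
  NULL
}

#' Sample ligand strings from a trained model
#'
#' Draws latent points from the standard normal prior and decodes each with
#' feasibility-masked fragment assembly, so every returned string parses and
#' assembles into a chemically valid molecule.  Anchor-pattern validity is
#' not forced: measure it downstream with [check_anchor_validity()].  Draws
#' whose decoding dead-ends are resampled; the count is reported as an
#' attribute.
#'
#' @param model trained `jtvae_model`.
#' @param n number of samples.
#' @param seed integer seed.
#' @param temperature decoder softmax temperature.
#' @return character vector of anchored-SMILES strings with attribute
#'   `resampled`.
#' @export
jtvae_sample <- function(model, n, seed = 1L, temperature = 1.0) {
  if (n == 0L) return(character(0))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Z <- model$config$latent_tree + model$config$latent_graph
  out <- character(n)
  resampled <- 0L
  for (k in seq_len(n)) {
    repeat {
      z <- stats::rnorm(Z)
      dec <- decode_z(model, z, mode = "sample", temperature = temperature)
      if (!is.null(dec)) { out[k] <- dec$smiles; break }
      resampled <- resampled + 1L
      if (resampled > 50L * n) stop("decoder failure rate too high")
    }
  }
  attr(out, "resampled") <- resampled
  out
}

#' Reconstruct a record through the autoencoder
#'
#' Encodes to the latent mean (no sampling noise) and decodes greedily;
#' the match flag compares canonical anchored strings.
#'
#' @param model trained `jtvae_model`.
#' @param record a corpus record (must be inside the vocabulary closure).
#' @return list(smiles, match).
#' @export
jtvae_reconstruct <- function(model, record) {
  seqs <- jtree_serialize(tree_decompose(record$anchored_smiles))
  if (!all(seqs %in% model$vocab$tokens))
    stop("record outside the vocabulary closure: ",
         paste(setdiff(seqs, model$vocab$tokens), collapse = " "))
  mu <- encode_mu(model, list(record))
  dec <- decode_z(model, as.numeric(mu), mode = "greedy")
  target <- as.character(canonicalize_anchored(record$anchored_smiles))
  if (is.null(dec)) return(list(smiles = NA_character_, match = FALSE))
  list(smiles = dec$smiles, match = identical(dec$smiles, target))
}
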