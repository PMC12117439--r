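# Bk_M steric-bulk descriptor.
#
# Quantifies steric bulk around the metal-anchor atom(s) as a sum of atomic
# van-der-Waals volumes intersecting a probe sphere placed on the vacant
# coordination vector of each anchor.  A single 3D conformer comes from a
# seeded distance-geometry embedding; kappa-2 ligands sum the contributions
# of both probes.

BONDI_RADII <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

#' Default Bk_M probe configuration
#'
#' Probe geometry: probe center offset 2.0 angstrom from the anchor along its
#' vacant coordination vector, probe radius 3.5 angstrom, grid spacing
#' 0.2 angstrom, Bondi van-der-Waals radii.  Exposed as a config block so an
#' alternative probe definition can be swapped in.
#'
#' @param offset anchor-to-probe-center distance (angstrom).
#' @param probe_radius probe sphere radius (angstrom).
#' @param grid grid spacing for volume integration (angstrom).
#' @param radii named vector of van-der-Waals radii (angstrom).
#' @export
bk_m_config <- function(offset = 2.0, probe_radius = 3.5, grid = 0.2,
                        radii = BONDI_RADII) {
  list(offset = offset, probe_radius = probe_radius, grid = grid, radii = radii)
}

# 3D embedding through a batched distance-geometry service (RDKit ETKDG with
# a fixed random seed + force-field cleanup), so a (molecule, seed) pair is
# fully deterministic.  Results are cached per process; label whole corpora
# with embed_prewarm() to amortize interpreter startup.
.embed_cache <- new.env(parent = emptyenv())

embed_script <- function() {
  p <- system.file("python", "embed3d.py", package = "tmligen")
  if (!nzchar(p)) p <- file.path("inst", "python", "embed3d.py")
  if (!file.exists(p)) stop("embedding helper script not found")
  p
}

# run the embedding service on a batch of order-preserving SMILES strings
embed_batch_raw <- function(smiles, seed) {
  if (!nzchar(Sys.which("python")))
    stop("python (with RDKit) not found on PATH; required for 3D embedding")
  inp <- tempfile(); writeLines(smiles, inp)
  out <- suppressWarnings(system2("python",
    c(shQuote(embed_script()), as.integer(seed)),
    stdout = TRUE, stderr = FALSE, stdin = inp))
  unlink(inp)
  if (length(out) != length(smiles))
    stop("embedding failure: service returned ", length(out), " records for ",
         length(smiles), " molecules")
  lapply(out, jsonlite::fromJSON, simplifyVector = TRUE)
}

# embed one molecule (cached); returns list(coords, elements, bonds, sdf_row)
embed_3d <- function(mol, seed = 1L) {
  smi <- write_smiles(mol)   # order-preserving traversal
  emit <- attr(smi, "atom_order")
  key <- paste0(seed, "\r", as.character(smi))
  rec <- .embed_cache[[key]]
  if (is.null(rec)) {
    rec <- embed_batch_raw(as.character(smi), seed)[[1]]
    .embed_cache[[key]] <- rec
  }
  if (!isTRUE(rec$ok))
    stop("embedding failure: ", rec$error %||% "unknown")
  coords <- rec$coords
  if (!is.matrix(coords)) coords <- matrix(unlist(coords), ncol = 3, byrow = TRUE)
  elems <- rec$elements
  bonds <- data.frame(a1 = rec$bonds[, 1], a2 = rec$bonds[, 2])
  # heavy atoms come back in SMILES emission order; map molecule index -> row
  sdf_row <- integer(mol_natoms(mol))
  sdf_row[emit] <- seq_along(emit)
  for (k in seq_along(emit)) {
    if (elems[k] != mol$atoms$element[emit[k]])
      stop("embedding failure: atom order mismatch against service output")
  }
  list(coords = coords, elements = elems, bonds = bonds, sdf_row = sdf_row)
}

# warm the embedding cache for many ligands in one service call
embed_prewarm <- function(mols, seed = 1L) {
  smis <- lapply(mols, write_smiles)
  keys <- vapply(smis, function(s) paste0(seed, "\r", as.character(s)), "")
  todo <- which(vapply(keys, function(k) is.null(.embed_cache[[k]]), TRUE))
  if (!length(todo)) return(invisible(0L))
  recs <- embed_batch_raw(vapply(smis[todo], as.character, ""), seed)
  for (i in seq_along(todo)) .embed_cache[[keys[todo[i]]]] <- recs[[i]]
  invisible(length(todo))
}

# vacant coordination vector of an anchor: opposite the mean of unit vectors
# to its bonded neighbors (including H)
vacant_vector <- function(emb, row) {
  nb <- c(emb$bonds$a2[emb$bonds$a1 == row], emb$bonds$a1[emb$bonds$a2 == row])
  if (!length(nb)) stop("geometry error: anchor atom has no neighbors")
  p0 <- emb$coords[row, ]
  dirs <- t(vapply(nb, function(j) {
    d <- emb$coords[j, ] - p0
    d / sqrt(sum(d^2))
  }, numeric(3)))
  v <- -colSums(dirs)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-6) {
    # symmetric environment (e.g. linear anchor): take any perpendicular
    ref <- dirs[1, ]
    aux <- if (abs(ref[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(ref[2] * aux[3] - ref[3] * aux[2],
           ref[3] * aux[1] - ref[1] * aux[3],
           ref[1] * aux[2] - ref[2] * aux[1])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-6) stop("geometry error: no vacant coordination vector")
  }
  v / nv
}

# per-probe occupied volume: sum over atoms (anchor excluded) of the overlap
# between the atom's vdW sphere and the probe sphere
probe_overlap_volume <- function(emb, center, exclude_rows, cfg,
                                 method = c("grid", "mc"), mc_points = 1e6,
                                 seed = NULL) {
  method <- match.arg(method)
  rows <- setdiff(seq_len(nrow(emb$coords)), exclude_rows)
  radii <- cfg$radii[emb$elements[rows]]
  if (anyNA(radii))
    stop("no van-der-Waals radius for element(s): ",
         paste(unique(emb$elements[rows][is.na(radii)]), collapse = ", "))
  pr <- cfg$probe_radius
  if (method == "grid") {
    h <- cfg$grid
    ax <- seq(center[1] - pr, center[1] + pr, by = h)
    ay <- seq(center[2] - pr, center[2] + pr, by = h)
    az <- seq(center[3] - pr, center[3] + pr, by = h)
    pts <- as.matrix(expand.grid(ax, ay, az))
    inside_probe <- rowSums(sweep(pts, 2, center)^2) <= pr^2
    pts <- pts[inside_probe, , drop = FALSE]
    vol_per_pt <- h^3
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    if (!is.null(seed)) set.seed(seed)
    u <- matrix(stats::rnorm(3 * mc_points), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- pr * stats::runif(mc_points)^(1 / 3)
    pts <- sweep(u * r, 2, center, `+`)
    vol_per_pt <- (4 / 3) * pi * pr^3 / mc_points
  }
  total <- 0
  for (k in seq_along(rows)) {
    d2 <- rowSums(sweep(pts, 2, emb$coords[rows[k], ])^2)
    total <- total + sum(d2 <= radii[k]^2) * vol_per_pt
  }
  total
}

#' Steric-bulk descriptor Bk_M
#'
#' Places a probe point 2.0 angstrom from each anchor atom along its vacant
#' coordination vector and sums, over all ligand atoms, the overlap volume
#' between each atom's van-der-Waals sphere and a 3.5 angstrom probe sphere
#' centered at that point; kappa-2 ligands sum both probes.  Volumes are
#' obtained by grid integration at 0.2 angstrom spacing (see [bk_m_config()]).
#'
#' @param ligand an [anchored_ligand()].
#' @param conformer_seed seed of the distance-geometry embedding; one seed,
#'   one conformer.
#' @param cfg probe configuration from [bk_m_config()].
#' @param method "grid" (default) or "mc" (Monte-Carlo rejection sampling,
#'   used as an independent cross-check).
#' @param mc_points number of Monte-Carlo points when `method = "mc"`.
#' @return steric bulk in cubic angstrom.
#' @export
bk_m <- function(ligand, conformer_seed = 1L, cfg = bk_m_config(),
                 method = c("grid", "mc"), mc_points = 1e6) {
  stopifnot(inherits(ligand, "anchored_ligand"))
  method <- match.arg(method)
  emb <- embed_3d(ligand$mol, seed = conformer_seed)
  anchor_rows <- emb$sdf_row[ligand$anchors]
  total <- 0
  for (k in seq_along(anchor_rows)) {
    row <- anchor_rows[k]
    v <- vacant_vector(emb, row)
    center <- emb$coords[row, ] + cfg$offset * v
    total <- total + probe_overlap_volume(
      emb, center, exclude_rows = row, cfg = cfg, method = method,
      mc_points = mc_points, seed = conformer_seed)
  }
  total
}
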