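# Quality metrics for generated ligand sets: the validity -> uniqueness ->
# novelty funnel, pairwise-similarity diversity statistics, distribution
# reports and the drug-like subset.

#' Funnel quality metrics for a generated set
#'
#' Validity is the anchor-pattern check for the declared mode; uniqueness is
#' assessed among the valid strings and novelty among the valid-and-unique,
#' so the funnel counts are non-increasing by construction.  Uniqueness and
#' novelty compare canonical anchored strings, so one skeleton with two
#' different coordination modes counts as two ligands.
#'
#' @param generated character vector of generated anchored-SMILES strings.
#' @param training training records (or character vector of anchored SMILES).
#' @param mode 1 or 2.
#' @return object of class `generation_report`.
#' @export
funnel_metrics <- function(generated, training, mode) {
  if (!length(training)) stop("training set must be non-empty")
  train_smiles <- if (is.character(training)) training
    else vapply(training, `[[`, "", "anchored_smiles")
  train_canon <- unique(vapply(train_smiles, function(s)
    as.character(canonicalize_anchored(s)), ""))

  n <- length(generated)
  valid <- vapply(generated, function(s) check_anchor_validity(s, mode)$valid, TRUE)
  valid_canon <- vapply(generated[valid], function(s)
    as.character(canonicalize_anchored(s)), "")
  uniq <- unique(valid_canon)
  novel <- setdiff(uniq, train_canon)

  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  div <- if (length(novel) >= 2L) diversity(novel) else
    list(avg_tanimoto = NA_real_, intdiv2 = NA_real_)
  sa <- if (length(novel)) vapply(novel, function(s)
    sa_score(decode_anchored(s)$mol), 0) else numeric(0)

  structure(list(
    counts = c(generated = n, valid = sum(valid), unique = length(uniq),
               novel = length(novel)),
    valid_pct = pct(sum(valid), n),
    unique_pct = pct(length(uniq), sum(valid)),
    novel_pct = pct(length(novel), length(uniq)),
    avg_tanimoto = div$avg_tanimoto,
    intdiv2 = div$intdiv2,
    sa_mean = if (length(sa)) mean(sa) else NA_real_,
    sa_above_half_pct = if (length(sa)) 100 * mean(sa > 0.5) else NA_real_
  ), class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat("<generation_report>\n")
  cat(sprintf("  funnel: %d generated -> %d valid -> %d unique -> %d novel\n",
              x$counts["generated"], x$counts["valid"], x$counts["unique"],
              x$counts["novel"]))
  cat(sprintf("  valid %.1f%% | unique %.1f%% | novel %.1f%%\n",
              x$valid_pct, x$unique_pct, x$novel_pct))
  cat(sprintf("  diversity: avg TC %.3f, IntDiv2 %.3f\n",
              x$avg_tanimoto, x$intdiv2))
  cat(sprintf("  SA: mean %.2f, %.1f%% above 0.5\n",
              x$sa_mean, x$sa_above_half_pct))
  invisible(x)
}

#' Diversity statistics of a ligand set
#'
#' `avg_tanimoto` is the mean Tanimoto coefficient over all unordered
#' distinct pairs; `intdiv2` is the p = 2 internal-diversity statistic
#' 1 - sqrt(mean over all ordered pairs, self-pairs included, of TC^2).
#' Fingerprints are computed on the decoded free ligands (placeholders
#' stripped).
#'
#' @param set character vector of anchored-SMILES strings (length >= 2), or
#'   a list of molecules / anchored ligands.
#' @return list(avg_tanimoto, intdiv2).
#' @export
diversity <- function(set) {
  if (length(set) < 2L) stop("diversity needs at least 2 molecules")
  fps <- lapply(set, function(s) {
    if (is.character(s)) s <- decode_anchored(s)$mol
    if (inherits(s, "anchored_ligand")) s <- s$mol
    morgan_fingerprint(s)
  })
  n <- length(fps)
  tc <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tc[i, j] <- tc[j, i] <- tanimoto(fps[[i]], fps[[j]])
  }
  avg <- mean(tc[upper.tri(tc)])
  intdiv2 <- 1 - sqrt(mean(tc^2))
  list(avg_tanimoto = avg, intdiv2 = intdiv2)
}

#' Distribution report over a decoded ligand set
#'
#' Normalized histograms over heteroatom composition, coordination
#' environment patterns, and molecular size (atoms per ligand, hydrogens
#' included).
#'
#' @param set character vector of anchored SMILES or list of anchored ligands.
#' @return list of named numeric vectors, each summing to 1.
#' @export
distribution_report <- function(set) {
  ligs <- lapply(set, function(s)
    if (is.character(s)) decode_anchored(s) else s)
  hetero <- table(unlist(lapply(ligs, function(l) {
    el <- l$mol$atoms$element
    el[!el %in% c("C", "H")]
  })))
  coord <- table(vapply(ligs, coordination_environment, ""))
  sizes <- vapply(ligs, function(l) {
    mol_natoms(l$mol) + sum(vapply(seq_len(mol_natoms(l$mol)),
                                   function(i) mol_hcount(l$mol, i), 0L))
  }, 0L)
  size_hist <- table(sizes)
  norm <- function(tb) {
    v <- as.numeric(tb) / sum(tb)
    stats::setNames(v, names(tb))
  }
  list(heteroatoms = norm(hetero), coordination = norm(coord),
       size = norm(size_hist), mean_size = mean(sizes))
}

#' Drug-like subset of a ligand set
#'
#' Removes every ligand containing an element uncommon in organic molecules;
#' the default exclusion list is B, Si, P, As, Se and I, and can be extended
#' (e.g. with Cl and Br).
#'
#' @param set character vector of anchored SMILES.
#' @param exclude elements whose presence excludes a ligand.
#' @return the retained subset (character vector).
#' @export
drug_like_subset <- function(set, exclude = c("B", "Si", "P", "As", "Se", "I")) {
  keep <- vapply(set, function(s) {
    lig <- tryCatch(decode_anchored(s), error = function(e) NULL)
    if (is.null(lig)) return(FALSE)
    !any(lig$mol$atoms$element %in% exclude)
  }, TRUE)
  set[keep]
}
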