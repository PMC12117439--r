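# Corpus handling: records, training filters, CSV round trips.

#' Build a corpus record from an anchored SMILES string
#'
#' @param smiles anchored-SMILES string.
#' @param id record identifier.
#' @param source one of "training", "generated", "fixture".
#' @return list with fields `id`, `ligand`, `anchored_smiles`, `source`.
#' @export
corpus_record <- function(smiles, id, source = "training") {
  lig <- decode_anchored(smiles)
  list(id = as.character(id), ligand = lig,
       anchored_smiles = as.character(encode_anchored(lig)),
       source = match.arg(source, c("training", "generated", "fixture")))
}

#' Apply the training filters to a corpus
#'
#' Keeps neutral ligands with at least `min_heavy` heavy atoms (placeholders
#' excluded) whose denticity matches `mode`, with kappa-2 anchors bound to
#' two nonadjacent atoms, and drops ligands containing high-valent anionic
#' atoms (e.g. anionic pentavalent phosphorus), a pattern arising from
#' erroneous charge assignment in upstream data.  All rejections are tallied
#' by reason in the returned report.
#'
#' @param records list of corpus records.
#' @param mode 1 or 2.
#' @param min_heavy minimum heavy-atom count (default 4).
#' @return list(records = kept records, report = filter report with
#'   `input_count`, `kept_count` and `rejection_counts`).
#' @export
apply_training_filters <- function(records, mode, min_heavy = 4L) {
  mode <- as.integer(mode)
  reasons <- c(denticity = 0L, size = 0L, adjacency = 0L, charge = 0L,
               high_valent_anion = 0L)
  keep <- logical(length(records))
  for (k in seq_along(records)) {
    lig <- records[[k]]$ligand
    if (lig$denticity != mode) { reasons["denticity"] <- reasons["denticity"] + 1L; next }
    if (mol_formal_charge(lig$mol) != 0L) { reasons["charge"] <- reasons["charge"] + 1L; next }
    if (length(mol_heavy_atoms(lig$mol)) < min_heavy) { reasons["size"] <- reasons["size"] + 1L; next }
    if (lig$denticity == 2L &&
        (isTRUE(lig$haptic) ||
         mol_distance(lig$mol, lig$anchors[1], lig$anchors[2]) == 1L)) {
      reasons["adjacency"] <- reasons["adjacency"] + 1L; next
    }
    if (has_high_valent_anion(lig$mol)) {
      reasons["high_valent_anion"] <- reasons["high_valent_anion"] + 1L; next
    }
    keep[k] <- TRUE
  }
  report <- list(input_count = length(records), kept_count = sum(keep),
                 rejection_counts = reasons)
  stopifnot(report$kept_count + sum(reasons) == report$input_count)
  list(records = records[keep], report = report)
}

# an atom with negative formal charge whose explicit valence exceeds its
# element's lowest standard valence (e.g. anionic pentavalent P)
has_high_valent_anion <- function(mol) {
  for (i in seq_len(mol_natoms(mol))) {
    if (mol$atoms$charge[i] >= 0L) next
    el <- mol$atoms$element[i]
    base <- STD_VALENCE[[el]]
    if (is.null(base)) next
    used <- mol_bond_valence(mol, i) + mol_hcount(mol, i)
    if (used > min(base)) return(TRUE)
  }
  FALSE
}

#' Write a corpus to CSV
#'
#' Columns: id, smiles (anchored), anchor_indices / bond_orders
#' (semicolon-separated, in the free ligand's atom order), denticity, source.
#'
#' @param records list of corpus records.
#' @param path output file.
#' @export
write_corpus <- function(records, path) {
  df <- data.frame(
    id = vapply(records, `[[`, "", "id"),
    smiles = vapply(records, `[[`, "", "anchored_smiles"),
    anchor_indices = vapply(records, function(r)
      paste(r$ligand$anchors, collapse = ";"), ""),
    bond_orders = vapply(records, function(r)
      paste(r$ligand$bond_orders, collapse = ";"), ""),
    denticity = vapply(records, function(r) r$ligand$denticity, 0L),
    source = vapply(records, `[[`, "", "source"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a corpus from CSV
#'
#' Tolerates `#` comment lines.  Records that fail to parse are skipped and
#' reported; well-formed records are unaffected.  Alternate column spellings
#' can be mapped with `col_map` (names = canonical, values = file columns),
#' which is how tmQMg-L-style exports are ingested.
#'
#' @param path CSV file.
#' @param col_map optional named character vector remapping column names.
#' @return list(records, errors) where errors is a data.frame of line/message.
#' @export
read_corpus <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(df))
        names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  if (!all(c("id", "smiles") %in% names(df)))
    stop("corpus file must have at least 'id' and 'smiles' columns")
  if (is.null(df$source)) df$source <- "training"
  records <- list()
  errors <- data.frame(line = integer(), message = character())
  for (k in seq_len(nrow(df))) {
    rec <- tryCatch(corpus_record(df$smiles[k], df$id[k], df$source[k]),
                    error = function(e)
                      structure(conditionMessage(e), class = "corpus_error"))
    if (inherits(rec, "corpus_error")) {
      errors <- rbind(errors, data.frame(line = k + 1L,
                                         message = as.character(rec)))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  list(records = records, errors = errors)
}
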