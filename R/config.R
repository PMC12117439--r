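# Run configuration and the global seed tree.

RUN_CONFIG_KEYS <- c("mode", "seed", "log_level", "paths", "model",
                     "descriptors", "campaign")

#' Build or read a run configuration
#'
#' A flat, fully serializable configuration: generation mode, global seed,
#' log level, paths, model hyperparameters ([jtvae_config()] fields),
#' descriptor settings and campaign spec.  Unknown keys are rejected.
#' Every stochastic stage derives its own seed from the global seed via
#' [stage_seed()], so stages are independently reproducible.
#'
#' @param path optional YAML-style key-value file (parsed with a minimal
#'   `key: value` reader; nested keys as `section.key: value`).
#' @param ... overrides.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(mode = 1L, seed = 1L, log_level = "info", paths = list(),
              model = jtvae_config(), descriptors = list(bk_grid = 0.35),
              campaign = list(regions = "C", directions = paste0("D", 1:8),
                              k = 5L, tc_threshold = 0.2))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    for (ln in readLines(path)) {
      ln <- sub("#.*$", "", ln)
      if (!nzchar(trimws(ln))) next
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(kv) < 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      val <- utils::type.convert(val, as.is = TRUE)
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (!parts[1] %in% RUN_CONFIG_KEYS)
        stop("unknown config key: ", key)
      if (length(parts) == 1L) cfg[[parts[1]]] <- val
      else cfg[[parts[1]]][[parts[2]]] <- val
    }
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% RUN_CONFIG_KEYS) stop("unknown config key: ", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Derive a stage seed from the global seed
#'
#' Deterministic expansion of one global seed into independent per-stage
#' seeds (kept below 2^31).
#'
#' @param seed global integer seed.
#' @param stage stage name, e.g. "fixtures", "train", "sample".
#' @export
stage_seed <- function(seed, stage) {
  (str_hash(paste0(stage, "/", seed)) %% 2147483629L) + 1L
}
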