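#' Write a session bundle to a directory
#'
#' Lays a session out as plain-text files: `counts.tsv` (dense integer
#' matrix, one row per channel in `array_map` order, tab-separated, no
#' header), `trials.csv`, `kinematics.csv` (when present), `array_map.csv`
#' and `meta.json` (bin rate, seed, task, generator-config echo). Times are
#' seconds from session start; bins are half-open `[k/50, (k+1)/50)`.
#'
#' @param session An `ibci_session`.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(session$counts, file.path(dir, "counts.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  if (!is.null(session$kinematics))
    utils::write.csv(session$kinematics, file.path(dir, "kinematics.csv"),
                     row.names = FALSE)
  utils::write.csv(session$array_map, file.path(dir, "array_map.csv"),
                   row.names = FALSE)
  meta <- list(bin_rate = session$bin_rate, seed = session$seed,
               task = session$task,
               config = unclass(session$config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Inverse of [write_session_bundle()]. Ground-truth matrices are never
#' written, so the round trip preserves everything except `$truth`.
#'
#' @param dir Bundle directory.
#' @return An `ibci_session`.
#' @export
read_session_bundle <- function(dir) {
  counts <- as.matrix(utils::read.table(file.path(dir, "counts.tsv"),
                                        sep = "\t", header = FALSE))
  dimnames(counts) <- NULL
  storage.mode(counts) <- "integer"
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- meta$config
  if (!is.null(cfg$phase_durations_s))
    cfg$phase_durations_s <- unlist(cfg$phase_durations_s)
  cfg <- structure(cfg, class = "generator_config")
  kin_path <- file.path(dir, "kinematics.csv")
  kin <- if (file.exists(kin_path)) utils::read.csv(kin_path) else NULL
  structure(list(counts = counts,
                 bin_rate = meta$bin_rate,
                 trials = utils::read.csv(file.path(dir, "trials.csv")),
                 kinematics = kin,
                 array_map = utils::read.csv(file.path(dir, "array_map.csv")),
                 seed = as.integer(meta$seed),
                 task = meta$task,
                 config = cfg,
                 truth = NULL),
            class = "ibci_session")
}
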