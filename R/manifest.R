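#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-identically with the
#' same code version: the configuration file's MD5 hash, the seed(s), the
#' horizon in use, capping-event count, package version, timestamp and
#' the invoked command with its flags. Written as JSON alongside a run's
#' outputs (the bundled command-line script writes one per invocation).
#'
#' @param path Output JSON path.
#' @param config_path Path of the configuration the run used (hashed).
#' @param seed Seed(s) used, or `NULL`.
#' @param command Name of the stage or subcommand.
#' @param flags Named list of flag values.
#' @param horizon_cycles Horizon used.
#' @param capped_rows Number of capped transition rows observed.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config_path = NULL, seed = NULL,
                           command = "run", flags = list(),
                           horizon_cycles = NULL, capped_rows = 0L) {
  manifest <- list(
    command = command,
    flags = flags,
    config_md5 = if (!is.null(config_path) && file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    },
    seed = seed,
    horizon_cycles = horizon_cycles,
    capped_rows = capped_rows,
    package_version = as.character(utils::packageVersion("pahcea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
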