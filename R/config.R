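#' Read a simulation configuration file
#'
#' YAML configuration with the same nesting as [network_params()] plus
#' optional `hebb`, `protocol` and `seed` blocks; every default is
#' overridable. Unknown top-level keys raise an error so that typos do not
#' silently fall back to defaults.
#'
#' @param path YAML file.
#' @return list with `params` (a `pps_params`), `hebb` (a `hebb_params` or
#'   NULL), `protocol` (argument list for [training_protocol()] or NULL)
#'   and `seed` (integer or NULL).
#' @export
read_pps_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("tactile", "auditory", "ms", "synapses", "hand", "stimulus",
             "noise", "integration", "hebb", "protocol", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("configuration error: unknown config keys: ",
         paste(bad, collapse = ", "))
  net_keys <- intersect(names(cfg),
                        c("tactile", "auditory", "ms", "synapses", "hand",
                          "stimulus", "noise", "integration"))
  params <- do.call(network_params, cfg[net_keys])
  hebb <- if (!is.null(cfg$hebb)) do.call(hebb_params, cfg$hebb) else NULL
  list(params = params, hebb = hebb, protocol = cfg$protocol,
       seed = cfg$seed)
}

#' Write a run manifest next to simulation outputs
#'
#' Records the effective parameters, the seed, the package version and a
#' short hash of the parameter set, so a run can be reproduced from its
#' output directory alone.
#'
#' @param dir output directory (created if needed).
#' @param params a `pps_params`.
#' @param seed integer seed used for the run (or NULL).
#' @param extra optional named list merged into the manifest.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, params, seed = NULL, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pstr <- paste(utils::capture.output(utils::str(unclass(params))),
                collapse = "\n")
  manifest <- c(list(
    package = "ppsnet",
    version = as.character(utils::packageVersion("ppsnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params_hash = sprintf("%08x", sum(utf8ToInt(pstr) *
                                        seq_along(utf8ToInt(pstr))) %%
                            .Machine$integer.max),
    params = unclass(params)), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a summary table as tab-separated text
#'
#' @param x data.frame.
#' @param path output file; existing files are not overwritten unless
#'   `overwrite = TRUE`.
#' @param overwrite replace an existing file.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing output: ", path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
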