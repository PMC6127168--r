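#' Write a simulation trace as CSV
#'
#' @param sim An `mn_sim` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  stopifnot(inherits(sim, "mn_sim"))
  df <- data.frame(time = sim$time, U_MN = sim$U)
  for (g in c("m", "h", "n"))
    if (!is.null(sim[[g]])) df[[g]] <- sim[[g]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run metadata as JSON
#'
#' Serialises every parameter of a simulation (membrane constants, synapse
#' conductances, volley and visual specification, configuration, package
#' version) so a run can be reproduced exactly.
#'
#' @param sim An `mn_sim` object.
#' @param path Output file; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_run_meta <- function(sim, path = NULL) {
  stopifnot(inherits(sim, "mn_sim"))
  meta <- list(
    package = "mnb1sim",
    version = as.character(utils::packageVersion("mnb1sim")),
    neuron = unclass(sim$neuron),
    synapse = unclass(sim$synapse),
    volley = if (!is.null(sim$volley)) unclass(sim$volley),
    visual = if (!is.null(sim$visual)) unclass(sim$visual),
    waveform = unclass(sim$waveform),
    config = unclass(sim$config),
    rest = sim$rest)
  js <- jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Export per-cycle sensilla spike times as CSV
#'
#' @param spec A [volley_spec()].
#' @param n_cycles Number of stroke cycles to export.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_volley_csv <- function(spec, n_cycles, path) {
  rows <- lapply(seq_len(n_cycles) - 1, function(cy) {
    d <- volley_times(spec, cy)
    cbind(cycle = cy, d)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("cycle", "nerve", "sensillum_id", "time_ms")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a model configuration from YAML
#'
#' Reads a YAML file with optional top-level sections `neuron`, `synapse`,
#' `volley`, `visual`, `waveform` and `config`, each holding the fields of
#' the corresponding constructor, and returns the constructed objects
#' (missing sections give the package defaults; an absent `volley` or
#' `visual` section gives `NULL`).
#'
#' @param path YAML file.
#' @return List with elements `neuron`, `synapse`, `volley`, `visual`,
#'   `waveform`, `config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  build <- function(fn, args) do.call(fn, as.list(args %||% list()))
  `%||%` <- function(a, b) if (is.null(a)) b else a
  list(neuron = build(neuron_params, y$neuron),
       synapse = build(synapse_params, y$synapse),
       volley = if (!is.null(y$volley)) build(volley_spec, y$volley),
       visual = if (!is.null(y$visual)) build(visual_signal, y$visual),
       waveform = build(waveform_template, y$waveform),
       config = build(sim_config, y$config))
}
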