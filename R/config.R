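#' Read a pairing configuration from YAML
#'
#' Recognized keys: `window`, `filters_enabled`, `cross_section_windows`;
#' missing keys fall back to the [pairing_config()] defaults.
#'
#' @param path YAML file path.
#' @return A [pairing_config()].
#' @export
pairing_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  d <- pairing_config()
  pairing_config(
    window = y$window %||% d$window,
    filters_enabled = unlist(y$filters_enabled) %||% d$filters_enabled,
    cross_section_windows = y$cross_section_windows %||% d$cross_section_windows)
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()]; `n_notes` is required,
#' everything else falls back to the defaults.
#'
#' @param path YAML file path.
#' @param n_notes,seed Overrides taking precedence over the file.
#' @return An [sim_config()].
#' @export
sim_config_from_yaml <- function(path, n_notes = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(sim_config)))]
  if (!is.null(n_notes)) args$n_notes <- n_notes
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, args)
}
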