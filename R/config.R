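#' Load a configuration file
#'
#' Reads a YAML (or JSON) override file, merges it over the packaged
#' defaults (population presets, projection attributes, kinetics,
#' simulation and analysis settings), validates the result and returns an
#' [lgn_config()].  Projection overrides are matched on their `(pre, post)`
#' pathway.  A top-level `variant: in_suppressed` key applies
#' [apply_in_suppression()] after merging.  An empty file yields the exact
#' defaults.
#'
#' @param path file path, or `NULL` for pure defaults.
#' @param quiet suppress the resolved-configuration log line.
#' @return An [lgn_config()].
#' @examples
#' cfg <- load_config(NULL)
#' cfg$variant
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  overrides <- NULL
  variant <- "base"
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_config: no such file: ", path)
    overrides <- if (grepl("\\.json$", path))
      jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path)
    if (is.null(overrides)) overrides <- list()
    if (!is.null(overrides$variant)) {
      variant <- match.arg(overrides$variant, c("base", "in_suppressed"))
      overrides$variant <- NULL
    }
  }
  cfg <- lgn_config(variant = variant,
                    overrides = if (length(overrides)) overrides)
  if (!quiet)
    message(sprintf("configuration resolved: variant=%s, %d+%d+%d neurons, %d pathways",
                    cfg$variant, cfg$populations$TCR$size,
                    cfg$populations$IN$size, cfg$populations$TRN$size,
                    nrow(cfg$projections)))
  cfg
}

#' Write a configuration snapshot
#'
#' Serializes the resolved configuration (populations, projections,
#' kinetics, variant, simulation and analysis settings) as YAML so a run
#' can be reproduced from its artifacts.
#'
#' @param cfg an [lgn_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "lgn_config"))
  proj <- lapply(seq_len(nrow(cfg$projections)), function(i)
    as.list(cfg$projections[i, ]))
  yaml::write_yaml(list(
    variant = cfg$variant,
    kinetics = list(tau_e = cfg$kinetics$tau_e, tau_i = cfg$kinetics$tau_i),
    populations = cfg$populations,
    projections = proj,
    simulation = cfg$simulation,
    analysis = cfg$analysis,
    dvs = cfg$dvs), path)
  invisible(path)
}
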