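# Run configuration files.
#
# Configs are nested lists. YAML is used when the yaml package is
# available; JSON (jsonlite) always works, so offline installations fall
# back to it transparently.

#' Read a run configuration (YAML or JSON)
#'
#' Recognised keys (all optional, dotted here for readability):
#' `rscconv.enabled`, `rscconv.gate_calibration`, `neck.type`
#' (`"ascff"` or `"channel_mapper"`), `neck.out_channels`,
#' `neck.attention.reduction`, `neck.attention.spatial_kernel`,
#' `detector.*` (any [detector_config()] argument), `pretrained.enabled`.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is not installed; use a JSON config instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' Turn a configuration list into a detector configuration
#'
#' @param conf List from [read_config()] (may be empty).
#' @param ... Overrides passed straight to [detector_config()].
#' @return A [detector_config()].
#' @export
config_to_detector <- function(conf = list(), ...) {
  args <- list(...)
  pick <- function(name, default) {
    v <- conf
    for (part in strsplit(name, ".", fixed = TRUE)[[1]]) {
      if (is.null(v)) break
      v <- v[[part]]
    }
    if (is.null(v)) default else v
  }
  base <- list(
    use_rscconv = isTRUE(pick("rscconv.enabled", FALSE)),
    gate_calibration = isTRUE(pick("rscconv.gate_calibration", FALSE)),
    use_ascff = identical(pick("neck.type", "channel_mapper"), "ascff"),
    neck_channels = pick("neck.out_channels", 16L),
    reduction = pick("neck.attention.reduction", 16L),
    spatial_kernel = pick("neck.attention.spatial_kernel", 7L),
    use_pretrained = isTRUE(pick("pretrained.enabled", FALSE)))
  det <- conf$detector
  if (is.list(det)) base[names(det)] <- det
  base[names(args)] <- args
  do.call(detector_config, base)
}
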