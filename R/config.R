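#' Pipeline configuration
#'
#' A single YAML-backed configuration object carries every tunable default
#' of the pipeline: tile side, plant scale range, CIELAB8 color targets,
#' chroma threshold, translator choice, placement options, split
#' proportions, and the master seed. Loading validates each field against
#' the owning module's invariants and names the offending field on
#' failure.
#'
#' @param path YAML file path, or `NULL` for the package defaults
#' @return list of class `pipeline_config`
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @export
default_config <- function() {
  list(
    tile_side = 256L,
    scale_min = 0.50,
    scale_max = 0.85,
    color_targets = c(170, 100, 160),
    color_correct = TRUE,
    chroma_threshold = 30,
    min_component_area = 0L,
    translator = list(name = "identity"),
    placement = "random",
    rows = 2L,
    jitter = 0L,
    n_plants = 4L,
    single_class = TRUE,
    split = c(0.8, 0.1, 0.1),
    seed = 0L
  )
}

validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid config field '", field, "': ", why, call. = FALSE)
  }
  if (!is.numeric(cfg$tile_side) || cfg$tile_side < 16) {
    fail("tile_side", "must be a number >= 16")
  }
  ok <- tryCatch(scale_range(cfg$scale_min, cfg$scale_max),
                 error = function(e) NULL)
  if (is.null(ok)) fail("scale_min/scale_max", "need 0 < min <= max <= 1")
  if (length(cfg$color_targets) != 3L || any(cfg$color_targets < 0) ||
      any(cfg$color_targets > 255)) {
    fail("color_targets", "must be 3 values in [0, 255]")
  }
  if (!is.numeric(cfg$chroma_threshold) || length(cfg$chroma_threshold) != 1L) {
    fail("chroma_threshold", "must be a single number")
  }
  if (cfg$min_component_area < 0) fail("min_component_area", "must be >= 0")
  if (!cfg$placement %in% c("random", "rows")) {
    fail("placement", "must be 'random' or 'rows'")
  }
  if (cfg$rows < 1) fail("rows", "must be >= 1")
  if (cfg$jitter < 0) fail("jitter", "must be >= 0")
  if (cfg$n_plants < 1) fail("n_plants", "must be >= 1")
  sp <- tryCatch(split_spec(cfg$split[1], cfg$split[2], cfg$split[3]),
                 error = function(e) NULL)
  if (is.null(sp)) fail("split", "must be 3 positive fractions summing to 1")
  if (is.null(cfg$translator$name)) fail("translator", "must name a translator")
  structure(cfg, class = "pipeline_config")
}

#' Instantiate the translator named in a config
#'
#' Registry of built-in translators: `identity`, `stats_transfer` (options
#' `reference_means`, `strength`) and `external` (option `command`, a
#' template with `{input}`/`{output}` placeholders).
#'
#' @param cfg a `pipeline_config`
#' @return a [translator()]
#' @export
config_translator <- function(cfg) {
  tcfg <- cfg$translator
  switch(tcfg$name,
    identity = identity_translator(),
    stats_transfer = stats_transfer_translator(
      reference_means = if (is.null(tcfg$reference_means))
        c(150, 110, 150) else unlist(tcfg$reference_means),
      strength = if (is.null(tcfg$strength)) 0.5 else tcfg$strength),
    external = {
      if (is.null(tcfg$command)) {
        stop("external translator needs a 'command' option", call. = FALSE)
      }
      external_translator_adapter(tcfg$command)
    },
    stop("unknown translator '", tcfg$name, "'", call. = FALSE)
  )
}
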