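#' Pipeline configuration
#'
#' Nested list of every tunable in the pipeline, with defaults matching the
#' acquisition and analysis settings used throughout: 504 x 504 px FOVs at
#' 92.45 nm/px, 120 nm matching radius, 80/20 stratified split, 10 CV folds,
#' tuning budget 10, 100 scrambling repeats. The config round-trips through
#' YAML losslessly.
#'
#' @param ... Named overrides replacing defaults at the top level (nested
#'   lists are merged).
#' @return A list of class `nb_config`.
#' @export
nb_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out = "nb_out",
    scheme = list(n_levels = 3L),
    het = list(radius_mean = 50, radius_cv = 0.1, encapsulation_sd = 0.25),
    optical = list(gain = 600, background_rate = 5, read_noise_sd = 2,
                   offset = 100, Q = 50, numerical_aperture = 1.4),
    image = list(dim = 504L, pixel_size_nm = 92.45, fovs = 4L,
                 min_sep_nm = 1000),
    simulate = list(particles_per_class = 100L, mode = "features",
                    noise = TRUE, classes = NULL, detect_k = 5),
    detect = list(sigma_px = 1.1, threshold_k = 5, min_sep_px = 3),
    match = list(radius_nm = 120),
    reader = list(test_fraction = 0.2, folds = 10L, budget = 10L,
                  roster = NULL, family = NULL),
    scramble = list(repeats = 100L),
    curve = list(sizes = c(50L, 100L, 200L)),
    mix = list(classes = NULL, n_per_class = 50L),
    pca = list(components = 3L, scale = FALSE)
  )
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- c("nb_config", "list")
  cfg
}

#' Read / write a pipeline config as YAML
#' @param path YAML file path.
#' @return `read_config`: an `nb_config` (file values merged over
#'   defaults); `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  cfg <- merge_config(nb_config(), vals)
  class(cfg) <- c("nb_config", "list")
  cfg
}

# recursive merge that, unlike modifyList, keeps explicit nulls as NULL
# values (null in the file means "unset / use the default semantics")
merge_config <- function(base, vals) {
  for (k in names(vals)) {
    v <- vals[[k]]
    if (is.list(v) && is.list(base[[k]]) && !is.null(names(v))) {
      base[[k]] <- merge_config(base[[k]], v)
    } else {
      base[k] <- list(v)
    }
  }
  base
}

#' @rdname read_config
#' @param config An `nb_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Apply flat dotted overrides to a config
#'
#' @param config An `nb_config`.
#' @param overrides Character vector of `section.key=value` strings; values
#'   are parsed as YAML scalars (so `true`, `3`, `0.05` get native types).
#' @return The updated config.
#' @export
apply_overrides <- function(config, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("bad override '%s' (expected key=value)", ov))
    path <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    value <- yaml::yaml.load(kv[2])
    node <- config
    # validate the key path exists
    for (i in seq_along(path)) {
      if (i < length(path)) {
        if (!is.list(node) || is.null(node[[path[i]]])) {
          stop(sprintf("unknown config key '%s'", kv[1]))
        }
        node <- node[[path[i]]]
      }
    }
    config[[path]] <- value
  }
  config
}

# build domain objects from a config
config_model <- function(cfg) {
  optical_model(gain = cfg$optical$gain,
                background_rate = cfg$optical$background_rate,
                read_noise_sd = cfg$optical$read_noise_sd,
                offset = cfg$optical$offset,
                Q = rep(cfg$optical$Q, 3L),
                numerical_aperture = cfg$optical$numerical_aperture)
}

config_het <- function(cfg) {
  het_params(cfg$het$radius_mean, cfg$het$radius_cv, cfg$het$encapsulation_sd)
}

config_codes <- function(cfg) {
  codes <- enumerate_barcodes(cfg$scheme$n_levels)
  if (!is.null(cfg$simulate$classes)) {
    codes <- codes[codes$id %in% cfg$simulate$classes, , drop = FALSE]
  }
  codes
}
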