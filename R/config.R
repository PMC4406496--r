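#' Default pipeline configuration
#'
#' All tunables of the pipeline in one nested list, mirroring the YAML
#' layout accepted by [read_config()]:
#'
#' ```yaml
#' preprocessing:
#'   fir_order: 50
#'   asef_k: 5
#'   jump_factor: 10
#'   segmentation: {pre_start: 90, pre_end: 30, min_len: 50,
#'                  dce_prop_max: 0.1, dce_remi_max: 0.1}
#' amif:
#'   n_bins: 32
#'   q_set: [0.1, 0.2, 0.5, 2, 3, 5, 10, 30, 50, 100]
#' evaluation:
#'   corr_threshold: 0.7
#'   n_iter: 1000
#'   min_sen: 60
#'   min_spe: 60
#'   max_size: 4
#' synthetic:
#'   n_per_class: 100
#'   effect_size: 1
#'   artifact_rate: 2
#'   mains_amp: 1
#' ```
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    preprocessing = list(
      fir_order = 50L, asef_k = 5, jump_factor = 10,
      segmentation = list(pre_start = 90, pre_end = 30, min_len = 50,
                          dce_prop_max = 0.1, dce_remi_max = 0.1)),
    amif = list(n_bins = 32L, q_set = default_q_set()),
    evaluation = list(corr_threshold = 0.7, n_iter = 1000L,
                      min_sen = 60, min_spe = 60, max_size = 4L),
    synthetic = list(n_per_class = 100L, effect_size = 1,
                     artifact_rate = 0.5, mains_amp = 1))
}

#' Read a YAML configuration file
#'
#' Values present in the file override the defaults; everything else
#' keeps its default.  Unknown keys are kept verbatim (forward
#' compatibility).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  .merge_lists(cfg, user)
}

.merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Segmentation config from a configuration list
#' @param cfg A configuration list from [read_config()].
#' @return A [segmentation_config()].
#' @export
config_segmentation <- function(cfg = default_config()) {
  s <- cfg$preprocessing$segmentation
  segmentation_config(s$pre_start, s$pre_end, s$min_len,
                      s$dce_prop_max, s$dce_remi_max)
}
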