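# Configuration files, signal CSV/JSON readers and writers.

.config_keys <- c("model", "sequence", "output", "seed", "verbosity")
.model_keys_common <- c("type", "preset", "t1a", "t1b", "t2a", "t2b",
                        "t2b_us", "ka", "f", "delta_b", "m0", "lineshape",
                        "g0", "t1", "t2")
.sequence_keys <- c("type", "tr", "alpha_deg", "phi0_deg", "n_pulses",
                    "n_echoes", "esp", "b1_scale", "b1_ut", "flip_max_deg",
                    "variant", "n_slices", "refocus_deg", "slice_offset_hz",
                    "energy_preset")

#' Load and validate a run configuration
#'
#' Reads a flat YAML configuration with top-level blocks `model` and
#' `sequence` (plus optional `output`, `seed`, `verbosity`). Unknown keys at
#' any level are rejected with a field-level message. Angles are given in
#' degrees in configuration files and converted to radians internally.
#'
#' @param path YAML file path.
#' @return object of class `run_config` (a validated named list).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), .config_keys)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$model)) {
    bad <- setdiff(names(cfg$model), .model_keys_common)
    if (length(bad)) stop("unknown model key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$sequence)) {
    bad <- setdiff(names(cfg$sequence), .sequence_keys)
    if (length(bad)) stop("unknown sequence key(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a run configuration
#'
#' @param cfg a `run_config` or plain list (validated before writing).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build a tissue model from a configuration block
#'
#' @param cfg a `run_config` or its `model` block.
#' @return an `epgx_model`.
#' @export
config_to_model <- function(cfg) {
  m <- if (!is.null(cfg$model)) cfg$model else cfg
  if (!is.null(m$preset)) return(tissue_preset(m$preset))
  type <- m$type
  if (is.null(type)) stop("model block needs 'type' or 'preset'")
  get_or <- function(key, default) if (is.null(m[[key]])) default else m[[key]]
  switch(type,
    bm = epgx_bm_model(m$t1a, m$t1b, m$t2a, m$t2b, m$ka, m$f,
                       delta_b = get_or("delta_b", 0), m0 = get_or("m0", 1)),
    mt = epgx_mt_model(m$t1a, m$t1b, m$t2a, m$t2b_us, m$ka, m$f,
                       lineshape = get_or("lineshape", "super_lorentzian"),
                       g0 = m$g0, m0 = get_or("m0", 1)),
    single = single_pool_model(m$t1, m$t2, m0 = get_or("m0", 1)),
    stop("unknown model type: ", type))
}

#' Build a pulse train from a configuration block
#'
#' @param cfg a `run_config` or its `sequence` block.
#' @return a [pulse_train()] (for `type: spgr`, `bssfp`, `mrf`) or the
#'   sequence block itself for engines with their own entry points
#'   (`cpmg`, `multislice`).
#' @export
config_to_train <- function(cfg) {
  s <- if (!is.null(cfg$sequence)) cfg$sequence else cfg
  if (is.null(s$type)) stop("sequence block needs 'type'")
  d2r <- pi / 180
  get_or <- function(key, default) if (is.null(s[[key]])) default else s[[key]]
  switch(s$type,
    spgr = spgr_sequence(tr = get_or("tr", 5),
                         alpha = get_or("alpha_deg", 10) * d2r,
                         phi0 = get_or("phi0_deg", 117) * d2r,
                         n_pulses = s$n_pulses,
                         b1_ut = get_or("b1_ut", 13.5)),
    bssfp = bssfp_sequence(tr = get_or("tr", 5),
                           alpha = get_or("alpha_deg", 10) * d2r,
                           n_pulses = s$n_pulses,
                           b1_ut = get_or("b1_ut", 13.5)),
    mrf = mrf_train(n_pulses = get_or("n_pulses", 256),
                    tr = get_or("tr", 12),
                    flip_max = get_or("flip_max_deg", 50) * d2r,
                    phi0 = get_or("phi0_deg", 150) * d2r,
                    variant = get_or("variant", "spgr")),
    cpmg = s,
    multislice = s,
    stop("unknown sequence type: ", s$type))
}

#' Write a signal series to CSV with a JSON metadata sidecar
#'
#' The CSV holds columns `time_ms, re, im, mag`; `<path>.json` records the
#' package version, mode and train summary.
#'
#' @param series an `epgx_signal`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(series, path) {
  stopifnot(inherits(series, "epgx_signal"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  meta <- list(
    package = "epgx",
    version = as.character(utils::packageVersion("epgx")),
    mode = series$mode,
    n_pulses = length(series$signal),
    tr_ms = series$train$tr,
    dephasing_cycles = series$train$dephasing_cycles)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a signal series written by [write_signal()]
#'
#' @param path CSV path.
#' @return list with `times`, complex `signal`, and `meta` (if the sidecar
#'   exists).
#' @export
read_signal <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  list(times = df$time_ms,
       signal = complex(real = df$re, imaginary = df$im),
       meta = if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL)
}
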