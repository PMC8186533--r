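#' Latent subject parameters and group-effect presets
#'
#' The simulator describes each subject by six latent motor parameters:
#' \describe{
#'   \item{base_speed}{typical drag speed, screen units/s.}
#'   \item{speed_cv}{within-bout multiplicative speed variability
#'     (coefficient of variation, dimensionless).}
#'   \item{heading_noise_sd}{per-step direction jitter, radians.}
#'   \item{goal_gain}{attraction toward the goal in \[0, 1\]; 1 means every
#'     step heads straight at the goal (straightness 1).}
#'   \item{fragmentation_rate}{expected finger lifts per drag; lifts split a
#'     drag into several short finite trajectories.}
#'   \item{accel_burst_sd}{SD of additive acceleration bursts,
#'     screen units/s^2.}
#' }
#'
#' A group-effect configuration gives, per group, a mean and SD for each
#' latent parameter. Two named presets ship with the package:
#' \code{"default"} plants the contrast directions seen in autistic dragging
#' (less straight, more direction change, shorter and more fragmented bouts,
#' faster but more variable speed); \code{"null"} gives both groups identical
#' distributions, for chance-level calibration.
#'
#' @param preset `"default"` or `"null"`.
#' @return a `group_effect_config`: a list with elements `ASD` and `TD`, each
#'   holding numeric vectors `mean` and `sd` over the six latent parameters.
#' @export
group_effect_preset <- function(preset = c("default", "null")) {
  preset <- match.arg(preset)
  td <- list(
    mean = c(base_speed = 500, speed_cv = 0.25, heading_noise_sd = 0.25,
             goal_gain = 0.85, fragmentation_rate = 0.6, accel_burst_sd = 300),
    sd = c(base_speed = 80, speed_cv = 0.05, heading_noise_sd = 0.05,
           goal_gain = 0.05, fragmentation_rate = 0.2, accel_burst_sd = 80)
  )
  asd <- list(
    mean = c(base_speed = 650, speed_cv = 0.50, heading_noise_sd = 0.55,
             goal_gain = 0.55, fragmentation_rate = 2.5, accel_burst_sd = 900),
    sd = c(base_speed = 100, speed_cv = 0.10, heading_noise_sd = 0.10,
           goal_gain = 0.08, fragmentation_rate = 0.6, accel_burst_sd = 200)
  )
  cfg <- switch(preset,
    default = list(ASD = asd, TD = td),
    null = list(ASD = td, TD = td)
  )
  structure(cfg, preset = preset, class = "group_effect_config")
}

latent_param_names <- function() {
  c("base_speed", "speed_cv", "heading_noise_sd", "goal_gain",
    "fragmentation_rate", "accel_burst_sd")
}

# Hard validity ranges used to truncate sampled profiles.
latent_param_ranges <- function() {
  list(
    base_speed = c(1, Inf), speed_cv = c(0, Inf), heading_noise_sd = c(0, Inf),
    goal_gain = c(0, 1), fragmentation_rate = c(0, Inf), accel_burst_sd = c(0, Inf)
  )
}

validate_effect_config <- function(effect_config) {
  pars <- latent_param_names()
  for (g in c("ASD", "TD")) {
    grp <- effect_config[[g]]
    if (is.null(grp) || !all(pars %in% names(grp$mean)) || !all(pars %in% names(grp$sd))) {
      tk_stop("touchkin_config_error",
              "group-effect config is incomplete for group '%s'", g)
    }
    if (any(grp$sd[pars] < 0)) {
      tk_stop("touchkin_config_error", "negative SD in group-effect config ('%s')", g)
    }
  }
  invisible(effect_config)
}

resolve_effect_config <- function(effect) {
  if (inherits(effect, "group_effect_config")) return(validate_effect_config(effect))
  if (is.character(effect) && length(effect) == 1) {
    if (!effect %in% c("default", "null")) {
      tk_stop("touchkin_config_error", "unknown effect preset '%s'", effect)
    }
    return(group_effect_preset(effect))
  }
  if (is.list(effect)) return(validate_effect_config(structure(effect, class = "group_effect_config")))
  tk_stop("touchkin_config_error", "cannot interpret effect config of class '%s'",
          paste(class(effect), collapse = "/"))
}

#' Read and write flat key-value configuration files
#'
#' The on-disk configuration dialect is one `key: value` pair per line
#' (YAML-like but strictly flat). Blank lines and lines starting with `#` are
#' ignored. Values are parsed as numbers when possible, otherwise kept as
#' strings. Writing then reading a config round-trips losslessly.
#'
#' @param path file path.
#' @return `read_config()`: a named list. `write_config()`: `path`, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) tk_stop("touchkin_io_error", "config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) tk_stop("touchkin_config_error", "malformed config line: '%s'", ln)
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar values.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  fmt <- vapply(config, function(v) {
    if (is.numeric(v)) format(v, digits = 17, scientific = FALSE) else as.character(v)
  }, character(1))
  writeLines(paste0(names(config), ": ", fmt), path)
  invisible(path)
}
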