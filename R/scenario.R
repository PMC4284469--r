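## Plate scenario configurations (YAML dialect).

scenario_defaults <- list(
  template = "custom",
  agar = 1.5,                 # % w/v
  plate_radius_um = 5000,
  kappa = 0.002,              # rad/um, counterclockwise
  width_um = 5,
  seg_um = 2,
  dt_s = 5,
  duration_s = 7200,
  doubling_time_s = 21600,    # 6 h: accelerated desk-scale growth
  encounters = TRUE,
  seed = 1L
)

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("glidekin_config_error", "error",
                                     "condition")))
}

## Fill defaults and validate a scenario list; errors name the offending
## key and its allowed range.
validate_scenario <- function(sc) {
  if (!is.list(sc)) config_error("scenario config must be a key-value list")
  for (k in names(scenario_defaults))
    if (is.null(sc[[k]])) sc[[k]] <- scenario_defaults[[k]]
  num1 <- function(key, lo = -Inf, hi = Inf, lo_open = FALSE) {
    v <- sc[[key]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      (if (lo_open) v > lo else v >= lo) && v <= hi
    if (!ok)
      config_error(sprintf(
        "config key '%s' = %s is invalid; allowed range %s%g, %g]",
        key, paste(format(v), collapse = ","),
        if (lo_open) "(" else "[", lo, hi))
    v
  }
  num1("agar", 0, 3, lo_open = TRUE)
  num1("dt_s", 0, Inf, lo_open = TRUE)
  num1("duration_s", 0, Inf, lo_open = TRUE)
  num1("width_um", 0, Inf, lo_open = TRUE)
  num1("seg_um", 0, Inf, lo_open = TRUE)
  num1("kappa", 0, Inf)
  num1("plate_radius_um", 0, Inf, lo_open = TRUE)
  if (sc$seg_um > sc$width_um / 2)
    config_error("config key 'seg_um' must not exceed width_um / 2 ",
                 "(trail segment within the deposit radius)")
  if (is.null(sc$inoculum) || !length(sc$inoculum))
    config_error("config key 'inoculum' must list at least one filament")
  for (i in seq_along(sc$inoculum)) {
    ino <- sc$inoculum[[i]]
    need <- c("x_um", "y_um", "heading_rad", "length_um")
    if (!all(need %in% names(ino)))
      config_error(sprintf("config key 'inoculum[%d]' needs fields %s", i,
                           paste(need, collapse = ", ")))
    if (!is.numeric(ino$length_um) || ino$length_um <= 0)
      config_error(sprintf(
        "config key 'inoculum[%d].length_um' must be positive", i))
  }
  sc$encounters <- isTRUE(sc$encounters)
  sc
}

#' Generate a plate scenario configuration
#'
#' Emits a simulator configuration for one of three study templates:
#' `"plug"` — a cluster of short filaments at the plate centre with
#' radiating headings (an agar plug transferred to a fresh plate);
#' `"sparse"` — isolated filaments scattered over the plate; and
#' `"two-filament-encounter"` — two filaments on crossing courses, for
#' studying the left-turn encounter rule.
#'
#' @param template one of `"plug"`, `"sparse"`,
#'   `"two-filament-encounter"`.
#' @param seed integer seed (recorded in the config; drives both inoculum
#'   placement and the simulation).
#' @param agar agar concentration, % w/v.
#' @param n_filaments inoculum size for the plug/sparse templates.
#' @param ... overrides for any scenario default (e.g. `duration_s`,
#'   `doubling_time_s`, `kappa`).
#' @return a validated scenario configuration list.
#' @export
generate_plate_scenario <- function(template = c("plug", "sparse",
                                                 "two-filament-encounter"),
                                    seed = 1L, agar = 1.5,
                                    n_filaments = NULL, ...) {
  if (is.character(template) && length(template) == 1L &&
      !template %in% c("plug", "sparse", "two-filament-encounter"))
    stop("unknown scenario template '", template,
         "'; use plug, sparse or two-filament-encounter")
  template <- match.arg(template)
  sc <- utils::modifyList(scenario_defaults,
                          c(list(template = template, agar = agar,
                                 seed = as.integer(seed)), list(...)))
  sc$inoculum <- with_seed(seed, switch(
    template,
    plug = {
      n <- if (is.null(n_filaments)) 12L else n_filaments
      plug_radius <- 300
      lapply(seq_len(n), function(i) {
        ang <- stats::runif(1, 0, 2 * pi)
        r <- plug_radius * sqrt(stats::runif(1))
        list(x_um = r * cos(ang), y_um = r * sin(ang),
             heading_rad = ang + stats::rnorm(1, 0, 0.3),  # radiating
             length_um = 100)
      })
    },
    sparse = {
      n <- if (is.null(n_filaments)) 8L else n_filaments
      lapply(seq_len(n), function(i) {
        ang <- stats::runif(1, 0, 2 * pi)
        r <- 0.6 * sc$plate_radius_um * sqrt(stats::runif(1))
        list(x_um = r * cos(ang), y_um = r * sin(ang),
             heading_rad = stats::runif(1, 0, 2 * pi), length_um = 100)
      })
    },
    `two-filament-encounter` = list(
      # advancing filament heads east; obstacle crosses its course at x=200
      list(x_um = 0, y_um = 0, heading_rad = 0, length_um = 200),
      list(x_um = 200, y_um = 0, heading_rad = pi / 2, length_um = 300))
  ))
  validate_scenario(sc)
}

#' Read a plate scenario configuration from YAML
#'
#' @param path YAML file path.
#' @return a validated scenario configuration list.
#' @export
read_scenario_config <- function(path) {
  sc <- yaml::read_yaml(path)
  validate_scenario(sc)
}

#' Write a plate scenario configuration to YAML
#'
#' The write-read-write round trip is byte-identical.
#'
#' @param sc scenario configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(sc, path) {
  sc <- validate_scenario(sc)
  writeLines(yaml::as.yaml(sc, precision = 15), path)
  invisible(path)
}
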