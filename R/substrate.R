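## Condition anchors: measured kinetics on 1.5% and 2.0% (w/v) agar.
## v_term/tau are the fitted decay parameters; mean_v the pooled mean speed
## used to fix v_max through the cycle-average identity at T = 450 s.
.agar_anchors <- data.frame(
  agar   = c(1.5, 2.0),
  v_term = c(0.169, 0.148),
  tau    = c(99, 108),
  mean_v = c(0.216, 0.162)
)

## Reference cycle duration (s): midpoint of the 5-10 min reversal range.
.reference_cycle_duration <- 450

## Agar concentration below which filaments sink into the gel and grow
## submerged rather than on the surface.
.submergence_threshold <- 1.1

#' Substrate parameters from agar concentration
#'
#' Maps an agar concentration (% w/v) to the kinetic and geometric
#' parameters the plate simulator needs.  Terminal speed, time constant and
#' condition mean speed are linearly interpolated (and extrapolated, clipped
#' at physical bounds) between the two measured anchor conditions, 1.5% agar
#' (v_term = 0.169 µm/s, tau = 99 s, mean 0.216 µm/s) and 2.0% agar
#' (v_term = 0.148 µm/s, tau = 108 s, mean 0.162 µm/s).  The post-reversal
#' maximum `v_max` is then fixed by [solve_vmax_for_average()] at the
#' reference cycle duration of 450 s so the law reproduces the condition
#' mean.  Below 1.1% agar the filaments become submerged in the gel; the
#' returned parameters carry a `submerged` flag (the simulator then runs but
#' disables spiral classification).
#'
#' @param concentration agar concentration, % w/v; must lie in (0, 3].
#' @param kappa lateral curvature rate on virgin substrate, rad/µm,
#'   counterclockwise-positive.  Default 0.002.
#' @param period_min,period_max reversal-interval bounds, s.
#' @return An object of class `"substrate_params"`: list with fields
#'   `concentration`, `kinetics` (a [kinetic_params()]), `kappa`,
#'   `submerged`.
#' @examples
#' agar_to_params(1.5)$kinetics
#' agar_to_params(0.7)$submerged
#' @export
agar_to_params <- function(concentration, kappa = 0.002,
                           period_min = 300, period_max = 600) {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration <= 0 || concentration > 3)
    stop("'concentration' must be an agar percentage in (0, 3]")
  if (!is.numeric(kappa) || kappa < 0)
    stop("'kappa' must be a non-negative curvature rate (rad/um)")
  a <- .agar_anchors
  interp <- function(y) {
    y[1] + (y[2] - y[1]) * (concentration - a$agar[1]) /
      (a$agar[2] - a$agar[1])
  }
  v_term <- max(0, interp(a$v_term))
  tau <- max(1e-6, interp(a$tau))
  mean_v <- max(v_term, interp(a$mean_v))
  v_max <- solve_vmax_for_average(v_term, tau, .reference_cycle_duration,
                                  mean_v)
  structure(list(
    concentration = concentration,
    kinetics = kinetic_params(v_term, v_max, tau, period_min, period_max),
    kappa = kappa,
    submerged = concentration < .submergence_threshold
  ), class = "substrate_params")
}

#' @export
print.substrate_params <- function(x, ...) {
  cat(sprintf("Substrate: %.2f%% agar%s, kappa = %g rad/um\n",
              x$concentration,
              if (x$submerged) " (submerged)" else "", x$kappa))
  print(x$kinetics)
  invisible(x)
}
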