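#' Fit the post-reversal speed decay law
#'
#' Nonlinear least-squares fit of
#' \eqn{v(t) = v_{term} + (v_{max} - v_{term}) e^{-t/\tau}} to
#' (time-since-reversal, speed) pairs from one or more reversal cycles,
#' estimating the terminal velocity, the post-reversal maximum and the time
#' constant of the decline.  This is the central estimator of the package:
#' its output characterizes a motility condition (e.g. one agar
#' concentration).
#'
#' In `"pooled"` mode all cycles are stacked into a single regression
#' (cycles share the law; only the elapsed time since their own reversal
#' matters).  In `"per-cycle"` mode each cycle is fitted separately and the
#' estimates are averaged, with between-cycle standard errors.  Fitting
#' uses bounded Levenberg--Marquardt least squares with
#' \eqn{v_{term} \ge 0}, \eqn{v_{max} \ge v_{term}} and
#' \eqn{\tau \in (0, 10 \cdot \max(\mathrm{duration})]}, initialized at the
#' minimum speed, the maximum speed and a third of the mean cycle duration.
#' Non-convergence (including unidentifiable, essentially constant-speed
#' data) is flagged, not raised.
#'
#' @param cycles list of cycle segments from [segment_cycles()], or a
#'   data.frame with columns `t_rel` and `speed` (treated as one pooled
#'   cycle of samples).
#' @param mode `"pooled"` (default) or `"per-cycle"`.
#' @return an object of class `"decay_fit"` with components
#'   `coefficients` (`v_max`, `v_term`, `tau`), `se`, `converged`,
#'   `n_cycles`, `n_points`, `mode`, `data`, and (pooled mode) the
#'   underlying `nls` fit.  Supported methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' p <- kinetic_params(0.169, 0.385, 99)
#' t <- 0:450
#' cyc <- data.frame(t_rel = t, speed = instantaneous_speed(p, t))
#' fit <- fit_decay(cyc)
#' coef(fit)
#' @export
fit_decay <- function(cycles, mode = c("pooled", "per-cycle")) {
  mode <- match.arg(mode)
  if (is.data.frame(cycles)) {
    stopifnot(all(c("t_rel", "speed") %in% names(cycles)))
    cycles <- list(list(t_rel = cycles$t_rel, speed = cycles$speed,
                        duration = max(cycles$t_rel)))
  }
  if (!length(cycles)) stop("at least one cycle is required")
  sizes <- vapply(cycles, function(cy) length(cy$t_rel), integer(1))
  dropped <- sum(sizes < 4L)
  cycles <- cycles[sizes >= 4L]
  if (!length(cycles))
    stop("too few points: every cycle has fewer than 4 samples")
  df <- do.call(rbind, lapply(seq_along(cycles), function(i) {
    cy <- cycles[[i]]
    data.frame(cycle = i, t_rel = cy$t_rel, speed = cy$speed)
  }))
  durations <- vapply(cycles, function(cy)
    if (!is.null(cy$duration)) cy$duration else max(cy$t_rel), numeric(1))

  if (mode == "pooled") {
    res <- fit_decay_one(df$t_rel, df$speed, mean(durations), max(durations))
    out <- list(coefficients = res$coefficients, se = res$se,
                converged = res$converged, n_cycles = length(cycles),
                n_points = nrow(df), n_dropped_cycles = dropped,
                mode = mode, data = df, fit = res$fit)
  } else {
    per <- lapply(seq_along(cycles), function(i) {
      cy <- cycles[[i]]
      fit_decay_one(cy$t_rel, cy$speed, durations[i], durations[i])
    })
    ok <- vapply(per, function(r) r$converged, logical(1))
    use <- if (any(ok)) per[ok] else per
    est <- do.call(rbind, lapply(use, function(r) r$coefficients))
    se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
    out <- list(coefficients = colMeans(est), se = se,
                converged = mean(ok) > 0.5, n_cycles = length(cycles),
                n_points = nrow(df), n_dropped_cycles = dropped,
                mode = mode, data = df, per_cycle = est)
  }
  class(out) <- "decay_fit"
  out
}

## Single bounded NLS fit; never raises on non-convergence.
fit_decay_one <- function(t_rel, speed, mean_dur, max_dur) {
  dat <- data.frame(t = t_rel, v = speed)
  start <- list(v_term = max(min(speed), 0), dv = max(diff(range(speed)), 1e-6),
                tau = max(mean_dur / 3, 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ v_term + dv * exp(-t / tau), data = dat,
                      start = start,
                      lower = c(v_term = 0, dv = 0, tau = 1e-6),
                      upper = c(v_term = Inf, dv = Inf, tau = 10 * max_dur),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(v_max = max(speed), v_term = min(speed), tau = NA_real_)
    return(list(coefficients = cf, se = c(v_max = NA_real_,
                                          v_term = NA_real_, tau = NA_real_),
                converged = FALSE, fit = NULL))
  }
  cf <- stats::coef(fit)
  se_raw <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 3))
  v_term <- unname(cf["v_term"]); dv <- unname(cf["dv"])
  tau <- unname(cf["tau"])
  # tau is unidentifiable when the fitted decay amplitude is negligible or
  # tau sits at its upper bound (flat data)
  identifiable <- is.finite(tau) && dv > 1e-3 * max(v_term + dv, 1e-12) &&
    tau < 10 * max_dur * (1 - 1e-6) &&
    is.finite(se_raw[["tau"]]) && se_raw[["tau"]] < 10 * tau
  se_vmax <- sqrt(sum(se_raw[c("v_term", "dv")]^2, na.rm = TRUE))
  list(coefficients = c(v_max = v_term + dv, v_term = v_term, tau = tau),
       se = c(v_max = se_vmax, v_term = unname(se_raw[["v_term"]]),
              tau = unname(se_raw[["tau"]])),
       converged = identifiable, fit = fit)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
print.decay_fit <- function(x, ...) {
  cat("Post-reversal speed decay fit",
      sprintf("(%s, %d cycle(s), %d points)\n", x$mode, x$n_cycles,
              x$n_points))
  cf <- x$coefficients; se <- x$se
  cat(sprintf("  v_max  = %.4f +/- %.4f um/s\n", cf["v_max"], se["v_max"]))
  cat(sprintf("  v_term = %.4f +/- %.4f um/s\n", cf["v_term"], se["v_term"]))
  cat(sprintf("  tau    = %.1f +/- %.1f s\n", cf["tau"], se["tau"]))
  if (!x$converged) cat("  [not converged / tau unidentifiable]\n")
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  r <- stats::residuals(object)
  structure(list(fit = object, rmse = sqrt(mean(r^2)),
                 dropped = object$n_dropped_cycles),
            class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMSE: %.4f um/s\n", x$rmse))
  if (x$dropped > 0)
    cat(sprintf("  %d cycle(s) dropped (< 4 samples)\n", x$dropped))
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t_rel
       else if (is.data.frame(newdata)) newdata$t_rel
       else as.numeric(newdata)
  cf <- object$coefficients
  tau <- if (is.finite(cf["tau"])) cf["tau"] else Inf
  unname(cf["v_term"] + (cf["v_max"] - cf["v_term"]) * exp(-t / tau))
}

#' @export
fitted.decay_fit <- function(object, ...) predict(object)

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$speed - predict(object)
}

#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$data$t_rel, x$data$speed, pch = 16, cex = 0.4,
       col = grDevices::adjustcolor("grey30", 0.4),
       xlab = "time since reversal (s)", ylab = "speed (um/s)",
       main = "Post-reversal speed decay", ...)
  tt <- seq(0, max(x$data$t_rel), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate tracks from a fitted decay law
#'
#' Draws synthetic tip trajectories from the fitted kinetic parameters via
#' [generate_track()], closing the generate-analyze loop.
#'
#' @param object a [fit_decay()] result (must have converged).
#' @param nsim number of tracks.
#' @param seed integer seed.
#' @param ... passed to [track_gen_config()] (e.g. `duration`, `noise_sd`).
#' @return list of [generate_track()] results.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cf <- object$coefficients
  if (!is.finite(cf["tau"]))
    stop("cannot simulate from a fit with unidentifiable tau")
  params <- kinetic_params(v_term = unname(cf["v_term"]),
                           v_max = unname(cf["v_max"]),
                           tau = unname(cf["tau"]))
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  lapply(seeds, function(s)
    generate_track(track_gen_config(params = params, seed = s, ...)))
}
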