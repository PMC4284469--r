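#' Summarize a pooled speed distribution
#'
#' Pools absolute velocities over all time points of one or more velocity
#' series and summarizes them on linear and logarithmic scales.  Pooled
#' speed distributions of gliding filaments are right-skewed and close to
#' log-normal — a direct consequence of the exponential post-reversal
#' decline — so both scales are reported, together with sample skewness on
#' each.  Zero speeds are excluded from the log-scale statistics and
#' counted.
#'
#' @param series a list of [compute_velocity()] results, a single one, or a
#'   numeric vector of speeds.
#' @param breaks passed to [graphics::hist()] for both histograms.
#' @return an object of class `"distribution_summary"`: list with `n`,
#'   `mean`, `sd`, `skewness`, `n_zero`, `log_mean`, `log_sd`,
#'   `log_skewness` (log10 scale), and `hist_linear` / `hist_log`
#'   (histogram objects).
#' @export
summarize_distribution <- function(series, breaks = "Sturges") {
  speeds <-
    if (is.numeric(series)) abs(series)
    else if (inherits(series, "velocity_series")) abs(series$v)
    else if (is.list(series)) {
      stopifnot(all(vapply(series, inherits, logical(1), "velocity_series")))
      abs(unlist(lapply(series, function(s) s$v)))
    } else stop("'series' must be velocity series or a numeric vector")
  speeds <- speeds[is.finite(speeds)]
  if (!length(speeds)) stop("no pooled speeds to summarize")
  pos <- speeds[speeds > 0]
  h_lin <- graphics::hist(speeds, breaks = breaks, plot = FALSE)
  out <- list(
    n = length(speeds),
    mean = mean(speeds),
    sd = stats::sd(speeds),
    skewness = sample_skewness(speeds),
    n_zero = sum(speeds == 0),
    log_mean = if (length(pos)) mean(log10(pos)) else NA_real_,
    log_sd = if (length(pos) > 1L) stats::sd(log10(pos)) else NA_real_,
    log_skewness = if (length(pos)) sample_skewness(log10(pos)) else NA_real_,
    hist_linear = h_lin,
    hist_log = if (length(pos))
      graphics::hist(log10(pos), breaks = breaks, plot = FALSE) else NULL,
    all_zero = !length(pos)
  )
  class(out) <- "distribution_summary"
  out
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("Pooled speed distribution: n = %d\n", x$n))
  cat(sprintf("  mean |v| = %.4f um/s, SD = %.4f, skewness = %.2f\n",
              x$mean, x$sd, x$skewness))
  if (x$all_zero) {
    cat("  [all speeds zero: log-scale summary empty]\n")
  } else {
    cat(sprintf("  log10 scale: mean = %.3f, SD = %.3f, skewness = %.2f",
                x$log_mean, x$log_sd, x$log_skewness))
    if (x$n_zero > 0) cat(sprintf(" (%d zero speed(s) excluded)", x$n_zero))
    cat("\n")
  }
  invisible(x)
}

#' Compare pooled speeds between two conditions
#'
#' Tests whether two pooled speed samples (e.g. two agar concentrations)
#' differ.  Because the distributions are log-normal-like with unequal
#' sample sizes, the default is Welch's two-sample t-test on log speeds;
#' the Mann--Whitney (Wilcoxon rank-sum) test on raw speeds is available as
#' an option.  Non-positive speeds are dropped before taking logs.
#'
#' @param a,b numeric speed samples, each with >= 3 values, µm/s.
#' @param alpha significance level, default 0.05.
#' @param method `"welch-log"` (default) or `"mann-whitney"`.
#' @return an object of class `"condition_comparison"`: list with
#'   `statistic`, `p_value`, `significant`, `method`, `alpha`, `n_a`,
#'   `n_b`.
#' @export
compare_conditions <- function(a, b, alpha = 0.05,
                               method = c("welch-log", "mann-whitney")) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("each sample needs at least 3 finite values")
  stopifnot(alpha > 0, alpha < 1)
  if (method == "welch-log") {
    la <- log(a[a > 0]); lb <- log(b[b > 0])
    if (length(la) < 3L || length(lb) < 3L)
      stop("too few positive speeds for the log-scale test")
    ht <- stats::t.test(la, lb, var.equal = FALSE)
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
  }
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 significant = ht$p.value < alpha, method = method,
                 alpha = alpha, n_a = length(a), n_b = length(b)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison (%s): n = %d vs %d\n", x$method,
              x$n_a, x$n_b))
  cat(sprintf("  statistic = %.3f, p = %.3g -> %ssignificant at alpha = %g\n",
              x$statistic, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Displacement-duration relation of reversal cycles
#'
#' Tabulates, per cycle, the duration and the net displacement, and reports
#' the upper-limit slope: the maximum of displacement/duration over cycles.
#' Cycles travelled at constant maximal speed lie on the limiting line
#' `displacement = slope * duration`; oscillating or decaying cycles fall
#' below it.
#'
#' @param cycles list of cycle segments from [segment_cycles()].
#' @return list with `table` (data.frame `duration_s`,
#'   `displacement_um`, `mean_velocity_um_s`) and `upper_limit_slope`
#'   (µm/s).
#' @export
displacement_duration_table <- function(cycles) {
  if (!length(cycles)) stop("at least one cycle is required")
  d <- data.frame(
    duration_s = vapply(cycles, function(cy) cy$duration, numeric(1)),
    displacement_um = vapply(cycles, function(cy) cy$displacement_um,
                             numeric(1)))
  d$mean_velocity_um_s <- d$displacement_um / d$duration_s
  list(table = d, upper_limit_slope = max(d$mean_velocity_um_s))
}

#' Saturating relation between filament length and net velocity
#'
#' Longer filaments achieve larger net velocities, saturating at an upper
#' limit.  Fits the saturating form
#' \eqn{v_{net}(L) = a (1 - e^{-L/\lambda})} by least squares and reports
#' the asymptote `a` and the length scale `lambda`.  Constant net velocity
#' across lengths drives `lambda` to its lower boundary, which is flagged.
#'
#' @param lengths filament lengths, µm; >= 4 points spanning at least one
#'   decade.
#' @param v_net net velocities, µm/s.
#' @return list with `a`, `lambda`, `lambda_boundary` (logical),
#'   `fitted` (function of L), `n`.
#' @export
length_velocity_relation <- function(lengths, v_net) {
  stopifnot(is.numeric(lengths), is.numeric(v_net),
            length(lengths) == length(v_net))
  keep <- is.finite(lengths) & is.finite(v_net) & lengths > 0
  lengths <- lengths[keep]; v_net <- v_net[keep]
  if (length(lengths) < 4L) stop("at least 4 points are required")
  if (max(lengths) <= min(lengths))
    stop("degenerate length range: lengths must vary")
  if (max(lengths) / min(lengths) < 10)
    warning("lengths span less than one decade; the saturation length ",
            "scale may be poorly constrained")
  lam_floor <- 1e-6 * stats::median(lengths)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a * (1 - exp(-L / lambda)),
                      data = data.frame(L = lengths, v = v_net),
                      start = list(a = max(v_net),
                                   lambda = stats::median(lengths)),
                      lower = c(a = 0, lambda = lam_floor),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a <- mean(v_net); lambda <- lam_floor; boundary <- TRUE
  } else {
    cf <- stats::coef(fit)
    a <- unname(cf["a"]); lambda <- unname(cf["lambda"])
    boundary <- lambda <= lam_floor * (1 + 1e-6)
    if (boundary) a <- mean(v_net)
  }
  list(a = a, lambda = lambda, lambda_boundary = boundary,
       fitted = function(L) a * (1 - exp(-L / lambda)),
       n = length(lengths))
}
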