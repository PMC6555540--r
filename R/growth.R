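#' Estimate a doubling time by log-linear regression
#'
#' Fits ordinary least squares of log2(OD) on time over the exponential
#' phase and returns tau = 1/slope in minutes. The exponential window is
#' chosen automatically: if the full series fits with R2 >= 0.99 it is
#' used as-is; otherwise every contiguous run of >= 4 points is scanned
#' and the best-R2 run is used (ties broken toward the longer, then
#' earlier, run). A manual window can be forced with `window`.
#'
#' @param curve a `growth_curve` (see [simulate_growth_curve()]) or data
#'   frame with columns `time` (minutes) and `od` (> 0).
#' @param window optional integer vector of point indices to fit
#'   (overrides the automatic selection); >= 4 indices.
#' @return A `doubling_estimate` list: `strain`, `tau_hat` (min), `se`
#'   (delta-method standard error), `window` (indices used),
#'   `r_squared`, `slope` (log2 OD per min).
#' @examples
#' gc <- simulate_growth_curve(180, seq(0, 540, by = 60))
#' fit_doubling_time(gc)$tau_hat
#' @export
fit_doubling_time <- function(curve, window = NULL) {
  curve <- as.data.frame(curve)
  if (!all(c("time", "od") %in% names(curve)))
    stop("growth curve needs columns 'time' and 'od'")
  if (nrow(curve) < 4L) stop("need >= 4 time points")
  if (any(curve$od <= 0)) stop("OD values must be strictly positive")
  if (any(diff(curve$time) <= 0)) stop("times must be strictly increasing")
  t <- curve$time
  y <- log2(curve$od)

  fit_window <- function(ii) {
    f <- stats::lm.fit(cbind(1, t[ii]), y[ii])
    slope <- f$coefficients[2]
    ss_res <- sum(f$residuals^2)
    ss_tot <- sum((y[ii] - mean(y[ii]))^2)
    r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
    list(slope = slope, r2 = r2, ii = ii,
         se_slope = {
           n <- length(ii)
           sxx <- sum((t[ii] - mean(t[ii]))^2)
           if (n > 2) sqrt(ss_res / (n - 2) / sxx) else NA_real_
         })
  }

  if (!is.null(window)) {
    window <- sort(unique(as.integer(window)))
    if (length(window) < 4L || any(window < 1L) || any(window > nrow(curve)))
      stop("'window' must hold >= 4 valid point indices")
    best <- fit_window(window)
  } else {
    best <- fit_window(seq_along(t))
    if (best$r2 < 0.99) {
      n <- length(t)
      for (len in seq(n, 4L)) {
        for (s in seq_len(n - len + 1L)) {
          cand <- fit_window(s:(s + len - 1L))
          # higher R2 wins; longer (outer loop) and earlier windows win ties
          if (cand$r2 > best$r2 + 1e-9) best <- cand
        }
      }
    }
  }
  if (!is.finite(best$slope) || best$slope <= 0)
    stop("no positive growth detected (log-linear slope <= 0)")
  tau <- 1 / best$slope
  structure(list(strain = attr(curve, "strain") %||% "strain",
                 tau_hat = unname(tau),
                 se = unname(best$se_slope / best$slope^2),
                 window = best$ii, r_squared = best$r2,
                 slope = unname(best$slope)),
            class = "doubling_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.doubling_estimate <- function(x, ...) {
  cat(sprintf("%s: doubling time %.1f min (se %.2f, R2 %.4f, %d points)\n",
              x$strain, x$tau_hat, x$se, x$r_squared, length(x$window)))
  invisible(x)
}

#' Suppression index from three doubling times
#'
#' Fraction of the mutant growth defect rescued by a suppressor:
#' (tau_mut - tau_double) / (tau_mut - tau_wt). 1 means the double mutant
#' grows like wild type (full rescue), 0 means no rescue.
#'
#' @param tau_wt,tau_mut,tau_double doubling times (same units) of the
#'   wild type, single mutant, and mutant + suppressor. Requires
#'   `tau_mut > tau_wt`.
#' @return A `suppression_index` list: `value`, `tau_wt`, `tau_mut`,
#'   `tau_double`.
#' @examples
#' suppression_index(102, 180, 135)$value  # ~0.577
#' @export
suppression_index <- function(tau_wt, tau_mut, tau_double) {
  for (v in list(tau_wt, tau_mut, tau_double))
    check_scalar(v, "tau", lower = 0, strict_lower = TRUE)
  if (tau_mut <= tau_wt)
    stop("tau_mut must exceed tau_wt (no growth defect to suppress)")
  structure(list(value = (tau_mut - tau_double) / (tau_mut - tau_wt),
                 tau_wt = tau_wt, tau_mut = tau_mut, tau_double = tau_double),
            class = "suppression_index")
}

#' Suppressor frequency with exact binomial confidence interval
#'
#' Frequency = colonies / (cells plated x survival fraction), with a
#' Clopper-Pearson 95% CI on the per-viable-cell probability.
#'
#' @param fc a `fluctuation_counts` object (see [simulate_fluctuation()])
#'   or a list with `cells_plated`, `suppressor_colonies`,
#'   `survival_fraction`, `condition`.
#' @param conf_level confidence level. Default 0.95.
#' @return A `frequency_estimate` list: `condition`, `frequency`,
#'   `ci` (length 2), `colonies`, `viable_cells`.
#' @export
estimate_frequency <- function(fc, conf_level = 0.95) {
  if (is.null(fc$cells_plated) || fc$cells_plated <= 0)
    stop("cells_plated must be > 0")
  viable <- round(fc$cells_plated * fc$survival_fraction)
  x <- fc$suppressor_colonies
  if (x > viable)
    stop("more colonies than viable cells")
  # Clopper-Pearson interval in closed form (beta quantiles); avoids
  # binom.test(), whose p-value computation is O(n) in the cell count
  alpha <- 1 - conf_level
  ci <- c(if (x == 0) 0 else stats::qbeta(alpha / 2, x, viable - x + 1),
          if (x == viable) 1 else stats::qbeta(1 - alpha / 2, x + 1,
                                               viable - x))
  structure(list(condition = fc$condition %||% "unknown",
                 frequency = x / viable,
                 ci = as.numeric(ci),
                 colonies = x,
                 viable_cells = viable),
            class = "frequency_estimate")
}

#' Fold increase in suppressor frequency (e.g. after UV)
#'
#' Ratio of two frequency estimates with a log-scale delta-method CI from
#' the two binomial standard errors.
#'
#' @param spont,uv `frequency_estimate` objects (see
#'   [estimate_frequency()]) for the baseline and treated condition.
#' @param conf_level confidence level. Default 0.95.
#' @return A list: `fold`, `ci`, `log_se`.
#' @export
uv_fold <- function(spont, uv, conf_level = 0.95) {
  if (spont$frequency <= 0)
    stop("spontaneous frequency is zero; report a lower bound on the fold ",
         "instead (use the CI upper limit of the spontaneous frequency)")
  fold <- uv$frequency / spont$frequency
  # var(log p-hat) ~ (1 - p) / (n p) for binomial counts
  vlog <- function(fe) {
    if (fe$colonies == 0) return(NA_real_)
    (1 - fe$frequency) / (fe$viable_cells * fe$frequency)
  }
  log_se <- sqrt(vlog(spont) + vlog(uv))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(log_se)) c(NA_real_, NA_real_)
        else fold * exp(c(-1, 1) * z * log_se)
  list(fold = fold, ci = ci, log_se = log_se)
}
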