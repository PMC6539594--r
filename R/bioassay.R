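#' Competitive-ELISA percent inhibition
#'
#' `inh = 100 - (S - NS) * 100 / (Pmax - NS)`, where `S` is the signal with
#' inhibitor, `NS` the negative-control signal and `Pmax` the maximum binding
#' signal without inhibitor. `S = Pmax` gives 0 percent, `S = NS` gives 100
#' percent, and the value is invariant under a joint affine transformation of
#' all three signals.
#'
#' @param S Measured signal(s) with inhibitor (vectorised).
#' @param NS Negative-control signal.
#' @param Pmax Maximum binding signal (no inhibitor).
#' @return Percent inhibition, same length as `S`.
#' @export
percent_inhibition <- function(S, NS, Pmax) {
  if (any(Pmax == NS)) {
    stop("percent inhibition undefined: Pmax equals NS", call. = FALSE)
  }
  100 - (S - NS) * 100 / (Pmax - NS)
}

#' Replicate summary: mean and sample standard deviation
#'
#' @param values Numeric replicate values.
#' @return List with `mean`, `sd` (n-1 denominator; `NA` and `flagged = TRUE`
#'   when fewer than 2 values are supplied) and `n`.
#' @export
summarize_replicates <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1) stop("no values supplied", call. = FALSE)
  list(mean = mean(values),
       sd = if (n >= 2) stats::sd(values) else NA_real_,
       n = n, flagged = n < 2)
}

#' Fit a log-logistic dose-response curve
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of
#' `inh(c) = 100 / (1 + 10^(h * (logIC50 - log10 c)))`, which rises to 100
#' percent inhibition as the concentration grows. The Hill slope `h` is
#' fitted by default (initialised at 1) or can be fixed to 1.
#'
#' @param conc Molar concentrations (at least 4 distinct values spanning the
#'   transition).
#' @param inh Percent inhibition at each concentration.
#' @param fix_hill If `TRUE`, fix the Hill slope at 1.
#' @return Object of class `dose_response_fit`: list with `logIC50`,
#'   `logIC50_se`, `hill`, `hill_se` (`NA` when fixed), `r.squared`,
#'   `fitted`, `ic50_uM` and the `nls` fit.
#' @export
fit_dose_response <- function(conc, inh, fix_hill = FALSE) {
  stopifnot(length(conc) == length(inh))
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(unique(conc)) < 4) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  x <- log10(conc)
  start_l50 <- x[which.min(abs(inh - 50))]
  dat <- data.frame(x = x, inh = inh)
  fit <- tryCatch({
    if (fix_hill) {
      minpack.lm::nlsLM(inh ~ 100 / (1 + 10^(l50 - x)),
                        data = dat, start = list(l50 = start_l50))
    } else {
      minpack.lm::nlsLM(inh ~ 100 / (1 + 10^(h * (l50 - x))),
                        data = dat, start = list(l50 = start_l50, h = 1),
                        lower = c(l50 = -Inf, h = 1e-3))
    }
  }, error = function(e) {
    stop("dose-response fit did not converge: ", conditionMessage(e),
         call. = FALSE)
  })
  sm <- summary(fit)
  est <- sm$coefficients
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((inh - mean(inh))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  logIC50 <- est["l50", "Estimate"]
  structure(list(
    logIC50 = logIC50,
    logIC50_se = est["l50", "Std. Error"],
    hill = if (fix_hill) 1 else est["h", "Estimate"],
    hill_se = if (fix_hill) NA_real_ else est["h", "Std. Error"],
    r.squared = r2,
    fitted = as.numeric(stats::fitted(fit)),
    ic50_uM = ic50_micromolar(logIC50),
    fit = fit), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("log IC50 = %.3f +/- %.2g (IC50 = %.2f uM), Hill = %.2f, R^2 = %.4f\n",
              x$logIC50, x$logIC50_se, x$ic50_uM, x$hill, x$r.squared))
  invisible(x)
}

#' Convert a molar log10 IC50 to micromolar
#'
#' `IC50 [uM] = 10^(logIC50 + 6)`; reports conventionally round to 2 decimal
#' places (e.g. -5.076 corresponds to 8.39 uM).
#'
#' @param logIC50 Base-10 logarithm of the molar IC50.
#' @return IC50 in micromolar (unrounded).
#' @export
ic50_micromolar <- function(logIC50) {
  stopifnot(is.finite(logIC50))
  10^(logIC50 + 6)
}

#' Fit an exponential stability decay and half-life
#'
#' Least-squares fit of `f(t) = 100 * exp(-k t)` to a fraction-remaining time
#' series (percent), with `t_half = ln(2) / k`. When the fitted decline over
#' the observation window is below a resolution threshold the series is
#' flagged censored and the half-life is reported as a lower bound at the
#' window end, mirroring how slow degradation ("half-life far exceeding the
#' observation window") can only be bounded, not measured.
#'
#' @param time Times in hours; must include 0 and be non-negative.
#' @param fraction Percent of compound remaining at each time.
#' @param resolution Smallest resolvable decline over the window, in percent
#'   points (default 10).
#' @return Object of class `decay_fit`: list with `k` (1/h), `t_half` (h,
#'   `Inf` when no decay), `censored`, `t_half_lower` (window end when
#'   censored, otherwise `NA`), `r.squared` and `fitted`.
#' @export
fit_decay <- function(time, fraction, resolution = 10) {
  stopifnot(length(time) == length(fraction))
  if (any(time < 0)) stop("negative times are not allowed", call. = FALSE)
  if (length(time) < 3) stop("need at least 3 time points", call. = FALSE)
  if (min(time) > 0) stop("series must include t = 0", call. = FALSE)
  tmax <- max(time)
  if (stats::sd(fraction) == 0) {
    return(structure(list(k = 0, t_half = Inf, censored = TRUE,
                          t_half_lower = tmax, r.squared = NA_real_,
                          fitted = fraction), class = "decay_fit"))
  }
  # log-linear start value, guarded against non-positive fractions
  pos <- fraction > 0
  k0 <- -stats::coef(stats::lm(log(fraction[pos] / 100) ~ 0 + time[pos]))[[1]]
  k0 <- max(k0, 1e-6)
  dat <- data.frame(time = time, fraction = fraction)
  fit <- minpack.lm::nlsLM(fraction ~ 100 * exp(-k * time), data = dat,
                           start = list(k = k0), lower = c(k = 0))
  k <- stats::coef(fit)[["k"]]
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((fraction - mean(fraction))^2)
  decline <- 100 * (1 - exp(-k * tmax))
  censored <- decline < resolution
  structure(list(
    k = k,
    k_se = summary(fit)$coefficients["k", "Std. Error"],
    t_half = if (k > 0) log(2) / k else Inf,
    censored = censored,
    t_half_lower = if (censored) tmax else NA_real_,
    r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
    fitted = as.numeric(stats::fitted(fit)),
    fit = fit), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("decay below resolution: t1/2 > %g h (censored)\n",
                x$t_half_lower))
  } else {
    cat(sprintf("k = %.4g 1/h, t1/2 = %.1f h\n", x$k, x$t_half))
  }
  invisible(x)
}
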