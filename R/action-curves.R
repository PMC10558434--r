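#' Physiological action curves and on-board signals
#'
#' The p-LSTM preprocessing layer convolves the raw insulin and CHO
#' channels with fixed, non-learnable decay curves to obtain
#' insulin-on-board (IOB) and carbohydrates-on-board (COB): the amount of
#' previously delivered insulin (U) or ingested carbohydrate (g) still
#' pharmacologically active.  The curve family is the remaining fraction
#' \deqn{r(t) = (1 + t/\tau)\, e^{-t/\tau}}
#' (the integral of a biexponential activity profile), with \eqn{\tau}
#' chosen so the fraction has decayed to 1\% at the stated duration, then
#' truncated to exactly zero there.
#'
#' @name action_curves
NULL

# solve (1 + x) exp(-x) = 0.01 once: x = duration / tau
.r_root <- local({
  f <- function(x) (1 + x) * exp(-x) - 0.01
  stats::uniroot(f, c(1, 20), tol = 1e-12)$root
})

.action_curve <- function(duration_min, step_min, kind) {
  if (duration_min <= 0) stop("duration must be > 0")
  if (step_min > duration_min) stop("step exceeds the curve duration")
  if (duration_min %% step_min != 0)
    stop("duration must be a multiple of the grid step")
  tau <- duration_min / .r_root
  tmin <- seq(0, duration_min, by = step_min)
  taps <- (1 + tmin / tau) * exp(-tmin / tau)
  taps[tmin >= duration_min] <- 0
  structure(list(taps = taps, step_min = step_min, kind = kind,
                 duration_min = duration_min),
            class = "action_curve")
}

#' @export
print.action_curve <- function(x, ...) {
  cat(sprintf("<action_curve> %s, %g min support, %d taps @ %g min\n",
              x$kind, x$duration_min, length(x$taps), x$step_min))
  invisible(x)
}

#' Insulin action curve
#'
#' Remaining-fraction curve of rapid-acting insulin.  The 6-hour default
#' matches the duration-of-insulin-action setting of typical bolus
#' calculators.
#'
#' @param duration_min total duration of insulin action, minutes.
#' @param step_min grid step, minutes.
#' @return an \code{action_curve}.
#' @rdname action_curves
#' @export
insulin_action_curve <- function(duration_min = 360, step_min = 5) {
  .action_curve(duration_min, step_min, "insulin")
}

#' Carbohydrate action curve
#'
#' Remaining-fraction curve of meal absorption.  Carbohydrates absorb
#' faster than subcutaneous insulin acts, so even the slow curve is shorter
#' than the insulin curve: 'slow' spans 4 hours (mixed/high-fat meals),
#' 'fast' 2 hours (rapidly absorbed carbohydrates).
#'
#' @param speed \code{"slow"} or \code{"fast"}.
#' @rdname action_curves
#' @export
cho_action_curve <- function(speed = c("slow", "fast"), step_min = 5) {
  speed <- match.arg(speed)
  .action_curve(if (speed == "slow") 240 else 120, step_min, "cho")
}

#' On-board convolution
#'
#' Causal convolution of a rate channel with an action curve:
#' \deqn{OB[t] = \sum_{k} x[t-k]\, \Delta t\, h[k]}
#' so that a single bolus of U units (delivered as U/step over one bin)
#' yields exactly U at its own bin.  Samples before the series start are
#' taken at \code{warmup} (the series' basal delivery floor for insulin --
#' the minimum of the channel, which is the basal rate under a
#' basal-bolus regimen -- and zero for CHO), suppressing start-of-series
#' transients without inventing phantom pre-history boluses.
#'
#' @param x rate channel (U/min or g/min).
#' @param curve an \code{action_curve}.
#' @param step_min grid step of \code{x}; must equal the curve's step.
#' @param warmup pre-history rate value.
#' @return numeric vector of on-board amounts (U or g).
#' @keywords internal
#' @noRd
.onboard <- function(x, curve, step_min, warmup) {
  if (!isTRUE(all.equal(step_min, curve$step_min)))
    stop("grid step does not match the action curve step")
  K <- length(curve$taps) - 1L
  padded <- c(rep(warmup, K), x)
  y <- stats::filter(padded, curve$taps, method = "convolution", sides = 1)
  as.numeric(y[(K + 1):length(padded)]) * step_min
}

#' Insulin-on-board signal
#'
#' @param s a \code{\link{glucose_series}} (or a numeric U/min channel with
#'   \code{step_min} given).
#' @param curve an insulin \code{action_curve}.
#' @param step_min grid step when \code{s} is a bare numeric channel.
#' @return IOB in units (U) per sample.
#' @export
iob <- function(s, curve = insulin_action_curve(), step_min = NULL) {
  if (inherits(s, "glucose_series")) {
    x <- s$insulin
    step_min <- s$grid$step_min
  } else {
    x <- s
    if (is.null(step_min)) stop("step_min required for a bare channel")
  }
  .onboard(x, curve, step_min, warmup = min(x))
}

#' Carbohydrates-on-board signal
#'
#' @param s a \code{\link{glucose_series}} (or a numeric g/min channel).
#' @param curve a CHO \code{action_curve}.
#' @param step_min grid step when \code{s} is a bare numeric channel.
#' @return COB in grams per sample.
#' @export
cob <- function(s, curve = cho_action_curve("slow"), step_min = NULL) {
  if (inherits(s, "glucose_series")) {
    x <- s$cho
    step_min <- s$grid$step_min
  } else {
    x <- s
    if (is.null(step_min)) stop("step_min required for a bare channel")
  }
  .onboard(x, curve, step_min, warmup = 0)
}

#' Export an action curve as a two-column CSV (minutes, fraction)
#'
#' @param curve an \code{action_curve}.
#' @param path output path.
#' @export
write_action_curve_csv <- function(curve, path) {
  df <- data.frame(minutes = curve$step_min * (seq_along(curve$taps) - 1),
                   fraction = curve$taps)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
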