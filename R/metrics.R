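#' Forecast accuracy metrics
#'
#' Standard point-forecast metrics for glucose prediction: mean absolute
#' error, root mean square error, the effective forecast delay, and the
#' time gain TG = PH - delay.  All operate on anchor-aligned vectors --
#' element \code{t} of \code{ghat} is the forecast issued at anchor
#' \code{t} for time \code{t + PH} and is compared with element \code{t}
#' of \code{g}, the realized value at \code{t + PH}.  \code{NA}s (missing
#' targets or unemitted forecasts) are dropped pairwise.
#'
#' @param g realized values at the forecast target times, mg/dl.
#' @param ghat forecasts, mg/dl.
#' @return scalar metric value.
#' @name accuracy_metrics
NULL

.paired <- function(g, ghat) {
  if (length(g) != length(ghat)) stop("'g' and 'ghat' must be the same length")
  ok <- !is.na(g) & !is.na(ghat)
  if (!any(ok)) stop("no common anchors between target and forecast")
  list(g = g[ok], ghat = ghat[ok], n = sum(ok))
}

#' @rdname accuracy_metrics
#' @export
mae <- function(g, ghat) {
  p <- .paired(g, ghat)
  mean(abs(p$g - p$ghat))
}

#' @rdname accuracy_metrics
#' @export
rmse <- function(g, ghat) {
  p <- .paired(g, ghat)
  sqrt(mean((p$g - p$ghat)^2))
}

#' Effective forecast delay
#'
#' The temporal shift that minimizes the distance between the forecast and
#' the target profile: the forecast series is shifted \code{j} minutes back
#' in time (candidate \code{j} in \code{0, step, ..., PH}) and scored by
#' mean squared error against the target on the overlapping anchors; the
#' minimizing shift is the delay (ties break towards the smallest
#' \code{j}).  A perfect predictor has delay 0; a persistence forecast on a
#' ramp has delay PH.
#'
#' @param g realized values at target times (anchor-aligned, as in
#'   \code{\link{mae}}).
#' @param ghat forecasts.
#' @param ph_min prediction horizon, minutes (multiple of \code{step_min}).
#' @param step_min grid step, minutes.
#' @return delay in minutes.
#' @export
delay <- function(g, ghat, ph_min, step_min = 5) {
  if (ph_min %% step_min != 0) stop("'ph_min' must be a multiple of 'step_min'")
  if (length(g) != length(ghat)) stop("'g' and 'ghat' must be the same length")
  n <- length(g)
  shifts <- seq(0, ph_min, by = step_min)
  best_j <- NA_real_
  best_mse <- Inf
  for (j in shifts) {
    js <- j / step_min
    if (js >= n) next
    # forecast shifted js steps earlier: ghat[t + js] scored against g[t]
    a <- g[seq_len(n - js)]
    b <- ghat[seq_len(n - js) + js]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    m <- mean((a[ok] - b[ok])^2)
    if (m < best_mse - 1e-12) {
      best_mse <- m
      best_j <- j
    }
  }
  if (is.na(best_j)) stop("no overlapping anchors at any candidate shift")
  best_j
}

#' Time gain
#'
#' TG = PH - delay: the useful anticipation the forecaster provides.
#'
#' @inheritParams delay
#' @return time gain in minutes, in \code{[0, PH]}.
#' @export
time_gain <- function(g, ghat, ph_min, step_min = 5) {
  ph_min - delay(g, ghat, ph_min, step_min)
}

#' Time in glycemic ranges
#'
#' Percentage of non-missing CGM samples below 70 mg/dl (TBR), within the
#' normoglycemic interval [70, 180] mg/dl inclusive (TIR), and above 180
#' mg/dl (TAR).  The three percentages sum to 100.
#'
#' @param x a \code{\link{glucose_series}} or numeric mg/dl vector
#'   (\code{NA} = missing, excluded from numerator and denominator).
#' @return a list of class \code{range_report}: \code{tbr}, \code{tir},
#'   \code{tar} (percent) and \code{n} (samples evaluated).
#' @export
time_in_ranges <- function(x) {
  if (inherits(x, "glucose_series")) x <- x$cgm
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no non-missing samples")
  n <- length(x)
  structure(list(tbr = 100 * sum(x < 70) / n,
                 tir = 100 * sum(x >= 70 & x <= 180) / n,
                 tar = 100 * sum(x > 180) / n,
                 n = n),
            class = "range_report")
}

#' @export
print.range_report <- function(x, ...) {
  cat(sprintf("TBR %.1f%% | TIR %.1f%% | TAR %.1f%% (n = %d)\n",
              x$tbr, x$tir, x$tar, x$n))
  invisible(x)
}

#' Full accuracy report for a forecast set
#'
#' Convenience wrapper assembling MAE, RMSE, delay and TG from a forecast
#' table (as returned by \code{\link{predict_series}}) and the series the
#' forecasts target.
#'
#' @param s the evaluated \code{\link{glucose_series}}.
#' @param forecasts data.frame from \code{\link{predict_series}}.
#' @param ph_min prediction horizon, minutes.
#' @return a list of class \code{accuracy_report}: \code{mae}, \code{rmse},
#'   \code{delay}, \code{tg} and \code{n}.
#' @export
accuracy_report <- function(s, forecasts, ph_min) {
  step <- s$grid$step_min
  al <- align_forecasts(s, forecasts, ph_min)
  structure(list(mae = mae(al$g, al$ghat),
                 rmse = rmse(al$g, al$ghat),
                 delay = delay(al$g, al$ghat, ph_min, step),
                 tg = time_gain(al$g, al$ghat, ph_min, step),
                 n = sum(!is.na(al$g) & !is.na(al$ghat))),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("MAE %.2f mg/dl | RMSE %.2f mg/dl | delay %g min | TG %g min (n = %d)\n",
              x$mae, x$rmse, x$delay, x$tg, x$n))
  invisible(x)
}

#' Align a forecast table with its target series
#'
#' Produces anchor-aligned vectors over every possible anchor of \code{s}:
#' \code{g[t]} is the realized CGM at \code{t + PH} and \code{ghat[t]} the
#' forecast issued at \code{t}, \code{NA} where either is unavailable.
#'
#' @inheritParams accuracy_report
#' @return list with numeric vectors \code{g} and \code{ghat}.
#' @export
align_forecasts <- function(s, forecasts, ph_min) {
  step <- s$grid$step_min
  hs <- as.integer(ph_min / step)
  n <- s$grid$n
  n_anchor <- n - hs
  if (n_anchor < 1) stop("series shorter than the prediction horizon")
  g <- s$cgm[seq_len(n_anchor) + hs]
  ghat <- rep(NA_real_, n_anchor)
  keep <- forecasts$anchor <= n_anchor
  ghat[forecasts$anchor[keep]] <- forecasts$yhat[keep]
  list(g = g, ghat = ghat)
}
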