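# Reference forecasters used as test doubles wherever a predictor is
# consumed (explanation, bolus suggestion, replay policies).

# linear model on the anchor's channel values: ghat = b0 + b %*% x_t
linear_stub <- function(beta0, beta, lookback = 12L) {
  stopifnot(all(c("cgm", "insulin", "cho") %in% names(beta)))
  structure(list(beta0 = beta0, beta = beta,
                 config = list(lookback = as.integer(lookback))),
            class = "linear_stub")
}

predict_anchor.linear_stub <- function(m, s, t) {
  if (any(is.na(s$cgm[(t - m$config$lookback + 1):t]))) return(NA_real_)
  m$beta0 + m$beta[["cgm"]] * s$cgm[t] +
    m$beta[["insulin"]] * s$insulin[t] + m$beta[["cho"]] * s$cho[t]
}

.S3method("predict_anchor", "linear_stub", predict_anchor.linear_stub)

# forecast that is a pure function of the candidate dose
dose_stub <- function(fun, lookback = 1L) {
  structure(list(fun = fun, config = list(lookback = as.integer(lookback))),
            class = "dose_stub")
}

predict_anchor.dose_stub <- function(m, s, t) m$fun(0)
predict_counterfactual.dose_stub <- function(m, s, t, extra_bolus) {
  if (any(extra_bolus < 0)) stop("extra_bolus must be >= 0")
  m$fun(extra_bolus)
}

.S3method("predict_anchor", "dose_stub", predict_anchor.dose_stub)
.S3method("predict_counterfactual", "dose_stub",
          predict_counterfactual.dose_stub)

# quick gapless series builder on a 5-min grid
make_series <- function(cgm, insulin = NULL, cho = NULL,
                        start = "2023-03-01 00:00:00", step_min = 5) {
  n <- length(cgm)
  if (is.null(insulin)) insulin <- rep(0.012, n)
  if (is.null(cho)) cho <- rep(0, n)
  glucose_series(time_grid(as.POSIXct(start, tz = "UTC"), step_min, n),
                 cgm, insulin, cho)
}
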