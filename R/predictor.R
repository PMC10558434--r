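#' Forecaster configuration
#'
#' One configuration per (variant, prediction horizon) pair.  The two
#' variants share an identical architecture (a single layer of 64 LSTM
#' units feeding a linear read-out) and training procedure; the only
#' difference is the preprocessing flag: variant \code{"np"} feeds the raw
#' CGM/insulin/CHO channels, variant \code{"p"} first convolves insulin and
#' CHO with fixed physiological action curves into IOB and COB (see
#' \code{\link{action_curves}}).
#'
#' @param variant \code{"np"} (raw channels) or \code{"p"} (physiological
#'   preprocessing).
#' @param ph_min prediction horizon in minutes; must be a multiple of the
#'   grid step (30 and 60 are the study settings).
#' @param lookback input window length in samples (default 12 = 60 min on
#'   a 5-min grid).
#' @param hidden LSTM units.
#' @param epochs maximum training epochs.
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param val_frac chronological tail fraction of training windows held
#'   out for early stopping.
#' @param patience early-stopping patience, epochs.
#' @param seed integer seed for weight initialization and shuffling.
#' @param insulin_duration_min insulin action-curve duration (p variant).
#' @param cho_speed CHO action-curve speed (p variant).
#' @return a list of class \code{model_config}.
#' @export
model_config <- function(variant = c("np", "p"), ph_min = 30, lookback = 12,
                         hidden = 64, epochs = 30, batch = 256, lr = 5e-3,
                         val_frac = 0.2, patience = 10, seed = 1L,
                         insulin_duration_min = 360, cho_speed = "slow") {
  variant <- match.arg(variant)
  if (lookback < 1) stop("lookback must be >= 1")
  structure(list(variant = variant, ph_min = ph_min, lookback = lookback,
                 hidden = hidden, epochs = epochs, batch = batch, lr = lr,
                 val_frac = val_frac, patience = patience,
                 seed = as.integer(seed),
                 insulin_duration_min = insulin_duration_min,
                 cho_speed = cho_speed),
            class = "model_config")
}

.model_curves <- function(config, step_min) {
  if (config$variant != "p") return(NULL)
  list(insulin = insulin_action_curve(config$insulin_duration_min, step_min),
       cho = cho_action_curve(config$cho_speed, step_min))
}

# feature matrix (n x 3): cgm plus raw or on-board insulin/cho channels
.series_features <- function(s, config, curves) {
  if (config$variant == "p") {
    cbind(cgm = s$cgm, insulin = iob(s, curves$insulin),
          cho = cob(s, curves$cho))
  } else {
    cbind(cgm = s$cgm, insulin = s$insulin, cho = s$cho)
  }
}

# per-channel normalization stats from a training series
.compute_norm <- function(feat) {
  mu <- colMeans(feat, na.rm = TRUE)
  sd <- apply(feat, 2, stats::sd, na.rm = TRUE)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

#' Build windowed training/evaluation data
#'
#' One window per admissible anchor \code{t}: the \code{lookback} input
#' samples \code{t-L+1..t} must all carry a CGM reading (windows touching
#' an un-interpolated gap are excluded) and, when a target is required, the
#' CGM at \code{t + PH} must be present.  The target is strictly future and
#' windows are strictly causal.
#'
#' @param s an aligned \code{\link{glucose_series}}.
#' @param config a \code{\link{model_config}}.
#' @param norm optional normalization stats (list \code{mu}, \code{sd});
#'   when given, channels and targets are standardized.
#' @param require_target if \code{TRUE} anchors without an observed target
#'   are dropped (training); if \code{FALSE} all anchors with a complete
#'   input window are kept (real-time forecasting).
#' @return list with \code{x} (array N x 3 x L), \code{y} (targets, or
#'   \code{NULL}), \code{anchors} (1-based sample indices).
#' @export
make_windows <- function(s, config, norm = NULL, require_target = TRUE) {
  L <- config$lookback
  step <- s$grid$step_min
  if (config$ph_min %% step != 0)
    stop("prediction horizon must be a multiple of the grid step")
  hs <- as.integer(config$ph_min / step)
  n <- s$grid$n
  if (n < L + hs) stop("series shorter than lookback + horizon")
  curves <- .model_curves(config, step)
  feat <- .series_features(s, config, curves)

  ok_in <- !is.na(s$cgm)
  # complete input window: rolling all() over the last L samples
  csum <- cumsum(ok_in)
  full_win <- rep(FALSE, n)
  idx <- L:n
  full_win[idx] <- (csum[idx] - c(0, csum)[idx - L + 1]) == L
  anchors <- which(full_win)
  anchors <- anchors[anchors >= L]
  if (require_target) {
    anchors <- anchors[anchors + hs <= n]
    anchors <- anchors[!is.na(s$cgm[anchors + hs])]
  } else {
    anchors <- anchors[anchors <= n]  # forecasts may extend past the series
  }
  N <- length(anchors)
  x <- array(NA_real_, dim = c(N, 3L, L))
  for (l in seq_len(L)) x[, , l] <- feat[anchors - L + l, , drop = FALSE]
  y <- if (require_target) s$cgm[anchors + hs]
  if (!is.null(norm)) {
    for (f in 1:3) x[, f, ] <- (x[, f, ] - norm$mu[f]) / norm$sd[f]
    if (!is.null(y)) y <- (y - norm$mu[1]) / norm$sd[1]
  }
  list(x = x, y = y, anchors = anchors)
}

#' Train a glucose forecaster
#'
#' Minimizes mean squared error on standardized windows with Adam; the
#' chronological tail of the training windows (\code{val_frac}) is held out
#' for early stopping, and the weights with the best held-out loss are
#' kept.  Normalization statistics come from the training series only.
#' With a fixed seed the loss trajectory is reproducible on a fixed
#' numerical backend.
#'
#' @param train_series preprocessed training \code{\link{glucose_series}}
#'   (short gaps interpolated).
#' @param config a \code{\link{model_config}}.
#' @return an object of class \code{trained_predictor}.
#' @export
train_predictor <- function(train_series, config) {
  stopifnot(inherits(config, "model_config"))
  step <- train_series$grid$step_min
  curves <- .model_curves(config, step)
  feat <- .series_features(train_series, config, curves)
  norm <- .compute_norm(feat)
  w <- make_windows(train_series, config, norm = norm, require_target = TRUE)
  N <- dim(w$x)[1]
  if (N < 100) stop("insufficient data: only ", N, " training windows")
  n_val <- max(1L, floor(config$val_frac * N))
  i_tr <- seq_len(N - n_val)
  i_va <- (N - n_val + 1):N

  set.seed(config$seed)
  weights <- .lstm_init_cpp(3L, config$hidden)
  fit <- NULL
  if (config$epochs > 0) {
    res <- .lstm_fit_cpp(weights,
                         w$x[i_tr, , , drop = FALSE], w$y[i_tr],
                         w$x[i_va, , , drop = FALSE], w$y[i_va],
                         config$epochs, config$batch, config$lr,
                         config$patience)
    weights <- res$weights
    fit <- res[c("val_loss", "train_loss", "best_val_loss", "best_epoch")]
  }
  structure(list(config = config, norm = norm, weights = weights,
                 curves = curves, step_min = step, fit = fit),
            class = "trained_predictor")
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf("<trained_predictor> %s-LSTM, PH = %d min, %d units%s\n",
              x$config$variant, x$config$ph_min, x$config$hidden,
              if (is.null(x$fit)) " (untrained)" else
                sprintf(", best val MSE %.4f @ epoch %d",
                        x$fit$best_val_loss, x$fit$best_epoch)))
  invisible(x)
}

.check_variant <- function(m) {
  if (m$config$variant == "p" && is.null(m$curves))
    stop("p-variant predictor is missing its action curves")
  if (m$config$variant == "np" && !is.null(m$curves))
    stop("np-variant predictor unexpectedly stores action curves")
}

# raw (unstandardized) L x 3 feature window ending at anchor t;
# computed on a slice so masked/counterfactual series stay cheap
.window_at <- function(m, s, t) {
  L <- m$config$lookback
  if (t < L || t > s$grid$n) stop("anchor out of range")
  if (any(is.na(s$cgm[(t - L + 1):t]))) return(NULL)  # gap: inadmissible
  if (m$config$variant == "p") {
    K <- length(m$curves$insulin$taps) - 1L
    Kc <- length(m$curves$cho$taps) - 1L
    lo <- max(1L, t - L + 1L - max(K, Kc))
    ins <- s$insulin[lo:t]
    ch <- s$cho[lo:t]
    # pad with the series' basal floor only when the slice starts at the
    # series start (otherwise full history is inside the slice)
    io <- .onboard(ins, m$curves$insulin, s$grid$step_min,
                   warmup = min(s$insulin))
    co <- .onboard(ch, m$curves$cho, s$grid$step_min, warmup = 0)
    rows <- (t - L + 1):t - lo + 1L
    cbind(s$cgm[(t - L + 1):t], io[rows], co[rows])
  } else {
    cbind(s$cgm[(t - L + 1):t], s$insulin[(t - L + 1):t],
          s$cho[(t - L + 1):t])
  }
}

# forward pass over a list of raw L x 3 windows -> mg/dl forecasts
.forward_windows <- function(m, windows) {
  L <- m$config$lookback
  N <- length(windows)
  x <- array(NA_real_, dim = c(N, 3L, L))
  for (i in seq_len(N)) x[i, , ] <- t(windows[[i]])
  for (f in 1:3) x[, f, ] <- (x[, f, ] - m$norm$mu[f]) / m$norm$sd[f]
  out <- as.numeric(.lstm_forward_cpp(m$weights, x))
  unname(m$norm$mu[1]) + unname(m$norm$sd[1]) * out
}

#' Forecast at a single anchor
#'
#' Generic so that test doubles and simple reference models can stand in
#' for a trained LSTM wherever a forecaster is consumed (explanation,
#' bolus suggestion).
#'
#' @param m a forecaster.
#' @param s a \code{\link{glucose_series}}.
#' @param t 1-based anchor sample index.
#' @return forecast of CGM at \code{t + PH}, mg/dl, or \code{NA} if the
#'   anchor's input window is incomplete.
#' @export
predict_anchor <- function(m, s, t) UseMethod("predict_anchor")

#' @export
predict_anchor.trained_predictor <- function(m, s, t) {
  .check_variant(m)
  w <- .window_at(m, s, t)
  if (is.null(w)) return(NA_real_)
  .forward_windows(m, list(w))
}

#' Real-time forecasts over a series
#'
#' Emits one forecast per admissible anchor (complete input window, no
#' un-interpolated CGM gap).  Strictly causal: the forecast at anchor
#' \code{t} uses samples up to \code{t} only, so appending future samples
#' never changes earlier forecasts.  No imputation is applied.
#'
#' @param m a \code{trained_predictor}.
#' @param s an aligned \code{\link{glucose_series}}.
#' @return data.frame with columns \code{anchor} (sample index),
#'   \code{time}, \code{target_time} and \code{yhat} (mg/dl).
#' @export
predict_series <- function(m, s) {
  stopifnot(inherits(m, "trained_predictor"))
  .check_variant(m)
  w <- make_windows(s, m$config, norm = m$norm, require_target = FALSE)
  out <- as.numeric(.lstm_forward_cpp(m$weights, w$x))
  yhat <- unname(m$norm$mu[1]) + unname(m$norm$sd[1]) * out
  times <- grid_times(s)
  data.frame(anchor = w$anchors,
             time = times[w$anchors],
             target_time = times[w$anchors] + 60 * m$config$ph_min,
             yhat = yhat)
}

#' Counterfactual forecast under an extra insulin bolus
#'
#' Returns the forecast at anchor \code{t} after adding \code{extra_bolus}
#' units to the insulin channel in bin \code{t} (as U/step U/min); for the
#' p variant the IOB input is recomputed accordingly (at the anchor itself
#' this raises IOB by exactly the bolus size, since the action curve opens
#' at 1).  The original series is not modified.
#'
#' @param m a forecaster.
#' @param s a \code{\link{glucose_series}}.
#' @param t anchor sample index.
#' @param extra_bolus candidate corrective dose, U (>= 0).
#' @return counterfactual forecast, mg/dl.
#' @export
predict_counterfactual <- function(m, s, t, extra_bolus) {
  UseMethod("predict_counterfactual")
}

#' @export
predict_counterfactual.default <- function(m, s, t, extra_bolus) {
  if (extra_bolus < 0) stop("extra_bolus must be >= 0")
  s2 <- s
  s2$insulin[t] <- s2$insulin[t] + extra_bolus / s$grid$step_min
  predict_anchor(m, s2, t)
}

#' @export
predict_counterfactual.trained_predictor <- function(m, s, t, extra_bolus) {
  if (any(extra_bolus < 0)) stop("extra_bolus must be >= 0")
  .counterfactual_grid(m, s, t, extra_bolus)
}

# vectorized over doses: one batched forward pass
.counterfactual_grid <- function(m, s, t, doses) {
  .check_variant(m)
  base <- .window_at(m, s, t)
  if (is.null(base)) return(rep(NA_real_, length(doses)))
  L <- m$config$lookback
  step <- s$grid$step_min
  windows <- lapply(doses, function(d) {
    w <- base
    # an extra bolus in bin t adds d/step U/min raw, i.e. d units of IOB
    w[L, 2] <- w[L, 2] + if (m$config$variant == "p") d else d / step
    w
  })
  .forward_windows(m, windows)
}

#' Naive persistence forecast
#'
#' The zero-skill reference \eqn{\hat g(t+PH|t) = g(t)}.
#'
#' @inheritParams predict_series
#' @param ph_min prediction horizon, minutes.
#' @return forecast data.frame in the \code{\link{predict_series}} layout.
#' @export
predict_persistence <- function(s, ph_min) {
  anchors <- which(!is.na(s$cgm))
  times <- grid_times(s)
  data.frame(anchor = anchors, time = times[anchors],
             target_time = times[anchors] + 60 * ph_min,
             yhat = s$cgm[anchors])
}

#' Save / load a trained forecaster bundle
#'
#' A bundle is a directory holding the weights in R's standard
#' serialization (\code{weights.rds}) plus a JSON sidecar with the
#' configuration and normalization statistics, so a bundle remains
#' inspectable without loading it.
#'
#' @param m a \code{trained_predictor}.
#' @param dir bundle directory (created if needed).
#' @return \code{dir} (save) or the restored \code{trained_predictor}
#'   (load), invisibly for save.
#' @export
save_predictor <- function(m, dir) {
  stopifnot(inherits(m, "trained_predictor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(m$weights, file.path(dir, "weights.rds"))
  meta <- list(config = unclass(m$config), norm = lapply(m$norm, as.list),
               step_min = m$step_min, fit = m$fit,
               package_version = as.character(utils::packageVersion("glucodss")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$config)
  weights <- readRDS(file.path(dir, "weights.rds"))
  norm <- list(mu = unlist(meta$norm$mu), sd = unlist(meta$norm$sd))
  structure(list(config = cfg, norm = norm, weights = weights,
                 curves = .model_curves(cfg, meta$step_min),
                 step_min = meta$step_min, fit = meta$fit),
            class = "trained_predictor")
}
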