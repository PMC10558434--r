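#' Per-channel background values
#'
#' Background (reference) values used when a channel is masked out of a
#' coalition: the per-channel training-set means, mirroring the use of
#' expectations in the closed-form linear attribution.
#'
#' @param s the training \code{\link{glucose_series}}.
#' @return named list with \code{cgm}, \code{insulin}, \code{cho}.
#' @export
channel_background <- function(s) {
  list(cgm = mean(s$cgm, na.rm = TRUE),
       insulin = mean(s$insulin),
       cho = mean(s$cho))
}

.CHANNELS <- c("cgm", "insulin", "cho")

#' Explain one forecast by channel-level Shapley attribution
#'
#' Treats the three input channels as the players of a coalitional game:
#' the value of coalition \code{S} is the model forecast when every channel
#' not in \code{S} is replaced, across the whole input window, by its
#' background value.  For the p variant the masking is applied to the raw
#' insulin/CHO channels before the IOB/COB filters, so attributions refer
#' to the same physical inputs in both variants.  All 8 coalition values
#' are evaluated and the attribution comes from exact enumeration, so the
#' efficiency identity base + sum(phi) = prediction holds to machine
#' precision.
#'
#' @param m a forecaster (anything with a \code{\link{predict_anchor}}
#'   method).
#' @param s a \code{\link{glucose_series}}.
#' @param t anchor sample index (must be admissible).
#' @param background per-channel background values, as from
#'   \code{\link{channel_background}}.
#' @param lookback input window length; taken from \code{m$config} when
#'   present.
#' @return an object of class \code{explanation}: \code{anchor},
#'   \code{phi} (named mg/dl attributions), \code{base} (forecast with all
#'   channels at background), \code{prediction}, \code{feature_values}
#'   (channel values at the anchor) and \code{window_means} (channel means
#'   over the input window).
#' @export
explain_instance <- function(m, s, t, background, lookback = NULL) {
  for (ch in .CHANNELS)
    if (is.null(background[[ch]]))
      stop("background is missing channel '", ch, "'")
  L <- lookback %||% m$config$lookback
  if (is.null(L)) stop("lookback not given and not available from the model")
  if (t < L || t > s$grid$n) stop("anchor out of range")
  rows <- (t - L + 1):t

  masked_series <- function(mask) {
    s2 <- s
    for (j in 1:3) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) == 0) {
        ch <- .CHANNELS[j]
        s2[[ch]][rows] <- background[[ch]]
      }
    }
    s2$missing_mask <- is.na(s2$cgm)
    s2
  }
  v <- vapply(0:7, function(mask) predict_anchor(m, masked_series(mask), t),
              numeric(1))
  if (anyNA(v)) stop("anchor is inadmissible (incomplete input window)")
  phi <- shapley_exact(coalition_game(3L, v))
  names(phi) <- .CHANNELS
  fv <- c(cgm = s$cgm[t], insulin = s$insulin[t], cho = s$cho[t])
  wm <- c(cgm = mean(s$cgm[rows]), insulin = mean(s$insulin[rows]),
          cho = mean(s$cho[rows]))
  structure(list(anchor = t, phi = phi, base = v[1], prediction = v[8],
                 feature_values = fv, window_means = wm),
            class = "explanation")
}

#' @export
print.explanation <- function(x, ...) {
  cat(sprintf("<explanation> anchor %d: base %.1f + [%s] = %.1f mg/dl\n",
              x$anchor,
              x$base,
              paste(sprintf("%s %+.2f", names(x$phi), x$phi), collapse = ", "),
              x$prediction))
  invisible(x)
}

#' Explain a corpus of anchors
#'
#' @param m a forecaster.
#' @param s a \code{\link{glucose_series}}.
#' @param anchors anchor indices to explain.
#' @param background see \code{\link{explain_instance}}.
#' @return list of \code{explanation} objects.
#' @export
explain_anchors <- function(m, s, anchors, background) {
  lapply(anchors, function(t) explain_instance(m, s, t, background))
}

#' Corpus-level attribution summary
#'
#' Operationalizes the reading of a Shapley summary plot: per channel, the
#' importance (mean absolute attribution), the importance rank, and the
#' sign-consistency -- the Spearman rank correlation between the channel's
#' value over the input window and its attribution across instances.  A
#' positive sign-consistency means high channel values push the forecast
#' up; a physiologically sound glucose model shows negative insulin and
#' positive CHO sign-consistency.  Channels constant across the corpus get
#' an \code{NA} correlation.
#'
#' @param explanations list of \code{\link{explain_instance}} results
#'   (at least 30).
#' @return an object of class \code{shap_summary}: \code{stats} (one row
#'   per channel: importance, rank, sign_consistency, counts of
#'   positive/negative attributions among high-feature-value instances)
#'   and \code{values} (the full per-instance (feature value, phi) table
#'   for plotting).
#' @export
summarize_explanations <- function(explanations) {
  if (length(explanations) < 30)
    stop("need at least 30 explanations for a stable summary")
  phi <- t(vapply(explanations, function(e) e$phi, numeric(3)))
  wm <- t(vapply(explanations, function(e) e$window_means, numeric(3)))
  colnames(phi) <- colnames(wm) <- .CHANNELS
  importance <- colMeans(abs(phi))
  rank <- as.integer(rank(-importance, ties.method = "first"))
  sign_consistency <- vapply(1:3, function(j) {
    if (stats::sd(wm[, j]) < 1e-12 || stats::sd(phi[, j]) < 1e-12)
      return(NA_real_)
    stats::cor(wm[, j], phi[, j], method = "spearman")
  }, numeric(1))
  high <- vapply(1:3, function(j) wm[, j] > stats::median(wm[, j]),
                 logical(nrow(wm)))
  n_pos_high <- vapply(1:3, function(j) sum(phi[high[, j], j] > 0), 0L)
  n_neg_high <- vapply(1:3, function(j) sum(phi[high[, j], j] < 0), 0L)
  stats <- data.frame(channel = .CHANNELS, importance = importance,
                      rank = rank, sign_consistency = sign_consistency,
                      n_pos_high = n_pos_high, n_neg_high = n_neg_high,
                      row.names = NULL)
  values <- do.call(rbind, lapply(explanations, function(e)
    data.frame(anchor = e$anchor, channel = .CHANNELS,
               feature_value = unname(e$window_means),
               anchor_value = unname(e$feature_values),
               phi = unname(e$phi))))
  structure(list(stats = stats, values = values), class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  cat("<shap_summary>\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Export explanations as a flat CSV
#'
#' @param explanations list of explanations.
#' @param path output path.
#' @export
write_explanations_csv <- function(explanations, path) {
  df <- do.call(rbind, lapply(explanations, function(e) {
    data.frame(anchor = e$anchor, base = e$base, prediction = e$prediction,
               cgm_value = e$feature_values["cgm"],
               insulin_value = e$feature_values["insulin"],
               cho_value = e$feature_values["cho"],
               phi_cgm = e$phi["cgm"], phi_insulin = e$phi["insulin"],
               phi_cho = e$phi["cho"], row.names = NULL)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Beeswarm-style summary plot
#'
#' Simple base-graphics rendering of the summary-plot reading: one row per
#' channel (ordered by importance), points at the per-instance attribution,
#' shaded by the feature value (light = low, dark = high).
#'
#' @param x a \code{shap_summary}.
#' @param ... ignored.
#' @export
plot.shap_summary <- function(x, ...) {
  st <- x$stats[order(x$stats$rank, decreasing = TRUE), ]
  vals <- x$values
  plot(NULL, xlim = range(vals$phi), ylim = c(0.5, 3.5), yaxt = "n",
       xlab = "Shapley value (mg/dl)", ylab = "")
  graphics::axis(2, at = 1:3, labels = st$channel, las = 1)
  graphics::abline(v = 0, lty = 2, col = "grey60")
  for (i in 1:3) {
    v <- vals[vals$channel == st$channel[i], ]
    q <- rank(v$feature_value) / nrow(v)
    graphics::points(v$phi, jitter(rep(i, nrow(v)), amount = 0.15),
                     pch = 16, cex = 0.5, col = grDevices::grey(1 - 0.8 * q))
  }
  invisible(x)
}
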