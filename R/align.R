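#' Align raw CGM samples and diary events to a uniform grid
#'
#' Snaps every CGM reading to the nearest grid point (ties resolved towards
#' the earlier point), converts discrete events to per-bin rates -- a bolus
#' of U units becomes U/step U/min in its bin, a meal of G grams becomes
#' G/step g/min -- and fills basal segments bin by bin.  Grid bins with no
#' CGM reading are flagged missing.
#'
#' The grid is anchored so that bin timestamps fall on multiples of
#' \code{step_min} within the hour (e.g. 12:00, 12:05, ...), spanning from
#' the earliest to the latest snapped sample or event.
#'
#' @param events an \code{\link{event_list}}.
#' @param samples data.frame of raw CGM readings with columns \code{time}
#'   (POSIXct) and \code{cgm} (mg/dl).
#' @param step_min grid step in minutes; must divide 60.
#' @return a \code{\link{glucose_series}}.
#' @export
align_to_grid <- function(events, samples, step_min = 5) {
  if ((nrow(samples) %||% 0L) == 0L) stop("no CGM samples to align")
  if (60 %% step_min != 0) stop("'step_min' must divide 60")
  t_cgm <- as.POSIXct(samples$time, tz = "UTC")
  if (anyNA(t_cgm)) stop("raw samples contain invalid timestamps")
  step_s <- 60 * step_min

  snap_idx <- function(t, origin) {
    m <- as.numeric(t - origin, units = "secs") / step_s
    ceiling(m - 0.5)  # ties -> earlier grid point
  }

  all_times <- c(t_cgm, events$meals$time, events$boluses$time,
                 events$basal$start)
  origin0 <- min(all_times)
  # anchor to the clock: round origin down to a step boundary within its day
  day0 <- as.POSIXct(trunc(origin0, units = "days"), tz = "UTC")
  origin <- day0 + step_s * floor(as.numeric(origin0 - day0, units = "secs") / step_s)

  k_cgm <- snap_idx(t_cgm, origin)
  k_all <- c(k_cgm,
             if (nrow(events$meals)) snap_idx(events$meals$time, origin),
             if (nrow(events$boluses)) snap_idx(events$boluses$time, origin))
  k_min <- min(k_all); k_max <- max(k_all)
  n <- k_max - k_min + 1L
  grid <- time_grid(origin + step_s * k_min, step_min, n)

  cgm <- rep(NA_real_, n)
  pos <- k_cgm - k_min + 1L
  # two readings snapping to one bin: keep the nearer in time, warn
  bin_time <- as.numeric(grid$start, units = "secs") + step_s * (pos - 1)
  dist <- abs(as.numeric(t_cgm) - bin_time)
  ord <- order(pos, dist)
  dup <- duplicated(pos[ord])
  if (any(dup))
    warning(sum(dup), " CGM reading(s) discarded: multiple readings snapped",
            " to one grid bin (kept the nearer in time)")
  keep <- ord[!dup]
  cgm[pos[keep]] <- samples$cgm[keep]

  insulin <- numeric(n)
  cho <- numeric(n)
  if (nrow(events$basal)) {
    tmins <- as.numeric(grid_times(grid))
    for (i in seq_len(nrow(events$basal))) {
      inseg <- tmins >= as.numeric(events$basal$start[i]) &
        tmins < as.numeric(events$basal$end[i])
      insulin[inseg] <- events$basal$rate_Umin[i]
    }
  }
  if (nrow(events$boluses)) {
    kb <- snap_idx(events$boluses$time, origin) - k_min + 1L
    for (i in seq_along(kb))
      insulin[kb[i]] <- insulin[kb[i]] + events$boluses$units[i] / step_min
  }
  if (nrow(events$meals)) {
    km <- snap_idx(events$meals$time, origin) - k_min + 1L
    for (i in seq_along(km))
      cho[km[i]] <- cho[km[i]] + events$meals$grams[i] / step_min
  }
  glucose_series(grid, cgm, insulin, cho)
}

#' Linearly interpolate short CGM gaps
#'
#' Gaps strictly shorter than \code{max_gap_min} are filled with a first
#' order polynomial between the flanking readings and unmasked; longer gaps
#' and gaps touching the series boundary are left untouched.  The insulin
#' and CHO channels are never modified.  In the study pipeline this is
#' applied to training data only -- the test set receives no imputation.
#'
#' @param s a \code{\link{glucose_series}}.
#' @param max_gap_min gap-length threshold in minutes (strict inequality);
#'   must be a multiple of the grid step.  On a 5-min grid the default 30
#'   means runs of up to 5 consecutive missing samples are filled.
#' @return a \code{glucose_series} with short gaps filled.
#' @export
interpolate_short_gaps <- function(s, max_gap_min = 30) {
  stopifnot(inherits(s, "glucose_series"))
  step <- s$grid$step_min
  if (max_gap_min %% step != 0)
    stop("'max_gap_min' must be a multiple of the grid step")
  miss <- s$missing_mask
  if (!any(miss)) return(s)
  cgm <- s$cgm
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    len <- r$lengths[i]
    if (len * step >= max_gap_min) next
    lo <- starts[i] - 1L
    hi <- ends[i] + 1L
    if (lo < 1L || hi > length(cgm)) next  # boundary gap: no flank
    w <- seq_len(len) / (len + 1)
    cgm[starts[i]:ends[i]] <- (1 - w) * cgm[lo] + w * cgm[hi]
  }
  glucose_series(s$grid, cgm, s$insulin, s$cho)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
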