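#' Write a gridded series (and optionally its events) to CSV
#'
#' Canonical schema: columns \code{timestamp,cgm_mgdl,insulin_Umin,cho_gmin}
#' with ISO-8601 timestamps and an empty \code{cgm_mgdl} field for missing
#' readings.  Values survive a write/read round trip to better than 1e-9.
#' Events, when given, go to a sidecar CSV with columns
#' \code{type,time,amount,announced} (\code{type} one of meal/bolus/basal;
#' basal rows use \code{time} for segment start, \code{announced} stores the
#' segment end).
#'
#' @param s a \code{\link{glucose_series}}.
#' @param path output CSV path.
#' @param events optional \code{\link{event_list}}.
#' @param events_path sidecar path; default replaces \code{.csv} with
#'   \code{_events.csv}.
#' @return \code{path}, invisibly.
#' @export
write_series_csv <- function(s, path, events = NULL, events_path = NULL) {
  stopifnot(inherits(s, "glucose_series"))
  df <- data.frame(
    timestamp = format(grid_times(s), "%Y-%m-%dT%H:%M:%S"),
    cgm_mgdl = ifelse(is.na(s$cgm), "", sprintf("%.12g", s$cgm)),
    insulin_Umin = sprintf("%.12g", s$insulin),
    cho_gmin = sprintf("%.12g", s$cho))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(events)) {
    if (is.null(events_path)) events_path <- sub("\\.csv$", "_events.csv", path)
    fmt <- "%Y-%m-%dT%H:%M:%S"
    ev <- rbind(
      if (nrow(events$meals)) data.frame(
        type = "meal", time = format(events$meals$time, fmt),
        amount = events$meals$grams,
        announced = as.character(events$meals$announced)),
      if (nrow(events$boluses)) data.frame(
        type = "bolus", time = format(events$boluses$time, fmt),
        amount = events$boluses$units, announced = ""),
      if (nrow(events$basal)) data.frame(
        type = "basal", time = format(events$basal$start, fmt),
        amount = events$basal$rate_Umin,
        announced = format(events$basal$end, fmt)))
    utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a canonical series CSV (and optional events sidecar)
#'
#' @param path CSV written by \code{\link{write_series_csv}} (or following
#'   the same schema).
#' @param events_path optional sidecar path; if \code{NULL} the default
#'   sidecar name is probed and read when present.
#' @return a list with elements \code{series} (\code{glucose_series}) and
#'   \code{events} (\code{event_list} or \code{NULL}).
#' @export
read_series_csv <- function(path, events_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  wanted <- c("timestamp", "cgm_mgdl", "insulin_Umin", "cho_gmin")
  extra <- setdiff(names(df), wanted)
  if (length(extra))
    stop("unknown columns in ", path, ": ", paste(extra, collapse = ", "))
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in ", path)
  d <- diff(as.numeric(ts))
  if (nrow(df) > 1) {
    if (any(d <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-6) stop("timestamps must be uniformly spaced")
  }
  step_min <- if (nrow(df) > 1) d[1] / 60 else 5
  cgm <- suppressWarnings(as.numeric(df$cgm_mgdl))
  cgm[df$cgm_mgdl == ""] <- NA_real_
  s <- glucose_series(time_grid(ts[1], step_min, nrow(df)), cgm,
                      as.numeric(df$insulin_Umin), as.numeric(df$cho_gmin))
  if (is.null(events_path)) {
    probe <- sub("\\.csv$", "_events.csv", path)
    if (file.exists(probe)) events_path <- probe
  }
  ev <- NULL
  if (!is.null(events_path)) {
    e <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                         colClasses = "character")
    fmt <- "%Y-%m-%dT%H:%M:%S"
    pt <- function(x) as.POSIXct(x, format = fmt, tz = "UTC")
    m <- e[e$type == "meal", , drop = FALSE]
    b <- e[e$type == "bolus", , drop = FALSE]
    ba <- e[e$type == "basal", , drop = FALSE]
    ev <- event_list(
      meals = if (nrow(m)) data.frame(time = pt(m$time),
                                      grams = as.numeric(m$amount),
                                      announced = as.logical(m$announced)),
      boluses = if (nrow(b)) data.frame(time = pt(b$time),
                                        units = as.numeric(b$amount)),
      basal = if (nrow(ba)) data.frame(start = pt(ba$time),
                                       end = pt(ba$announced),
                                       rate_Umin = as.numeric(ba$amount)))
  }
  list(series = s, events = ev)
}

#' Read an OhioT1DM-style XML file
#'
#' Adapter for the XML layout used by the OhioT1DM dataset: a
#' \code{<patient>} element containing \code{<glucose_level>},
#' \code{<basal>}, \code{<bolus>} and \code{<meal>} event collections.
#' Units are converted on read (basal U/hr to U/min) and everything is
#' passed through \code{\link{align_to_grid}}.
#'
#' @param path XML file path.
#' @param step_min grid step for alignment (default 5).
#' @return a list with elements \code{series} and \code{events}.
#' @export
read_ohio_xml <- function(path, step_min = 5) {
  doc <- xml2::read_xml(path)
  ts_fmt <- "%d-%m-%Y %H:%M:%S"
  pt <- function(x) as.POSIXct(x, format = ts_fmt, tz = "UTC")

  gl <- xml2::xml_find_first(doc, ".//glucose_level")
  if (is.na(gl)) stop("missing required element: glucose_level")
  gl_ev <- xml2::xml_find_all(gl, ".//event")
  if (length(gl_ev) == 0) stop("glucose_level element contains no events")
  samples <- data.frame(
    time = pt(xml2::xml_attr(gl_ev, "ts")),
    cgm = as.numeric(xml2::xml_attr(gl_ev, "value")))

  bol <- xml2::xml_find_all(doc, ".//bolus/event")
  boluses <- if (length(bol)) data.frame(
    time = pt(xml2::xml_attr(bol, "ts_begin")),
    units = as.numeric(xml2::xml_attr(bol, "dose")))
  ml <- xml2::xml_find_all(doc, ".//meal/event")
  meals <- if (length(ml)) data.frame(
    time = pt(xml2::xml_attr(ml, "ts")),
    grams = as.numeric(xml2::xml_attr(ml, "carbs")),
    announced = TRUE)
  bas <- xml2::xml_find_all(doc, ".//basal/event")
  basal <- NULL
  if (length(bas)) {
    bt <- pt(xml2::xml_attr(bas, "ts"))
    rate_hr <- as.numeric(xml2::xml_attr(bas, "value"))
    o <- order(bt)
    bt <- bt[o]; rate_hr <- rate_hr[o]
    span_end <- max(c(samples$time, bt)) + 60 * step_min
    basal <- data.frame(start = bt,
                        end = c(bt[-1], span_end),
                        rate_Umin = rate_hr / 60)
  }
  events <- event_list(meals = meals, boluses = boluses, basal = basal)
  list(series = align_to_grid(events, samples, step_min), events = events)
}
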