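#' Uniform time grid
#'
#' A regular sampling grid: sample \code{k} (0-based) lies at
#' \code{start + k * step} minutes.  All series in the package live on such a
#' grid; 5 minutes is the conventional CGM sampling period.
#'
#' @param start grid origin, a \code{POSIXct} timestamp (or anything
#'   coercible via \code{as.POSIXct}).
#' @param step_min sampling period in minutes (> 0).
#' @param n number of samples (>= 1).
#' @return an object of class \code{time_grid}.
#' @export
time_grid <- function(start, step_min = 5, n) {
  start <- as.POSIXct(start, tz = "UTC")
  if (length(start) != 1L || is.na(start)) stop("'start' must be a single timestamp")
  if (!is.numeric(step_min) || step_min <= 0) stop("'step_min' must be > 0")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  structure(list(start = start, step_min = as.numeric(step_min), n = n),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d samples every %g min from %s\n",
              x$n, x$step_min, format(x$start)))
  invisible(x)
}

#' Timestamps of a grid or series
#' @param x a \code{time_grid} or \code{glucose_series}.
#' @return \code{POSIXct} vector of sample times.
#' @export
grid_times <- function(x) {
  g <- if (inherits(x, "glucose_series")) x$grid else x
  g$start + 60 * g$step_min * (seq_len(g$n) - 1)
}

#' Minutes since grid start for each sample
#' @keywords internal
#' @noRd
grid_minutes <- function(x) {
  g <- if (inherits(x, "glucose_series")) x$grid else x
  g$step_min * (seq_len(g$n) - 1)
}

#' Gridded CGM / insulin / CHO series
#'
#' The universal exchange object: three channels on a shared uniform grid.
#' \code{cgm} is in mg/dl with \code{NA} marking missing sensor readings;
#' \code{insulin} is the delivery rate in U/min (basal rate plus boluses
#' spread over their delivery bin); \code{cho} is carbohydrate intake in
#' g/min (meals spread over one bin).
#'
#' @param grid a \code{\link{time_grid}}.
#' @param cgm numeric vector, mg/dl, \code{NA} = missing.
#' @param insulin numeric vector, U/min, no missing values allowed.
#' @param cho numeric vector, g/min, no missing values allowed.
#' @return an object of class \code{glucose_series} with fields \code{grid},
#'   \code{cgm}, \code{insulin}, \code{cho} and \code{missing_mask}.
#' @export
glucose_series <- function(grid, cgm, insulin, cho) {
  stopifnot(inherits(grid, "time_grid"))
  n <- grid$n
  if (length(cgm) != n || length(insulin) != n || length(cho) != n)
    stop("all channels must have the grid's length (", n, ")")
  if (anyNA(insulin) || anyNA(cho))
    stop("insulin and cho channels must not contain missing values")
  if (any(insulin < 0)) stop("insulin must be >= 0 everywhere")
  if (any(cho < 0)) stop("cho must be >= 0 everywhere")
  if (any(!is.na(cgm) & cgm <= 0)) stop("cgm must be > 0 wherever present")
  structure(list(grid = grid, cgm = as.numeric(cgm),
                 insulin = as.numeric(insulin), cho = as.numeric(cho),
                 missing_mask = is.na(cgm)),
            class = "glucose_series")
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf(
    "<glucose_series> %d samples @ %g min from %s (%.1f%% CGM missing)\n",
    x$grid$n, x$grid$step_min, format(x$grid$start),
    100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
length.glucose_series <- function(x) x$grid$n

#' Extract a contiguous slice of a series
#'
#' @param s a \code{glucose_series}.
#' @param from,to 1-based sample indices (inclusive).
#' @return a \code{glucose_series} on the sliced grid.
#' @export
series_slice <- function(s, from, to) {
  stopifnot(inherits(s, "glucose_series"))
  if (from < 1 || to > s$grid$n || from > to) stop("invalid slice bounds")
  idx <- from:to
  g <- time_grid(s$grid$start + 60 * s$grid$step_min * (from - 1),
                 s$grid$step_min, length(idx))
  glucose_series(g, s$cgm[idx], s$insulin[idx], s$cho[idx])
}

#' Diary events: meals, boluses and basal segments
#'
#' Raw therapy events before gridding.  Meals carry grams and an
#' \code{announced} flag (only announced meals are visible to forecasters
#' and to postprandial window selection); boluses carry units; basal
#' segments carry a delivery rate in U/min over a half-open interval
#' \code{[start, end)}.
#'
#' @param meals data.frame with columns \code{time} (POSIXct), \code{grams}
#'   (> 0) and optionally \code{announced} (logical, default \code{TRUE}).
#' @param boluses data.frame with columns \code{time}, \code{units} (>= 0).
#' @param basal data.frame with columns \code{start}, \code{end},
#'   \code{rate_Umin}.
#' @return an object of class \code{event_list}.
#' @export
event_list <- function(meals = NULL, boluses = NULL, basal = NULL) {
  empty_meals <- data.frame(time = as.POSIXct(character(), tz = "UTC"),
                            grams = numeric(), announced = logical())
  empty_bol <- data.frame(time = as.POSIXct(character(), tz = "UTC"),
                          units = numeric())
  empty_bas <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          rate_Umin = numeric())
  if (is.null(meals)) meals <- empty_meals
  if (is.null(boluses)) boluses <- empty_bol
  if (is.null(basal)) basal <- empty_bas
  if (nrow(meals) && is.null(meals$announced)) meals$announced <- TRUE
  meals$time <- as.POSIXct(meals$time, tz = "UTC")
  boluses$time <- as.POSIXct(boluses$time, tz = "UTC")
  if (nrow(basal)) {
    basal$start <- as.POSIXct(basal$start, tz = "UTC")
    basal$end <- as.POSIXct(basal$end, tz = "UTC")
  }
  if (nrow(meals) && any(meals$grams <= 0)) stop("meal grams must be > 0")
  if (nrow(boluses) && any(boluses$units < 0)) stop("bolus units must be >= 0")
  structure(list(meals = meals, boluses = boluses, basal = basal),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d meals, %d boluses, %d basal segments\n",
              nrow(x$meals), nrow(x$boluses), nrow(x$basal)))
  invisible(x)
}

#' Chronological train/test split
#'
#' @param train,test \code{glucose_series}; \code{train} must precede
#'   \code{test} with no temporal overlap.
#' @return an object of class \code{data_split}.
#' @export
data_split <- function(train, test) {
  stopifnot(inherits(train, "glucose_series"), inherits(test, "glucose_series"))
  train_end <- train$grid$start + 60 * train$grid$step_min * train$grid$n
  if (as.numeric(test$grid$start) < as.numeric(train_end) - 1e-6)
    stop("train must precede test with no overlap")
  structure(list(train = train, test = test), class = "data_split")
}
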