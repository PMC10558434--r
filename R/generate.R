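#' Configuration for the synthetic corpus generator
#'
#' Defaults encode the statistical structure of a compliant, sensor-wearing
#' adult with type 1 diabetes whose prandial dosing is suboptimal: three
#' announced meals per day, boluses nearly proportional to announced
#' carbohydrates (the meal/bolus collinearity that confounds learning),
#' systematic under-bolusing producing prolonged postprandial
#' hyperglycemia, iid CGM sensor noise, and short sensor dropouts.
#'
#' @param days total monitoring days.
#' @param split_days days assigned to the training split (the remainder is
#'   the chronologically later test split).
#' @param params \code{\link{minimal_model_params}} of the virtual patient.
#' @param basal_Umin basal insulin rate, U/min.
#' @param meal_times_min clock times of breakfast/lunch/dinner, minutes
#'   after midnight.
#' @param meal_jitter_sd meal-time jitter, minutes.
#' @param cho_range meal size range, grams (uniform draw).
#' @param carb_ratio carbohydrate-to-insulin ratio CR, g/U: the nominal
#'   prandial bolus is grams/CR.
#' @param bolus_error_sd relative dosing noise: each bolus is
#'   \code{(grams/CR) * (1 + e) * under_bolus} with \code{e ~ N(0, sd)},
#'   floored at zero.  Small values give near-perfect collinearity.
#' @param under_bolus under-bolusing factor in (0, 1]; values below 1 model
#'   systematically insufficient prandial doses.
#' @param miss_bolus_prob probability a meal is severely under-dosed (the
#'   patient delivers only \code{miss_bolus_factor} of the nominal dose --
#'   carb-counting failures and forgotten extended boluses; these meals
#'   produce the prolonged hyperglycemic excursions the decision-support
#'   evaluation replays).
#' @param miss_bolus_factor fraction of the nominal dose delivered at a
#'   severely under-dosed meal.
#' @param correction_prob probability the patient later self-corrects a
#'   severely under-dosed meal with a non-prandial bolus (roughly the
#'   missing insulin), 2.5-4 h after the meal.  Such corrective boluses are
#'   routine self-management; they also decouple insulin from carbohydrate
#'   timing in the training data.
#' @param announce_prob probability a meal is announced.
#' @param cgm_noise_sd CGM noise, mg/dl.
#' @param gaps_per_day expected number of sensor dropouts per day.
#' @param gap_len_range short-dropout length range, minutes.
#' @param long_gap_prob probability a dropout is long (not interpolatable).
#' @param long_gap_range long-dropout length range, minutes.
#' @return a list of class \code{corpus_config}.
#' @export
corpus_config <- function(days = 31, split_days = 21,
                          params = minimal_model_params(),
                          basal_Umin = 0.012,
                          meal_times_min = c(450, 750, 1140),
                          meal_jitter_sd = 20,
                          cho_range = c(40, 90),
                          carb_ratio = 12,
                          bolus_error_sd = 0.05,
                          under_bolus = 0.85,
                          miss_bolus_prob = 0.35,
                          miss_bolus_factor = 0.35,
                          correction_prob = 0.5,
                          announce_prob = 1,
                          cgm_noise_sd = 5,
                          gaps_per_day = 1,
                          gap_len_range = c(10, 25),
                          long_gap_prob = 0.15,
                          long_gap_range = c(35, 60)) {
  if (carb_ratio <= 0) stop("carb_ratio must be > 0")
  if (under_bolus <= 0 || under_bolus > 1) stop("under_bolus must be in (0, 1]")
  structure(as.list(environment()), class = "corpus_config")
}

#' Draw a randomized meal/bolus scenario from a corpus configuration
#'
#' Meal times are jittered around the configured breakfast/lunch/dinner
#' clock times, meal sizes are uniform in \code{cho_range}, and each bolus
#' is proportional to the announced grams through the carb ratio, perturbed
#' by the relative dosing noise and scaled by the under-bolusing factor.
#' Boluses are delivered in the meal's grid bin.  A fixed seed yields an
#' identical scenario on repeat.
#'
#' @param config a \code{\link{corpus_config}}.
#' @param seed integer seed.
#' @return a \code{\link{scenario}} spanning \code{config$days} days.
#' @export
generate_scenario <- function(config, seed = 1L) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(seed)
  dur <- config$days * 1440
  meals <- NULL
  boluses <- NULL
  for (d in seq_len(config$days) - 1L) {
    tt <- sort(d * 1440 + config$meal_times_min +
                 stats::rnorm(length(config$meal_times_min), 0,
                              config$meal_jitter_sd))
    tt <- pmin(pmax(tt, d * 1440), (d + 1) * 1440 - 5)
    grams <- round(stats::runif(length(tt), config$cho_range[1],
                                config$cho_range[2]))
    eps <- stats::rnorm(length(tt), 0, config$bolus_error_sd)
    nominal <- grams / config$carb_ratio * (1 + eps)
    units <- pmax(0, nominal * config$under_bolus)
    missed <- stats::runif(length(tt)) < config$miss_bolus_prob
    units[missed] <- units[missed] * config$miss_bolus_factor
    announced <- stats::runif(length(tt)) < config$announce_prob
    meals <- rbind(meals, data.frame(time_min = tt, grams = grams,
                                     announced = announced))
    keep <- units > 0
    boluses <- rbind(boluses, data.frame(time_min = tt[keep],
                                         units = units[keep]))
    # delayed self-corrections of severely under-dosed meals
    correct <- missed & stats::runif(length(tt)) < config$correction_prob
    if (any(correct)) {
      deficit <- pmax(0, nominal[correct] - units[correct])
      ct <- tt[correct] + stats::runif(sum(correct), 150, 240)
      cu <- deficit * stats::runif(sum(correct), 0.6, 1.0)
      ok <- ct < (d + 1) * 1440 & cu > 0.1
      if (any(ok))
        boluses <- rbind(boluses, data.frame(time_min = ct[ok],
                                             units = cu[ok]))
    }
  }
  gaps <- NULL
  n_gaps <- stats::rpois(config$days, config$gaps_per_day)
  for (d in seq_len(config$days) - 1L) {
    if (n_gaps[d + 1] == 0) next
    g0 <- sort(stats::runif(n_gaps[d + 1], d * 1440, (d + 1) * 1440 - 60))
    long <- stats::runif(n_gaps[d + 1]) < config$long_gap_prob
    len <- ifelse(long,
                  stats::runif(n_gaps[d + 1], config$long_gap_range[1],
                               config$long_gap_range[2]),
                  stats::runif(n_gaps[d + 1], config$gap_len_range[1],
                               config$gap_len_range[2]))
    gaps <- rbind(gaps, data.frame(start_min = g0, length_min = len))
  }
  scenario(duration_min = dur, basal_Umin = config$basal_Umin, meals = meals,
           boluses = boluses, cgm_noise_sd = config$cgm_noise_sd,
           gap_spec = gaps, seed = seed)
}

#' Events of a scenario as an absolute-time event list
#'
#' @param sc a \code{\link{scenario}}.
#' @param start the grid origin the scenario was simulated at.
#' @return an \code{\link{event_list}}.
#' @export
scenario_events <- function(sc, start = as.POSIXct("2023-01-01 00:00:00", tz = "UTC")) {
  event_list(
    meals = if (nrow(sc$meals)) data.frame(
      time = start + 60 * sc$meals$time_min,
      grams = sc$meals$grams,
      announced = sc$meals$announced),
    boluses = if (nrow(sc$boluses)) data.frame(
      time = start + 60 * sc$boluses$time_min,
      units = sc$boluses$units),
    basal = data.frame(start = start, end = start + 60 * sc$duration_min,
                       rate_Umin = sc$basal_Umin))
}

#' Generate a synthetic training/test corpus
#'
#' Runs one continuous simulation of \code{config$days} days and splits it
#' chronologically at \code{config$split_days}.  Short CGM gaps in the
#' training split are linearly interpolated (see
#' \code{\link{interpolate_short_gaps}}); the test split is left untouched,
#' mirroring the convention that no imputation is performed on evaluation
#' data.
#'
#' @param config a \code{\link{corpus_config}}.
#' @param seed integer seed.
#' @return a list of class \code{glucose_corpus}: \code{train} and
#'   \code{test} (\code{glucose_series}), \code{events}
#'   (\code{event_list}), \code{scenario}, \code{params},
#'   \code{true_glucose} and the split sample index \code{split_at}.
#' @export
make_training_corpus <- function(config, seed = 1L) {
  stopifnot(inherits(config, "corpus_config"))
  if (config$split_days >= config$days)
    stop("split_days must be smaller than days")
  sc <- generate_scenario(config, seed)
  sim <- simulate_scenario(config$params, sc)
  step <- sim$series$grid$step_min
  split_at <- as.integer(config$split_days * 1440 / step)
  train <- interpolate_short_gaps(series_slice(sim$series, 1, split_at))
  test <- series_slice(sim$series, split_at + 1, sim$series$grid$n)
  structure(list(train = train, test = test,
                 events = scenario_events(sc, sim$series$grid$start),
                 scenario = sc, params = config$params, config = config,
                 true_glucose = sim$true_glucose, split_at = split_at),
            class = "glucose_corpus")
}
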