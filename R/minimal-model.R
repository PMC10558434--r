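#' Minimal-model parameters
#'
#' Parameters of the glucose-insulin minimal model extended with
#' two-compartment subcutaneous insulin kinetics and a three-compartment
#' oral glucose absorption chain.  Defaults are population values for an
#' adult with type 1 diabetes; every rate is per minute.
#'
#' Model equations (states G, X, Isc1, Isc2, Ip, Qsto1, Qsto2, Qgut):
#' \deqn{dG/dt = -(SG + X) G + SG Gb + Ra / (VG BW)}
#' \deqn{dX/dt = -p2 [X - SI (Ip - Ipb)]}
#' \deqn{dIsc1/dt = -kd Isc1 + u(t) / (VI BW)}
#' \deqn{dIsc2/dt = kd Isc1 - ka2 Isc2, \quad dIp/dt = ka2 Isc2 - ke Ip}
#' \deqn{dQsto1/dt = -kgri Qsto1 + CHO(t)}
#' \deqn{dQsto2/dt = kgri Qsto1 - kempt Qsto2, \quad dQgut/dt = kempt Qsto2 - kabs Qgut}
#' with glucose rate of appearance \eqn{Ra = fabs \cdot kabs \cdot Qgut}.
#'
#' @param SG glucose effectiveness, 1/min.
#' @param SI insulin sensitivity, ml/uU/min.
#' @param p2 insulin-action rate constant, 1/min.
#' @param Gb basal glucose, mg/dl (70-300).
#' @param VG glucose distribution volume, dl/kg.
#' @param kd,ka2,ke subcutaneous-to-plasma insulin rate constants, 1/min.
#' @param VI insulin distribution volume, l/kg.
#' @param kgri,kempt,kabs gastric grinding, gastric emptying and intestinal
#'   absorption rate constants, 1/min.
#' @param fabs carbohydrate bioavailability, dimensionless in (0, 1].
#' @param BW body weight, kg.
#' @return an object of class \code{mm_params} (named numeric vector).
#' @export
minimal_model_params <- function(SG = 0.008, SI = 8e-4, p2 = 0.02, Gb = 120,
                                 VG = 1.45, kd = 0.035, ka2 = 0.025,
                                 ke = 0.127, VI = 0.126, kgri = 0.18,
                                 kempt = 0.18, kabs = 0.012, fabs = 0.9,
                                 BW = 70) {
  p <- c(SG = SG, SI = SI, p2 = p2, Gb = Gb, VG = VG, kd = kd, ka2 = ka2,
         ke = ke, VI = VI, kgri = kgri, kempt = kempt, kabs = kabs,
         fabs = fabs, BW = BW)
  rates <- c("SG", "SI", "p2", "kd", "ka2", "ke", "kgri", "kempt", "kabs")
  if (any(p[rates] <= 0)) stop("all rate parameters must be > 0")
  if (fabs <= 0 || fabs > 1) stop("fabs must be in (0, 1]")
  if (Gb < 70 || Gb > 300) stop("Gb must lie in [70, 300] mg/dl")
  if (VG <= 0 || VI <= 0 || BW <= 0) stop("volumes and body weight must be > 0")
  structure(p, class = "mm_params")
}

#' Steady state of the minimal model at a constant basal rate
#'
#' Solves the equilibrium analytically: no meals, constant insulin delivery
#' \code{basal_Umin}, glucose at \code{Gb}, insulin action at zero.
#'
#' @param params \code{\link{minimal_model_params}}.
#' @param basal_Umin basal insulin delivery, U/min.
#' @return named state vector (including the cumulative-absorption
#'   bookkeeping state \code{Aabs}).
#' @export
mm_steady_state <- function(params, basal_Umin) {
  p <- unclass(params)
  uins <- basal_Umin * 1000 / (p["VI"] * p["BW"])  # uU/ml/min
  isc1 <- uins / p["kd"]
  isc2 <- p["kd"] * isc1 / p["ka2"]
  ip <- p["ka2"] * isc2 / p["ke"]
  st <- c(G = p[["Gb"]], X = 0, Isc1 = isc1[[1]], Isc2 = isc2[[1]],
          Ip = ip[[1]], Qsto1 = 0, Qsto2 = 0, Qgut = 0, Aabs = 0)
  st
}

#' Basal plasma insulin implied by a basal delivery rate
#' @keywords internal
#' @noRd
mm_ipb <- function(params, basal_Umin) {
  p <- unclass(params)
  unname(basal_Umin * 1000 / (p["VI"] * p["BW"] * p["ke"]))
}

#' Integrate the minimal model over gridded input channels
#'
#' Low-level driver shared by scenario simulation, identification and
#' replay: integrates from an explicit initial state with per-bin constant
#' insulin (U/min) and CHO (g/min) inputs.
#'
#' @param params \code{\link{minimal_model_params}}.
#' @param y0 initial state, as from \code{\link{mm_steady_state}}.
#' @param insulin,cho per-bin input channels (equal length).
#' @param basal_Umin basal rate defining the insulin-action reference
#'   (plasma insulin at this rate produces zero remote action).
#' @param step_min bin width in minutes.
#' @param rtol,atol integrator tolerances.
#' @return matrix of states at bin boundaries, \code{length(insulin) + 1}
#'   rows; row 1 is \code{y0}.
#' @export
mm_integrate <- function(params, y0, insulin, cho, basal_Umin,
                         step_min = 5, rtol = 1e-6, atol = 1e-8) {
  par <- c(unclass(params), Ipb = mm_ipb(params, basal_Umin))
  out <- .mm_integrate_cpp(par, as.numeric(y0), as.numeric(insulin),
                           as.numeric(cho), step_min, rtol, atol)
  colnames(out) <- c("G", "X", "Isc1", "Isc2", "Ip", "Qsto1", "Qsto2",
                     "Qgut", "Aabs")
  out
}

#' Simulation scenario
#'
#' Encodes one continuous monitoring period: basal delivery, meal and bolus
#' schedules, CGM noise level and sensor dropouts.
#'
#' @param duration_min total duration in minutes.
#' @param basal_Umin basal insulin rate, U/min.
#' @param meals data.frame with \code{time_min}, \code{grams} and optional
#'   \code{announced} (default \code{TRUE}).
#' @param boluses data.frame with \code{time_min}, \code{units}.
#' @param cgm_noise_sd iid Gaussian CGM noise, mg/dl (>= 0).
#' @param gap_spec data.frame with \code{start_min}, \code{length_min}
#'   giving CGM dropout runs.
#' @param seed integer seed driving the CGM noise draw.
#' @return an object of class \code{scenario}.
#' @export
scenario <- function(duration_min, basal_Umin = 0.012, meals = NULL,
                     boluses = NULL, cgm_noise_sd = 0, gap_spec = NULL,
                     seed = 1L) {
  if (is.null(meals)) meals <- data.frame(time_min = numeric(), grams = numeric())
  if (is.null(boluses)) boluses <- data.frame(time_min = numeric(), units = numeric())
  if (is.null(gap_spec)) gap_spec <- data.frame(start_min = numeric(),
                                                length_min = numeric())
  if (nrow(meals) && is.null(meals$announced)) meals$announced <- TRUE
  if (cgm_noise_sd < 0) stop("cgm_noise_sd must be >= 0")
  if (nrow(meals) && any(meals$time_min < 0 | meals$time_min >= duration_min))
    stop("meal times must lie within the scenario duration")
  if (nrow(boluses) && any(boluses$time_min < 0 | boluses$time_min >= duration_min))
    stop("bolus times must lie within the scenario duration")
  structure(list(duration_min = duration_min, basal_Umin = basal_Umin,
                 meals = meals, boluses = boluses,
                 cgm_noise_sd = cgm_noise_sd, gap_spec = gap_spec,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' Build the per-bin input channels of a scenario
#' @keywords internal
#' @noRd
scenario_channels <- function(sc, step_min) {
  n <- ceiling(sc$duration_min / step_min)
  insulin <- rep(sc$basal_Umin, n)
  cho <- numeric(n)
  if (nrow(sc$boluses)) {
    k <- floor(sc$boluses$time_min / step_min) + 1L
    for (i in seq_along(k)) insulin[k[i]] <- insulin[k[i]] + sc$boluses$units[i] / step_min
  }
  if (nrow(sc$meals)) {
    k <- floor(sc$meals$time_min / step_min) + 1L
    for (i in seq_along(k)) cho[k[i]] <- cho[k[i]] + sc$meals$grams[i] / step_min
  }
  list(insulin = insulin, cho = cho, n = n)
}

#' Simulate a scenario on the minimal model
#'
#' Starts at the analytic steady state for the scenario's basal rate,
#' integrates the model over the gridded meal/bolus inputs, then overlays
#' iid Gaussian sensor noise (clipped below at 40 mg/dl, a typical sensor
#' floor) and applies the scheduled CGM dropouts.  With the scenario's seed
#' fixed the result is bit-reproducible.
#'
#' @param params \code{\link{minimal_model_params}}.
#' @param sc a \code{\link{scenario}}.
#' @param step_min grid step in minutes.
#' @param start grid origin timestamp for the emitted series.
#' @param rtol,atol integrator tolerances.
#' @return an object of class \code{simulation_result}: list with
#'   \code{series} (noisy \code{glucose_series}), \code{true_glucose}
#'   (noise-free mg/dl per sample) and \code{states} (full trajectories).
#' @export
simulate_scenario <- function(params, sc, step_min = 5,
                              start = as.POSIXct("2023-01-01 00:00:00", tz = "UTC"),
                              rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(sc, "scenario"))
  ch <- scenario_channels(sc, step_min)
  y0 <- mm_steady_state(params, sc$basal_Umin)
  states <- mm_integrate(params, y0, ch$insulin, ch$cho, sc$basal_Umin,
                         step_min, rtol, atol)
  true_g <- states[seq_len(ch$n), "G"]  # sample k at time (k-1)*step
  if (any(!is.finite(true_g)) || any(true_g <= 0))
    stop("simulation produced non-positive glucose; check parameters")

  cgm <- true_g
  if (sc$cgm_noise_sd > 0) {
    rng_ok <- exists(".Random.seed", envir = globalenv())
    if (rng_ok) old <- get(".Random.seed", envir = globalenv())
    set.seed(sc$seed)
    cgm <- pmax(40, true_g + stats::rnorm(ch$n, 0, sc$cgm_noise_sd))
    if (rng_ok) assign(".Random.seed", old, envir = globalenv())
  }
  tmin <- step_min * (seq_len(ch$n) - 1)
  if (nrow(sc$gap_spec)) {
    for (i in seq_len(nrow(sc$gap_spec))) {
      g0 <- sc$gap_spec$start_min[i]
      cgm[tmin >= g0 & tmin < g0 + sc$gap_spec$length_min[i]] <- NA_real_
    }
  }
  series <- glucose_series(time_grid(start, step_min, ch$n), cgm,
                           ch$insulin, ch$cho)
  structure(list(series = series, true_glucose = true_g, states = states,
                 scenario = sc, params = params),
            class = "simulation_result")
}
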