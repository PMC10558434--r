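#' Select postprandial evaluation windows
#'
#' One candidate window per announced meal, spanning \code{span_min}
#' minutes from the meal.  A window is retained only if (1) no further
#' carbohydrate intake occurs in \code{(start, start + span]} and (2) no
#' corrective (non-prandial) bolus is delivered during the span, where a
#' bolus is prandial if it falls within \code{prandial_tol_min} of a meal.
#' The window must also lie entirely inside the series.
#'
#' @param s the evaluated \code{\link{glucose_series}} (typically the test
#'   split).
#' @param events aligned \code{\link{event_list}}.
#' @param span_min window length, minutes (default 480 = 8 h).
#' @param prandial_tol_min tolerance for classifying a bolus as prandial.
#' @return list of \code{postprandial_window} objects: \code{start_index}
#'   (sample index of the meal bin in \code{s}), \code{meal_time},
#'   \code{meal_grams}, \code{meal_bolus_U}, \code{n_samples} and
#'   \code{series} (the window slice).
#' @export
select_postprandial_windows <- function(s, events, span_min = 480,
                                        prandial_tol_min = 15) {
  step <- s$grid$step_min
  t0 <- as.numeric(s$grid$start)
  meal_min <- (as.numeric(events$meals$time) - t0) / 60
  bolus_min <- (as.numeric(events$boluses$time) - t0) / 60
  span_samples <- as.integer(span_min / step)
  out <- list()
  for (i in seq_len(nrow(events$meals))) {
    if (!events$meals$announced[i]) next
    m0 <- meal_min[i]
    k0 <- floor(m0 / step) + 1L
    if (k0 < 1 || k0 + span_samples - 1L > s$grid$n) next
    later_cho <- any(meal_min > m0 & meal_min <= m0 + span_min)
    if (later_cho) next
    in_span <- bolus_min >= m0 & bolus_min <= m0 + span_min
    prandial <- vapply(bolus_min, function(b)
      any(abs(b - meal_min) <= prandial_tol_min), logical(1))
    if (any(in_span & !prandial)) next
    meal_bolus <- sum(events$boluses$units[in_span & prandial])
    out[[length(out) + 1]] <- structure(
      list(start_index = k0,
           meal_time = events$meals$time[i],
           meal_grams = events$meals$grams[i],
           meal_bolus_U = meal_bolus,
           n_samples = span_samples,
           series = series_slice(s, k0, k0 + span_samples - 1L)),
      class = "postprandial_window")
  }
  out
}

#' @export
print.postprandial_window <- function(x, ...) {
  cat(sprintf("<postprandial_window> %s: %g g meal, %.2f U bolus, %d samples\n",
              format(x$meal_time), x$meal_grams, x$meal_bolus_U, x$n_samples))
  invisible(x)
}

#' Identification priors
#'
#' Independent log-normal priors on the free parameter subset
#' \code{SI, SG, p2, kabs, kempt}, centered at population values; the
#' remaining parameters stay fixed at \code{params}.
#'
#' @param params population \code{\link{minimal_model_params}} supplying
#'   prior centers and the fixed parameters.
#' @param sdlog named log-scale prior standard deviations.
#' @param noise_sd assumed CGM measurement noise, mg/dl (Gaussian
#'   likelihood scale).
#' @return list of class \code{identification_priors}.
#' @export
identification_priors <- function(params = minimal_model_params(),
                                  sdlog = c(SI = 0.5, SG = 0.3, p2 = 0.3,
                                            kabs = 0.3, kempt = 0.3),
                                  noise_sd = 5) {
  free <- c("SI", "SG", "p2", "kabs", "kempt")
  if (!all(free %in% names(sdlog))) stop("sdlog must name all free parameters")
  structure(list(params = params, free = free, sdlog = sdlog[free],
                 noise_sd = noise_sd),
            class = "identification_priors")
}

#' MAP identification of the minimal model on one postprandial window
#'
#' Maximum-a-posteriori estimation of \code{SI, SG, p2, kabs, kempt} from
#' the window's CGM trace under a Gaussian likelihood and the log-normal
#' priors, by multi-start quasi-Newton optimization in log-parameter space
#' (best of \code{n_starts} jittered starts).  The model is initialized at
#' the steady state implied by the window's basal rate, with basal glucose
#' pinned to the first CGM reading.
#'
#' @param window a \code{postprandial_window} (or bare
#'   \code{glucose_series} covering the window).
#' @param priors \code{\link{identification_priors}}.
#' @param seed integer seed (start jitter).
#' @param n_starts number of optimization starts.
#' @return object of class \code{identified_model}: \code{params}
#'   (posterior-mode \code{mm_params}), \code{fit_rmse} (CGM RMSE of the
#'   fitted trajectory), \code{basal_Umin}, \code{Gb}, \code{priors},
#'   \code{converged}.
#' @export
identify_model <- function(window, priors = identification_priors(),
                           seed = 1L, n_starts = 4L) {
  s <- if (inherits(window, "postprandial_window")) window$series else window
  step <- s$grid$step_min
  obs <- s$cgm
  if (mean(is.na(obs)) >= 0.2)
    stop("window has >= 20% missing CGM; identification refused")
  basal <- min(s$insulin)  # basal rate = floor of the delivery channel
  Gb <- obs[which(!is.na(obs))[1]]
  Gb <- min(max(Gb, 70), 300)
  pop <- unclass(priors$params)
  free <- priors$free
  mu_log <- log(pop[free])
  sdlog <- priors$sdlog
  ok <- !is.na(obs)

  objective <- function(theta_log) {
    p <- pop
    p[free] <- exp(theta_log)
    p["Gb"] <- Gb
    pars <- do.call(minimal_model_params, as.list(p))
    y0 <- mm_steady_state(pars, basal)
    g <- tryCatch(
      mm_integrate(pars, y0, s$insulin, s$cho, basal, step)[seq_len(s$grid$n), "G"],
      error = function(e) NULL)
    if (is.null(g) || any(!is.finite(g))) return(1e12)
    sum((obs[ok] - g[ok])^2) / (2 * priors$noise_sd^2) +
      sum((theta_log - mu_log)^2 / (2 * sdlog^2))
  }

  set.seed(seed)
  starts <- rbind(mu_log,
                  matrix(rep(mu_log, n_starts - 1), ncol = length(free),
                         byrow = TRUE) +
                    matrix(stats::rnorm((n_starts - 1) * length(free), 0,
                                        sdlog), ncol = length(free),
                           byrow = TRUE))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                   lower = mu_log - 3 * sdlog, upper = mu_log + 3 * sdlog,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("identification failed: no optimization start converged")

  p <- pop
  p[free] <- exp(best$par)
  p["Gb"] <- Gb
  pars <- do.call(minimal_model_params, as.list(p))
  y0 <- mm_steady_state(pars, basal)
  g <- mm_integrate(pars, y0, s$insulin, s$cho, basal, step)[seq_len(s$grid$n), "G"]
  structure(list(params = pars, fit_rmse = sqrt(mean((obs[ok] - g[ok])^2)),
                 basal_Umin = basal, Gb = Gb, priors = priors,
                 converged = best$convergence == 0),
            class = "identified_model")
}

#' @export
print.identified_model <- function(x, ...) {
  cat(sprintf("<identified_model> SI=%.2e SG=%.3g p2=%.3g kabs=%.3g kempt=%.3g (fit RMSE %.1f mg/dl)\n",
              x$params["SI"], x$params["SG"], x$params["p2"],
              x$params["kabs"], x$params["kempt"], x$fit_rmse))
  invisible(x)
}

#' Corrective-bolus policy configuration
#'
#' @param g0 target glucose, mg/dl.
#' @param trigger_threshold suggestion threshold: a bolus is only
#'   considered while current CGM exceeds this, mg/dl.
#' @param trigger_delay_min quiet period after the meal before the policy
#'   activates, minutes.
#' @param dose_grid candidate doses, U; must contain 0.  The default spans
#'   0-1.5 U in pump-resolution steps of 0.1 U: a titration design --
#'   small single corrections that cannot overshoot even a self-resolving
#'   excursion, re-issued after the lockout while hyperglycemia persists
#'   so the total delivered insulin adapts to excursion severity.  The cap
#'   was fixed by control-design simulation on the population model.
#' @param insulin_penalty weight of the squared-dose penalty in the cost,
#'   (mg/dl)^2 / U^2.
#' @param cadence_min re-evaluation cadence during replay, minutes.
#' @param lockout_min minimum spacing between suggested boluses, minutes.
#' @return list of class \code{cib_config}.
#' @export
cib_config <- function(g0 = 120, trigger_threshold = 180,
                       trigger_delay_min = 120,
                       dose_grid = seq(0, 1.5, by = 0.1),
                       insulin_penalty = 10, cadence_min = 5,
                       lockout_min = 120) {
  if (!any(dose_grid == 0)) stop("dose grid must contain 0")
  if (any(dose_grid < 0) || any(!is.finite(dose_grid)))
    stop("dose grid values must be finite and >= 0")
  if (g0 >= trigger_threshold) stop("g0 must be below the trigger threshold")
  structure(list(g0 = g0, trigger_threshold = trigger_threshold,
                 trigger_delay_min = trigger_delay_min,
                 dose_grid = sort(dose_grid),
                 insulin_penalty = insulin_penalty,
                 cadence_min = cadence_min, lockout_min = lockout_min),
            class = "cib_config")
}

#' Suggest a corrective insulin bolus
#'
#' Implements the quadratic-cost grid search: if the current CGM exceeds
#' the trigger threshold, every candidate dose \eqn{i_n} is scored by
#' \deqn{J(i_n) = (\hat g_n(k+PH|k) - g_0)^2 + 10\, i_n^2}
#' where \eqn{\hat g_n} is the forecaster's counterfactual prediction under
#' the extra dose, and the minimizing dose is suggested.  No suggestion is
#' returned when CGM is at or below threshold, when the anchor is
#' inadmissible (gap), or when the grid minimum is 0 U.
#'
#' @param m a forecaster.
#' @param s series history up to (and including) time \code{k}.
#' @param cfg a \code{\link{cib_config}}.
#' @param k current sample index (the decision anchor).
#' @return \code{NULL}, or a list of class \code{recommendation}:
#'   \code{time_index}, \code{dose_U}, \code{cost_curve} (data.frame dose,
#'   forecast, cost) and \code{forecast} at the chosen dose.
#' @export
suggest_cib <- function(m, s, cfg, k) {
  g_now <- s$cgm[k]
  if (is.na(g_now) || g_now <= cfg$trigger_threshold) return(NULL)
  doses <- cfg$dose_grid
  if (inherits(m, "trained_predictor")) {
    gh <- predict_counterfactual(m, s, k, doses)  # one batched forward pass
  } else {
    gh <- vapply(doses, function(d) predict_counterfactual(m, s, k, d),
                 numeric(1))
  }
  if (anyNA(gh)) return(NULL)
  cost <- (gh - cfg$g0)^2 + cfg$insulin_penalty * doses^2
  j <- which.min(cost)
  if (doses[j] == 0) return(NULL)
  structure(list(time_index = k, dose_U = doses[j],
                 cost_curve = data.frame(dose = doses, forecast = gh,
                                         cost = cost),
                 forecast = gh[j]),
            class = "recommendation")
}

#' Replay a postprandial window under a bolus policy
#'
#' Closed-loop re-simulation on the identified patient model: the original
#' meal and therapy are replayed, and (under a DSS policy) the
#' corrective-bolus algorithm reads the simulated CGM history at every
#' cadence tick after the trigger delay, may add a bolus to the simulation
#' (respecting the lockout), and the trajectory continues from there.  The
#' simulated trace fed to the policy carries no added sensor noise.
#'
#' @param model an \code{\link{identify_model}} result.
#' @param window a \code{postprandial_window}.
#' @param policy \code{"none"} (replay original therapy only) or
#'   \code{"dss"}.
#' @param m forecaster driving the DSS policy (required when
#'   \code{policy = "dss"}).
#' @param cfg a \code{\link{cib_config}} (required for the DSS policy).
#' @return object of class \code{replay_outcome}: \code{glucose} (replayed
#'   trace, mg/dl), \code{ranges} (\code{\link{time_in_ranges}} report),
#'   \code{boluses} (data.frame time_index, dose_U), \code{total_insulin_U}
#'   (correction insulin only) and \code{series} (the replayed series).
#' @export
replay_window <- function(model, window, policy = c("none", "dss"),
                          m = NULL, cfg = NULL) {
  policy <- match.arg(policy)
  s0 <- window$series
  step <- s0$grid$step_min
  n <- s0$grid$n
  pars <- model$params
  basal <- model$basal_Umin
  y0 <- mm_steady_state(pars, basal)
  insulin <- s0$insulin
  cho <- s0$cho

  run <- function(ins) mm_integrate(pars, y0, ins, cho, basal,
                                    step)[seq_len(n), "G"]

  boluses <- data.frame(time_index = integer(), dose_U = numeric())
  if (policy == "dss") {
    if (is.null(m) || is.null(cfg))
      stop("the DSS policy needs a forecaster and a cib_config")
    lookback <- m$config$lookback %||% 12L
    cadence <- as.integer(cfg$cadence_min / step)
    first_k <- as.integer(cfg$trigger_delay_min / step) + 1L
    lock_until <- -Inf
    for (k in seq(first_k, n, by = cadence)) {
      if (k < lookback) next
      if (k <= lock_until) next
      g_sim <- run(insulin)
      s_k <- glucose_series(time_grid(s0$grid$start, step, k),
                            g_sim[seq_len(k)], insulin[seq_len(k)],
                            cho[seq_len(k)])
      rec <- suggest_cib(m, s_k, cfg, k)
      if (!is.null(rec)) {
        insulin[k] <- insulin[k] + rec$dose_U / step
        boluses <- rbind(boluses,
                         data.frame(time_index = k, dose_U = rec$dose_U))
        lock_until <- k + cfg$lockout_min / step
      }
    }
  }
  g <- run(insulin)
  if (any(!is.finite(g))) stop("replay simulation diverged")
  series <- glucose_series(s0$grid, pmax(g, 1e-6), insulin, cho)
  structure(list(glucose = g, ranges = time_in_ranges(g), boluses = boluses,
                 total_insulin_U = sum(boluses$dose_U), series = series,
                 policy = policy),
            class = "replay_outcome")
}

#' @export
print.replay_outcome <- function(x, ...) {
  cat(sprintf("<replay_outcome> %s: TIR %.1f%%, TBR %.1f%%, TAR %.1f%%, %d bolus(es), %.1f U\n",
              x$policy, x$ranges$tir, x$ranges$tbr, x$ranges$tar,
              nrow(x$boluses), x$total_insulin_U))
  invisible(x)
}

#' Evaluate windows under No-DS and DSS policies
#'
#' For every window: identify the patient model, replay without decision
#' support and under each supplied forecaster-driven DSS, and tabulate
#' TBR/TIR/TAR, correction insulin and bolus counts; aggregate across
#' windows as median and quartiles.
#'
#' @param windows list of \code{postprandial_window}s.
#' @param predictors named list of forecasters (e.g.
#'   \code{list("p-LSTM" = m)}); the names label the policies.
#' @param cfg a \code{\link{cib_config}}.
#' @param priors \code{\link{identification_priors}}.
#' @param seed integer seed for identification.
#' @return list of class \code{replay_evaluation}: \code{per_window}
#'   (one row per window x policy) and \code{summary} (median [IQR] per
#'   policy).
#' @export
evaluate_windows <- function(windows, predictors, cfg = cib_config(),
                             priors = identification_priors(), seed = 1L) {
  if (length(windows) < 1) stop("need at least one window")
  rows <- list()
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    idm <- identify_model(w, priors, seed = seed + i)
    base <- replay_window(idm, w, "none")
    rows[[length(rows) + 1]] <- data.frame(
      window = i, policy = "No DS", tbr = base$ranges$tbr,
      tir = base$ranges$tir, tar = base$ranges$tar,
      insulin_U = NA_real_, n_boluses = NA_integer_)
    for (nm in names(predictors)) {
      out <- replay_window(idm, w, "dss", m = predictors[[nm]], cfg = cfg)
      rows[[length(rows) + 1]] <- data.frame(
        window = i, policy = nm, tbr = out$ranges$tbr, tir = out$ranges$tir,
        tar = out$ranges$tar, insulin_U = out$total_insulin_U,
        n_boluses = nrow(out$boluses))
    }
  }
  per_window <- do.call(rbind, rows)
  q <- function(x) if (all(is.na(x))) c(NA, NA, NA) else
    stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  summ <- do.call(rbind, lapply(unique(per_window$policy), function(p) {
    d <- per_window[per_window$policy == p, ]
    f <- function(v) {
      z <- q(v)
      sprintf("%.1f [%.1f-%.1f]", z[1], z[2], z[3])
    }
    data.frame(policy = p, tbr = f(d$tbr), tir = f(d$tir), tar = f(d$tar),
               insulin_U = if (all(is.na(d$insulin_U))) "-" else f(d$insulin_U),
               n_boluses = if (all(is.na(d$n_boluses))) "-" else f(d$n_boluses))
  }))
  structure(list(per_window = per_window, summary = summ),
            class = "replay_evaluation")
}

#' @export
print.replay_evaluation <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
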