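params <- minimal_model_params()

# a self-consistent postprandial window simulated from known parameters
sim_window <- function(grams = 60, bolus = 1.5, noise = 0, seed = 1,
                       extra_bolus_min = NULL, extra_bolus_U = 0,
                       params = minimal_model_params()) {
  b <- data.frame(time_min = 0, units = bolus)
  if (!is.null(extra_bolus_min))
    b <- rbind(b, data.frame(time_min = extra_bolus_min,
                             units = extra_bolus_U))
  sc <- scenario(480, meals = data.frame(time_min = 0, grams = grams),
                 boluses = b[b$units > 0, ], cgm_noise_sd = noise,
                 seed = seed)
  r <- simulate_scenario(params, sc)
  structure(list(start_index = 1L, meal_time = r$series$grid$start,
                 meal_grams = grams, meal_bolus_U = bolus,
                 n_samples = r$series$grid$n, series = r$series),
            class = "postprandial_window")
}

test_that("postprandial window selection applies both exclusion rules", {
  s <- make_series(runif(600, 100, 200))  # 50 h span
  t0 <- s$grid$start
  hours <- function(h) t0 + h * 3600
  events <- event_list(
    meals = data.frame(
      time = c(hours(2), hours(7), hours(26)),
      grams = c(50, 60, 70), announced = TRUE),
    boluses = data.frame(
      time = c(hours(2), hours(7), hours(26)),
      units = c(4, 5, 6)))
  w <- select_postprandial_windows(s, events)
  # meal at 2 h is followed by a meal within 8 h; meals at 7 h and 26 h pass
  expect_length(w, 2)
  expect_equal(vapply(w, `[[`, 0, "meal_grams"), c(60, 70))
  expect_equal(w[[1]]$series$grid$n, 96)

  # a corrective (non-prandial) bolus 3 h after a lone meal rejects it
  events2 <- event_list(
    meals = data.frame(time = hours(7), grams = 60, announced = TRUE),
    boluses = data.frame(time = c(hours(7), hours(10)), units = c(5, 2)))
  expect_length(select_postprandial_windows(s, events2), 0)

  # a lone meal with only its prandial bolus is accepted
  events3 <- event_list(
    meals = data.frame(time = hours(7), grams = 60, announced = TRUE),
    boluses = data.frame(time = hours(7) + 600, units = 5))  # +10 min
  expect_length(select_postprandial_windows(s, events3), 1)

  # unannounced meals produce no windows
  events4 <- event_list(
    meals = data.frame(time = hours(7), grams = 60, announced = FALSE))
  expect_length(select_postprandial_windows(s, events4), 0)
})

test_that("MAP identification recovers parameters from noise-free data", {
  # the virtual patient deviates from the prior centers
  truth <- minimal_model_params(SI = 8e-4 * 1.3, kabs = 0.012 * 0.85)
  w <- sim_window(grams = 70, bolus = 2, params = truth)
  idm <- identify_model(w, identification_priors(params), seed = 5)
  expect_lt(abs(idm$params["SI"] - truth["SI"]) / truth["SI"], 0.10)
  expect_lt(idm$fit_rmse, 2)
})

test_that("identification fits noisy data to about the noise floor", {
  w <- sim_window(grams = 70, bolus = 2, noise = 5, seed = 8)
  idm <- identify_model(w, identification_priors(params), seed = 5)
  expect_lt(idm$fit_rmse, 5 + 2)
  expect_true(idm$converged)
})

test_that("identification refuses windows with too many gaps", {
  w <- sim_window()
  w$series$cgm[1:30] <- NA
  w$series$missing_mask[1:30] <- TRUE
  expect_error(identify_model(w), "missing")
})

test_that("bolus suggestion solves the worked quadratic-cost case", {
  s <- make_series(rep(250, 30))
  stub <- dose_stub(function(i) 250 - 20 * i)
  cfg <- cib_config(dose_grid = seq(0, 10, by = 0.1))
  rec <- suggest_cib(stub, s, cfg, 25)
  expect_equal(rec$dose_U, 6.3)
  # independent brute-force scan of the same grid
  doses <- seq(0, 10, by = 0.1)
  J <- (250 - 20 * doses - 120)^2 + 10 * doses^2
  expect_equal(rec$dose_U, doses[which.min(J)])
  expect_equal(rec$forecast, 250 - 20 * 6.3)
})

test_that("bolus suggestion honors the trigger and zero-dose rules", {
  stub <- dose_stub(function(i) 250 - 20 * i)
  cfg <- cib_config()
  s_low <- make_series(rep(150, 30))
  expect_null(suggest_cib(stub, s_low, cfg, 25))   # below threshold
  s_gap <- make_series(c(rep(250, 24), NA, rep(250, 5)))
  expect_null(suggest_cib(stub, s_gap, cfg, 25))   # anchor in a gap
  rising <- dose_stub(function(i) 200 + 5 * i)     # misattributed insulin
  s_hi <- make_series(rep(250, 30))
  expect_null(suggest_cib(rising, s_hi, cfg, 25))  # argmin at 0 U
})

test_that("suggestion equals an exhaustive scan for random cost shapes", {
  set.seed(64)
  cfg <- cib_config(dose_grid = seq(0, 4, by = 0.1))
  s <- make_series(rep(260, 30))
  for (i in 1:25) {
    a <- runif(1, 150, 320)
    b <- runif(1, -40, 20)
    cvt <- runif(1, -3, 3)
    f <- function(d) a + b * d + cvt * d^2
    rec <- suggest_cib(dose_stub(f), s, cfg, 25)
    J <- (f(cfg$dose_grid) - cfg$g0)^2 +
      cfg$insulin_penalty * cfg$dose_grid^2
    best <- cfg$dose_grid[which.min(J)]
    if (best == 0) expect_null(rec) else expect_equal(rec$dose_U, best)
  }
})

test_that("any non-decreasing dose response yields no suggestion", {
  set.seed(65)
  cfg <- cib_config()
  s <- make_series(rep(300, 30))
  for (i in 1:20) {
    a <- runif(1, 185, 350)
    slope <- runif(1, 0, 30)
    rec <- suggest_cib(dose_stub(function(d) a + slope * d), s, cfg, 25)
    expect_null(rec)
  }
})

test_that("replaying the original therapy reproduces the source trace", {
  w <- sim_window(grams = 60, bolus = 1.5)
  idm <- structure(list(params = params, basal_Umin = 0.012, Gb = 120,
                        fit_rmse = 0, converged = TRUE),
                   class = "identified_model")
  out <- replay_window(idm, w, "none")
  r_true <- simulate_scenario(params, scenario(
    480, meals = data.frame(time_min = 0, grams = 60),
    boluses = data.frame(time_min = 0, units = 1.5)))
  expect_equal(out$glucose, r_true$true_glucose, tolerance = 1e-8)
  expect_equal(nrow(out$boluses), 0)
  expect_equal(out$total_insulin_U, 0)
  # idempotent: replaying again gives the same trace
  expect_equal(replay_window(idm, w, "none")$glucose, out$glucose)
})

test_that("a delivered bolus lowers the replayed trace pointwise", {
  w <- sim_window(grams = 80, bolus = 1)   # under-bolused: stays high
  idm <- structure(list(params = params, basal_Umin = 0.012, Gb = 120,
                        fit_rmse = 0, converged = TRUE),
                   class = "identified_model")
  none <- replay_window(idm, w, "none")
  eager <- dose_stub(function(i) 400 - 30 * i)  # always wants insulin
  cfg <- cib_config()
  dss <- replay_window(idm, w, "dss", m = eager, cfg = cfg)
  expect_gt(nrow(dss$boluses), 0)
  k0 <- min(dss$boluses$time_index)
  expect_true(all(dss$glucose[(k0 + 1):96] <= none$glucose[(k0 + 1):96] + 1e-9))
  expect_true(all(dss$glucose[1:k0] == none$glucose[1:k0]))
  # lockout respected
  if (nrow(dss$boluses) > 1)
    expect_true(all(diff(dss$boluses$time_index) >= cfg$lockout_min / 5))
})

test_that("evaluate_windows tabulates policies and aggregates quartiles", {
  w <- sim_window(grams = 70, bolus = 1, noise = 3, seed = 6)
  stub <- dose_stub(function(i) 260 - 25 * i)
  ev <- evaluate_windows(list(w), list("stub DSS" = stub, "stub DSS 2" = stub),
                         cfg = cib_config(),
                         priors = identification_priors(params), seed = 2)
  pw <- ev$per_window
  expect_equal(nrow(pw), 3)
  nods <- pw[pw$policy == "No DS", ]
  expect_true(is.na(nods$insulin_U))
  a <- pw[pw$policy == "stub DSS", -2]
  b <- pw[pw$policy == "stub DSS 2", -2]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  expect_equal(ev$summary$insulin_U[ev$summary$policy == "No DS"], "-")
  # single window: median equals the window value
  tirs <- sprintf("%.1f", pw$tir[pw$policy == "No DS"])
  expect_match(ev$summary$tir[ev$summary$policy == "No DS"], tirs,
               fixed = TRUE)
  expect_error(evaluate_windows(list(), list(), cib_config()),
               "at least one")
})
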