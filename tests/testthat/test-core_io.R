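test_that("align_to_grid snaps readings and converts events to rates", {
  t0 <- as.POSIXct("2023-03-01 12:00:00", tz = "UTC")
  samples <- data.frame(time = t0 + c(0, 300, 600), cgm = c(100, 110, 120))
  events <- event_list(
    boluses = data.frame(time = t0 + 3 * 60, units = 5),  # 12:03 -> 12:05 bin
    basal = data.frame(start = t0 - 600, end = t0 + 3600, rate_Umin = 0.02))
  s <- align_to_grid(events, samples, step_min = 5)
  expect_equal(s$grid$step_min, 5)
  k <- which(abs(as.numeric(grid_times(s) - (t0 + 300))) < 1)
  expect_equal(s$insulin[k], 0.02 + 5 / 5)  # 5 U over one 5-min bin
  expect_equal(s$insulin[-k], rep(0.02, s$grid$n - 1))
  expect_equal(s$cgm, c(100, 110, 120))
})

test_that("align_to_grid flags unfilled CGM bins as missing", {
  t0 <- as.POSIXct("2023-03-01 12:00:00", tz = "UTC")
  samples <- data.frame(time = t0 + c(0, 600), cgm = c(100, 120))
  s <- align_to_grid(event_list(), samples, step_min = 5)
  expect_equal(s$grid$n, 3L)
  expect_true(s$missing_mask[2])
  expect_false(any(s$missing_mask[c(1, 3)]))
})

test_that("two readings snapping to one bin keep the nearer and warn", {
  t0 <- as.POSIXct("2023-03-01 12:00:00", tz = "UTC")
  samples <- data.frame(time = t0 + c(0, 4 * 60, 6 * 60, 600),
                        cgm = c(100, 104, 106, 120))
  expect_warning(s <- align_to_grid(event_list(), samples, 5), "discarded")
  # 12:04 and 12:06 both snap to 12:05; 12:04 and 12:06 are equidistant
  # from the bin, the first-sorted (12:04) survives the tie
  expect_equal(s$cgm[2], 104)
})

test_that("alignment conserves insulin and carbohydrate totals", {
  set.seed(5)
  t0 <- as.POSIXct("2023-03-01 06:00:00", tz = "UTC")
  samples <- data.frame(time = t0 + seq(0, 86100, by = 300),
                        cgm = runif(288, 80, 250))
  events <- event_list(
    meals = data.frame(time = t0 + sort(runif(4, 3600, 80000)),
                       grams = runif(4, 30, 90), announced = TRUE),
    boluses = data.frame(time = t0 + sort(runif(5, 3600, 80000)),
                         units = runif(5, 1, 8)),
    basal = data.frame(start = t0, end = t0 + 86400, rate_Umin = 0.015))
  s <- align_to_grid(events, samples, 5)
  basal_total <- 0.015 * 5 * s$grid$n  # basal fills every bin here
  expect_equal(sum(s$insulin) * 5, sum(events$boluses$units) + basal_total,
               tolerance = 1e-9)
  expect_equal(sum(s$cho) * 5, sum(events$meals$grams), tolerance = 1e-9)
})

test_that("align_to_grid rejects empty input and bad steps", {
  expect_error(align_to_grid(event_list(), data.frame()), "no CGM samples")
  t0 <- as.POSIXct("2023-03-01 12:00:00", tz = "UTC")
  samples <- data.frame(time = t0, cgm = 100)
  expect_error(align_to_grid(event_list(), samples, step_min = 7),
               "divide 60")
})

test_that("short gaps are linearly interpolated, long gaps untouched", {
  s <- make_series(c(100, NA, NA, 130, 140))
  out <- interpolate_short_gaps(s)
  expect_equal(out$cgm, c(100, 110, 120, 130, 140))
  expect_false(any(out$missing_mask))

  # 7 consecutive missing samples = 35 min >= 30 min: untouched
  s7 <- make_series(c(100, rep(NA, 7), 180, 190))
  out7 <- interpolate_short_gaps(s7)
  expect_equal(out7$cgm, s7$cgm)

  # exactly 6 missing = 30 min is NOT shorter than 30 min: untouched
  s6 <- make_series(c(100, rep(NA, 6), 180))
  expect_equal(interpolate_short_gaps(s6)$cgm, s6$cgm)
  # 5 missing = 25 min < 30 min: filled
  s5 <- make_series(c(100, rep(NA, 5), 160))
  expect_false(anyNA(interpolate_short_gaps(s5)$cgm))
})

test_that("interpolation never alters observed samples or boundary gaps", {
  set.seed(8)
  cgm <- runif(50, 80, 250)
  cgm[c(1, 2, 20, 21, 48, 49, 50)] <- NA  # boundary gaps + interior gap
  s <- make_series(cgm)
  out <- interpolate_short_gaps(s)
  obs <- !is.na(cgm)
  expect_equal(out$cgm[obs], cgm[obs])
  expect_true(all(is.na(out$cgm[c(1, 2, 48, 49, 50)])))  # no flank
  expect_false(anyNA(out$cgm[20:21]))
  expect_identical(out$insulin, s$insulin)
  s_clean <- make_series(runif(20, 80, 200))
  expect_equal(interpolate_short_gaps(s_clean)$cgm, s_clean$cgm)
})

test_that("canonical CSV round trip is lossless and encodes missing CGM", {
  set.seed(9)
  cgm <- runif(100, 60, 300)
  cgm[c(10, 11, 50)] <- NA
  s <- make_series(cgm, insulin = runif(100, 0, 0.5), cho = runif(100, 0, 2))
  ev <- event_list(
    meals = data.frame(time = grid_times(s)[c(5, 40)], grams = c(50, 70),
                       announced = c(TRUE, FALSE)),
    boluses = data.frame(time = grid_times(s)[c(5, 60)], units = c(4, 2.5)),
    basal = data.frame(start = grid_times(s)[1], end = grid_times(s)[100],
                       rate_Umin = 0.012))
  path <- file.path(tempdir(), "series.csv")
  write_series_csv(s, path, events = ev)
  back <- read_series_csv(path)
  expect_equal(back$series$cgm, s$cgm, tolerance = 1e-9)
  expect_equal(back$series$insulin, s$insulin, tolerance = 1e-9)
  expect_equal(back$series$cho, s$cho, tolerance = 1e-9)
  expect_identical(back$series$missing_mask, s$missing_mask)
  expect_equal(back$events$meals$grams, ev$meals$grams)
  expect_equal(back$events$boluses$units, ev$boluses$units, tolerance = 1e-9)
  expect_equal(back$events$meals$announced, ev$meals$announced)
})

test_that("CSV reader rejects malformed files", {
  s <- make_series(c(100, 110, 120))
  path <- file.path(tempdir(), "bad.csv")
  write_series_csv(s, path)
  df <- utils::read.csv(path, colClasses = "character")
  utils::write.csv(df[c(2, 1, 3), ], path, row.names = FALSE, quote = FALSE)
  expect_error(read_series_csv(path), "increasing")

  df2 <- utils::read.csv(file.path(tempdir(), "bad.csv"),
                         colClasses = "character")
  df2$extra_col <- "x"
  path2 <- file.path(tempdir(), "bad2.csv")
  utils::write.csv(df2, path2, row.names = FALSE, quote = FALSE)
  expect_error(read_series_csv(path2), "unknown columns")
})

test_that("OhioT1DM-style XML is parsed, aligned and unit-converted", {
  xml <- paste0(
    '<patient id="999">',
    '<glucose_level>',
    '<event ts="01-03-2023 12:00:00" value="100"/>',
    '<event ts="01-03-2023 12:05:00" value="110"/>',
    '<event ts="01-03-2023 12:10:00" value="120"/>',
    '</glucose_level>',
    '<basal><event ts="01-03-2023 11:00:00" value="1.2"/></basal>',
    '<bolus><event ts_begin="01-03-2023 12:03:00" ts_end="01-03-2023 12:03:00" dose="5"/></bolus>',
    '<meal><event ts="01-03-2023 12:04:00" carbs="60"/></meal>',
    '</patient>')
  path <- file.path(tempdir(), "ohio.xml")
  writeLines(xml, path)
  out <- read_ohio_xml(path)
  s <- out$series
  expect_equal(sum(!s$missing_mask), 3L)
  k <- which(format(grid_times(s), "%H:%M") == "12:05")
  expect_equal(s$insulin[k], 1.2 / 60 + 5 / 5, tolerance = 1e-12)
  expect_equal(s$cho[k], 60 / 5)
  expect_equal(out$events$basal$rate_Umin, 0.02)

  bad <- file.path(tempdir(), "bad.xml")
  writeLines("<patient><glucose_level></glucose", bad)
  expect_error(read_ohio_xml(bad))
  noglc <- file.path(tempdir(), "noglc.xml")
  writeLines("<patient><basal/></patient>", noglc)
  expect_error(read_ohio_xml(noglc), "glucose_level")
})

test_that("series and split constructors enforce their invariants", {
  expect_error(glucose_series(time_grid(Sys.time(), 5, 3), c(100, -1, 120),
                              rep(0, 3), rep(0, 3)), "cgm")
  expect_error(glucose_series(time_grid(Sys.time(), 5, 3), rep(100, 3),
                              c(0, -0.1, 0), rep(0, 3)), "insulin")
  s <- make_series(runif(20, 80, 200))
  expect_error(data_split(series_slice(s, 10, 20), series_slice(s, 1, 9)),
               "precede")
  sp <- data_split(series_slice(s, 1, 10), series_slice(s, 11, 20))
  expect_s3_class(sp, "data_split")
})
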