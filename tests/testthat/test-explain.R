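# independent brute-force Shapley evaluator used as the oracle
oracle_shapley <- function(n, v) {
  phi <- numeric(n)
  masks <- 0:(2^n - 1)
  size <- function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0)
  for (j in seq_len(n)) {
    bit <- 2^(j - 1)
    for (m in masks) {
      if (bitwAnd(m, bit) > 0) next
      s <- size(m)
      w <- factorial(s) * factorial(n - s - 1) / factorial(n)
      phi[j] <- phi[j] + w * (v[bitwOr(m, bit) + 1] - v[m + 1])
    }
  }
  phi
}

rand_game <- function(n) coalition_game(n, c(0, rnorm(2^n - 1)))

test_that("exact Shapley values reproduce a worked three-player game", {
  # v indexed by bitmask + 1: {}, {1}, {2}, {1,2}, {3}, {1,3}, {2,3}, {1,2,3}
  v <- c(0, 1, 2, 4, 0, 1, 2, 4)
  phi <- shapley_exact(coalition_game(3, v))
  expect_equal(phi, c(1.5, 2.5, 0))
  expect_equal(phi, oracle_shapley(3, v))
  expect_equal(sum(phi), v[8] - v[1])
})

test_that("exact Shapley attribution satisfies the fairness axioms", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    g <- rand_game(n)
    phi <- shapley_exact(g)
    # efficiency
    expect_equal(sum(phi), g$v[2^n] - g$v[1], tolerance = 1e-9)
    # oracle agreement
    expect_equal(phi, oracle_shapley(n, g$v), tolerance = 1e-9)
    # null player: make player n irrelevant
    vnull <- g$v
    bit <- 2^(n - 1)
    for (m in 0:(2^n - 1))
      if (bitwAnd(m, bit) > 0) vnull[m + 1] <- vnull[bitwAnd(m, bitwNot(bit)) %% 2^n + 1]
    expect_equal(shapley_exact(coalition_game(n, vnull))[n], 0,
                 tolerance = 1e-12)
    # symmetry: symmetrize players 1 and 2
    swap12 <- function(m) {
      b1 <- bitwAnd(m, 1L) > 0
      b2 <- bitwAnd(m, 2L) > 0
      m - b1 * 1L - b2 * 2L + b1 * 2L + b2 * 1L
    }
    vsym <- vapply(0:(2^n - 1), function(m)
      (g$v[m + 1] + g$v[swap12(m) + 1]) / 2, numeric(1))
    psym <- shapley_exact(coalition_game(n, vsym))
    expect_equal(psym[1], psym[2], tolerance = 1e-9)
    # linearity in v
    g2 <- rand_game(n)
    a <- runif(1, 0.5, 2)
    comb <- coalition_game(n, g$v + a * g2$v)
    expect_equal(shapley_exact(comb),
                 phi + a * shapley_exact(g2), tolerance = 1e-9)
  }
})

test_that("kernel estimator reproduces exact values when enumerating", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(3:5, 1)
    g <- rand_game(n)
    expect_equal(shapley_kernel(g, n_coalition_samples = 2^n),
                 shapley_exact(g), tolerance = 1e-9)
  }
})

test_that("kernel estimator recovers additive games and is seed-stable", {
  cc <- c(1.5, -2, 0.5, 3)
  v <- vapply(0:15, function(m)
    sum(cc[which(bitwAnd(m, 2^(0:3)) > 0)]), numeric(1))
  g <- coalition_game(4, v)
  expect_equal(shapley_kernel(g, 14), cc, tolerance = 1e-9)
  # sampled mode fits additive games exactly from any full-rank design
  p1 <- shapley_kernel(g, 13, seed = 1)
  expect_equal(p1, cc, tolerance = 1e-9)
  # sampled mode on a general game: efficiency exact, estimate near exact
  set.seed(71)
  g6 <- rand_game(6)
  ex6 <- shapley_exact(g6)
  for (sd in 1:2) {
    ps <- shapley_kernel(g6, 48, seed = sd)
    expect_equal(sum(ps), g6$v[64] - g6$v[1], tolerance = 1e-9)
    expect_lt(max(abs(ps - ex6)), 1.5)  # Monte-Carlo tolerance
  }
  expect_error(shapley_kernel(g, 1), "degenerate")
  expect_error(shapley_kernel(coalition_game(1, c(0, 1))), "at least 2")
})

test_that("missing coalition values are reported by bitmask", {
  v <- c(0, 1, NA, 3, 0, 1, 2, 4)
  expect_error(shapley_exact(coalition_game(3, v)), "bitmask 2")
})

test_that("closed-form linear attributions follow the mean deviation", {
  expect_equal(linear_shap_closed_form(1.5, 120, 100), 30)
  beta <- c(1.2, -30, 4)
  x <- c(150, 0.4, 2)
  mu <- c(120, 0.1, 0.5)
  phi <- linear_shap_closed_form(beta, x, mu)
  expect_equal(phi, beta * (x - mu))
  expect_equal(linear_shap_closed_form(beta, mu, mu), c(0, 0, 0))
  b0 <- 10
  expect_equal(sum(phi) + b0 + sum(beta * mu), b0 + sum(beta * x))
  expect_error(linear_shap_closed_form(beta, x[1:2], mu), "length")
})

test_that("masking explanation of a linear forecaster matches closed form", {
  set.seed(202)
  s <- make_series(runif(200, 80, 250), insulin = runif(200, 0, 0.5),
                   cho = runif(200, 0, 3))
  stub <- linear_stub(beta0 = 20,
                      beta = c(cgm = 0.9, insulin = -40, cho = 12))
  bg <- channel_background(s)
  for (t in sample(12:200, 25)) {
    e <- explain_instance(stub, s, t, bg)
    closed <- linear_shap_closed_form(
      stub$beta, c(s$cgm[t], s$insulin[t], s$cho[t]),
      c(bg$cgm, bg$insulin, bg$cho))
    expect_equal(unname(e$phi), unname(closed), tolerance = 1e-9)
    expect_equal(e$base + sum(e$phi), e$prediction, tolerance = 1e-9)
  }
})

test_that("an instance at background values receives zero attribution", {
  s <- make_series(rep(120, 60), insulin = rep(0.012, 60), cho = rep(0, 60))
  stub <- linear_stub(5, c(cgm = 1, insulin = -20, cho = 8))
  bg <- list(cgm = 120, insulin = 0.012, cho = 0)
  e <- explain_instance(stub, s, 20, bg)
  expect_equal(unname(e$phi), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(e$base, e$prediction)
  expect_error(explain_instance(stub, s, 20, list(cgm = 1, insulin = 1)),
               "missing channel")
})

test_that("efficiency holds on explanations of a trained network", {
  corp <- tiny_corpus()
  m <- tiny_model("p", 30)
  bg <- channel_background(corp$train)
  fc <- predict_series(m, corp$test)
  set.seed(4)
  for (t in sample(fc$anchor, 10)) {
    e <- explain_instance(m, corp$test, t, bg)
    expect_equal(e$base + sum(e$phi), e$prediction, tolerance = 1e-6)
    expect_equal(e$prediction, fc$yhat[match(t, fc$anchor)],
                 tolerance = 1e-6)
  }
})

test_that("summary statistics expose importance ranks and effect signs", {
  set.seed(9)
  # block-constant channels make the window mean equal the anchor value,
  # so a monotone stub yields perfect rank correlation
  n <- 30 * 13
  blocks <- rep(seq_len(30), each = 13)
  cho <- rep(runif(30, 0, 3), each = 13)
  ins <- rep(runif(30, 0, 0.5), each = 13)
  s <- make_series(rep(120, n), insulin = ins, cho = cho)
  bg <- list(cgm = 120, insulin = mean(ins), cho = mean(cho))
  anchors <- seq(13, n, by = 13)  # last sample of each block

  up <- linear_stub(0, c(cgm = 0, insulin = 0, cho = 15))
  ss <- summarize_explanations(explain_anchors(up, s, anchors, bg))
  st <- ss$stats
  expect_equal(st$sign_consistency[st$channel == "cho"], 1)
  expect_equal(st$rank[st$channel == "cho"], 1L)
  expect_equal(st$importance[st$channel == "insulin"], 0)
  expect_true(is.na(st$sign_consistency[st$channel == "cgm"]))  # constant

  down <- linear_stub(0, c(cgm = 0, insulin = -40, cho = 0))
  ss2 <- summarize_explanations(explain_anchors(down, s, anchors, bg))
  expect_equal(ss2$stats$sign_consistency[
    ss2$stats$channel == "insulin"], -1)

  e1 <- explain_anchors(up, s, anchors, bg)
  expect_identical(summarize_explanations(c(e1, e1))$stats$sign_consistency,
                   summarize_explanations(e1)$stats$sign_consistency)
  expect_error(summarize_explanations(e1[1:5]), "at least 30")
})

test_that("explanations export to CSV with one row per anchor", {
  s <- make_series(runif(60, 90, 200))
  stub <- linear_stub(0, c(cgm = 1, insulin = 0, cho = 0))
  ex <- explain_anchors(stub, s, 12:45, channel_background(s))
  path <- file.path(tempdir(), "explanations.csv")
  write_explanations_csv(ex, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 34)
  expect_true(all(c("phi_cgm", "phi_insulin", "phi_cho") %in% names(df)))
})
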