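#' Coalitional game over input features
#'
#' A cooperative game with \code{n_players} players and a value function
#' defined on all \eqn{2^n} coalitions.  Coalitions are encoded as bitmasks
#' (bit \code{j - 1} set = player \code{j} in the coalition), so \code{v}
#' is a numeric vector of length \eqn{2^n} with \code{v[mask + 1]} the
#' value of coalition \code{mask}; \code{v[1]} is the empty coalition.
#'
#' @param n_players number of players.
#' @param v numeric vector of coalition values, length \code{2^n_players}
#'   (entries may be \code{NA} if never queried by the exact solver).
#' @return object of class \code{coalition_game}.
#' @export
coalition_game <- function(n_players, v) {
  n_players <- as.integer(n_players)
  if (length(v) != 2^n_players)
    stop("v must have length 2^n_players = ", 2^n_players)
  structure(list(n_players = n_players, v = as.numeric(v)),
            class = "coalition_game")
}

#' Exact Shapley values by coalition enumeration
#'
#' Computes, for every player \code{j},
#' \deqn{\phi_j = \sum_{S \subseteq M \setminus \{j\}}
#'   \frac{|S|!\,(|M|-|S|-1)!}{|M|!}\,[v(S \cup \{j\}) - v(S)]}
#' the weighted mean of the player's marginal contributions.  Efficiency
#' holds exactly: \eqn{\sum_j \phi_j = v(M) - v(\emptyset)}.
#'
#' @param game a \code{\link{coalition_game}} with at most 12 players.
#' @return numeric vector of Shapley values, one per player.
#' @export
shapley_exact <- function(game) {
  stopifnot(inherits(game, "coalition_game"))
  n <- game$n_players
  if (n > 12) stop("exact enumeration supported up to 12 players")
  v <- game$v
  if (anyNA(v)) {
    bad <- which(is.na(v))[1] - 1
    stop("value map is missing coalition with bitmask ", bad)
  }
  masks <- 0:(2^n - 1)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0), 0)
  fact <- factorial(0:n)
  phi <- numeric(n)
  for (j in seq_len(n)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- masks[bitwAnd(masks, bit) == 0]
    s <- sizes[without + 1]
    wgt <- fact[s + 1] * fact[n - s] / fact[n + 1]
    phi[j] <- sum(wgt * (v[bitwOr(without, bit) + 1] - v[without + 1]))
  }
  phi
}

#' Shapley kernel weight for a coalition size
#' @keywords internal
#' @noRd
.shapley_kernel_weight <- function(n, s) {
  (n - 1) / (choose(n, s) * s * (n - s))
}

#' Kernel-weighted least-squares Shapley estimator
#'
#' The KernelSHAP estimator: regresses sampled coalition values on
#' coalition membership indicators under the Shapley kernel weights, with
#' the efficiency constraint \eqn{\sum_j \phi_j = v(M) - v(\emptyset)}
#' imposed exactly.  When the sampling budget covers all \eqn{2^n - 2}
#' proper non-empty coalitions the estimator enumerates them and the
#' result equals \code{\link{shapley_exact}}.
#'
#' @param game a \code{\link{coalition_game}}.
#' @param n_coalition_samples sampling budget.
#' @param seed integer seed for coalition sampling.
#' @return numeric vector of estimated Shapley values.
#' @export
shapley_kernel <- function(game, n_coalition_samples = 2048, seed = 1L) {
  stopifnot(inherits(game, "coalition_game"))
  n <- game$n_players
  if (n < 2) stop("kernel estimator needs at least 2 players")
  v <- game$v
  all_proper <- 2^n - 2
  if (n_coalition_samples >= all_proper) {
    masks <- 1:(2^n - 2)
    sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0), 0)
    wts <- .shapley_kernel_weight(n, sizes)
  } else {
    set.seed(seed)
    # sample coalition sizes with probability proportional to the total
    # kernel mass at each size, then members uniformly within the size
    size_mass <- vapply(1:(n - 1), function(s)
      choose(n, s) * .shapley_kernel_weight(n, s), 0)
    sizes <- sample(1:(n - 1), n_coalition_samples, replace = TRUE,
                    prob = size_mass)
    masks <- vapply(sizes, function(s)
      sum(bitwShiftL(1L, sample.int(n, s) - 1L)), 0)
    wts <- rep(1, n_coalition_samples)  # kernel absorbed in sampling
    if (length(unique(masks)) < n)
      stop("degenerate coalition sample: too few distinct coalitions")
  }
  z <- t(vapply(masks, function(m) as.numeric(bitwAnd(m, 2^(0:(n - 1))) > 0),
                numeric(n)))
  y <- v[masks + 1] - v[1]
  total <- v[2^n] - v[1]
  # impose efficiency by eliminating phi_n:
  # y - z_n * total = (z_j - z_n) phi_j for j < n
  zr <- z[, -n, drop = FALSE] - z[, n]
  yr <- y - z[, n] * total
  A <- t(zr * wts) %*% zr
  b <- t(zr * wts) %*% yr
  phi <- as.numeric(solve(A, b))
  c(phi, total - sum(phi))
}

#' Closed-form Shapley values of a linear model
#'
#' For a linear predictor \eqn{f(x) = \beta_0 + \sum_j \beta_j x_j} with
#' independent background expectations \eqn{E[x_j]}, the Shapley value of
#' feature \code{j} at instance \code{x} is the deviation of the feature
#' from its mean scaled by its weight:
#' \deqn{\phi_j = \beta_j (x_j - E[x_j]).}
#'
#' @param beta coefficient vector (no intercept).
#' @param x feature values of the explained instance.
#' @param means background expectations \code{E[x]}.
#' @return numeric vector of Shapley values.
#' @export
linear_shap_closed_form <- function(beta, x, means) {
  if (length(beta) != length(x) || length(x) != length(means))
    stop("beta, x and means must have equal length")
  beta * (x - means)
}
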