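# Differential-evolution MCMC (DE-MCMC) engine. Chains evolve by crossover
# proposals built from the difference of two other randomly chosen chains,
# scaled by gamma = 2.38/sqrt(2d) with small uniform jitter; during burn-in a
# small migration probability lets a random ring of chains exchange states so
# stragglers are absorbed. Proposals for all chains are evaluated in one
# vectorized call to the target.

#' Sampler configuration
#'
#' @param n_chains number of interacting chains; default (`NULL`) is three
#'   times the number of free parameters, chosen at fit time.
#' @param n_iter retained iterations per chain (after burn-in).
#' @param n_burn burn-in iterations per chain.
#' @param migration probability of a migration step per iteration during
#'   burn-in only.
#' @param jitter half-width of the uniform jitter added to crossover
#'   proposals.
#' @param gamma crossover step size; default `2.38/sqrt(2d)`.
#' @param seed integer seed used for every source of randomness in the fit.
#' @param init `"mode"` starts chains scattered around a posterior mode found
#'   by Nelder-Mead (short burn-in suffices); `"prior"` starts chains from
#'   prior draws (longer burn-in needed).
#' @return a list of class `ddm_sampler_config`.
#' @export
sampler_config <- function(n_chains = NULL, n_iter = 1000, n_burn = 500,
                           migration = 0.05, jitter = 1e-3, gamma = NULL,
                           seed = 1L, init = c("mode", "prior")) {
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
                 migration = migration, jitter = jitter, gamma = gamma,
                 seed = seed, init = match.arg(init)),
            class = "ddm_sampler_config")
}

# target(theta_mat d x K) must return list(lp = K log-posteriors,
# ll = K log-likelihoods). init: d x K matrix of start points with finite lp.
de_mcmc <- function(target, init, config, pnames = NULL) {
  d <- nrow(init); K <- ncol(init)
  gamma <- config$gamma %||% (2.38 / sqrt(2 * d))
  n_tot <- config$n_burn + config$n_iter
  cur <- init
  ev <- target(cur)
  lp <- ev$lp; ll <- ev$ll
  if (any(!is.finite(lp))) stop_input("non-finite log-posterior at start points")
  draws <- array(NA_real_, c(K, config$n_iter, d),
                 dimnames = list(NULL, NULL, pnames))
  lp_out <- matrix(NA_real_, K, config$n_iter)
  ll_out <- matrix(NA_real_, K, config$n_iter)
  for (it in seq_len(n_tot)) {
    if (it <= config$n_burn && runif(1) < config$migration && K >= 3) {
      # migration: a random ring of chains, each offered its neighbor's state
      m <- sample(2:max(2, ceiling(K / 2)), 1)
      ring <- sample.int(K, m)
      prev <- c(ring[m], ring[-m])
      acc <- log(runif(m)) < lp[prev] - lp[ring]
      cur[, ring[acc]] <- cur[, prev[acc], drop = FALSE]
      lp[ring[acc]] <- lp[prev[acc]]
      ll[ring[acc]] <- ll[prev[acc]]
    } else {
      r1 <- integer(K); r2 <- integer(K)
      for (k in seq_len(K)) {
        pick <- sample.int(K - 1L, 2L)
        pick <- pick + (pick >= k)
        r1[k] <- pick[1]; r2[k] <- pick[2]
      }
      prop <- cur + gamma * (cur[, r1, drop = FALSE] - cur[, r2, drop = FALSE]) +
        matrix(runif(d * K, -config$jitter, config$jitter), d, K)
      evp <- target(prop)
      acc <- log(runif(K)) < evp$lp - lp
      if (any(acc)) {
        cur[, acc] <- prop[, acc, drop = FALSE]
        lp[acc] <- evp$lp[acc]
        ll[acc] <- evp$ll[acc]
      }
    }
    if (it > config$n_burn) {
      j <- it - config$n_burn
      draws[, j, ] <- t(cur)
      lp_out[, j] <- lp
      ll_out[, j] <- ll
    }
  }
  list(draws = draws, lp = lp_out, ll = ll_out)
}

# posterior mode by Nelder-Mead from the prior means (invalid regions
# penalized); used to seed chains so burn-in only has to adapt covariance
find_mode <- function(target, priors, spec, maxit = 1500) {
  th0 <- pmin(pmax(priors$mean, priors$lower + 0.02), priors$upper - 0.02)
  if (!theta_valid(spec, th0)) th0[spec$sz_idx] <- 0.05
  f <- function(th) {
    lp <- target(matrix(th, ncol = 1))$lp
    if (!is.finite(lp)) 1e10 else -lp
  }
  opt <- stats::optim(th0, f, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  opt$par
}

# scatter chains around a center, clamped into support and validity-checked
scatter_chains <- function(target, center, priors, spec, K, max_tries = 200) {
  d <- length(center)
  scale <- pmax(0.05 * abs(center), 0.01)
  cur <- matrix(NA_real_, d, K)
  need <- rep(TRUE, K)
  for (try in seq_len(max_tries)) {
    m <- sum(need)
    if (!m) break
    cand <- center + matrix(rnorm(d * m, 0, scale * try), d, m)
    cand <- pmin(pmax(cand, priors$lower + 1e-6), priors$upper - 1e-6)
    ok <- theta_valid(spec, cand)
    if (any(ok)) {
      lpc <- target(cand[, ok, drop = FALSE])$lp
      good <- which(ok)[is.finite(lpc)]
      if (length(good)) {
        slots <- which(need)[seq_len(min(length(good), m))]
        cur[, slots] <- cand[, good[seq_along(slots)], drop = FALSE]
        need[slots] <- FALSE
      }
    }
  }
  if (any(need)) stop_input("could not initialize sampler start points")
  cur
}

# draw chain start points from independent truncated normals, rejecting
# columns with invalid support or non-finite target
init_chains <- function(target, priors, spec, K, max_tries = 200) {
  d <- nrow(priors)
  cur <- matrix(NA_real_, d, K)
  need <- rep(TRUE, K)
  for (try in seq_len(max_tries)) {
    m <- sum(need)
    if (!m) break
    cand <- matrix(rtnorm(d * m, priors$mean, priors$sd, priors$lower,
                          priors$upper), d, m)
    ok <- theta_valid(spec, cand)
    if (any(ok)) {
      lpc <- target(cand[, ok, drop = FALSE])$lp
      good <- which(ok)[is.finite(lpc)]
      if (length(good)) {
        slots <- which(need)[seq_len(min(length(good), m))]
        cur[, slots] <- cand[, good[seq_along(slots)], drop = FALSE]
        need[slots] <- FALSE
      }
    }
  }
  if (any(need)) stop_input("could not initialize sampler start points")
  cur
}
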