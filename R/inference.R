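# Bayesian estimation of the reference-back DDM: per-subject and hierarchical
# DE-MCMC sampling, DIC, and per-subject model selection.

# Precompute trial vectors once; returns function(theta_mat) -> list(lp, ll).
# log_prior_fn(theta_mat) must return K log prior densities (-Inf invalid).
make_target <- function(trials, spec, log_prior_fn) {
  rt <- trials$rt
  upper <- trials$response == "same"
  cell <- as.integer(trials$cell)
  function(theta) {
    if (!is.matrix(theta)) theta <- matrix(theta, ncol = 1)
    K <- ncol(theta)
    lp <- rep(-Inf, K)
    ll <- rep(-Inf, K)
    ok <- theta_valid(spec, theta)
    lpri <- log_prior_fn(theta)
    ok <- ok & is.finite(lpri)
    if (any(ok)) {
      cp <- theta_to_cells(spec, theta[, ok, drop = FALSE])
      llo <- ddm_loglik_mat_cpp(rt, upper, cell, cp$V, cp$A, cp$T0,
                                cp$Z, cp$SV, cp$SZ)
      ll[ok] <- llo
      lp[ok] <- llo + lpri[ok]
    }
    list(lp = lp, ll = ll)
  }
}

#' Log-posterior of a parameter vector for one subject
#'
#' Sum of the trial log-likelihood (see [log_likelihood()]) and the log prior
#' densities; `-Inf` outside the parameter support (including the joint
#' start-point constraint).
#'
#' @param theta numeric vector conforming to `spec$par_names`.
#' @param trials cleaned annotated trials of one subject.
#' @param spec a [model_spec()].
#' @param priors prior data frame as from [default_priors()].
#' @return a single log-probability.
#' @export
log_posterior <- function(theta, trials, spec, priors = default_priors(spec)) {
  if (length(theta) != spec$n_free) stop_input("theta has wrong length")
  tgt <- make_target(trials, spec, function(th) log_prior_mat(th, priors))
  tgt(theta)$lp
}

#' Fit the DDM to one subject by DE-MCMC
#'
#' Non-hierarchical sampling of one subject's free parameters under
#' truncated-normal priors. Chains are initialized from the priors; retained
#' draws are those after burn-in; split-chain R-hat is reported per
#' parameter. Fixed seed gives identical draws on repeat.
#'
#' @param trials the subject's cleaned, annotated trials.
#' @param spec a [model_spec()].
#' @param priors prior data frame (defaults to [default_priors()]).
#' @param config a [sampler_config()].
#' @return an object of class `ddm_fit`: retained draws
#'   (chain x iteration x parameter), log-posterior and log-likelihood per
#'   draw, R-hat, and the inputs needed to recompute the deviance.
#' @export
fit_subject <- function(trials, spec, priors = default_priors(spec),
                        config = sampler_config()) {
  cells_present <- unique(trials$cell)
  if (length(setdiff(1:8, cells_present)) && spec$variant != "drift-fixed")
    warning("some design cells have no trials; their parameters are ",
            "informed by the prior only")
  set.seed(config$seed)
  K <- config$n_chains %||% (3L * spec$n_free)
  tgt <- make_target(trials, spec, function(th) log_prior_mat(th, priors))
  init <- if ((config$init %||% "mode") == "mode") {
    scatter_chains(tgt, find_mode(tgt, priors, spec), priors, spec, K)
  } else {
    init_chains(tgt, priors, spec, K)
  }
  run <- de_mcmc(tgt, init, config, pnames = spec$par_names)
  structure(list(draws = run$draws, lp = run$lp, ll = run$ll,
                 pnames = spec$par_names, spec = spec, priors = priors,
                 config = config, trials = trials,
                 rhat = rhat(run$draws)),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("DDM fit (", x$spec$variant, "): ", dim(x$draws)[1], " chains x ",
      dim(x$draws)[2], " retained iterations, max R-hat ",
      round(max(x$rhat), 3), "\n", sep = "")
  invisible(x)
}

# flatten draws array to (chains*iters) x d
flat_draws <- function(draws) {
  d <- dim(draws)
  matrix(draws, d[1] * d[2], d[3], dimnames = list(NULL, dimnames(draws)[[3]]))
}

#' Refuse unconverged samples
#'
#' Downstream analyses call this gate and stop when any split-chain R-hat
#' exceeds `max_rhat`, unless overridden.
#'
#' @param fit a `ddm_fit` or `ddm_hfit`.
#' @param max_rhat convergence bound.
#' @param override set `TRUE` to proceed anyway (a warning is issued).
#' @return invisibly, the maximum R-hat.
#' @export
check_convergence <- function(fit, max_rhat = 1.1, override = FALSE) {
  r <- max(fit$rhat, na.rm = TRUE)
  if (r > max_rhat) {
    msg <- sprintf("max R-hat %.3f exceeds %.2f", r, max_rhat)
    if (override) warning(msg, "; proceeding (override)") else stop_input(msg)
  }
  invisible(r)
}

#' Maximum a posteriori estimate
#'
#' The retained draw with the highest log-posterior (used for
#' individual-difference analyses without hierarchical shrinkage).
#'
#' @param fit a `ddm_fit`.
#' @return named parameter vector.
#' @export
map_estimate <- function(fit) {
  i <- which.max(fit$lp)
  th <- flat_draws(fit$draws)[i, ]
  names(th) <- fit$pnames
  th
}

#' Deviance information criterion
#'
#' `D(theta) = -2 log-likelihood`; `Dbar` is its posterior mean over retained
#' draws, `pD = Dbar - D(theta_bar)` (Spiegelhalter form) with `theta_bar`
#' the posterior mean, and `DIC = Dbar + pD`. If the posterior mean falls
#' outside the support, the highest-posterior draw is used instead (recorded
#' in the result).
#'
#' @param fit a `ddm_fit`.
#' @return list with `dic`, `dbar`, `pd`, and `fallback` (logical).
#' @export
dic <- function(fit) {
  dbar <- mean(-2 * fit$ll)
  theta_bar <- colMeans(flat_draws(fit$draws))
  tgt <- make_target(fit$trials, fit$spec,
                     function(th) log_prior_mat(th, fit$priors))
  fallback <- FALSE
  ll_hat <- tgt(theta_bar)$ll
  if (!is.finite(ll_hat)) {
    fallback <- TRUE
    ll_hat <- tgt(map_estimate(fit))$ll
  }
  dhat <- -2 * ll_hat
  pd <- dbar - dhat
  list(dic = dbar + pd, dbar = dbar, pd = pd, fallback = fallback)
}

#' Per-subject model selection by DIC
#'
#' Fits each model variant to each subject non-hierarchically, computes DIC,
#' and assigns each subject to the variant with the lowest DIC. The summary
#' table mirrors the standard model-selection layout: free-parameter count,
#' summed DIC difference from the top model, and the number and percentage of
#' subjects preferring each variant.
#'
#' @param trials cleaned annotated trials for all subjects.
#' @param variants model variant names (>= 2).
#' @param config a [sampler_config()]; per-subject/variant seeds are derived
#'   from `config$seed`.
#' @param priors optional named list of prior data frames per variant.
#' @return an object of class `ddm_model_comparison`: the summary data frame
#'   with the per-subject DIC matrix in attribute `"dic"` and fits dropped.
#' @export
select_models <- function(trials,
                          variants = c("top", "threshold-fixed",
                                       "drift-fixed", "ndt-fixed"),
                          config = sampler_config(), priors = NULL) {
  if (length(variants) < 2) stop_input("need at least two variants")
  subjects <- unique(trials$subject)
  if (!length(subjects)) stop_input("need at least one subject")
  DIC <- matrix(NA_real_, length(subjects), length(variants),
                dimnames = list(subjects, variants))
  for (vi in seq_along(variants)) {
    spec <- model_spec(variants[vi])
    pri <- priors[[variants[vi]]] %||% default_priors(spec)
    for (si in seq_along(subjects)) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * si + vi
      f <- fit_subject(trials[trials$subject == subjects[si], ], spec, pri, cfg)
      DIC[si, vi] <- dic(f)$dic
    }
  }
  pref <- variants[apply(DIC, 1, which.min)]
  n_pref <- vapply(variants, function(v) sum(pref == v), integer(1))
  ref <- if ("top" %in% variants) "top" else variants[1]
  out <- data.frame(variant = variants,
                    n_parameters = vapply(variants, function(v)
                      model_spec(v)$n_free, integer(1)),
                    dic_sum = colSums(DIC),
                    delta_dic = colSums(DIC) - sum(DIC[, ref]),
                    n = n_pref,
                    pct = round(100 * n_pref / length(subjects), 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dic") <- DIC
  class(out) <- c("ddm_model_comparison", "data.frame")
  out
}

# ---- hierarchical model -----------------------------------------------------

#' Fit the hierarchical DDM
#'
#' Fully hierarchical estimation: subject-level parameters are drawn from
#' truncated-normal population distributions (truncation at the parameter
#' support) whose hyper-means carry the subject-level priors and whose
#' hyper-SDs carry half-normal priors. Sampling alternates DE-MCMC crossover
#' updates of the group block and of each subject's block within every
#' iteration, with burn-in-only migration; the population structure shrinks
#' subject-level estimates toward the group average.
#'
#' @param trials cleaned annotated trials for >= 2 subjects.
#' @param spec a [model_spec()].
#' @param priors prior data frame for the hyper-means.
#' @param config a [sampler_config()].
#' @param hyper_sd_scale scale of the half-normal hyper-SD prior.
#' @return an object of class `ddm_hfit` with arrays `mu` and `sigma`
#'   (chain x iteration x parameter), `phi`
#'   (chain x iteration x subject x parameter), per-subject log-likelihoods,
#'   and group-level R-hat.
#' @export
fit_hierarchical <- function(trials, spec, priors = default_priors(spec),
                             config = sampler_config(),
                             hyper_sd_scale = 1) {
  subjects <- unique(trials$subject)
  S <- length(subjects)
  if (S < 2) stop_input("hierarchical fit needs >= 2 subjects")
  d <- spec$n_free
  set.seed(config$seed)
  K <- config$n_chains %||% (3L * d)
  gamma_s <- config$gamma %||% (2.38 / sqrt(2 * d))
  gamma_g <- config$gamma %||% (2.38 / sqrt(2 * 2))  # componentwise 2-d blocks

  lik_fns <- lapply(subjects, function(s) {
    dat <- trials[trials$subject == s, ]
    rt <- dat$rt; upper <- dat$response == "same"; cell <- as.integer(dat$cell)
    function(theta) {
      ok <- theta_valid(spec, theta)
      ll <- rep(-Inf, ncol(theta))
      if (any(ok)) {
        cp <- theta_to_cells(spec, theta[, ok, drop = FALSE])
        ll[ok] <- ddm_loglik_mat_cpp(rt, upper, cell, cp$V, cp$A, cp$T0,
                                     cp$Z, cp$SV, cp$SZ)
      }
      ll
    }
  })

  lower <- spec$lower; upper_b <- spec$upper
  # log density of subject params under chain-specific population model
  pop_ld <- function(phi, mu, sigma) {
    colSums(dtnorm(phi, mu, sigma, lower, upper_b, log = TRUE))
  }
  # elementwise (d x K) group-conditional log posterior: the hyper-parameter
  # conditionals factorize over parameters given the subject-level draws
  grp_mat <- function(mu, sigma) {
    bad <- sigma < 1e-4 | mu <= lower | mu >= upper_b
    sg <- pmax(sigma, 1e-4)
    pop <- Reduce(`+`, lapply(seq_len(S), function(s)
      dtnorm(phi[[s]], mu, sg, lower, upper_b, log = TRUE)))
    lp <- pop + dtnorm(mu, priors$mean, priors$sd, priors$lower, priors$upper,
                       log = TRUE) +
      dtnorm(sg, 0, hyper_sd_scale, 0, Inf, log = TRUE)
    lp[bad] <- -Inf
    lp
  }

  # initialize: per-subject posterior modes (non-hierarchical) seed the
  # subject chains; hyper-means start near the mode average, hyper-SDs near
  # the between-mode spread
  modes <- matrix(NA_real_, d, S)
  for (s in seq_len(S)) {
    tgt_s <- make_target(trials[trials$subject == subjects[s], ], spec,
                         function(th) log_prior_mat(th, priors))
    modes[, s] <- if ((config$init %||% "mode") == "mode")
      find_mode(tgt_s, priors, spec, maxit = 1000)
    else pmin(pmax(priors$mean, priors$lower + 0.02), priors$upper - 0.02)
  }
  mu_c <- pmin(pmax(rowMeans(modes), priors$lower + 1e-3), priors$upper - 1e-3)
  sd_c <- pmax(apply(modes, 1, sd), 0.02)
  mu <- mu_c + matrix(rnorm(d * K, 0, pmax(0.05 * abs(mu_c), 0.01)), d, K)
  mu <- pmin(pmax(mu, priors$lower + 1e-6), priors$upper - 1e-6)
  sigma <- abs(sd_c + matrix(rnorm(d * K, 0, sd_c / 4), d, K)) + 1e-3
  phi <- vector("list", S)      # each d x K
  ll_s <- matrix(NA_real_, S, K)
  for (s in seq_len(S)) {
    lik_wrap <- function(th) list(lp = lik_fns[[s]](th), ll = NULL)
    phi[[s]] <- scatter_chains(lik_wrap, modes[, s], priors, spec, K)
    ll_s[s, ] <- lik_fns[[s]](phi[[s]])
  }
  n_tot <- config$n_burn + config$n_iter
  mu_out <- array(NA_real_, c(K, config$n_iter, d),
                  dimnames = list(NULL, NULL, spec$par_names))
  sg_out <- array(NA_real_, c(K, config$n_iter, d),
                  dimnames = list(NULL, NULL, spec$par_names))
  phi_out <- array(NA_real_, c(K, config$n_iter, S, d),
                   dimnames = list(NULL, NULL, subjects, spec$par_names))
  ll_out <- array(NA_real_, c(K, config$n_iter, S))

  pick2 <- function(K, k) {
    p <- sample.int(K - 1L, 2L)
    p + (p >= k)
  }

  for (it in seq_len(n_tot)) {
    # componentwise group update: per-parameter DE-Metropolis on
    # (hyper-mean, hyper-SD), vectorized over parameters and chains
    lp_grp <- grp_mat(mu, sigma)
    r1 <- integer(K); r2 <- integer(K)
    for (k in seq_len(K)) { p <- pick2(K, k); r1[k] <- p[1]; r2[k] <- p[2] }
    mu_p <- mu + gamma_g * (mu[, r1] - mu[, r2]) +
      matrix(runif(d * K, -config$jitter, config$jitter), d, K)
    sg_p <- sigma + gamma_g * (sigma[, r1] - sigma[, r2]) +
      matrix(runif(d * K, -config$jitter, config$jitter), d, K)
    lp_p <- grp_mat(mu_p, sg_p)
    acc <- matrix(log(runif(d * K)), d, K) < lp_p - lp_grp
    mu[acc] <- mu_p[acc]
    sigma[acc] <- sg_p[acc]

    # subject block updates conditional on current group chains
    for (s in seq_len(S)) {
      cur <- phi[[s]]
      lp_cur <- ll_s[s, ] + pop_ld(cur, mu, sigma)
      r1 <- integer(K); r2 <- integer(K)
      for (k in seq_len(K)) { p <- pick2(K, k); r1[k] <- p[1]; r2[k] <- p[2] }
      prop <- cur + gamma_s * (cur[, r1] - cur[, r2]) +
        matrix(runif(d * K, -config$jitter, config$jitter), d, K)
      ll_p <- lik_fns[[s]](prop)
      lp_p <- ll_p + pop_ld(prop, mu, sigma)
      acc <- is.finite(lp_p) & (log(runif(K)) < lp_p - lp_cur)
      if (any(acc)) {
        cur[, acc] <- prop[, acc, drop = FALSE]
        ll_s[s, acc] <- ll_p[acc]
      }
      phi[[s]] <- cur
    }

    if (it > config$n_burn) {
      j <- it - config$n_burn
      mu_out[, j, ] <- t(mu)
      sg_out[, j, ] <- t(sigma)
      for (s in seq_len(S)) phi_out[, j, s, ] <- t(phi[[s]])
      ll_out[, j, ] <- t(ll_s)
    }
  }
  grp <- array(c(mu_out, sg_out), c(K, config$n_iter, 2 * d),
               dimnames = list(NULL, NULL,
                               c(paste0("mu.", spec$par_names),
                                 paste0("sigma.", spec$par_names))))
  structure(list(mu = mu_out, sigma = sg_out, phi = phi_out, ll = ll_out,
                 pnames = spec$par_names, subjects = subjects, spec = spec,
                 priors = priors, config = config, rhat = rhat(grp)),
            class = "ddm_hfit")
}

#' @export
print.ddm_hfit <- function(x, ...) {
  cat("Hierarchical DDM fit (", x$spec$variant, "): ",
      length(x$subjects), " subjects, ", dim(x$mu)[1], " chains x ",
      dim(x$mu)[2], " retained iterations, max group R-hat ",
      round(max(x$rhat), 3), "\n", sep = "")
  invisible(x)
}

#' Posterior means of subject-level parameters
#'
#' @param hfit a `ddm_hfit`.
#' @return matrix subjects x parameters of posterior means.
#' @export
subject_means <- function(hfit) {
  out <- apply(hfit$phi, c(3, 4), mean)
  dimnames(out) <- list(hfit$subjects, hfit$pnames)
  out
}
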