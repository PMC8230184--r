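# Bayesian machinery: log-posterior arithmetic, sampler determinism and
# support, DIC identities, MAP, and hierarchical structure/shrinkage.

make_small_data <- function(n_subjects = 1, n_trials = 256, seed = 1,
                            group = NULL, spec = model_spec("top")) {
  g <- group %||% default_group_model(spec)
  simd <- simulate_dataset(g, spec, n_subjects = n_subjects,
                           n_trials = n_trials, n_blocks = 2, seed = seed)
  list(trials = clean_trials(simd$trials)$trials, truth = simd$subject_params)
}

test_that("log-posterior adds likelihood and prior and respects support", {
  spec <- model_spec("top")
  priors <- default_priors(spec)
  dat <- make_small_data(n_trials = 64, seed = 2)
  th <- dat$truth[1, ]

  # outside support
  th_bad <- th; th_bad["a.ref"] <- -1
  expect_identical(log_posterior(th_bad, dat$trials, spec, priors), -Inf)
  th_bad2 <- th; th_bad2["sz"] <- 0.89; th_bad2["z"] <- 0.94
  expect_identical(log_posterior(th_bad2, dat$trials, spec, priors), -Inf)

  # near-flat prior: log-posterior tracks the likelihood up to a constant
  flat <- priors; flat$sd <- 1e6
  th2 <- th; th2[1:8] <- th2[1:8] * 1.1
  lp_diff <- log_posterior(th, dat$trials, spec, flat) -
    log_posterior(th2, dat$trials, spec, flat)
  p8 <- function(t) {
    cp <- refbackddm:::theta_to_cells(spec, t)
    ll <- 0
    for (i in seq_len(nrow(dat$trials))) {
      cl <- dat$trials$cell[i]
      pp <- ddm_params(v = cp$V[cl, 1], a = cp$A[cl, 1], z = cp$Z,
                       t0 = cp$T0[cl, 1], sv = cp$SV, sz = cp$SZ)
      b <- if (dat$trials$response[i] == "same") "upper" else "lower"
      ll <- ll + log(max(ddm_density(dat$trials$rt[i], b, pp), 1e-10))
    }
    ll
  }
  expect_equal(lp_diff, p8(th) - p8(th2), tolerance = 1e-4)

  # full independent re-computation: densities + prior terms summed in R
  lp <- log_posterior(th, dat$trials, spec, priors)
  ref <- p8(th) + sum(dtnorm(th, priors$mean, priors$sd, priors$lower,
                             priors$upper, log = TRUE))
  expect_equal(lp, ref, tolerance = 1e-6)
})

test_that("the sampler is deterministic and stays in support", {
  spec <- model_spec("drift-fixed")
  dat <- make_small_data(n_trials = 128, seed = 3, spec = spec)
  cfg <- tiny_config(seed = 7)
  f1 <- fit_subject(dat$trials, spec, config = cfg)
  f2 <- fit_subject(dat$trials, spec, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$lp, f2$lp)

  fd <- refbackddm:::flat_draws(f1$draws)
  sup <- par_support(spec$par_names)
  expect_true(all(t(fd) > sup$lower & t(fd) < sup$upper))
  expect_equal(length(f1$rhat), spec$n_free)
})

test_that("MAP estimate maximizes the retained log-posterior", {
  spec <- model_spec("drift-fixed")
  dat <- make_small_data(n_trials = 128, seed = 4, spec = spec)
  fit <- fit_subject(dat$trials, spec, config = tiny_config(seed = 2))
  m <- map_estimate(fit)
  lp_m <- log_posterior(m, dat$trials, spec, fit$priors)
  expect_gte(lp_m + 1e-8, max(fit$lp))
})

test_that("DIC satisfies its defining identities", {
  spec <- model_spec("drift-fixed")
  dat <- make_small_data(n_trials = 128, seed = 5, spec = spec)
  fit <- fit_subject(dat$trials, spec, config = tiny_config(seed = 3))
  d <- dic(fit)
  expect_equal(d$dic, d$dbar + d$pd)                      # identity
  expect_equal(d$dbar, mean(-2 * fit$ll))                 # recomputed
  # D(theta_bar) recomputed independently through log_posterior arithmetic
  theta_bar <- colMeans(refbackddm:::flat_draws(fit$draws))
  ll_bar <- log_posterior(theta_bar, dat$trials, spec, fit$priors) -
    sum(dtnorm(theta_bar, fit$priors$mean, fit$priors$sd, fit$priors$lower,
               fit$priors$upper, log = TRUE))
  expect_equal(d$pd, d$dbar - (-2 * ll_bar), tolerance = 1e-6)
  # difference of a model with itself is zero
  expect_equal(d$dic - dic(fit)$dic, 0)
})

test_that("convergence gate refuses high R-hat unless overridden", {
  fake <- structure(list(rhat = c(a = 1.5)), class = "ddm_fit")
  expect_error(check_convergence(fake), "R-hat")
  expect_warning(check_convergence(fake, override = TRUE), "proceeding")
  ok <- structure(list(rhat = c(a = 1.02)), class = "ddm_fit")
  expect_silent(check_convergence(ok))
})

test_that("hierarchical fit returns linked group and subject draws and shrinks", {
  spec <- model_spec("top")
  g <- default_group_model(spec)
  dat <- make_small_data(n_subjects = 4, n_trials = 256, seed = 6, group = g)
  cfg <- sampler_config(n_chains = 24, n_iter = 80, n_burn = 120, seed = 5)
  hf <- fit_hierarchical(dat$trials, spec, config = cfg)
  expect_s3_class(hf, "ddm_hfit")
  expect_equal(dim(hf$mu), c(24, 80, spec$n_free))
  expect_equal(dim(hf$phi), c(24, 80, 4, spec$n_free))
  expect_equal(dimnames(hf$mu)[[3]], spec$par_names)
  expect_error(fit_hierarchical(dat$trials[dat$trials$subject == 1, ], spec,
                                config = cfg), ">= 2 subjects")

  # shrinkage: between-subject variance of hierarchical posterior means
  # no larger (on average over parameters) than of non-hierarchical means
  nh <- sapply(1:4, function(s) {
    f <- fit_subject(dat$trials[dat$trials$subject == s, ], spec,
                     config = sampler_config(n_chains = 24, n_iter = 80,
                                             n_burn = 120, seed = 10 + s))
    colMeans(refbackddm:::flat_draws(f$draws))
  })
  hm <- t(subject_means(hf))
  v_idx <- grep("^(v|t0)", spec$par_names)
  shrink <- apply(hm[v_idx, ], 1, var) / pmax(apply(nh[v_idx, ], 1, var), 1e-12)
  expect_lt(median(shrink), 1)
})

test_that("model selection table partitions subjects and counts parameters", {
  spec <- model_spec("drift-fixed")
  dat <- make_small_data(n_subjects = 3, n_trials = 128, seed = 7,
                         spec = spec, group = default_group_model(spec))
  sel <- select_models(dat$trials, variants = c("top", "drift-fixed"),
                       config = tiny_config(seed = 1))
  expect_equal(sum(sel$n), 3)
  expect_equal(sum(sel$pct), 100, tolerance = 0.2)
  expect_equal(sel$n_parameters,
               c(model_spec("top")$n_free, model_spec("drift-fixed")$n_free))
  expect_equal(sel$delta_dic[sel$variant == "top"], 0)
  dicm <- attr(sel, "dic")
  expect_equal(dim(dicm), c(3, 2))
  expect_error(select_models(dat$trials, variants = "top"), "two variants")
})
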