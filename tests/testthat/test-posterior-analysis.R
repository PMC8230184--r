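# Effect posteriors (Bayesian p, Z), posterior predictive checks, the
# recovery report, and individual-difference correlations.

fake_mu_draws <- function(n = 4000, v_ref = 2, v_comp = 2, seed = 1) {
  set.seed(seed)
  spec <- model_spec("top")
  mu <- matrix(NA_real_, n, spec$n_free,
               dimnames = list(NULL, spec$par_names))
  for (p in spec$par_names) {
    base <- switch(sub("\\..*$", "", p), v = 2, t0 = 0.35, a = 1.25,
                   z = 0.5, sz = 0.15, sv = 0.8)
    if (grepl("^v\\.ref", p)) base <- v_ref
    if (grepl("^v\\.comp", p)) base <- v_comp
    mu[, p] <- rnorm(n, base, 0.1)
  }
  mu
}

test_that("effect summaries obey the p and Z conventions", {
  # degenerate contrast: identical cells in every draw -> p 0.5, Z 0
  mu <- fake_mu_draws()
  mu[, 1:8] <- 2  # all drift cells equal, zero variance in the contrast
  e0 <- effect_posterior(mu, "updating", "v")
  expect_equal(e0$p, 0.5)
  expect_equal(e0$z, 0)
  expect_equal(e0$mean, 0)

  # p <= 0.5 always, for arbitrary contrasts and parameters
  for (s in 1:5) {
    mu <- fake_mu_draws(n = 500, v_ref = runif(1, 1, 3),
                        v_comp = runif(1, 1, 3), seed = s)
    for (m in rownames(cost_weights())) {
      expect_lte(effect_posterior(mu, m, "v")$p, 0.5)
    }
    e <- effect_posterior(mu, "updating", "t0")
    expect_equal(e$z, e$mean / e$sd)
    expect_equal(length(e$ci), 2)
    expect_true(e$ci[1] <= median(e$draws) && median(e$draws) <= e$ci[2])
  }

  # a planted hyper-mean drift deficit shows as a negative updating effect
  mu <- fake_mu_draws(n = 4000, v_ref = 1.5, v_comp = 2.5, seed = 3)
  ev <- effect_posterior(mu, "updating", "v")
  expect_lt(ev$mean, 0)
  expect_lt(ev$p, 0.01)
  # threshold contrast uses a.ref - a.comp
  mu[, "a.ref"] <- mu[, "a.ref"] + 0.3
  ea <- effect_posterior(mu, "updating", "a")
  expect_gt(ea$mean, 0.2)
  expect_error(effect_posterior(mu, "bogus", "v"), "unknown contrast")
})

test_that("posterior predictions cover self-generated data", {
  spec <- model_spec("top")
  g <- default_group_model(spec)
  simd <- simulate_dataset(g, spec, n_subjects = 4, n_trials = 256,
                           n_blocks = 2, seed = 17)
  cl <- clean_trials(simd$trials)
  cfg <- sampler_config(n_chains = 24, n_iter = 100, n_burn = 150, seed = 6)
  hf <- fit_hierarchical(cl$trials, spec, config = cfg)
  ppc <- posterior_predictive(hf, simd$trials, n_reps = 40, seed = 2,
                              check_convergence = FALSE)
  expect_s3_class(ppc, "ddm_ppc")
  # intervals contain their medians, and most observed summaries
  expect_true(all(ppc$cells$lo <= ppc$cells$median + 1e-12))
  expect_true(all(ppc$cells$hi >= ppc$cells$median - 1e-12))
  inside <- with(ppc$cells, observed >= lo & observed <= hi)
  expect_gt(mean(inside), 0.7)   # loose structural bound at this tiny size
  expect_equal(nrow(ppc$costs), 12)
  expect_equal(ppc$n_reps, 40)
  # the convergence gate is wired in
  expect_error(posterior_predictive(
    structure(list(rhat = 2), class = "ddm_hfit"), simd$trials), "R-hat")
})

test_that("recovery report covers every free parameter", {
  spec <- model_spec("drift-fixed")
  rec <- recovery_study(spec, default_group_model(spec), n_subjects = 2,
                        n_trials = 128, n_blocks = 2,
                        config = tiny_config(seed = 4), seed = 9)
  expect_setequal(unique(rec$estimates$parameter), spec$par_names)
  expect_equal(nrow(rec$estimates), 2 * spec$n_free)
  expect_setequal(rec$summary$family, c("v", "t0", "a", "z", "sz", "sv"))
  expect_true(all(is.finite(rec$estimates$est)))
})

test_that("individual-difference correlations behave on toy vectors", {
  eff <- data.frame(subject = 1:6, v.updating = c(1, 2, 3, 4, 5, 6))
  costs <- data.frame(subject = 1:6,
                      rt.updating = 2 * c(1, 2, 3, 4, 5, 6) + 1,
                      acc.updating = c(2, 1, 4, 3, 6, 5))
  r <- individual_difference_correlations(eff, costs, outlier_z = Inf)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["v.updating", "rt.updating"], 1)
  expect_equal(r, t(r))
  expect_error(individual_difference_correlations(eff[1:2, ], costs), "3 subjects")

  # outlier exclusion knocks out a planted extreme value
  eff2 <- eff; eff2$v.updating[6] <- 100
  r2 <- individual_difference_correlations(eff2, costs, outlier_z = 2)
  expect_gt(attr(r2, "n_excluded"), 0)
})

test_that("MAP effects carry the contrast algebra per subject", {
  spec <- model_spec("top")
  g <- flat_group_model(spec, updating_v = -1)
  dat <- simulate_dataset(g, spec, n_subjects = 2, n_trials = 128,
                          n_blocks = 2, seed = 12)
  cl <- clean_trials(dat$trials)
  fits <- lapply(1:2, function(s)
    fit_subject(cl$trials[cl$trials$subject == s, ], spec,
                config = tiny_config(seed = 20 + s)))
  names(fits) <- 1:2
  me <- map_effects(fits)
  expect_equal(nrow(me), 2)
  expect_true(all(c("v.updating", "t0.substitution", "a.updating") %in% names(me)))
  # algebra check against the MAP vector directly
  th <- map_estimate(fits[[1]])
  W <- cost_weights()
  expect_equal(me$v.updating[1], sum(W["updating", ] * th[spec$v_idx]))
})
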