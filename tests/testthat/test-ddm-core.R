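# The diffusion core: parameter validation, first-passage density against a
# brute-force simulation oracle, absorption probabilities, defective CDF
# against numerical integration, and the simulator's distributional accuracy.

test_that("parameter validation enforces the scaling and support constraints", {
  expect_s3_class(ddm_params(v = 1, a = 1), "ddm_params")
  expect_error(ddm_params(v = 1, a = 0), "boundary")
  expect_error(ddm_params(v = 1, a = 1, z = 1), "start point")
  expect_error(ddm_params(v = 1, a = 1, t0 = -0.1), "non-decision")
  expect_error(ddm_params(v = 1, a = 1, sv = -1), "sv")
  expect_error(ddm_params(v = 1, a = 1, z = 0.1, sz = 0.3), "z \\+/- sz/2")
  expect_error(ddm_params(v = 1, a = 1, dc = 0.5), "drift criterion")
  expect_error(ddm_params(v = 1, a = 1, st0 = 0.1), "st0")
})

test_that("density is zero before non-decision time and symmetric when unbiased", {
  p <- ddm_params(v = 1, a = 1, z = 0.5, t0 = 0.3)
  expect_equal(ddm_density(p$t0 - 0.01, "upper", p), 0)
  expect_equal(ddm_density(p$t0 - 0.01, "lower", p), 0)
  expect_error(ddm_density(Inf, "upper", p), "finite")

  p0 <- ddm_params(v = 0, a = 1.2, z = 0.5, t0 = 0.2)
  ts <- seq(0.25, 2, by = 0.05)
  expect_equal(ddm_density(ts, "upper", p0), ddm_density(ts, "lower", p0))
})

test_that("density matches a naive Euler simulation histogram", {
  # independent oracle: plain-R Euler-Maruyama at dt = 1e-4, no bridge
  p <- ddm_params(v = 1, a = 1, z = 0.5, t0 = 0.3, sv = 0, sz = 0)
  sim <- naive_euler_sim(p, 3e4, dt = 1e-4, seed = 99)
  up <- sim$rt[sim$boundary == "upper"]
  breaks <- c(0.35, 0.45, 0.55, 0.7, 0.9, 1.3)
  for (i in seq_len(length(breaks) - 1)) {
    mass <- ddm_cdf(breaks[i + 1], "upper", p) - ddm_cdf(breaks[i], "upper", p)
    obs <- mean(sim$boundary == "upper" & sim$rt > breaks[i] &
                  sim$rt <= breaks[i + 1])
    se <- sqrt(mass * (1 - mass) / nrow(sim))
    expect_lt(abs(obs - mass), 4 * se + 0.003)
  }
  # point check: histogram density estimate at t = 0.5
  d_at <- ddm_density(0.5, "upper", p)
  est <- mean(sim$boundary == "upper" & sim$rt > 0.48 & sim$rt <= 0.52) / 0.04
  expect_lt(abs(est - d_at) / d_at, 0.2)
})

test_that("absorption probabilities are conserved and match simulation", {
  p0 <- ddm_params(v = 0, a = 1, z = 0.5)
  expect_equal(ddm_boundary_prob("upper", p0), 0.5)
  for (p in list(ddm_params(v = 2, a = 1, z = 0.5),
                 ddm_params(v = -1, a = 1.5, z = 0.35, sv = 1.2, sz = 0.2),
                 ddm_params(v = 0.8, a = 2, z = 0.6, sv = 0.5))) {
    expect_equal(ddm_boundary_prob("upper", p) + ddm_boundary_prob("lower", p),
                 1, tolerance = 1e-10)
  }
  p <- ddm_params(v = 2, a = 1, z = 0.5)
  sim <- ddm_simulate(p, 1e5, seed = 7)
  pu <- ddm_boundary_prob("upper", p)
  se <- sqrt(pu * (1 - pu) / 1e5)
  expect_lt(abs(mean(sim$boundary == "upper") - pu), 3 * se)
})

test_that("defective CDF integrates the density", {
  p <- ddm_params(v = 1.2, a = 1.3, z = 0.45, t0 = 0.25, sv = 0.8, sz = 0.2)
  expect_equal(ddm_cdf(p$t0, "upper", p), 0)
  expect_equal(ddm_cdf(Inf, "upper", p), ddm_boundary_prob("upper", p))
  for (t in c(0.4, 0.7, 1.2)) {
    ref <- integrate(function(u) ddm_density(u, "upper", p), p$t0, t,
                     rel.tol = 1e-8)$value
    expect_equal(ddm_cdf(t, "upper", p), ref, tolerance = 1e-4)
  }
  ts <- seq(0.3, 2.5, by = 0.1)
  expect_true(all(diff(ddm_cdf(ts, "lower", p)) >= 0))
})

test_that("density normalizes to one across parameter sets", {
  grid <- list(ddm_params(v = 1, a = 1, z = 0.5, t0 = 0.3),
               ddm_params(v = 3, a = 0.8, z = 0.6, t0 = 0.4, sv = 0.5, sz = 0.3),
               ddm_params(v = -1.5, a = 1.5, z = 0.35, t0 = 0.25, sv = 1.5, sz = 0.1),
               ddm_params(v = 0.5, a = 2, z = 0.4, t0 = 0.2, sv = 1, sz = 0.2))
  for (p in grid) {
    tot <- integrate(function(t) ddm_density(t, "upper", p), p$t0, Inf)$value +
      integrate(function(t) ddm_density(t, "lower", p), p$t0, Inf)$value
    expect_equal(tot, 1, tolerance = 1e-4)
  }
})

test_that("simulated RT distributions agree with the analytic CDF", {
  p <- ddm_params(v = 1.5, a = 1.4, z = 0.45, t0 = 0.25, sv = 1.2, sz = 0.25)
  sim <- ddm_simulate(p, 1e5, seed = 11)
  expect_gt(min(sim$rt), p$t0)
  up <- sim$rt[sim$boundary == "upper"]
  expect_lt(ks_distance(up, p, "upper"), 0.01)
  # reproducible given seed
  sim2 <- ddm_simulate(p, 100, seed = 5)
  sim3 <- ddm_simulate(p, 100, seed = 5)
  expect_identical(sim2, sim3)
  expect_error(ddm_simulate(p, 0), "count")
})

test_that("shifting t0 shifts RTs additively without touching accuracy", {
  p1 <- ddm_params(v = 1.2, a = 1.1, z = 0.45, t0 = 0.3, sv = 0.5, sz = 0.1)
  p2 <- ddm_params(v = 1.2, a = 1.1, z = 0.45, t0 = 0.45, sv = 0.5, sz = 0.1)
  ts <- seq(0.35, 2, by = 0.05)
  expect_equal(ddm_density(ts, "upper", p1), ddm_density(ts + 0.15, "upper", p2))
  expect_equal(ddm_boundary_prob("upper", p1), ddm_boundary_prob("upper", p2))
  s1 <- ddm_simulate(p1, 2000, seed = 3)
  s2 <- ddm_simulate(p2, 2000, seed = 3)
  expect_equal(s2$rt, s1$rt + 0.15)
  expect_identical(s1$boundary, s2$boundary)
})

test_that("drift and threshold move accuracy and speed as they should", {
  # upper = correct response; median decision time from the normalized CDF
  med_rt <- function(p) {
    f <- function(t) ddm_cdf(t, "upper", p) / ddm_boundary_prob("upper", p) - 0.5
    uniroot(f, c(p$t0 + 1e-4, 20))$root
  }
  base <- ddm_params(v = 1, a = 1.2, z = 0.5, t0 = 0.3)
  fastv <- ddm_params(v = 2.5, a = 1.2, z = 0.5, t0 = 0.3)
  expect_gt(ddm_boundary_prob("upper", fastv), ddm_boundary_prob("upper", base))
  expect_lt(med_rt(fastv), med_rt(base))
  wide <- ddm_params(v = 1, a = 2, z = 0.5, t0 = 0.3)
  expect_gt(ddm_boundary_prob("upper", wide), ddm_boundary_prob("upper", base))
  expect_gt(med_rt(wide), med_rt(base))
})

test_that("log-likelihood sums per-trial log densities and is additive", {
  p1 <- ddm_params(v = 2, a = 1.2, z = 0.5, t0 = 0.3, sv = 0.6, sz = 0.1)
  p8 <- lapply(design_cells()$label, function(l)
    ddm_params(v = 2, a = 1.2, z = 0.5, t0 = 0.3, sv = 0.6, sz = 0.1))
  names(p8) <- design_cells()$label
  one <- toy_trials(0.55, cells = 3L)
  d <- ddm_density(0.55, if (one$response == "same") "upper" else "lower", p1)
  expect_equal(log_likelihood(one, p8), log(d))

  set.seed(8)
  A <- toy_trials(runif(6, 0.4, 1.2), cells = rep(1:3, 2))
  B <- toy_trials(runif(4, 0.4, 1.2), cells = rep(4:5, 2))
  expect_equal(log_likelihood(rbind(A, B), p8),
               log_likelihood(A, p8) + log_likelihood(B, p8))
  # independent oracle: per-trial densities summed in R
  ref <- sum(log(pmax(vapply(seq_len(nrow(A)), function(i)
    ddm_density(A$rt[i], ifelse(A$response[i] == "same", "upper", "lower"),
                p8[[A$cell[i]]]), numeric(1)), 1e-10)))
  expect_equal(log_likelihood(A, p8), ref)
  expect_error(log_likelihood(toy_trials(-0.2), p8), "rt")
  expect_error(log_likelihood(one, p8["ref.ns.same"]), "missing cell")
})

test_that("generating parameters beat distorted parameters in likelihood", {
  spec <- model_spec("top")
  g <- default_group_model(spec)
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    simd <- simulate_dataset(g, spec, n_subjects = 1, seed = 100 + r)
    cl <- clean_trials(simd$trials)
    th <- simd$subject_params[1, ]
    th2 <- th
    th2[grep("^v", names(th2))] <- pmin(th2[grep("^v", names(th2))] * 2, 9.9)
    tgt <- refbackddm:::make_target(cl$trials, spec, function(x) rep(0, ncol(x)))
    lls <- tgt(cbind(th, th2))$ll
    wins <- wins + (lls[1] > lls[2])
  }
  expect_gte(wins / n_rep, 0.95)
})
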