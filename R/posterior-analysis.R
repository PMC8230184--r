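# Posterior inference on cost effects, posterior predictive checks, the
# parameter-recovery study, and individual-difference correlations.

bayes_p <- function(draws) {
  if (all(draws == 0)) return(0.5)
  p0 <- mean(draws == 0) / 2
  min(mean(draws < 0) + p0, mean(draws > 0) + p0)
}

#' Posterior distribution of a canonical cost effect on a parameter
#'
#' Applies the contrast algebra of the six cost measures (see
#' [cost_weights()]) to the hyper-mean draws of a parameter family, per
#' posterior sample: e.g. the updating drift effect is the difference in
#' hyper-mean drift magnitude between repeated reference and repeated
#' comparison cells, computed draw by draw. For the threshold the contrast is
#' hyper-mean a(reference) minus a(comparison). Reported are the posterior
#' mean M, SD, the standardized magnitude Z = M/SD, the one-tailed Bayesian
#' p-value (posterior probability that the effect does not run in its most
#' sampled direction; draws at zero split evenly; degenerate all-zero
#' contrasts report p = 0.5 and Z = 0 by convention), and the equal-tailed
#' 95% credible interval.
#'
#' @param hfit a `ddm_hfit` from [fit_hierarchical()] (or a draws matrix with
#'   hyper-mean columns named as in the model spec).
#' @param contrast one of the six measure names in [cost_weights()]; ignored
#'   for `parameter = "a"` (the reference-vs-comparison shift).
#' @param parameter `"v"`, `"t0"` or `"a"`.
#' @param check_convergence gate on group-level R-hat (see
#'   [check_convergence()]).
#' @param override proceed despite R-hat above the gate.
#' @return object of class `ddm_effect`.
#' @export
effect_posterior <- function(hfit, contrast, parameter = c("v", "t0", "a"),
                             check_convergence = TRUE, override = FALSE) {
  parameter <- match.arg(parameter)
  if (inherits(hfit, "ddm_hfit")) {
    if (check_convergence) check_convergence(hfit, override = override)
    mu <- flat_draws(hfit$mu)
    spec <- hfit$spec
  } else {
    mu <- hfit
    spec <- model_spec("top")
  }
  if (parameter == "a") {
    if (!all(c("a.ref", "a.comp") %in% colnames(mu)))
      stop_input("threshold contrast needs separate a.ref and a.comp")
    draws <- mu[, "a.ref"] - mu[, "a.comp"]
    name <- "threshold reference-vs-comparison"
  } else {
    W <- cost_weights()
    if (!contrast %in% rownames(W)) stop_input("unknown contrast: ", contrast)
    idx <- if (parameter == "v") spec$v_idx else spec$t0_idx
    if (length(unique(idx)) == 1)
      stop_input("parameter '", parameter, "' has no cell effects in variant '",
                 spec$variant, "'")
    cells <- mu[, idx, drop = FALSE]
    draws <- as.numeric(cells %*% W[contrast, ])
    name <- paste(contrast, parameter, "effect")
  }
  m <- mean(draws); s <- sd(draws)
  structure(list(name = name, contrast = if (parameter == "a") "updating" else contrast,
                 parameter = parameter, draws = draws, mean = m, sd = s,
                 z = if (s > 0) m / s else 0, p = bayes_p(draws),
                 ci = unname(quantile(draws, c(0.025, 0.975)))),
            class = "ddm_effect")
}

#' @export
print.ddm_effect <- function(x, ...) {
  cat(sprintf("%s: M = %.4f, SD = %.4f, Z = %.2f, p = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$name, x$mean, x$sd, x$z, x$p, x$ci[1], x$ci[2]))
  invisible(x)
}

# simulate one predictive replicate of a dataset design from per-subject
# parameter vectors (rows of theta_mat aligned with `subjects`)
simulate_design <- function(trials, spec, theta_mat, subjects) {
  out <- trials
  for (i in seq_along(subjects)) {
    idx <- which(trials$subject == subjects[i] & !is.na(trials$cell))
    cp <- theta_to_cells(spec, theta_mat[i, ])
    cl <- trials$cell[idx]
    sim <- ddm_sim_cpp(length(idx), cp$V[cl, 1], cp$A[cl, 1],
                       rep(cp$Z, length(idx)), cp$T0[cl, 1],
                       rep(cp$SV, length(idx)), rep(cp$SZ, length(idx)))
    out$response[idx] <- ifelse(sim$upper, "same", "different")
    out$rt[idx] <- sim$rt
  }
  out$correct <- ifelse(out$response %in% c("same", "different"),
                        out$response == out$correct_answer, NA)
  out
}

#' Posterior predictive check
#'
#' Samples `n_reps` joint posterior predictions: for each replicate one
#' retained posterior draw per subject, a simulation of that subject's own
#' trial design, and the identical empirical summary pipeline
#' ([clean_trials()], [cell_summary()], [canonical_costs()]) that is applied
#' to the observed data — predictions and observations share one code path.
#' Credible intervals are equal-tailed 2.5/97.5 percentiles over replicates.
#'
#' @param hfit a `ddm_hfit`.
#' @param trials the observed annotated trials the model was fit to.
#' @param n_reps posterior predictive replicates (default 100 per subject).
#' @param seed optional integer seed.
#' @param check_convergence,override convergence gate as in
#'   [effect_posterior()].
#' @return list of class `ddm_ppc` with elements `cells` (per cell and
#'   statistic: observed value, predictive median and 95% interval) and
#'   `costs` (the same for the six cost measures, RT and accuracy).
#' @export
posterior_predictive <- function(hfit, trials, n_reps = 100, seed = NULL,
                                 check_convergence = TRUE, override = FALSE) {
  if (check_convergence) check_convergence(hfit, override = override)
  if (!is.null(seed)) set.seed(seed)
  cl <- clean_trials(trials)
  obs_sum <- cell_summary(cl$trials)
  obs_costs <- canonical_costs(obs_sum)
  subjects <- hfit$subjects
  K <- dim(hfit$phi)[1]; Ti <- dim(hfit$phi)[2]
  stats <- c("accuracy", "mean_rt", "q10", "q50", "q90")
  cell_rep <- array(NA_real_, c(n_reps, 8, length(stats)),
                    dimnames = list(NULL, design_cells()$label, stats))
  rt_rep <- matrix(NA_real_, n_reps, 6)
  ac_rep <- matrix(NA_real_, n_reps, 6)
  colnames(rt_rep) <- colnames(ac_rep) <- rownames(cost_weights())
  design <- trials[trials$subject %in% subjects, ]
  for (r in seq_len(n_reps)) {
    th <- t(vapply(seq_along(subjects), function(i)
      hfit$phi[sample.int(K, 1), sample.int(Ti, 1), i, ], numeric(length(hfit$pnames))))
    sim <- simulate_design(design, hfit$spec, th, subjects)
    scl <- clean_trials(sim)
    ssum <- cell_summary(scl$trials)
    cc <- canonical_costs(ssum)
    for (st in stats) cell_rep[r, , st] <- ssum$group[[st]]
    rt_rep[r, cc$measure] <- cc$rt_cost
    ac_rep[r, cc$measure] <- cc$acc_cost
  }
  qs <- function(x) quantile(x, c(0.025, 0.5, 0.975), na.rm = TRUE)
  cells <- do.call(rbind, lapply(seq_len(8), function(ci) {
    do.call(rbind, lapply(stats, function(st) {
      q <- qs(cell_rep[, ci, st])
      data.frame(cell = ci, label = design_cells()$label[ci], stat = st,
                 observed = obs_sum$group[[st]][obs_sum$group$cell == ci],
                 lo = q[1], median = q[2], hi = q[3],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
  costs <- do.call(rbind, lapply(rownames(cost_weights()), function(m) {
    qr <- qs(rt_rep[, m]); qa <- qs(ac_rep[, m])
    rbind(data.frame(measure = m, type = "rt",
                     observed = obs_costs$rt_cost[obs_costs$measure == m],
                     lo = qr[1], median = qr[2], hi = qr[3], row.names = NULL),
          data.frame(measure = m, type = "accuracy",
                     observed = obs_costs$acc_cost[obs_costs$measure == m],
                     lo = qa[1], median = qa[2], hi = qa[3], row.names = NULL))
  }))
  structure(list(cells = cells, costs = costs, n_reps = n_reps),
            class = "ddm_ppc")
}

#' Parameter-recovery study
#'
#' Simulates a dataset from known group parameters, refits it, and reports
#' true-vs-recovered subject-level estimates with Pearson r (pooled over
#' subjects and, for cell-varying families, cells), mean signed error, and
#' the fraction of generating values within 2 posterior SDs of the posterior
#' mean. By default the refit is the fully hierarchical model (the same
#' estimator used for group-level inference, whose shrinkage stabilizes
#' subject-level estimates); set `hierarchical = FALSE` for independent
#' per-subject fits.
#'
#' @param spec a [model_spec()].
#' @param group a [group_model()] of generating hyper-parameters.
#' @param n_subjects,n_trials,n_blocks simulated study size.
#' @param priors fitting priors.
#' @param config a [sampler_config()]; per-subject seeds derive from it.
#' @param seed master seed for data generation.
#' @param hierarchical fit the hierarchical model (default) or per-subject?
#' @return object of class `ddm_recovery`: list with `estimates` (subject,
#'   parameter, true, est, sd, family) and `summary` (per family: r,
#'   mean signed error, 2-SD coverage).
#' @export
recovery_study <- function(spec = model_spec("top"),
                           group = default_group_model(spec),
                           n_subjects = 20, n_trials = 512, n_blocks = 4,
                           priors = default_priors(spec),
                           config = sampler_config(), seed = 1L,
                           hierarchical = TRUE) {
  simd <- simulate_dataset(group, spec, n_subjects, n_trials, n_blocks,
                           seed = seed)
  cl <- clean_trials(simd$trials)
  rows <- vector("list", n_subjects)
  if (hierarchical) {
    hf <- fit_hierarchical(cl$trials, spec, priors, config)
    pm <- apply(hf$phi, c(3, 4), mean)
    ps <- apply(hf$phi, c(3, 4), sd)
    for (s in seq_len(n_subjects)) {
      rows[[s]] <- data.frame(subject = s, parameter = spec$par_names,
                              true = as.numeric(simd$subject_params[s, ]),
                              est = pm[s, ], sd = ps[s, ],
                              stringsAsFactors = FALSE, row.names = NULL)
    }
  } else {
    for (s in seq_len(n_subjects)) {
      cfg <- config
      cfg$seed <- config$seed + 7919L * s
      fit <- fit_subject(cl$trials[cl$trials$subject == s, ], spec, priors, cfg)
      fd <- flat_draws(fit$draws)
      rows[[s]] <- data.frame(subject = s, parameter = spec$par_names,
                              true = as.numeric(simd$subject_params[s, ]),
                              est = colMeans(fd), sd = apply(fd, 2, sd),
                              stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  est <- do.call(rbind, rows)
  est$family <- sub("\\..*$", "", est$parameter)
  summ <- do.call(rbind, lapply(unique(est$family), function(f) {
    d <- est[est$family == f, ]
    data.frame(family = f, n = nrow(d),
               r = if (sd(d$true) > 0) cor(d$true, d$est) else NA_real_,
               mean_signed_error = mean(d$est - d$true),
               coverage_2sd = mean(abs(d$est - d$true) <= 2 * d$sd),
               row.names = NULL)
  }))
  structure(list(estimates = est, summary = summ, spec = spec, group = group,
                 seed = seed),
            class = "ddm_recovery")
}

#' @export
print.ddm_recovery <- function(x, ...) {
  cat("Parameter recovery:\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Per-subject MAP parameter effects
#'
#' Applies the cost-contrast algebra to each subject's maximum a posteriori
#' estimate from a non-hierarchical fit (no shrinkage), yielding the
#' subject-level drift, non-decision-time and threshold effects used in
#' individual-difference analyses.
#'
#' @param fits named list of `ddm_fit` objects (names = subject ids), all of
#'   a variant with cell-varying drift and non-decision time.
#' @return data frame: subject plus one column per effect
#'   (`v.<measure>`, `t0.<measure>`, `a.updating`).
#' @export
map_effects <- function(fits) {
  W <- cost_weights()
  out <- lapply(names(fits), function(s) {
    fit <- fits[[s]]
    th <- map_estimate(fit)
    spec <- fit$spec
    row <- list(subject = s)
    v_cells <- th[spec$v_idx]
    t_cells <- th[spec$t0_idx]
    for (m in rownames(W)) {
      row[[paste0("v.", m)]] <- sum(W[m, ] * v_cells)
      row[[paste0("t0.", m)]] <- sum(W[m, ] * t_cells)
    }
    row[["a.updating"]] <- if (all(c("a.ref", "a.comp") %in% names(th)))
      th[["a.ref"]] - th[["a.comp"]] else NA_real_
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Individual-difference correlations
#'
#' Pearson correlations between subject-level MAP parameter effects and
#' empirical cost measures, with optional univariate outlier exclusion
#' (|z-score| above `outlier_z` on any variable sets that value to missing;
#' exclusions are recorded in the `"n_excluded"` attribute). Correlations use
#' pairwise-complete observations.
#'
#' @param effects data frame from [map_effects()] (column `subject` plus
#'   numeric effect columns).
#' @param costs data frame with column `subject` plus numeric cost columns
#'   (e.g. reshaped from [canonical_costs()]'s by-subject attribute).
#' @param outlier_z z-score threshold; `Inf` disables exclusion.
#' @return correlation matrix over all effect and cost variables.
#' @export
individual_difference_correlations <- function(effects, costs, outlier_z = 3) {
  d <- merge(effects, costs, by = "subject")
  if (nrow(d) < 3) stop_input("need at least 3 subjects")
  num <- d[, setdiff(names(d), "subject"), drop = FALSE]
  n_excl <- 0L
  if (is.finite(outlier_z)) {
    for (j in seq_along(num)) {
      x <- num[[j]]
      z <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
      bad <- !is.na(z) & abs(z) > outlier_z
      n_excl <- n_excl + sum(bad)
      num[[j]][bad] <- NA
    }
  }
  out <- cor(num, use = "pairwise.complete.obs")
  attr(out, "n_excluded") <- n_excl
  out
}
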