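# Truncated-normal helpers. These are thin compositions of pnorm/qnorm kept
# internal to the package; the truncation bounds always equal the parameter's
# support so that priors and population distributions share one family.

#' Truncated-normal density
#'
#' @param x quantiles (vector or matrix; recycled elementwise with the
#'   other arguments).
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds.
#' @param log return log density?
#' @return density values; 0 (or -Inf) outside \[lower, upper\].
#' @export
dtnorm <- function(x, mean = 0, sd = 1, lower = -Inf, upper = Inf, log = FALSE) {
  lz <- pnorm(lower, mean, sd)
  uz <- pnorm(upper, mean, sd)
  ld <- dnorm(x, mean, sd, log = TRUE) - log(pmax(uz - lz, 1e-300))
  ld[x < lower | x > upper] <- -Inf
  if (log) ld else exp(ld)
}

#' Truncated-normal random draws (inverse-CDF method)
#'
#' @param n number of draws.
#' @inheritParams dtnorm
#' @return numeric vector of draws inside \[lower, upper\].
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop_input("sd must be >= 0")
  lz <- pnorm(lower, mean, sd)
  uz <- pnorm(upper, mean, sd)
  u <- runif(n, lz, uz)
  x <- qnorm(u, mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Mean of a truncated normal
#'
#' Closed-form first moment, used as an analytic oracle for the synthetic
#' population model.
#'
#' @inheritParams dtnorm
#' @return the expectation of the truncated distribution.
#' @export
etnorm <- function(mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# parameter support by name prefix (shared by priors, model specs, groups)
par_support <- function(names) {
  pre <- sub("\\..*$", "", names)
  lower <- c(v = 0, t0 = 0.05, a = 0.1, z = 0.05, sz = 0, sv = 0)[pre]
  upper <- c(v = 10, t0 = 1, a = 5, z = 0.95, sz = 0.9, sv = 5)[pre]
  list(lower = unname(lower), upper = unname(upper))
}

#' Default priors for a model specification
#'
#' Independent truncated-normal priors over each free parameter, with
#' truncation at the parameter's support: drift magnitudes N(2, 3) on (0, 10),
#' thresholds N(1.5, 1) on (0.1, 5), start point N(0.5, 0.2) on (0.05, 0.95),
#' non-decision time N(0.3, 0.2) on (0.05, 1), drift variability N(1, 1) on
#' (0, 5) and start-point variability N(0.2, 0.2) on (0, 0.9). These are
#' deliberately weakly informative defaults and are fully configurable.
#'
#' @param spec a [model_spec()].
#' @return data frame with columns name, mean, sd, lower, upper.
#' @export
default_priors <- function(spec) {
  nm <- spec$par_names
  pre <- sub("\\..*$", "", nm)
  mean <- c(v = 2, t0 = 0.3, a = 1.5, z = 0.5, sz = 0.2, sv = 1)[pre]
  sd <- c(v = 3, t0 = 0.2, a = 1, z = 0.2, sz = 0.2, sv = 1)[pre]
  sup <- par_support(nm)
  data.frame(name = nm, mean = unname(mean), sd = unname(sd),
             lower = sup$lower, upper = sup$upper,
             stringsAsFactors = FALSE)
}

# summed log prior density for a theta matrix (n_free x K); -Inf outside support
log_prior_mat <- function(theta, priors) {
  ld <- dtnorm(theta, priors$mean, priors$sd, priors$lower, priors$upper,
               log = TRUE)
  if (is.matrix(theta)) colSums(ld) else sum(ld)
}
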