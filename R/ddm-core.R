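#' Diffusion-model parameter set for one design cell
#'
#' Bundles the parameters of the diffusion decision model (DDM) with the
#' conventions used throughout this package: diffusion coefficient s = 1
#' (modern scaling), relative start point z in (0, 1) measured from the lower
#' boundary, uniform start-point variability sz expressed as a fraction of the
#' boundary separation, and Gaussian across-trial drift variability sv. Drift
#' criterion and non-decision-time variability are fixed at zero to satisfy
#' the scaling constraint of evidence-accumulation models and are rejected if
#' set otherwise.
#'
#' @param v drift rate (evidence units per second, signed toward the upper
#'   boundary).
#' @param a boundary separation (> 0).
#' @param z relative start point, fraction of `a` in (0, 1).
#' @param t0 non-decision time in seconds (>= 0).
#' @param sv standard deviation of across-trial drift variability (>= 0).
#' @param sz width of uniform across-trial start-point variability, as a
#'   fraction of `a`; `z - sz/2 > 0` and `z + sz/2 < 1` are required.
#' @param dc drift criterion; must be 0.
#' @param st0 non-decision-time variability; must be 0.
#' @return an object of class `ddm_params`.
#' @examples
#' p <- ddm_params(v = 2, a = 1.2, z = 0.5, t0 = 0.3)
#' ddm_boundary_prob("upper", p)
#' @export
ddm_params <- function(v, a, z = 0.5, t0 = 0.3, sv = 0, sz = 0,
                       dc = 0, st0 = 0) {
  vals <- c(v = v, a = a, z = z, t0 = t0, sv = sv, sz = sz)
  if (any(!is.finite(vals))) stop_input("DDM parameters must be finite")
  if (a <= 0) stop_input("boundary separation a must be > 0")
  if (z <= 0 || z >= 1) stop_input("relative start point z must be in (0, 1)")
  if (t0 < 0) stop_input("non-decision time t0 must be >= 0")
  if (sv < 0) stop_input("drift variability sv must be >= 0")
  if (sz < 0) stop_input("start-point variability sz must be >= 0")
  if (z - sz / 2 <= 0 || z + sz / 2 >= 1)
    stop_input("start-point range z +/- sz/2 must lie strictly inside (0, 1)")
  if (!identical(dc, 0) && !isTRUE(all.equal(dc, 0)))
    stop_input("drift criterion dc is fixed at 0 (scaling constraint)")
  if (!identical(st0, 0) && !isTRUE(all.equal(st0, 0)))
    stop_input("non-decision-time variability st0 is fixed at 0")
  structure(list(v = v, a = a, z = z, t0 = t0, sv = sv, sz = sz,
                 dc = 0, st0 = 0, s = 1),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters (s = 1):\n")
  print(unlist(x[c("v", "a", "z", "t0", "sv", "sz")]))
  invisible(x)
}

check_boundary <- function(boundary) {
  boundary <- match.arg(boundary, c("upper", "lower"))
  boundary
}

#' First-passage-time density of the DDM
#'
#' Defective density of absorption at the given boundary at time `t`
#' (in seconds, including non-decision time). Evaluated with the standard
#' small-time/large-time series under adaptive truncation (target absolute
#' error 1e-8); Gaussian drift variability is marginalized analytically and
#' uniform start-point variability by fixed-order Gauss-Legendre quadrature
#' (order 11). The density is zero for `t <= t0` and integrates over
#' `(t0, Inf)` to [ddm_boundary_prob()].
#'
#' @param t time(s) in seconds; must be finite.
#' @param boundary `"upper"` or `"lower"`.
#' @param p a [ddm_params()] object.
#' @return vector of densities (1/s).
#' @export
ddm_density <- function(t, boundary, p) {
  boundary <- check_boundary(boundary)
  stopifnot(inherits(p, "ddm_params"))
  if (any(!is.finite(t))) stop_input("t must be finite")
  ddm_density_cpp(t, boundary == "upper", p$v, p$a, p$z, p$t0, p$sv, p$sz)
}

#' Probability of absorption at a boundary
#'
#' With `sv = sz = 0` this is the closed form for biased diffusion absorption;
#' drift variability is marginalized by Gauss-Hermite quadrature (order 21)
#' and start-point variability by Gauss-Legendre quadrature (order 11).
#'
#' @inheritParams ddm_density
#' @return probability in \[0, 1\]; upper and lower probabilities sum to 1.
#' @export
ddm_boundary_prob <- function(boundary, p) {
  boundary <- check_boundary(boundary)
  stopifnot(inherits(p, "ddm_params"))
  p_up_pure <- function(v, w) {
    # P(hit upper) for drift v, boundary a, start w*a; stable via expm1
    x <- -2 * v * p$a
    ifelse(abs(x) < 1e-10, w, expm1(x * w) / expm1(x))
  }
  p_up_v <- function(w) {
    if (p$sv > 0) {
      gh <- gauss_hermite(21L)
      vs <- p$v + sqrt(2) * p$sv * gh$x
      drop((gh$w / sqrt(pi)) %*% p_up_pure(vs, w))
    } else {
      p_up_pure(p$v, w)
    }
  }
  pu <- if (p$sz > 0) {
    gl <- gauss_legendre(11L)
    ws <- p$z + (p$sz / 2) * gl$x
    sum(gl$w / 2 * vapply(ws, p_up_v, numeric(1)))
  } else {
    p_up_v(p$z)
  }
  pu <- min(max(pu, 0), 1)
  if (boundary == "upper") pu else 1 - pu
}

#' Defective cumulative distribution of first-passage times
#'
#' `P(hit boundary, RT <= t)`, computed by cumulative integration of
#' [ddm_density()] on a fine time grid (trapezoid rule, grid spacing at most
#' 0.5 ms) with linear interpolation at the requested times. Nondecreasing in
#' `t`, zero at `t = t0`, and tending to [ddm_boundary_prob()] as t grows.
#'
#' @inheritParams ddm_density
#' @param t times in seconds; `Inf` is allowed and returns the boundary
#'   probability.
#' @return vector of probabilities.
#' @export
ddm_cdf <- function(t, boundary, p) {
  boundary <- check_boundary(boundary)
  stopifnot(inherits(p, "ddm_params"))
  out <- numeric(length(t))
  inf <- is.infinite(t) & t > 0
  out[inf] <- ddm_boundary_prob(boundary, p)
  fin <- !inf
  if (!any(fin)) return(out)
  tmax <- max(t[fin], p$t0 + 0.01)
  if (tmax <= p$t0) return(out)
  n <- min(32769L, max(2049L, ceiling((tmax - p$t0) / 5e-4) + 1L))
  grid <- seq(p$t0, tmax, length.out = n)
  dens <- ddm_density_cpp(grid, boundary == "upper",
                          p$v, p$a, p$z, p$t0, p$sv, p$sz)
  h <- grid[2] - grid[1]
  cdf <- c(0, cumsum((dens[-n] + dens[-1]) / 2 * h))
  out[fin] <- stats::approx(grid, cdf, xout = pmax(t[fin], p$t0),
                            yleft = 0, rule = 2)$y
  out
}

#' Simulate choices and response times from the DDM
#'
#' Simulates the diffusion process with exact Gaussian increments on a time
#' grid plus a Brownian-bridge correction for within-step boundary crossings,
#' so discretization bias is negligible at the default step size. Across-trial
#' variability in drift and start point is drawn per trial. All simulated RTs
#' exceed `t0` (non-decision-time variability is fixed at zero).
#'
#' @inheritParams ddm_density
#' @param n number of trials (>= 1).
#' @param seed optional integer seed (calls [set.seed()]); if `NULL` the
#'   current RNG state is used.
#' @param dt Euler step in seconds.
#' @return data frame with columns `boundary` ("upper"/"lower") and `rt`.
#' @export
ddm_simulate <- function(p, n, seed = NULL, dt = 1e-3) {
  stopifnot(inherits(p, "ddm_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop_input("n must be a count >= 1")
  if (!is.null(seed)) set.seed(seed)
  sim <- ddm_sim_cpp(as.integer(n), p$v, p$a, p$z, p$t0, p$sv, p$sz, dt)
  data.frame(boundary = ifelse(sim$upper, "upper", "lower"), rt = sim$rt,
             stringsAsFactors = FALSE)
}

#' Joint log-likelihood of annotated trials under per-cell DDM parameters
#'
#' Each trial contributes the log first-passage density at its response
#' boundary and RT, under the parameters of its design cell. The upper
#' boundary codes the "same" response. Densities are floored at `floor_dens`
#' before the log so outlier RTs keep the likelihood finite.
#'
#' @param trials data frame with columns `rt` (seconds, > 0), `response`
#'   ("same"/"different") and `cell` (label or index matching
#'   `names(cell_params)`).
#' @param cell_params named list of [ddm_params()] covering every cell present
#'   in `trials`.
#' @param floor_dens density floor applied before the log.
#' @return the summed log-likelihood (finite).
#' @export
log_likelihood <- function(trials, cell_params, floor_dens = 1e-10) {
  if (any(trials$rt <= 0)) stop_input("all rt must be > 0")
  if (!all(trials$response %in% c("same", "different")))
    stop_input("responses must be 'same' or 'different'")
  cells <- as.character(trials$cell)
  if (is.numeric(trials$cell) && all(trials$cell %in% 1:8) &&
      !any(cells %in% names(cell_params)))
    cells <- design_cells()$label[trials$cell]
  missing <- setdiff(unique(cells), names(cell_params))
  if (length(missing))
    stop_input("missing cell parameters for: ", paste(missing, collapse = ", "))
  ll <- 0
  for (cl in unique(cells)) {
    p <- cell_params[[cl]]
    stopifnot(inherits(p, "ddm_params"))
    for (resp in c("same", "different")) {
      idx <- cells == cl & trials$response == resp
      if (!any(idx)) next
      d <- ddm_density_cpp(trials$rt[idx], resp == "same",
                           p$v, p$a, p$z, p$t0, p$sv, p$sz)
      ll <- ll + sum(log(pmax(d, floor_dens)))
    }
  }
  ll
}
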