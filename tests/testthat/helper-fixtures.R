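# Shared fixtures: small in-code datasets and reduced sampler settings used
# across the unit tests. All randomness is seeded at point of use.

# a compact sampler schedule for structural tests (not for inference quality)
tiny_config <- function(seed = 1L) {
  sampler_config(n_chains = 24, n_iter = 60, n_burn = 60, seed = seed)
}

# reduced but usable schedule for small inference checks
small_config <- function(seed = 1L) {
  sampler_config(n_chains = 36, n_iter = 200, n_burn = 250, seed = seed)
}

# deterministic annotated toy table: one subject, one block, hand-written
# frames/stimuli so every annotation can be checked by eye
toy_sequence <- function() {
  #             1     2      3      4     5      6      7
  frames  <- c("red", "red", "blue", "blue", "red", "blue", "red")
  stimuli <- c("X",   "O",   "O",    "X",   "X",   "X",    "O")
  annotate_sequence(frames, stimuli, rep(1L, 7))
}

# small responded trial table with known RTs/responses per cell
toy_trials <- function(rts, responses = NULL, cells = NULL) {
  n <- length(rts)
  cells <- cells %||% rep_len(1:8, n)
  fac <- cell_factors(cells)
  responses <- responses %||% fac$match    # all correct by default
  data.frame(subject = 1L, block = 1L, trial = seq_len(n) + 1L,
             stimulus = "X", frame = "red", response = responses, rt = rts,
             referent_before = "X", correct_answer = fac$match,
             updating = fac$updating, switching = fac$switching,
             match = fac$match, cell = cells,
             cell_label = design_cells()$label[cells],
             excluded = FALSE,
             correct = responses == fac$match,
             stringsAsFactors = FALSE)
}

# naive Euler-Maruyama simulator in plain R: the independent brute-force
# oracle for the first-passage density (no bridge correction, small dt)
naive_euler_sim <- function(p, n, dt = 1e-4, seed = 1) {
  set.seed(seed)
  v <- rep(p$v, n) + if (p$sv > 0) rnorm(n, 0, p$sv) else 0
  w <- rep(p$z, n) + if (p$sz > 0) runif(n, -p$sz / 2, p$sz / 2) else 0
  x <- w * p$a
  t <- numeric(n)
  boundary <- rep(NA_character_, n)
  active <- seq_len(n)
  sq <- sqrt(dt)
  step <- 0L
  while (length(active) && step < 200000L) {
    step <- step + 1L
    x[active] <- x[active] + v[active] * dt + sq * rnorm(length(active))
    up <- x[active] >= p$a
    lo <- x[active] <= 0
    hit <- up | lo
    if (any(hit)) {
      idx <- active[hit]
      boundary[idx] <- ifelse(up[hit], "upper", "lower")
      t[idx] <- p$t0 + step * dt
      active <- active[!hit]
    }
  }
  data.frame(boundary = boundary, rt = t)[!is.na(boundary), ]
}

ks_distance <- function(rts, p, boundary) {
  rts <- sort(rts)
  n <- length(rts)
  cdf <- ddm_cdf(rts, boundary, p) / ddm_boundary_prob(boundary, p)
  max(abs(cdf - seq_len(n) / n), abs(cdf - (seq_len(n) - 1) / n))
}
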