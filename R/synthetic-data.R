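# Synthetic reference-back sessions generated from known group- and
# subject-level DDM parameters. These stand in for empirical data in the
# recovery, calibration and predictive-checking studies.

#' Generate a reference-back stimulus sequence
#'
#' The first trial of each block is red-framed (it installs the initial
#' referent and requires no response); all other frame colors and all probe
#' identities are i.i.d. equiprobable, so upcoming memory operations cannot
#' be predicted before trial onset.
#'
#' @param n_trials total number of trials (default one session of 512).
#' @param n_blocks number of blocks (must divide `n_trials`).
#' @param seed optional integer seed.
#' @return data frame with columns `block`, `trial`, `frame`, `stimulus`.
#' @export
generate_sequence <- function(n_trials = 512, n_blocks = 4, seed = NULL) {
  if (n_trials < n_blocks || n_trials %% n_blocks != 0)
    stop_input("n_trials must be a positive multiple of n_blocks")
  if (!is.null(seed)) set.seed(seed)
  per <- n_trials / n_blocks
  block <- rep(seq_len(n_blocks), each = per)
  trial <- rep(seq_len(per), n_blocks)
  frame <- sample(c("red", "blue"), n_trials, replace = TRUE)
  frame[trial == 1L] <- "red"
  stimulus <- sample(c("X", "O"), n_trials, replace = TRUE)
  data.frame(block = block, trial = trial, frame = frame,
             stimulus = stimulus, stringsAsFactors = FALSE)
}

#' Group-level population model
#'
#' A truncated-normal population distribution per free parameter: hyper-mean
#' and hyper-SD, truncated at the parameter's support bounds.
#'
#' @param spec a [model_spec()].
#' @param mean named numeric vector of hyper-means covering
#'   `spec$par_names`.
#' @param sd named numeric vector of hyper-SDs (>= 0); recycled from a single
#'   value if unnamed.
#' @return an object of class `ddm_group_model`.
#' @export
group_model <- function(spec, mean, sd) {
  nm <- spec$par_names
  if (!all(nm %in% names(mean)))
    stop_input("hyper-means missing for: ",
               paste(setdiff(nm, names(mean)), collapse = ", "))
  if (is.null(names(sd))) sd <- stats::setNames(rep_len(sd, length(nm)), nm)
  if (!all(nm %in% names(sd)))
    stop_input("hyper-SDs missing for: ",
               paste(setdiff(nm, names(sd)), collapse = ", "))
  if (any(sd[nm] < 0)) stop_input("hyper-SD must be >= 0")
  sup <- par_support(nm)
  structure(list(spec_variant = spec$variant, par_names = nm,
                 mean = mean[nm], sd = sd[nm],
                 lower = sup$lower, upper = sup$upper),
            class = "ddm_group_model")
}

# fixture hyper-SD scales by parameter family
.default_hyper_sd <- function(nm) {
  pre <- sub("\\..*$", "", nm)
  stats::setNames(c(v = 0.35, t0 = 0.035, a = 0.12, z = 0.04,
                    sz = 0.05, sv = 0.2)[pre], nm)
}

#' Default generating group model
#'
#' Fixture hyper-parameters for synthetic studies: per-cell drift and
#' non-decision-time hyper-means follow the qualitative structure of
#' reference-back performance (lower drift and longer non-decision time on
#' reference, switch and mismatch trials; a slightly higher threshold in
#' updating mode), with magnitudes in the plausible mid-range of the DDM
#' literature. These are synthetic fixture values, not empirical estimates.
#'
#' @param spec a [model_spec()].
#' @return a [group_model()].
#' @export
default_group_model <- function(spec = model_spec("top")) {
  v_cell <- c(ref.ns.same = 2.8, ref.ns.diff = 2.0, ref.sw.same = 2.4,
              ref.sw.diff = 1.6, comp.ns.same = 3.5, comp.ns.diff = 2.5,
              comp.sw.same = 3.0, comp.sw.diff = 2.1)
  t_cell <- c(ref.ns.same = 0.38, ref.ns.diff = 0.41, ref.sw.same = 0.38,
              ref.sw.diff = 0.41, comp.ns.same = 0.30, comp.ns.diff = 0.33,
              comp.sw.same = 0.36, comp.sw.diff = 0.39)
  nm <- spec$par_names
  mean <- stats::setNames(numeric(length(nm)), nm)
  for (p in nm) {
    mean[p] <- switch(sub("\\..*$", "", p),
      v = if (p == "v") 2.5 else v_cell[sub("^v\\.", "", p)],
      t0 = if (p == "t0") 0.36 else t_cell[sub("^t0\\.", "", p)],
      a = c(a = 1.27, a.ref = 1.35, a.comp = 1.2)[p],
      z = 0.5, sz = 0.15, sv = 0.8)
  }
  group_model(spec, mean, .default_hyper_sd(nm))
}

#' Flat group model with optional planted effects
#'
#' All cells share the same hyper-means (a null group), optionally perturbed
#' in reference cells to plant an updating effect: `updating_v` is added to
#' the drift hyper-mean of reference cells (use a negative value for a drift
#' deficit), `updating_t0` to their non-decision time, and `updating_a` to
#' the reference threshold.
#'
#' @param spec a [model_spec()].
#' @param v,t0,a,z,sv,sz baseline hyper-means.
#' @param updating_v,updating_t0,updating_a planted reference-cell effects.
#' @param sd optional named hyper-SD vector (fixture defaults otherwise).
#' @return a [group_model()].
#' @export
flat_group_model <- function(spec = model_spec("top"), v = 2.5, t0 = 0.35,
                             a = 1.25, z = 0.5, sv = 0.8, sz = 0.15,
                             updating_v = 0, updating_t0 = 0, updating_a = 0,
                             sd = NULL) {
  nm <- spec$par_names
  mean <- stats::setNames(numeric(length(nm)), nm)
  for (p in nm) {
    pre <- sub("\\..*$", "", p)
    mean[p] <- switch(pre,
      v = v + if (grepl("^v\\.ref\\.", p)) updating_v else 0,
      t0 = t0 + if (grepl("^t0\\.ref\\.", p)) updating_t0 else 0,
      a = a + if (p == "a.ref") updating_a else 0,
      z = z, sz = sz, sv = sv)
  }
  group_model(spec, mean, sd %||% .default_hyper_sd(nm))
}

#' Draw one subject's parameters from a group model
#'
#' Each free parameter is drawn from its truncated-normal population
#' distribution; draws violating the joint start-point constraint
#' (`z +/- sz/2` inside (0, 1)) are rejected and redrawn.
#'
#' @param group a [group_model()].
#' @param spec the matching [model_spec()].
#' @param seed optional integer seed.
#' @return named parameter vector.
#' @export
draw_subject_params <- function(group, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(group, "ddm_group_model"))
  if (!identical(group$par_names, spec$par_names))
    stop_input("group model does not cover this spec's parameters")
  for (try in 1:1000) {
    th <- rtnorm(length(group$mean), group$mean, group$sd,
                 group$lower, group$upper)
    names(th) <- group$par_names
    if (theta_valid(spec, th)) return(th)
  }
  stop_input("could not draw a valid parameter vector")
}

#' Simulate a full reference-back dataset
#'
#' For each subject: draw parameters from the group model, generate a stimulus
#' sequence, annotate it, and simulate every responded trial's choice and RT
#' from the subject's cell parameters. The default session is 512 trials in 4
#' blocks; first trials of blocks carry `response = "none"` and no RT.
#' Optionally a fraction of responded trials is replaced by contaminant
#' outliers (uniform fast guesses below 150 ms and slow stragglers above 3 s,
#' split evenly, with a random response) to exercise the outlier filter.
#'
#' @param group a [group_model()].
#' @param spec the matching [model_spec()].
#' @param n_subjects number of subjects.
#' @param n_trials,n_blocks session shape per subject.
#' @param seed master seed; the full dataset is reproducible from it.
#' @param outliers logical; add contaminant trials?
#' @param outlier_rate contamination rate when `outliers = TRUE`.
#' @return an object of class `ddm_sim_data`: list with `trials` (annotated
#'   data frame), `subject_params` (matrix, one row per subject), `group`,
#'   `spec`, `seed`.
#' @export
simulate_dataset <- function(group, spec = model_spec("top"), n_subjects = 20,
                             n_trials = 512, n_blocks = 4, seed = NULL,
                             outliers = FALSE, outlier_rate = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  pars <- matrix(NA_real_, n_subjects, spec$n_free,
                 dimnames = list(seq_len(n_subjects), spec$par_names))
  all_trials <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    th <- draw_subject_params(group, spec)
    pars[s, ] <- th
    sq <- generate_sequence(n_trials, n_blocks)
    ann <- annotate_sequence(sq$frame, sq$stimulus, sq$block)
    ann$subject <- s
    ann$response <- "none"
    ann$rt <- NA_real_
    resp <- which(!ann$excluded)
    cp <- theta_to_cells(spec, th)
    cl <- ann$cell[resp]
    sim <- ddm_sim_cpp(length(resp), cp$V[cl, 1], cp$A[cl, 1], rep(cp$Z, length(resp)),
                       cp$T0[cl, 1], rep(cp$SV, length(resp)), rep(cp$SZ, length(resp)))
    ann$response[resp] <- ifelse(sim$upper, "same", "different")
    ann$rt[resp] <- sim$rt
    if (outliers && outlier_rate > 0) {
      bad <- resp[runif(length(resp)) < outlier_rate]
      if (length(bad)) {
        fast <- runif(length(bad)) < 0.5
        ann$rt[bad] <- ifelse(fast, runif(length(bad), 0.03, 0.149),
                              runif(length(bad), 3.01, 6))
        ann$response[bad] <- sample(c("same", "different"), length(bad),
                                    replace = TRUE)
      }
    }
    all_trials[[s]] <- ann
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL
  trials$cell_label <- ifelse(is.na(trials$cell), NA_character_,
                              design_cells()$label[trials$cell])
  trials$correct <- ifelse(trials$response %in% c("same", "different"),
                           trials$response == trials$correct_answer, NA)
  trials <- trials[, c("subject", "block", "trial", "stimulus", "frame",
                       "response", "rt", "referent_before", "correct_answer",
                       "updating", "switching", "match", "cell", "cell_label",
                       "excluded", "correct")]
  structure(list(trials = trials, subject_params = pars, group = group,
                 spec = spec, seed = seed),
            class = "ddm_sim_data")
}

#' @export
print.ddm_sim_data <- function(x, ...) {
  cat("Synthetic reference-back dataset:", nrow(x$subject_params),
      "subjects,", nrow(x$trials), "trials (variant", x$spec$variant, ")\n")
  invisible(x)
}
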