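# Empirical-level analysis: outlier filtering, per-cell summaries, and the
# six canonical reference-back cost contrasts.

#' Filter annotated trials
#'
#' Removes the non-responded first trial of each block and RT outliers:
#' responses faster than 150 ms or slower than 3 s (strict inequalities, so
#' boundary RTs of exactly 0.150 and 3.000 s are retained).
#'
#' @param data annotated trial data frame (see [annotate_trials()]).
#' @param rt_min,rt_max retention bounds in seconds.
#' @return list with `trials` (the retained rows) and `exclusions` (named
#'   counts: `first`, `fast`, `slow`).
#' @export
clean_trials <- function(data, rt_min = 0.150, rt_max = 3) {
  first <- is.na(data$cell) | data$response == "none"
  resp <- !first
  fast <- resp & data$rt < rt_min
  slow <- resp & data$rt > rt_max
  keep <- resp & !fast & !slow
  if (!any(keep)) stop_input("no responded trials remain after filtering")
  list(trials = data[keep, , drop = FALSE],
       exclusions = c(first = sum(first), fast = sum(fast), slow = sum(slow)))
}

rt_quantiles <- function(x, probs = c(0.1, 0.5, 0.9)) {
  if (!length(x)) return(rep(NA_real_, length(probs)))
  unname(quantile(x, probs, type = 7))
}

#' Per-cell accuracy and RT summaries
#'
#' Summarizes each subject's cleaned trials per design cell: trial count,
#' accuracy, mean RT of correct responses, and the 0.1/0.5/0.9 RT quantiles
#' separately for correct and error responses. Group values are unweighted
#' averages over subjects (missing cells are dropped from the average).
#'
#' @param trials cleaned, annotated trial data frame.
#' @return list with `by_subject` and `group` data frames.
#' @export
cell_summary <- function(trials) {
  cells <- design_cells()
  grid <- expand.grid(subject = unique(trials$subject), cell = cells$cell)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- trials[trials$subject == grid$subject[i] & trials$cell == grid$cell[i], ]
    cor_rt <- d$rt[d$correct]
    err_rt <- d$rt[!d$correct]
    qc <- rt_quantiles(cor_rt)
    qe <- rt_quantiles(err_rt)
    data.frame(subject = grid$subject[i], cell = grid$cell[i],
               label = cells$label[grid$cell[i]], n = nrow(d),
               accuracy = if (nrow(d)) mean(d$correct) else NA_real_,
               mean_rt = if (length(cor_rt)) mean(cor_rt) else NA_real_,
               q10 = qc[1], q50 = qc[2], q90 = qc[3],
               mean_rt_error = if (length(err_rt)) mean(err_rt) else NA_real_,
               q10_error = qe[1], q50_error = qe[2], q90_error = qe[3],
               stringsAsFactors = FALSE)
  })
  by_subject <- do.call(rbind, rows)
  num <- setdiff(names(by_subject), c("subject", "cell", "label"))
  group <- do.call(rbind, lapply(cells$cell, function(cl) {
    d <- by_subject[by_subject$cell == cl & by_subject$n > 0, ]
    g <- data.frame(cell = cl, label = cells$label[cl], n = sum(d$n))
    for (v in num[num != "n"]) g[[v]] <- mean(d[[v]], na.rm = TRUE)
    g
  }))
  list(by_subject = by_subject, group = group)
}

#' Contrast weights for the six canonical cost measures
#'
#' Rows are measures, columns the eight design cells in [design_cells()]
#' order. A measure's RT cost is the weighted sum of cell mean RTs (costly
#' minus baseline condition, so slower-when-costly is positive); its accuracy
#' cost is the negated weighted sum of cell accuracies (less-accurate-when-
#' costly is positive). Updating and comparison use no-switch cells only;
#' substitution is the updating-by-match double difference averaged over
#' switch levels.
#'
#' @return a 6 x 8 numeric matrix with dimnames.
#' @export
cost_weights <- function() {
  W <- matrix(0, 6, 8, dimnames = list(
    c("updating", "comparison", "switching", "gate-opening", "gate-closing",
      "substitution"),
    design_cells()$label))
  W["updating", c("ref.ns.same", "ref.ns.diff")] <- 1 / 2
  W["updating", c("comp.ns.same", "comp.ns.diff")] <- -1 / 2
  W["comparison", c("ref.ns.diff", "comp.ns.diff")] <- 1 / 2
  W["comparison", c("ref.ns.same", "comp.ns.same")] <- -1 / 2
  W["switching", c("ref.sw.same", "ref.sw.diff", "comp.sw.same", "comp.sw.diff")] <- 1 / 4
  W["switching", c("ref.ns.same", "ref.ns.diff", "comp.ns.same", "comp.ns.diff")] <- -1 / 4
  W["gate-opening", c("ref.sw.same", "ref.sw.diff")] <- 1 / 2
  W["gate-opening", c("ref.ns.same", "ref.ns.diff")] <- -1 / 2
  W["gate-closing", c("comp.sw.same", "comp.sw.diff")] <- 1 / 2
  W["gate-closing", c("comp.ns.same", "comp.ns.diff")] <- -1 / 2
  W["substitution", c("ref.ns.diff", "ref.sw.diff")] <- 1 / 2
  W["substitution", c("ref.ns.same", "ref.sw.same")] <- -1 / 2
  W["substitution", c("comp.ns.diff", "comp.sw.diff")] <- -1 / 2
  W["substitution", c("comp.ns.same", "comp.sw.same")] <- 1 / 2
  W
}

apply_costs <- function(rt_by_cell, acc_by_cell) {
  W <- cost_weights()
  if (anyNA(rt_by_cell) || anyNA(acc_by_cell))
    stop_input("missing required cell in summaries")
  data.frame(measure = rownames(W),
             rt_cost = as.numeric(W %*% rt_by_cell),
             acc_cost = as.numeric(-W %*% acc_by_cell),
             stringsAsFactors = FALSE)
}

#' Per-subject canonical cost measures
#'
#' @param by_subject the `by_subject` component of [cell_summary()].
#' @return data frame with columns `subject`, `measure`, `rt_cost`,
#'   `acc_cost`. RT costs use mean RT over correct trials.
#' @export
subject_costs <- function(by_subject) {
  out <- lapply(unique(by_subject$subject), function(s) {
    d <- by_subject[by_subject$subject == s, ]
    d <- d[order(d$cell), ]
    cc <- apply_costs(d$mean_rt, d$accuracy)
    cc$subject <- s
    cc[, c("subject", "measure", "rt_cost", "acc_cost")]
  })
  do.call(rbind, out)
}

#' The six canonical reference-back cost measures
#'
#' Costs are computed per subject from their cell summaries and then averaged
#' across subjects (subject-as-random-effect logic). Updating is
#' no-switch/reference minus no-switch/comparison; comparison is
#' no-switch/different minus no-switch/same; switching is switch minus
#' no-switch; gate opening (closing) contrasts switch vs no-switch within
#' reference (comparison) trials; substitution is
#' (reference/different - reference/same) - (comparison/different -
#' comparison/same).
#'
#' @param summaries output of [cell_summary()] (or its `by_subject` part).
#' @return data frame with group-mean `rt_cost` (s) and `acc_cost` (proportion)
#'   per measure, plus standard errors; per-subject costs in attribute
#'   `"by_subject"`.
#' @export
canonical_costs <- function(summaries) {
  by_subject <- if (is.data.frame(summaries)) summaries else summaries$by_subject
  sc <- subject_costs(by_subject)
  agg <- function(v) {
    m <- tapply(sc[[v]], sc$measure, mean)
    se <- tapply(sc[[v]], sc$measure, function(x) sd(x) / sqrt(length(x)))
    list(m = m, se = se)
  }
  rtc <- agg("rt_cost"); acc <- agg("acc_cost")
  measures <- rownames(cost_weights())
  out <- data.frame(measure = measures,
                    rt_cost = as.numeric(rtc$m[measures]),
                    rt_se = as.numeric(rtc$se[measures]),
                    acc_cost = as.numeric(acc$m[measures]),
                    acc_se = as.numeric(acc$se[measures]),
                    stringsAsFactors = FALSE)
  attr(out, "by_subject") <- sc
  out
}
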