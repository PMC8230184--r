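# Reference-back design cells: the 2x2x2 factorial of updating mode
# (reference = red frame, update WM; comparison = blue frame, maintain),
# mode switching relative to the previous trial, and probe-referent match.

#' The eight reference-back design cells
#'
#' @return data frame with columns `cell` (index 1..8), `label`, `updating`,
#'   `switching` and `match`, one row per factorial cell.
#' @export
design_cells <- function() {
  g <- expand.grid(match = c("same", "different"),
                   switching = c("no-switch", "switch"),
                   updating = c("reference", "comparison"),
                   stringsAsFactors = FALSE)[, 3:1]
  lab <- paste(ifelse(g$updating == "reference", "ref", "comp"),
               ifelse(g$switching == "no-switch", "ns", "sw"),
               ifelse(g$match == "same", "same", "diff"), sep = ".")
  data.frame(cell = seq_len(8), label = lab, g, stringsAsFactors = FALSE)
}

#' Map factor levels to a design-cell index
#'
#' Deterministic bijection between the factorial levels and indices 1..8.
#'
#' @param updating "reference" or "comparison" (vectorized).
#' @param switching "switch" or "no-switch".
#' @param match "same" or "different".
#' @return integer cell indices.
#' @seealso [cell_factors()] for the inverse map.
#' @export
cell_of <- function(updating, switching, match) {
  iu <- match(updating, c("reference", "comparison"))
  is <- match(switching, c("no-switch", "switch"))
  im <- match(match, c("same", "different"))
  if (any(is.na(iu)) || any(is.na(is)) || any(is.na(im)))
    stop_input("invalid factor level")
  as.integer((iu - 1L) * 4L + (is - 1L) * 2L + im)
}

#' @rdname cell_of
#' @param cell integer indices in 1..8.
#' @export
cell_factors <- function(cell) {
  if (any(!cell %in% 1:8)) stop_input("cell index must be in 1..8")
  design_cells()[cell, c("updating", "switching", "match")]
}

#' Annotate a reference-back stimulus sequence
#'
#' Derives, for every trial, the referent held in working memory before the
#' trial, the correct answer, and the design-cell factors. The first trial of
#' each block must be red-framed; it only installs the initial referent,
#' requires no response, and is excluded from the design (`cell = NA`). On
#' every other trial the probe is compared against the referent *before* any
#' update, and the referent is then replaced by the probe on red (reference)
#' frames only. Switching on trial 2 of a block is defined against the forced
#' red first trial.
#'
#' @param frames character vector of frame colors ("red"/"blue").
#' @param stimuli character vector of probe identities ("X"/"O").
#' @param block block id per trial (same length); trials are assumed ordered
#'   within block.
#' @return data frame with columns `block`, `trial`, `frame`, `stimulus`,
#'   `referent_before`, `correct_answer`, `updating`, `switching`, `match`,
#'   `cell`, `excluded`.
#' @export
annotate_sequence <- function(frames, stimuli, block = rep(1L, length(frames))) {
  n <- length(frames)
  if (n == 0L) stop_input("empty sequence")
  if (length(stimuli) != n || length(block) != n)
    stop_input("frames, stimuli and block must have equal length")
  if (!all(frames %in% c("red", "blue"))) stop_input("frames must be red/blue")
  trial <- integer(n)
  referent_before <- updating <- switching <- mtch <- rep(NA_character_, n)
  cell <- rep(NA_integer_, n)
  excluded <- rep(FALSE, n)
  for (b in unique(block)) {
    idx <- which(block == b)
    if (!length(idx)) stop_input("empty block")
    if (frames[idx[1]] != "red")
      stop_input("first trial of block ", b, " must be red-framed")
    trial[idx] <- seq_along(idx)
    referent <- NA_character_
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (j == 1L) {
        excluded[i] <- TRUE
        referent <- stimuli[i]
        next
      }
      referent_before[i] <- referent
      updating[i] <- if (frames[i] == "red") "reference" else "comparison"
      switching[i] <- if (frames[i] == frames[idx[j - 1L]]) "no-switch" else "switch"
      mtch[i] <- if (stimuli[i] == referent) "same" else "different"
      if (frames[i] == "red") referent <- stimuli[i]
    }
  }
  ann <- !excluded
  cell[ann] <- cell_of(updating[ann], switching[ann], mtch[ann])
  data.frame(block = block, trial = trial, frame = frames,
             stimulus = stimuli, referent_before = referent_before,
             correct_answer = mtch, updating = updating,
             switching = switching, match = mtch, cell = cell,
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Annotate a raw trial table
#'
#' Applies [annotate_sequence()] per subject and block to a trial table with
#' columns `subject`, `block`, `trial`, `stimulus`, `frame`, `response`, `rt`,
#' adding the annotation columns (including `cell_label`) and a `correct`
#' indicator where a response was given.
#'
#' @param data raw trial data frame.
#' @return the annotated data frame.
#' @export
annotate_trials <- function(data) {
  need <- c("subject", "block", "stimulus", "frame", "response", "rt")
  if (!all(need %in% names(data)))
    stop_input("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "))
  parts <- split(data, list(data$subject), drop = TRUE)
  res <- lapply(parts, function(d) {
    d <- d[order(d$block, d$trial %||% seq_len(nrow(d))), , drop = FALSE]
    ann <- annotate_sequence(d$frame, d$stimulus, d$block)
    d$trial <- ann$trial
    for (col in c("referent_before", "correct_answer", "updating",
                  "switching", "match", "cell", "excluded"))
      d[[col]] <- ann[[col]]
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$cell_label <- ifelse(is.na(out$cell), NA_character_,
                           design_cells()$label[out$cell])
  out$correct <- ifelse(out$response %in% c("same", "different"),
                        out$response == out$correct_answer, NA)
  out
}

#' Build one of the four factorial DDM model variants
#'
#' The top model lets drift rate and non-decision time vary over all eight
#' design cells and the threshold over updating mode (reference vs
#' comparison); each constrained variant collapses one of those families to a
#' single parameter. Every variant has exactly one start point (z), one
#' start-point variability (sz) and one drift-rate variability (sv); drift
#' criterion and non-decision-time variability are fixed at zero. Free
#' parameter counts are 21, 20, 14 and 14.
#'
#' @param variant one of `"top"`, `"threshold-fixed"`, `"drift-fixed"`,
#'   `"ndt-fixed"`.
#' @return an object of class `ddm_model_spec` with the free-parameter names,
#'   support bounds, and index maps from design cells into the parameter
#'   vector.
#' @examples
#' model_spec("top")$n_free  # 21
#' @export
model_spec <- function(variant = c("top", "threshold-fixed", "drift-fixed",
                                   "ndt-fixed")) {
  variant <- match.arg(variant)
  cells <- design_cells()
  v_names <- if (variant == "drift-fixed") "v" else paste0("v.", cells$label)
  t_names <- if (variant == "ndt-fixed") "t0" else paste0("t0.", cells$label)
  a_names <- if (variant == "threshold-fixed") "a" else c("a.ref", "a.comp")
  par_names <- c(v_names, t_names, a_names, "z", "sz", "sv")
  sup <- par_support(par_names)
  v_idx <- if (variant == "drift-fixed") rep(1L, 8) else seq_len(8)
  t0_idx <- length(v_names) + (if (variant == "ndt-fixed") rep(1L, 8) else seq_len(8))
  a_off <- length(v_names) + length(t_names)
  a_idx <- a_off + (if (variant == "threshold-fixed") rep(1L, 8)
                    else ifelse(cells$updating == "reference", 1L, 2L))
  z_idx <- a_off + length(a_names) + 1L
  structure(list(variant = variant, par_names = par_names,
                 lower = sup$lower, upper = sup$upper,
                 v_idx = v_idx, t0_idx = t0_idx, a_idx = a_idx,
                 z_idx = z_idx, sz_idx = z_idx + 1L, sv_idx = z_idx + 2L,
                 v_sign = ifelse(cells$match == "same", 1, -1),
                 n_free = length(par_names)),
            class = "ddm_model_spec")
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  cat("DDM model variant '", x$variant, "': ", x$n_free,
      " free parameters\n", sep = "")
  cat(paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

# Expand free-parameter vectors (columns of theta) into per-cell arrays for
# the C++ likelihood: signed drift toward the "same" (upper) boundary.
theta_to_cells <- function(spec, theta) {
  if (!is.matrix(theta)) theta <- matrix(theta, ncol = 1)
  stopifnot(nrow(theta) == spec$n_free)
  list(V = theta[spec$v_idx, , drop = FALSE] * spec$v_sign,
       A = theta[spec$a_idx, , drop = FALSE],
       T0 = theta[spec$t0_idx, , drop = FALSE],
       Z = theta[spec$z_idx, ],
       SZ = theta[spec$sz_idx, ],
       SV = theta[spec$sv_idx, ])
}

# support check incl. the joint start-point constraint; returns logical per column
theta_valid <- function(spec, theta) {
  if (!is.matrix(theta)) theta <- matrix(theta, ncol = 1)
  ok <- colSums(theta > spec$lower & theta < spec$upper) == spec$n_free
  z <- theta[spec$z_idx, ]
  sz <- theta[spec$sz_idx, ]
  ok & (z - sz / 2 > 0) & (z + sz / 2 < 1)
}

#' Read and write reference-back trial tables
#'
#' Tab-delimited text with a header; columns `subject`, `block`, `trial`,
#' `stimulus`, `frame`, `response`, `rt` plus any annotation columns present.
#'
#' @param file path.
#' @param data trial data frame.
#' @return `read_trials()` returns the data frame; `write_trials()` the file
#'   path, invisibly.
#' @export
read_trials <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname read_trials
#' @export
write_trials <- function(data, file) {
  write.table(data, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
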