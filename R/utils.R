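#' @useDynLib refbackddm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm pnorm qnorm runif rnorm quantile var median cor sd
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gauss-Hermite nodes/weights (physicists' convention) by Golub-Welsch;
# used to marginalize Gaussian drift variability in absorption probabilities.
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(x = e$values[idx], w = sqrt(pi) * e$vectors[1, idx]^2)
}

# Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- off
  J[cbind(k + 1L, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(x = e$values[idx], w = 2 * e$vectors[1, idx]^2)
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat computed after splitting each chain in half, for each
#' parameter of a draws array.
#'
#' @param draws numeric array with dimensions (chain, iteration, parameter).
#' @return named numeric vector of R-hat values, one per parameter.
#' @export
rhat <- function(draws) {
  stopifnot(length(dim(draws)) == 3)
  n_par <- dim(draws)[3]
  out <- numeric(n_par)
  half <- floor(dim(draws)[2] / 2)
  for (j in seq_len(n_par)) {
    x <- draws[, , j, drop = FALSE]
    # split each chain into halves
    a <- x[, seq_len(half), 1, drop = FALSE]
    b <- x[, half + seq_len(half), 1, drop = FALSE]
    m <- rbind(matrix(a, nrow = dim(x)[1]), matrix(b, nrow = dim(x)[1]))
    n <- ncol(m)
    cm <- rowMeans(m)
    B <- n * var(cm)
    W <- mean(apply(m, 1, var))
    if (W <= 0) {
      out[j] <- 1
    } else {
      out[j] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  names(out) <- dimnames(draws)[[3]]
  out
}

stop_input <- function(...) stop(..., call. = FALSE)
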