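# MCMC convergence diagnostics: split-chain rank-normalized R-hat and
# rank-normalized (bulk) / quantile-indicator (tail) effective sample
# sizes, following the current-standard definitions (Vehtari et al. 2021).
# Draw matrices are chains x draws throughout.

split_chains <- function(m) {
  n <- ncol(m)
  half <- n %/% 2L
  if (half < 1L) stop("need at least 2 draws per chain", call. = FALSE)
  rbind(m[, seq_len(half), drop = FALSE],
        m[, (n - half + 1):n, drop = FALSE])
}

rank_normalize <- function(m) {
  S <- length(m)
  z <- stats::qnorm((rank(m, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow = nrow(m), ncol = ncol(m))
}

rhat_basic <- function(m) {
  mchains <- nrow(m); n <- ncol(m)
  means <- rowMeans(m)
  vars <- apply(m, 1, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Split-chain rank-normalized R-hat
#'
#' Potential scale reduction computed on rank-normalized split chains;
#' the reported value is the maximum of the bulk (rank-normalized) and
#' tail (folded rank-normalized) variants. Values at or above 1.01
#' indicate non-convergence under the usual bar.
#'
#' @param m numeric matrix of draws, chains in rows, draws in columns.
#' @return scalar R-hat (NA for constant draws).
#' @export
rhat <- function(m) {
  m <- as.matrix(m)
  s <- split_chains(m)
  bulk <- rhat_basic(rank_normalize(s))
  folded <- rhat_basic(rank_normalize(abs(s - stats::median(s))))
  max(bulk, folded)
}

# ESS for the mean of (possibly transformed) split chains, Geyer initial
# monotone positive sequence on chain-averaged autocorrelations
ess_mean <- function(m) {
  mchains <- nrow(m); n <- ncol(m)
  if (n < 3L) return(NA_real_)
  vars <- apply(m, 1, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- if (mchains > 1) n * stats::var(rowMeans(m)) else 0
  var_plus <- (n - 1) / n * W + B / n
  # chain-averaged autocovariances
  acov <- sapply(seq_len(mchains), function(ch) {
    a <- stats::acf(m[ch, ], lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus   # rho[1] is lag 0
  # Geyer: sum of adjacent pairs, truncated at first negative pair,
  # then enforced monotone nonincreasing
  max_pairs <- (n - 1) %/% 2L
  tau <- 1 + 2 * rho[2]  # will be rebuilt below; placeholder
  psum <- numeric(0)
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(p) || p <= 0) break
    psum <- c(psum, p)
  }
  if (length(psum)) psum <- cummin(psum)
  tau <- max(1 + 2 * sum(psum), 1 / log10(mchains * n + 1))
  ess <- mchains * n / tau
  min(ess, mchains * n * log10(mchains * n))
}

#' Bulk and tail effective sample sizes
#'
#' `ess_bulk()` is the effective sample size of the rank-normalized
#' split chains (sampling efficiency in the distribution's bulk);
#' `ess_tail()` is the minimum ESS of the 5% and 95% quantile
#' indicator variables (efficiency in the tails).
#'
#' @param m numeric matrix of draws, chains in rows, draws in columns.
#' @return scalar effective sample size (NA for constant draws).
#' @export
ess_bulk <- function(m) {
  m <- as.matrix(m)
  ess_mean(rank_normalize(split_chains(m)))
}

#' @rdname ess_bulk
#' @export
ess_tail <- function(m) {
  m <- as.matrix(m)
  s <- split_chains(m)
  q <- stats::quantile(s, c(0.05, 0.95), names = FALSE)
  lo <- ess_mean(matrix(as.numeric(s <= q[1]), nrow = nrow(s)))
  hi <- ess_mean(matrix(as.numeric(s <= q[2]), nrow = nrow(s)))
  min(lo, hi)
}
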