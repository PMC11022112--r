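# PSIS-LOO: Pareto-smoothed importance-sampling approximation to exact
# leave-one-out cross-validation, computed from the pointwise
# log-likelihood array of a fit.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit to exceedances (Zhang & Stephens 2009 profile
# posterior, with the usual weak-prior adjustment of the shape toward 0.5)
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  xi_of <- function(t) mean(log1p(-t * x))
  xi_j <- vapply(theta, xi_of, numeric(1))
  l_j <- n * (log(-theta / xi_j) - xi_j - 1)
  w <- exp(l_j - log_sum_exp(l_j))
  theta_hat <- sum(theta * w)
  xi <- xi_of(theta_hat)
  sigma <- -xi / theta_hat
  # regularize the shape toward 0.5 (prior pseudo-count 10)
  xi_reg <- (n * xi + 10 * 0.5) / (n + 10)
  list(k = xi_reg, sigma = sigma, k_raw = xi)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# smooth one vector of log importance weights; returns the smoothed
# (unnormalized) log weights and the Pareto shape estimate
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || length(unique(lw)) < 5) {
    return(list(lw = lw, k = -Inf))
  }
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_idx]) - cutoff
  if (all(exceed <= 0) || stats::sd(exceed) == 0) {
    return(list(lw = lw, k = -Inf))
  }
  fitk <- gpd_fit(exceed[exceed > 0])
  if (!is.finite(fitk$k)) return(list(lw = lw, k = -Inf))
  pj <- (seq_len(M) - 0.5) / M
  smoothed <- cutoff + vapply(pj, qgpd, numeric(1), k = fitk$k,
                              sigma = fitk$sigma)
  smoothed <- pmin(smoothed, exp(max(lw)))  # truncate at the largest raw weight
  # assign smoothed values in the rank order of the raw tail
  rk <- rank(lw[tail_idx], ties.method = "first")
  lw[tail_idx] <- log(smoothed[rk])
  list(lw = lw, k = fitk$k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Approximates exact leave-one-out cross-validation from a single fit
#' by Pareto-smoothed importance sampling: for each observation the
#' importance ratios `1/p(y_i | theta_s)` are tail-smoothed by a
#' generalized-Pareto fit before the weighted predictive density is
#' formed. Returns the expected log pointwise predictive density
#' `elpd_loo` (higher = better out-of-sample fit, sum scale), the
#' effective parameter count `p_loo`, its standard error, the pointwise
#' contributions and the per-observation Pareto shape diagnostics
#' (values above 0.7 make that observation's estimate unreliable and
#' trigger a warning).
#'
#' @param fit a `posterior_draws` with a pointwise log-likelihood
#'   array (see [fit_model()]).
#' @param model_name label carried into comparison tables.
#' @return object of class `loo_result`.
#' @export
compute_loo <- function(fit, model_name = fit$spec$kind) {
  if (is.null(fit$log_lik)) {
    stop("fit has no pointwise log-likelihood; refit with log_lik = TRUE",
         call. = FALSE)
  }
  d <- dim(fit$log_lik)
  S <- d[1] * d[2]; N <- d[3]
  ll <- matrix(fit$log_lik, nrow = S, ncol = N)
  pointwise <- numeric(N); lpd <- numeric(N); k <- numeric(N)
  for (i in seq_len(N)) {
    lli <- ll[, i]
    sm <- psis_smooth(-lli)
    lw <- sm$lw - log_sum_exp(sm$lw)  # normalized log weights
    pointwise[i] <- log_sum_exp(lw + lli)
    lpd[i] <- log_sum_exp(lli) - log(S)
    k[i] <- sm$k
  }
  n_bad <- sum(k > 0.7)
  if (n_bad > 0) {
    warning(sprintf("%d observation(s) with Pareto k > 0.7; PSIS-LOO may be unreliable",
                    n_bad))
  }
  structure(list(model = model_name,
                 elpd_loo = sum(pointwise),
                 p_loo = sum(lpd - pointwise),
                 se = sqrt(N * stats::var(pointwise)),
                 pointwise = pointwise,
                 pareto_k = k,
                 n_obs = N),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO [%s]: elpd_loo %.3f (SE %.3f), p_loo %.3f, n %d, max k %.2f\n",
              x$model, x$elpd_loo, x$se, x$p_loo, x$n_obs, max(x$pareto_k)))
  invisible(x)
}

stacking_weights <- function(lpd_mat) {
  K <- ncol(lpd_mat)
  if (K == 1L) return(1)
  # optimize over a softmax parameterization from the uniform start
  shift <- apply(lpd_mat, 1, max)
  expd <- exp(lpd_mat - shift)
  obj <- function(theta) {
    w <- exp(c(theta, 0)); w <- w / sum(w)
    -sum(log(expd %*% w))
  }
  opt <- stats::optim(rep(0, K - 1), obj, method = "BFGS",
                      control = list(maxit = 500))
  w <- exp(c(opt$par, 0)); w / sum(w)
}

pseudobma_weights <- function(lpd_mat, bb = TRUE, n_rep = 1000, seed = 1) {
  K <- ncol(lpd_mat); N <- nrow(lpd_mat)
  if (!bb) {
    elpd <- colSums(lpd_mat)
    w <- exp(elpd - max(elpd))
    return(w / sum(w))
  }
  set.seed(seed)
  acc <- rep(0, K)
  for (r in seq_len(n_rep)) {
    wts <- -log(stats::runif(N)); wts <- wts / sum(wts)  # Dirichlet(1,...,1)
    elpd_r <- N * colSums(lpd_mat * wts)
    wr <- exp(elpd_r - max(elpd_r))
    acc <- acc + wr / sum(wr)
  }
  acc / n_rep
}

#' Rank models by LOO
#'
#' Produces the standard comparison table: models sorted by `elpd_loo`
#' (rank 0 = best), the gap to the best model (`d_loo`), model weights
#' and per-model standard errors. Weights default to stacking of the
#' pointwise predictive densities; `method = "pseudobma"` gives
#' Bayesian-bootstrap pseudo-BMA+ weights instead.
#'
#' @param loos list of `loo_result` objects computed on the same
#'   observations.
#' @param method `"stacking"` (default) or `"pseudobma"`.
#' @param seed seed for the pseudo-BMA Bayesian bootstrap.
#' @return data frame of class `loo_comparison` with columns `rank`,
#'   `model`, `elpd_loo`, `p_loo`, `d_loo`, `weight`, `se`.
#' @export
compare_models <- function(loos, method = c("stacking", "pseudobma"),
                           seed = 1) {
  method <- match.arg(method)
  if (length(loos) < 2L) stop("need at least 2 models to compare", call. = FALSE)
  ns <- vapply(loos, function(l) l$n_obs, numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("models were evaluated on different numbers of observations",
         call. = FALSE)
  }
  lpd_mat <- vapply(loos, function(l) l$pointwise, numeric(ns[1]))
  w <- if (method == "stacking") stacking_weights(lpd_mat)
       else pseudobma_weights(lpd_mat, seed = seed)
  elpd <- vapply(loos, function(l) l$elpd_loo, numeric(1))
  tab <- data.frame(
    model = vapply(loos, function(l) l$model, character(1)),
    elpd_loo = elpd,
    p_loo = vapply(loos, function(l) l$p_loo, numeric(1)),
    weight = w,
    se = vapply(loos, function(l) l$se, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$elpd_loo), ]
  tab$rank <- seq_len(nrow(tab)) - 1L
  tab$d_loo <- tab$elpd_loo[1] - tab$elpd_loo
  tab <- tab[, c("rank", "model", "elpd_loo", "p_loo", "d_loo", "weight", "se")]
  rownames(tab) <- NULL
  class(tab) <- c("loo_comparison", "data.frame")
  tab
}

#' Write a comparison table as CSV
#'
#' Column layout mirrors the standard report: `rank`, `model`, `loo`,
#' `p_loo`, `d_loo`, `weight`, `se`.
#'
#' @param tab a `loo_comparison`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(tab, path) {
  out <- data.frame(rank = tab$rank, model = tab$model, loo = tab$elpd_loo,
                    p_loo = tab$p_loo, d_loo = tab$d_loo,
                    weight = tab$weight, se = tab$se)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
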