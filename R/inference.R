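#' Sampler configuration
#'
#' Defaults mirror the study's sampler settings: 1000 posterior draws
#' after 1000 tuning steps per chain, a 0.8 target acceptance rate, no
#' thinning, 4 chains. Sampling is run by JAGS's adaptive MCMC; the
#' tuning budget is split between JAGS's adaptation phase and burn-in,
#' and `target_accept` is recorded in the run metadata (JAGS tunes its
#' own samplers during adaptation).
#'
#' @param draws posterior draws per chain.
#' @param tune tuning (adaptation + burn-in) iterations per chain.
#' @param target_accept target acceptance rate in (0, 1), recorded for
#'   provenance.
#' @param chains number of chains.
#' @param seed integer seed; per-chain RNG seeds are derived from it.
#' @param thin thinning interval (1 = none).
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(draws = 1000, tune = 1000, target_accept = 0.8,
                           chains = 4, seed = 1, thin = 1) {
  cfg <- list(draws = as.integer(draws), tune = as.integer(tune),
              target_accept = target_accept, chains = as.integer(chains),
              seed = as.integer(seed), thin = as.integer(thin))
  if (any(unlist(cfg[c("draws", "tune", "chains", "thin")]) < 1L)) {
    stop("draws, tune, chains and thin must be positive", call. = FALSE)
  }
  if (target_accept <= 0 || target_accept >= 1) {
    stop("target_accept must lie in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sampler_config")
}

#' Fit a model by MCMC
#'
#' Samples the posterior of a `model_spec` with `cfg$chains` chains of
#' the package's adaptive No-U-Turn sampler (`engine = "nuts"`, the
#' default): `cfg$tune` warmup iterations per chain with dual-averaging
#' step-size adaptation toward `cfg$target_accept` and windowed diagonal
#' mass-matrix estimation, then `cfg$draws` retained draws. Bounded
#' parameters are sampled on unconstrained scales with exact Jacobian
#' and truncation-normalization terms, so the posterior is that of the
#' printed truncated hierarchy. `engine = "jags"` instead runs the same
#' model through JAGS adaptive MCMC (useful as an independent
#' cross-check; single-site updates mix poorly on the 5-PL ridge).
#'
#' Returns the draws with convergence diagnostics and the pointwise
#' log-likelihood array needed for LOO. The group-level mean of the
#' lower asymptote, `mu_a = alpha1 / (alpha1 + alpha2)`, is added as a
#' derived parameter for 5-PL-family fits so all five curve parameters
#' can be compared on the group level. A structured warning of class
#' `valtrans_convergence_warning` is raised if any parameter has
#' R-hat >= 1.01 or bulk ESS < 1000; a warning of class
#' `valtrans_divergence_warning` is raised if the post-warmup
#' divergence rate exceeds `divergence_warn`.
#'
#' @param spec a `model_spec` from one of the model builders.
#' @param cfg a [sampler_config()].
#' @param log_lik logical; compute the (chain, draw, observation)
#'   pointwise log-likelihood array (default TRUE; required by
#'   [compute_loo()]).
#' @param quiet suppress sampler progress output.
#' @param engine `"nuts"` (default) or `"jags"`.
#' @param divergence_warn post-warmup divergence rate above which a
#'   structured warning is raised (NUTS engine only).
#' @param init chain initialization for the NUTS engine: `"ls"`
#'   (default) starts every chain at a pooled least-squares curve fit
#'   (jittered), keeping chains inside the data-supported region of the
#'   ridge-shaped 5-PL posterior; `"prior"` starts at the prior centres.
#' @param metric mass-matrix structure for the NUTS engine: `"dense"`
#'   (default) estimates the full posterior covariance in warmup
#'   windows, absorbing the strong within-participant curve-parameter
#'   correlations; `"diag"` uses per-coordinate variances only.
#' @return object of class `posterior_draws`: list with `draws` (3-D
#'   array chain x draw x parameter), `log_lik` (chain x draw x
#'   observation, or NULL), `diagnostics` (per-parameter R-hat and
#'   ESS), `sample_stats` (per-draw NUTS statistics, NUTS engine only),
#'   `spec`, `config`.
#' @export
fit_model <- function(spec, cfg = sampler_config(), log_lik = TRUE,
                      quiet = TRUE, engine = c("nuts", "jags"),
                      divergence_warn = 0.01, init = c("ls", "prior"),
                      metric = c("dense", "diag")) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "sampler_config"))
  engine <- match.arg(engine)
  init <- match.arg(init)
  metric <- match.arg(metric)
  chain_seeds <- derive_seeds(cfg$seed, cfg$chains)
  sample_stats <- NULL
  if (engine == "nuts") {
    target <- make_target(spec)
    keep <- seq(cfg$thin, cfg$draws * cfg$thin, by = cfg$thin)
    params <- target$flat_names
    draws <- array(NA_real_, dim = c(cfg$chains, cfg$draws, length(params)),
                   dimnames = list(NULL, NULL, params))
    stats_list <- vector("list", cfg$chains)
    for (ch in seq_len(cfg$chains)) {
      res <- nuts_chain(target, n_warmup = cfg$tune,
                        n_draws = cfg$draws * cfg$thin,
                        seed = chain_seeds[ch],
                        target_accept = cfg$target_accept,
                        init_mode = init, metric = metric)
      draws[ch, , ] <- res$draws[keep, , drop = FALSE]
      st <- res$stats[keep, , drop = FALSE]
      st$chain <- ch
      stats_list[[ch]] <- st
      if (!quiet) {
        message(sprintf("chain %d: eps %.3g, %d warmup divergences",
                        ch, res$eps, res$divergences_warmup))
      }
    }
    sample_stats <- do.call(rbind, stats_list)
    div_rate <- mean(sample_stats$divergent)
    if (div_rate > divergence_warn) {
      w <- simpleWarning(sprintf(
        "%d divergent transitions after warmup (rate %.3f)",
        sum(sample_stats$divergent), div_rate))
      class(w) <- c("valtrans_divergence_warning", class(w))
      warning(w)
    }
  } else {
    code <- jags_model_code(spec)
    dat <- jags_data_list(spec)
    inits <- lapply(chain_seeds, function(s) jags_inits(spec, s))
    n_adapt <- max(100L, cfg$tune %/% 2L)
    n_burn <- max(0L, cfg$tune - n_adapt)
    run <- function() {
      jm <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                              n.chains = cfg$chains, n.adapt = n_adapt,
                              quiet = quiet)
      if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
      rjags::coda.samples(jm, variable.names = jags_monitors(spec),
                          n.iter = cfg$draws * cfg$thin, thin = cfg$thin,
                          progress.bar = "none")
    }
    samples <- if (quiet) suppressWarnings(run()) else run()
    params <- colnames(samples[[1]])
    draws <- array(NA_real_, dim = c(cfg$chains, cfg$draws, length(params)),
                   dimnames = list(NULL, NULL, params))
    for (ch in seq_len(cfg$chains)) draws[ch, , ] <- as.matrix(samples[[ch]])
  }

  if (spec$kind != "linear") {
    mu_a <- draws[, , "alpha1"] / (draws[, , "alpha1"] + draws[, , "alpha2"])
    dn <- c(dimnames(draws)[[3]], "mu_a")
    draws <- array(c(draws, mu_a), dim = dim(draws) + c(0, 0, 1),
                   dimnames = list(NULL, NULL, dn))
  }

  ll <- if (log_lik) pointwise_log_lik(spec, draws) else NULL
  diag_tab <- diagnostics_table(draws)
  fit <- structure(list(draws = draws, log_lik = ll, diagnostics = diag_tab,
                        sample_stats = sample_stats,
                        spec = spec, config = cfg,
                        participant_ids = spec$data$participant_ids),
                   class = "posterior_draws")
  bad <- diag_tab$rhat >= 1.01 | diag_tab$ess_bulk < 1000
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    w <- simpleWarning(sprintf(
      "convergence bar not met for %d parameter(s): max rhat %.4f, min bulk ESS %.0f",
      sum(bad), max(diag_tab$rhat, na.rm = TRUE),
      min(diag_tab$ess_bulk, na.rm = TRUE)))
    class(w) <- c("valtrans_convergence_warning", class(w))
    warning(w)
  }
  fit
}

# evaluate log p(y_n | theta_s) for every draw and observation
pointwise_log_lik <- function(spec, draws) {
  dn <- dimnames(draws)[[3]]
  n_chain <- dim(draws)[1]; n_draw <- dim(draws)[2]
  x <- spec$data$x; y <- spec$data$y; pid <- spec$data$pid
  N <- length(y)
  P <- length(spec$data$participant_ids)
  ll <- array(NA_real_, dim = c(n_chain, n_draw, N))
  pv <- function(flat, p) flat[, sprintf("%s[%d]", p, seq_len(P)), drop = FALSE]
  for (ch in seq_len(n_chain)) {
    flat <- draws[ch, , , drop = TRUE]
    if (is.null(dim(flat))) flat <- matrix(flat, nrow = 1, dimnames = list(NULL, dn))
    a <- pv(flat, "a"); b <- pv(flat, "b")
    sigma <- flat[, "sigma"]
    if (spec$kind == "linear") {
      for (s in seq_len(n_draw)) {
        mu <- b[s, pid] * x + a[s, pid]
        ll[ch, s, ] <- stats::dnorm(y, mu, sigma[s], log = TRUE)
      }
    } else {
      cc <- pv(flat, "c"); d <- pv(flat, "d"); g <- pv(flat, "g")
      en <- spec$covariates$numbing_z
      az <- spec$covariates$age_z
      for (s in seq_len(n_draw)) {
        B <- b[s, ]
        if (!is.null(en)) B <- B + en * flat[s, "EN"]
        if (!is.null(az) && "AGE" %in% dn) B <- B + az * flat[s, "AGE"]
        if ("INT" %in% dn) B <- B + en * az * flat[s, "INT"]
        mu <- d[s, pid] + (a[s, pid] - d[s, pid]) /
          (1 + (x / cc[s, pid])^B[pid])^g[s, pid]
        ll[ch, s, ] <- stats::dnorm(y, mu, sigma[s], log = TRUE)
      }
    }
  }
  ll
}

diagnostics_table <- function(draws) {
  params <- dimnames(draws)[[3]]
  out <- data.frame(parameter = params, rhat = NA_real_,
                    ess_bulk = NA_real_, ess_tail = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(params)) {
    m <- draws[, , j, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(draws)[1])
    out$rhat[j] <- rhat(m)
    out$ess_bulk[j] <- ess_bulk(m)
    out$ess_tail[j] <- ess_tail(m)
  }
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("posterior_draws: model '%s', %d chains x %d draws, %d parameters\n",
              x$spec$kind, d[1], d[2], d[3]))
  cat(sprintf("  max rhat %.4f, min bulk ESS %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess_bulk, na.rm = TRUE)))
  invisible(x)
}

#' Extract flattened draws of one parameter
#'
#' @param fit a `posterior_draws` object.
#' @param parameter parameter name, e.g. `"mu_b"` or `"b[3]"`.
#' @return numeric vector, chains concatenated in order.
#' @export
extract_draws <- function(fit, parameter) {
  if (!parameter %in% dimnames(fit$draws)[[3]]) {
    stop("parameter not found in fit: ", parameter, call. = FALSE)
  }
  as.vector(t(fit$draws[, , parameter]))
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws; ties in width are broken by the lowest starting index.
#' For a symmetric unimodal posterior this coincides with the central
#' interval. An attribute `multimodal_flag` is set when the interval
#' contains markedly fewer sorted points per unit width than the sample
#' overall, a hint that a single interval may misrepresent a multimodal
#' posterior.
#'
#' @param samples numeric vector of draws (at least 100 for a stable
#'   estimate; fewer are allowed with a warning).
#' @param mass probability mass in (0, 1); default 0.89.
#' @return numeric vector `c(low, high)`.
#' @export
hpd <- function(samples, mass = 0.89) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)", call. = FALSE)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) stop("need at least 2 finite samples", call. = FALSE)
  if (n < 100L) warning("fewer than 100 samples; HPD estimate is unstable")
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)  # which.min takes the first (lowest start) on ties
  out <- c(s[i], s[i + m - 1L])
  range_all <- s[n] - s[1]
  if (range_all > 0 && widths[i] > 0) {
    density_in <- m / widths[i]
    density_all <- n / range_all
    attr(out, "multimodal_flag") <- density_in < density_all
  }
  out
}

#' Posterior group comparison by subtraction
#'
#' Subtracts the draws of `fit2` from those of `fit1` parameter by
#' parameter (pass the TEC fit first and the pPTSD fit second to get
#' the reported TEC − pPTSD direction), pairing draws by flattened
#' (chain, draw) index — the two posteriors are independent, so this
#' pairing is equivalent to random pairing. A difference is robust when
#' 0 falls outside its `mass` HPD interval. Unequal draw counts are
#' reconciled by seeded subsampling of the longer set without
#' replacement.
#'
#' @param fit1,fit2 `posterior_draws` objects (group 1 minus group 2).
#' @param params character vector of parameter names present in both
#'   fits (e.g. `c("mu_a", "mu_b", "mu_c", "mu_d", "mu_g")`).
#' @param mass HPD mass, default 0.89.
#' @param seed seed for subsampling when draw counts differ.
#' @return data frame with columns `parameter`, `mean_diff`, `hpd_low`,
#'   `hpd_high`, `robust`; the difference draws are attached as the
#'   `"difference_draws"` attribute.
#' @export
compare_groups <- function(fit1, fit2, params, mass = 0.89, seed = 1) {
  have1 <- dimnames(fit1$draws)[[3]]; have2 <- dimnames(fit2$draws)[[3]]
  missing_p <- setdiff(params, intersect(have1, have2))
  if (length(missing_p)) {
    stop("parameter(s) missing from a fit: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  diffs <- list()
  rows <- lapply(params, function(p) {
    d1 <- extract_draws(fit1, p); d2 <- extract_draws(fit2, p)
    n <- min(length(d1), length(d2))
    if (length(d1) != length(d2)) {
      set.seed(seed)
      if (length(d1) > n) d1 <- d1[sort(sample.int(length(d1), n))]
      if (length(d2) > n) d2 <- d2[sort(sample.int(length(d2), n))]
    }
    dd <- d1 - d2
    h <- hpd(dd, mass)
    diffs[[p]] <<- dd
    data.frame(parameter = p, mean_diff = mean(dd),
               hpd_low = h[1], hpd_high = h[2],
               robust = (h[1] > 0 || h[2] < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "difference_draws") <- diffs
  out
}

#' Convergence report for a fit
#'
#' Per-parameter split-chain rank-normalized R-hat and rank-normalized
#' bulk/tail effective sample sizes, with a flag for any violation of
#' the convergence bar (R-hat < 1.01, bulk ESS > 1000).
#'
#' @param fit a `posterior_draws` with at least 2 chains.
#' @return data frame: `parameter`, `rhat`, `ess_bulk`, `ess_tail`,
#'   `flagged`.
#' @export
diagnostics_report <- function(fit) {
  if (dim(fit$draws)[1] < 2L) {
    stop("R-hat requires at least 2 chains", call. = FALSE)
  }
  tab <- fit$diagnostics
  tab$flagged <- (tab$rhat >= 1.01 | tab$ess_bulk <= 1000)
  tab$flagged[is.na(tab$flagged)] <- FALSE
  tab
}

# --- persistence: self-describing directory store ----------------------

#' Persist or restore a fit
#'
#' Writes a `posterior_draws` object to a self-describing directory
#' layout grouped like an inference-data store: `meta.json` (model
#' kind, dimensions, sampler config, parameter names),
#' `posterior.csv` (chain, draw, one column per parameter),
#' `sample_stats.csv` (the diagnostics table) and, when present,
#' `log_likelihood.csv` (chain, draw, one column per observation).
#'
#' @param fit a `posterior_draws`.
#' @param dir directory to create/overwrite.
#' @return `read_fit()` returns the restored `posterior_draws`;
#'   `write_fit()` returns `dir` invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(fit$draws)
  params <- dimnames(fit$draws)[[3]]
  meta <- list(kind = fit$spec$kind, chains = d[1], draws = d[2],
               parameters = params,
               participant_ids = fit$participant_ids,
               config = unclass(fit$config),
               has_log_lik = !is.null(fit$log_lik))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  model_spec_to_json(fit$spec, file.path(dir, "model_spec.json"))
  flat <- do.call(rbind, lapply(seq_len(d[1]), function(ch) {
    cbind(chain = ch, draw = seq_len(d[2]), fit$draws[ch, , , drop = TRUE])
  }))
  utils::write.csv(as.data.frame(flat), file.path(dir, "posterior.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$diagnostics, file.path(dir, "diagnostics.csv"),
                   row.names = FALSE)
  if (!is.null(fit$sample_stats)) {
    utils::write.csv(fit$sample_stats, file.path(dir, "sample_stats.csv"),
                     row.names = FALSE)
  }
  if (!is.null(fit$log_lik)) {
    N <- dim(fit$log_lik)[3]
    flatll <- do.call(rbind, lapply(seq_len(d[1]), function(ch) {
      cbind(chain = ch, draw = seq_len(d[2]), fit$log_lik[ch, , , drop = TRUE])
    }))
    colnames(flatll) <- c("chain", "draw", sprintf("obs_%d", seq_len(N)))
    utils::write.csv(as.data.frame(flatll),
                     file.path(dir, "log_likelihood.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  spec <- model_spec_from_json(file.path(dir, "model_spec.json"))
  post <- utils::read.csv(file.path(dir, "posterior.csv"), check.names = FALSE)
  params <- setdiff(colnames(post), c("chain", "draw"))
  draws <- array(NA_real_, dim = c(meta$chains, meta$draws, length(params)),
                 dimnames = list(NULL, NULL, params))
  for (ch in seq_len(meta$chains)) {
    draws[ch, , ] <- as.matrix(post[post$chain == ch, params])
  }
  ll <- NULL
  llp <- file.path(dir, "log_likelihood.csv")
  if (isTRUE(meta$has_log_lik) && file.exists(llp)) {
    f <- utils::read.csv(llp, check.names = FALSE)
    obs <- setdiff(colnames(f), c("chain", "draw"))
    ll <- array(NA_real_, dim = c(meta$chains, meta$draws, length(obs)))
    for (ch in seq_len(meta$chains)) {
      ll[ch, , ] <- as.matrix(f[f$chain == ch, obs])
    }
  }
  diag_tab <- utils::read.csv(file.path(dir, "diagnostics.csv"))
  ssp <- file.path(dir, "sample_stats.csv")
  sstats <- if (file.exists(ssp)) utils::read.csv(ssp) else NULL
  cfg <- do.call(sampler_config, meta$config)
  structure(list(draws = draws, log_lik = ll, diagnostics = diag_tab,
                 sample_stats = sstats,
                 spec = spec, config = cfg,
                 participant_ids = meta$participant_ids),
            class = "posterior_draws")
}
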