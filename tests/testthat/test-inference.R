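test_that("hpd matches the normal-quantile oracle on a large sample", {
  set.seed(1)
  z <- rnorm(1e6)
  h <- hpd(z, 0.89)
  # symmetric unimodal: HPD equals the central interval, +/-1.598 for 89%
  expect_equal(h[1], -1.598, tolerance = 0.01)
  expect_equal(h[2], 1.598, tolerance = 0.01)
})

test_that("hpd handles degenerate and limiting cases", {
  expect_equal(suppressWarnings(hpd(rep(3.2, 50), 0.89)), c(3.2, 3.2))
  set.seed(2)
  z <- rnorm(5000)
  wide <- hpd(z, 0.999999)
  expect_equal(wide, range(z))
  expect_error(hpd(z, 0), "mass")
  expect_error(hpd(z, 1), "mass")
  expect_warning(hpd(rnorm(20)), "100 samples")
})

test_that("hpd width is monotone in mass", {
  set.seed(3)
  z <- c(rnorm(3000), rnorm(1000, 4))  # asymmetric, bimodal-ish
  widths <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.89, 0.95), function(m) {
    diff(hpd(z, m))
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("rank-normalized split R-hat separates converged from stuck chains", {
  set.seed(4)
  iid <- matrix(rnorm(4000), nrow = 4)
  expect_gte(rhat(iid), 0.99)  # can dip fractionally below 1 by chance
  expect_lt(rhat(iid), 1.01)
  off <- iid; off[1, ] <- off[1, ] + 10
  expect_gt(rhat(off), 1.2)
  # within-chain trend is caught by chain splitting
  trend <- matrix(rnorm(4000), nrow = 4) +
    matrix(rep(seq(0, 3, length.out = 1000), each = 4), nrow = 4)
  expect_gt(rhat(trend), 1.01)
})

test_that("effective sample size behaves like the i.i.d. oracle", {
  set.seed(5)
  iid <- matrix(rnorm(4000), nrow = 4)
  e <- ess_bulk(iid)
  expect_gt(e, 4000 * 0.8)
  expect_lt(e, 4000 * 1.25)
  expect_gt(ess_tail(iid), 1000)
  # strong autocorrelation slashes the ESS
  ar <- matrix(0, nrow = 4, ncol = 1000)
  for (ch in 1:4) {
    x <- numeric(1000); x[1] <- rnorm(1)
    for (t in 2:1000) x[t] <- 0.95 * x[t - 1] + rnorm(1, 0, sqrt(1 - 0.95^2))
    ar[ch, ] <- x
  }
  expect_lt(ess_bulk(ar), 1000)
})

test_that("posterior recovery on the linear model matches least squares", {
  # with much data and weak priors, the Bayesian posterior mean of each
  # participant line must agree with the per-participant OLS oracle
  set.seed(6)
  norms <- fixture_norms(n_images = 25)
  x <- norms$valence_mean
  truth <- list(a = c(0.10, 0.22), b = c(0.05, 0.09))
  ratings <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(participant_id = paste0("p", i), image_id = norms$image_id,
               rating = pmin(1, pmax(0, truth$a[i] + truth$b[i] * x +
                                       rnorm(25, 0, 0.03))))
  }))
  spec <- build_linear_model(ratings, norms)
  fit <- suppressWarnings(fit_model(spec, sampler_config(draws = 500, tune = 500,
                                                         chains = 2, seed = 7),
                                    log_lik = FALSE))
  for (i in 1:2) {
    ols <- coef(lm(rating ~ x, data = cbind(ratings[ratings$participant_id ==
                                                      paste0("p", i), ], x = x)))
    pa <- extract_draws(fit, sprintf("a[%d]", i))
    pb <- extract_draws(fit, sprintf("b[%d]", i))
    expect_lt(abs(mean(pa) - ols[1]), 3 * sd(pa) + 0.01)
    expect_lt(abs(mean(pb) - ols[2]), 3 * sd(pb) + 0.005)
  }
})

test_that("posterior mean curves recover the generating curves", {
  # the identifiable quantity of the 5-PL fit is the curve itself (the
  # parameter vector rides a ridge); check function-space recovery
  for (seed in c(201, 202)) {
    norms <- generate_norms(n_images = 15, n_positive = 0, seed = seed)
    gen <- generator_config(n_per_group = 6, n_images = 15,
                            en_slope_coeff = 0, seed = seed + 1)
    sim <- generate_participants(gen, norms)
    spec <- build_5pl_model(sim$ratings, norms)
    fit <- suppressWarnings(fit_model(spec, sampler_config(
      draws = 250, tune = 300, chains = 2, seed = seed + 2), log_lik = FALSE))
    x <- norms$valence_mean
    err <- vapply(seq_along(fit$participant_ids), function(i) {
      pid <- fit$participant_ids[i]
      tr <- sim$truth[sim$truth$participant_id == pid, ]
      truth_curve <- five_pl(x, tr$a, tr$B, tr$c, tr$d, tr$g)
      par_of <- function(p) mean(extract_draws(fit, sprintf("%s[%d]", p, i)))
      # posterior-mean curve from pointwise posterior mean predictions
      draws_curve <- rowMeans(vapply(seq_len(200), function(s) {
        ch <- 1 + (s - 1) %/% 100; dr <- 1 + (s - 1) %% 100
        five_pl(x, fit$draws[ch, dr, sprintf("a[%d]", i)],
                fit$draws[ch, dr, sprintf("b[%d]", i)],
                fit$draws[ch, dr, sprintf("c[%d]", i)],
                fit$draws[ch, dr, sprintf("d[%d]", i)],
                fit$draws[ch, dr, sprintf("g[%d]", i)])
      }, numeric(length(x))))
      mean(abs(draws_curve - truth_curve))
    }, numeric(1))
    # mean absolute error well below the rating noise SD of 0.05
    expect_lt(mean(err), 0.03)
    # and the observation noise itself is recovered
    sig <- extract_draws(fit, "sigma")
    expect_lt(abs(mean(sig) - 0.05), 0.01)
  }
})

test_that("fits are deterministic under a fixed seed", {
  fit <- shared_small_fit()
  spec <- fit$spec
  cfg <- sampler_config(draws = 40, tune = 80, chains = 2, seed = 11)
  f1 <- suppressWarnings(fit_model(spec, cfg, log_lik = FALSE))
  f2 <- suppressWarnings(fit_model(spec, cfg, log_lik = FALSE))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_model(spec, sampler_config(draws = 40, tune = 80,
                                                        chains = 2, seed = 12),
                                   log_lik = FALSE))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("NUTS agrees with the independent JAGS engine on a small model", {
  fit <- shared_small_fit()
  jfit <- suppressWarnings(fit_model(fit$spec,
                                     sampler_config(draws = 1500, tune = 1500,
                                                    chains = 2, seed = 21),
                                     log_lik = FALSE, engine = "jags"))
  for (p in c("mu_d", "sigma", "alpha2")) {
    dn <- extract_draws(fit, p); dj <- extract_draws(jfit, p)
    pooled <- sqrt(sd(dn)^2 + sd(dj)^2)
    expect_lt(abs(mean(dn) - mean(dj)), 0.5 * pooled + 0.02)
  }
})

test_that("group comparison flags direction, antisymmetry and pairing", {
  fit <- shared_small_fit()
  # self-comparison: centred at zero, never robust
  cmp <- compare_groups(fit, fit, c("mu_a", "mu_b", "mu_c", "mu_d", "mu_g"))
  expect_equal(cmp$mean_diff, rep(0, 5))
  expect_false(any(cmp$robust))

  # shifted copy: robust with the expected sign, antisymmetric on swap
  fit2 <- fit
  fit2$draws[, , "mu_b"] <- fit2$draws[, , "mu_b"] + 1
  c12 <- compare_groups(fit, fit2, "mu_b")
  c21 <- compare_groups(fit2, fit, "mu_b")
  expect_true(c12$robust)
  expect_lt(c12$hpd_high, 0)
  expect_equal(c12$hpd_low, -c21$hpd_high, tolerance = 1e-12)
  expect_equal(c12$hpd_high, -c21$hpd_low, tolerance = 1e-12)

  expect_error(compare_groups(fit, fit2, "nonexistent"), "nonexistent")

  # pairwise subtraction vs random pairing: for independent posteriors
  # the two give the same interval within Monte-Carlo error
  set.seed(9)
  d1 <- rnorm(4000, 1.2, 0.3)
  d2 <- rnorm(4000, 1.45, 0.3)
  h_pair <- hpd(d1 - d2, 0.89)
  h_rand <- hpd(d1 - sample(d2), 0.89)
  # interval endpoints slide along a near-flat width profile, so compare
  # the stable summaries: width and centre
  expect_equal(diff(h_pair), diff(h_rand), tolerance = 0.05)
  expect_lt(abs(mean(h_pair) - mean(h_rand)), 0.1)
})

test_that("diagnostics report flags violations and needs multiple chains", {
  fit <- shared_small_fit()
  rep <- diagnostics_report(fit)
  expect_true(all(c("parameter", "rhat", "ess_bulk", "ess_tail", "flagged")
                  %in% names(rep)))
  one <- fit
  one$draws <- fit$draws[1, , , drop = FALSE]
  expect_error(diagnostics_report(one), "2 chains")
})

test_that("fits persist to the directory store and restore losslessly", {
  fit <- shared_small_fit()
  dir <- tempfile("fitstore")
  on.exit(unlink(dir, recursive = TRUE))
  write_fit(fit, dir)
  expect_true(file.exists(file.path(dir, "meta.json")))
  expect_true(file.exists(file.path(dir, "posterior.csv")))
  expect_true(file.exists(file.path(dir, "sample_stats.csv")))
  expect_true(file.exists(file.path(dir, "log_likelihood.csv")))
  back <- read_fit(dir)
  expect_equal(back$draws, fit$draws, tolerance = 1e-12)
  expect_equal(back$log_lik, fit$log_lik, tolerance = 1e-12)
  expect_equal(back$spec$kind, fit$spec$kind)
  expect_equal(back$participant_ids, fit$participant_ids)
})
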