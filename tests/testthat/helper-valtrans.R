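# shared fixtures and independent oracles for the test suite

# brute-force PCL-5 scorer: explicit loops over the printed cluster rule,
# kept deliberately independent of score_pcl5()
brute_force_pcl5 <- function(items) {
  total <- 0
  for (v in items) total <- total + v
  count_endorsed <- function(lo, hi) {
    k <- 0
    for (j in lo:hi) if (items[j] >= 2) k <- k + 1
    k
  }
  ok <- total > 33 &&
    count_endorsed(1, 5) >= 1 &&
    count_endorsed(6, 7) >= 1 &&
    count_endorsed(8, 14) >= 2 &&
    count_endorsed(15, 20) >= 2
  list(total = total,
       group = if (ok) "pPTSD" else "TEC",
       numbing = items[12] + items[13] + items[14])
}

# norms with zero jitter for deterministic screening fixtures
fixture_norms <- function(n_images = 10, n_positive = 0, seed = 99) {
  generate_norms(n_images = n_images, n_positive = n_positive, seed = seed,
                 jitter_frac = 0, sd_range = c(0.8, 1.6))
}

# one rating row per image, exactly on the rescaled norm mean
fixture_exact_ratings <- function(norms, pid = "p1") {
  data.frame(participant_id = pid, image_id = norms$image_id,
             rating = (norms$valence_mean - 1) / 8,
             stringsAsFactors = FALSE)
}

# small shared 5-PL fit, built once per test run
.fit_cache <- new.env(parent = emptyenv())
shared_small_fit <- function() {
  if (!is.null(.fit_cache$fit)) return(.fit_cache$fit)
  norms <- generate_norms(n_images = 12, n_positive = 0, seed = 301)
  cfg <- generator_config(n_per_group = 6, n_images = 12,
                          mu_b = c(TEC = 1.4, pPTSD = 1.4),
                          en_slope_coeff = 0, seed = 302)
  sim <- generate_participants(cfg, norms)
  spec <- build_5pl_model(sim$ratings, norms)
  fit <- suppressWarnings(
    fit_model(spec, sampler_config(draws = 300, tune = 300, chains = 2,
                                   seed = 303)))
  .fit_cache$fit <- fit
  .fit_cache$sim <- sim
  .fit_cache$norms <- norms
  fit
}

# analytic posterior draws and exact leave-one-out elpd for the conjugate
# normal-normal model with known observation SD
conjugate_posterior <- function(y, sigma, mu0, tau0) {
  n <- length(y)
  prec <- 1 / tau0^2 + n / sigma^2
  list(mean = (mu0 / tau0^2 + sum(y) / sigma^2) / prec, sd = sqrt(1 / prec))
}

exact_loo_conjugate <- function(y, sigma, mu0, tau0) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    post <- conjugate_posterior(y[-i], sigma, mu0, tau0)
    out[i] <- dnorm(y[i], post$mean, sqrt(sigma^2 + post$sd^2), log = TRUE)
  }
  sum(out)
}

# wrap analytic draws of mu into the minimal posterior_draws shape that
# compute_loo() consumes
conjugate_fake_fit <- function(mu_draws, y, sigma, chains = 2) {
  S <- length(mu_draws)
  per <- S %/% chains
  ll <- array(NA_real_, dim = c(chains, per, length(y)))
  for (ch in seq_len(chains)) {
    idx <- ((ch - 1) * per + 1):(ch * per)
    for (s in seq_along(idx)) {
      ll[ch, s, ] <- dnorm(y, mu_draws[idx[s]], sigma, log = TRUE)
    }
  }
  structure(list(log_lik = ll, spec = list(kind = "conjugate")),
            class = "posterior_draws")
}
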