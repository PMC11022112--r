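test_that("prior constants table carries the printed values exactly once", {
  tab <- default_priors("fivepl")
  expect_equal(sum(tab$parameter == "alpha1"), 1)
  row <- function(p) tab[tab$parameter == p, ]
  expect_equal(unlist(row("alpha1")[, c("mean", "sd", "lower", "upper")],
                      use.names = FALSE), c(2, 1, 1, Inf))
  expect_equal(unlist(row("alpha2")[, c("mean", "sd", "lower", "upper")],
                      use.names = FALSE), c(10, 1, -Inf, Inf))
  expect_equal(unlist(row("mu_b")[, c("mean", "sd", "lower", "upper")],
                      use.names = FALSE), c(2, 1, 1, Inf))
  expect_equal(unlist(row("mu_c")[, c("mean", "sd", "lower", "upper")],
                      use.names = FALSE), c(2, 1, 0.5, Inf))
  expect_equal(unlist(row("mu_d")[, c("mean", "sd", "lower", "upper")],
                      use.names = FALSE), c(2, 1, 0, Inf))
  expect_equal(unlist(row("mu_g")[, c("mean", "sd", "lower", "upper")],
                      use.names = FALSE), c(4, 1, 1, Inf))
  expect_equal(unlist(row("b")[, c("sd", "lower", "upper")],
                      use.names = FALSE), c(1, 0.5, Inf))
  expect_equal(unlist(row("c")[, c("sd", "lower", "upper")],
                      use.names = FALSE), c(1, 0.5, 5))
  expect_equal(unlist(row("d")[, c("sd", "lower", "upper")],
                      use.names = FALSE), c(1, 0.5, Inf))
  expect_equal(unlist(row("g")[, c("sd", "lower", "upper")],
                      use.names = FALSE), c(1, 0.8, Inf))
  expect_equal(row("sigma")$sd, 0.2)

  lin <- default_priors("linear")
  lrow <- function(p) lin[lin$parameter == p, ]
  expect_equal(unlist(lrow("mu_a")[, c("mean", "sd", "lower")],
                      use.names = FALSE), c(0, 0.2, 0))
  expect_equal(unlist(lrow("mu_b")[, c("mean", "sd", "lower")],
                      use.names = FALSE), c(0, 0.5, 0))
  expect_equal(default_priors("fivepl_en")[
    default_priors("fivepl_en")$parameter == "EN", c("mean", "sd")],
    data.frame(mean = 0, sd = 1), ignore_attr = TRUE)
})

test_that("model builders validate data bindings", {
  norms <- fixture_norms(n_images = 5)
  ratings <- do.call(rbind, lapply(c("p1", "p2", "p3"), function(p) {
    fixture_exact_ratings(norms, p)
  }))
  spec <- build_5pl_model(ratings, norms)
  expect_s3_class(spec, "model_spec")
  expect_equal(length(spec$data$participant_ids), 3)
  expect_equal(length(spec$data$y), 15)

  bad <- ratings; bad$image_id[1] <- "zzz"
  expect_error(build_5pl_model(bad, norms), "zzz")
  bad2 <- ratings; bad2$rating[1] <- 1.5
  expect_error(build_5pl_model(bad2, norms), "\\[0, 1\\]")
  expect_error(build_5pl_model(ratings[ratings$participant_id == "p1", ], norms),
               "2 participants")
  expect_error(build_5pl_model(ratings, norms, participant_index = c("p1", "p2")),
               "p3")
  expect_error(build_en_model(ratings, norms, numbing_z = c(0, 0)),
               "per participant")
  expect_error(build_en_model(ratings, norms, numbing_z = c(-1, 0, 1),
                              extra = "age"), "age_z")
  # prior overrides land in the table; unknown names are rejected
  sp <- build_5pl_model(ratings, norms, priors = list(mu_b = list(mean = 3)))
  expect_equal(sp$priors$mean[sp$priors$parameter == "mu_b"], 3)
  expect_error(build_5pl_model(ratings, norms, priors = list(zz = list(mean = 1))),
               "zz")
})

test_that("model structure exposes the printed hierarchy", {
  # 3 participants x 5 images: 6 group-level parameters, 5 participant
  # vectors of length 3, a likelihood scale, and the derived mu_a
  norms <- fixture_norms(n_images = 5)
  ratings <- do.call(rbind, lapply(c("p1", "p2", "p3"), function(p) {
    r <- fixture_exact_ratings(norms, p)
    r$rating <- pmin(1, pmax(0, r$rating + stats::rnorm(5, 0, 0.02)))
    r
  }))
  spec <- build_5pl_model(ratings, norms)
  fit <- suppressWarnings(fit_model(spec, sampler_config(draws = 50, tune = 100,
                                                         chains = 2, seed = 1),
                                    log_lik = FALSE))
  params <- dimnames(fit$draws)[[3]]
  group <- c("alpha1", "alpha2", "mu_b", "mu_c", "mu_d", "mu_g")
  expect_true(all(group %in% params))
  for (p in c("a", "b", "c", "d", "g")) {
    expect_true(all(sprintf("%s[%d]", p, 1:3) %in% params))
  }
  expect_true("sigma" %in% params)
  expect_true("mu_a" %in% params)
  expect_equal(length(params), 6 + 5 * 3 + 1 + 1)

  # posterior draws respect the printed truncations
  dr <- fit$draws
  expect_true(all(dr[, , "alpha1"] >= 1))
  expect_true(all(dr[, , "alpha2"] > 0))
  for (i in 1:3) {
    expect_true(all(dr[, , sprintf("a[%d]", i)] > 0 &
                      dr[, , sprintf("a[%d]", i)] < 1))
    expect_true(all(dr[, , sprintf("b[%d]", i)] >= 0.5))
    expect_true(all(dr[, , sprintf("c[%d]", i)] >= 0.5 &
                      dr[, , sprintf("c[%d]", i)] <= 5))
    expect_true(all(dr[, , sprintf("d[%d]", i)] >= 0.5))
    expect_true(all(dr[, , sprintf("g[%d]", i)] >= 0.8))
  }

  lspec <- build_linear_model(ratings, norms)
  lfit <- suppressWarnings(fit_model(lspec, sampler_config(draws = 50, tune = 100,
                                                           chains = 2, seed = 2),
                                     log_lik = FALSE))
  lp <- dimnames(lfit$draws)[[3]]
  expect_setequal(lp, c("mu_a", "mu_b", "sigma",
                        sprintf("a[%d]", 1:3), sprintf("b[%d]", 1:3)))
  expect_true(all(lfit$draws[, , "mu_a"] >= 0))
  expect_true(all(lfit$draws[, , "mu_b"] >= 0))
  for (i in 1:3) {
    expect_true(all(lfit$draws[, , sprintf("a[%d]", i)] >= 0))
    expect_true(all(lfit$draws[, , sprintf("b[%d]", i)] >= 0))
  }
})

test_that("log density is finite inside the support and -Inf outside", {
  norms <- fixture_norms(n_images = 5)
  ratings <- rbind(fixture_exact_ratings(norms, "p1"),
                   fixture_exact_ratings(norms, "p2"))
  spec <- build_5pl_model(ratings, norms)
  valid <- list(alpha1 = 2, alpha2 = 10, mu_b = 2, mu_c = 2, mu_d = 1,
                mu_g = 4, sigma = 0.1,
                a = c(0.1, 0.15), b = c(2, 2.2), c = c(2, 2.5),
                d = c(0.6, 0.65), g = c(1.5, 1.2))
  expect_true(is.finite(model_log_density(spec, valid)))
  bad_b <- valid; bad_b$b[1] <- 0.4              # below participant bound
  expect_identical(model_log_density(spec, bad_b), -Inf)
  bad_c <- valid; bad_c$c[2] <- 5.5              # above interval bound
  expect_identical(model_log_density(spec, bad_c), -Inf)
  bad_g <- valid; bad_g$g[1] <- 0.7
  expect_identical(model_log_density(spec, bad_g), -Inf)
  bad_a2 <- valid; bad_a2$alpha2 <- -0.5         # positivity guard
  expect_identical(model_log_density(spec, bad_a2), -Inf)
  bad_mu <- valid; bad_mu$mu_b <- 0.9            # below group bound
  expect_identical(model_log_density(spec, bad_mu), -Inf)
})

test_that("model specs serialize losslessly", {
  norms <- fixture_norms(n_images = 6)
  ratings <- rbind(fixture_exact_ratings(norms, "p1"),
                   fixture_exact_ratings(norms, "p2"),
                   fixture_exact_ratings(norms, "p3"))
  spec <- build_en_model(ratings, norms, numbing_z = c(-1.2, 0.2, 1.0),
                         priors = list(mu_b = list(mean = 2.5)))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  model_spec_to_json(spec, path)
  back <- model_spec_from_json(path)
  expect_equal(back$kind, spec$kind)
  expect_equal(back$priors, spec$priors)
  expect_equal(back$data$x, spec$data$x)
  expect_equal(back$data$y, spec$data$y)
  expect_equal(back$data$pid, spec$data$pid)
  expect_equal(back$covariates$numbing_z, spec$covariates$numbing_z)
  expect_equal(back$options, spec$options)
})

test_that("EN model with zero covariate leaves the coefficient at its prior", {
  norms <- fixture_norms(n_images = 8)
  set.seed(5)
  ratings <- do.call(rbind, lapply(c("p1", "p2", "p3", "p4"), function(p) {
    r <- fixture_exact_ratings(norms, p)
    r$rating <- pmin(1, pmax(0, r$rating + stats::rnorm(8, 0, 0.05)))
    r
  }))
  spec <- build_en_model(ratings, norms, numbing_z = rep(0, 4))
  fit <- suppressWarnings(fit_model(spec, sampler_config(draws = 400, tune = 400,
                                                         chains = 2, seed = 3),
                                    log_lik = FALSE))
  en <- extract_draws(fit, "EN")
  # likelihood is invariant to EN, so the posterior is its Normal(0,1) prior
  expect_lt(abs(mean(en)), 0.2)
  expect_gt(sd(en), 0.8)
  expect_lt(sd(en), 1.25)
})
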