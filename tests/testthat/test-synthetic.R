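test_that("generated norms span the design's valence range", {
  norms <- generate_norms(n_images = 35, n_positive = 5, seed = 3)
  expect_equal(nrow(norms), 40)
  neg <- norms$valence_mean[1:35]
  expect_equal(min(neg), 1.33)
  expect_equal(max(neg), 5.0)
  expect_true(all(diff(neg) > 0))
  pos <- norms$valence_mean[36:40]
  expect_true(all(pos >= 5.63 & pos <= 7.09))
  expect_true(all(norms$valence_sd >= 0.8 & norms$valence_sd <= 1.6))

  two <- generate_norms(n_images = 2, n_positive = 0, seed = 1, jitter_frac = 0)
  expect_equal(two$valence_mean, c(1.33, 5.0))

  expect_identical(generate_norms(seed = 42), generate_norms(seed = 42))
  expect_false(identical(generate_norms(seed = 42), generate_norms(seed = 43)))
})

test_that("generator config validates its invariants", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(noise_sd = 0), "SDs")
  expect_error(generator_config(mu_c = 5.5), "mu_c")
  expect_error(generator_config(mu_b = c(TEC = 0.2, pPTSD = 1.4)), ">= 0.5")
  expect_error(generator_config(mu_b = c(1.2, 1.4)), "named")
  # upper asymptote spilling over the VAS scale is a configuration error
  expect_error(generator_config(mu_d = 1.1, sd_d = 0.01), "outside")
  expect_error(generator_config(mu_d = 0.9, sd_d = 0.1), "outside")
})

test_that("noiseless limit reproduces the group curve exactly", {
  norms <- generate_norms(n_images = 8, n_positive = 0, seed = 4)
  eps <- 1e-9
  cfg <- generator_config(n_per_group = 3, n_images = 8,
                          mu_b = c(TEC = 2.0, pPTSD = 2.0),
                          sd_b = eps, sd_c = eps, sd_d = eps, sd_g = eps,
                          noise_sd = eps, en_slope_coeff = 0, seed = 5)
  sim <- generate_participants(cfg, norms)
  # every participant's ratings equal the group 5-PL curve at their own a_i
  for (pid in sim$truth$participant_id) {
    r <- sim$ratings$rating[sim$ratings$participant_id == pid]
    ai <- sim$truth$a[sim$truth$participant_id == pid]
    expect_equal(r, five_pl(norms$valence_mean, ai, cfg$mu_b[["TEC"]],
                            cfg$mu_c, cfg$mu_d, cfg$mu_g),
                 tolerance = 1e-5)
  }
})

test_that("generated data satisfy the structural invariants", {
  norms <- generate_norms(n_images = 20, n_positive = 3, seed = 6)
  cfg <- generator_config(n_per_group = 30, n_images = 20, seed = 7)
  sim <- generate_participants(cfg, norms)

  expect_true(all(sim$ratings$rating >= 0 & sim$ratings$rating <= 1))
  expect_equal(nrow(sim$ratings), 60 * 23)

  # screening labels reproduce the intended groups for every participant
  diag <- score_pcl5_table(sim$questionnaires)
  expect_equal(diag$group[match(sim$truth$participant_id, diag$participant_id)],
               sim$truth$group)
  # numbing is higher in the pPTSD group by construction
  expect_gt(mean(sim$truth$numbing[sim$truth$group == "pPTSD"]),
            mean(sim$truth$numbing[sim$truth$group == "TEC"]))
  # positive EN coupling: true slope correlates with the numbing z-score
  expect_gt(cor(sim$truth$B, sim$truth$en_z), 0)

  # determinism: identical seed, identical tables
  sim2 <- generate_participants(cfg, norms)
  expect_identical(sim, sim2)
})

test_that("per-participant least-squares slopes separate the groups", {
  norms <- generate_norms(n_images = 25, n_positive = 0, seed = 8)
  cfg <- generator_config(n_per_group = 15, n_images = 25,
                          en_slope_coeff = 0, seed = 9)
  sim <- generate_participants(cfg, norms)
  x <- norms$valence_mean
  ls_slope <- function(y) {
    sse <- function(p) sum((y - five_pl(x, p[1], p[2], p[3], p[4], p[5]))^2)
    stats::optim(c(0.1, 2, 2.5, 0.6, 1.5), sse, method = "L-BFGS-B",
                 lower = c(1e-3, 0.5, 0.5, 0.5, 0.8),
                 upper = c(0.999, 8, 5, 2, 8))$par[2]
  }
  ids <- sim$truth$participant_id
  slopes <- vapply(ids, function(pid) {
    ls_slope(sim$ratings$rating[sim$ratings$participant_id == pid])
  }, numeric(1))
  grp <- sim$truth$group
  expect_gt(mean(slopes[grp == "pPTSD"]), mean(slopes[grp == "TEC"]))
})

test_that("outlier injection drives the exclusion rule as constructed", {
  norms <- generate_norms(n_images = 12, n_positive = 0, seed = 10)
  cfg <- generator_config(n_per_group = 5, n_images = 12, seed = 11)
  sim <- generate_participants(cfg, norms)

  inj3 <- inject_outliers(sim$ratings, norms, n_participants = 3,
                          n_images_each = 3, seed = 12)
  v <- flag_outliers(inj3$ratings, norms)
  flagged <- v$participant_id[v$excluded]
  expect_true(all(inj3$participant_ids %in% flagged))

  inj2 <- inject_outliers(sim$ratings, norms, n_participants = 3,
                          n_images_each = 2, seed = 12)
  v2 <- flag_outliers(inj2$ratings, norms)
  expect_false(any(inj2$participant_ids %in% v2$participant_id[v2$excluded]))

  inj0 <- inject_outliers(sim$ratings, norms, n_participants = 0,
                          n_images_each = 3, seed = 12)
  expect_identical(inj0$ratings, sim$ratings)

  expect_error(inject_outliers(sim$ratings, norms, n_participants = 99,
                               n_images_each = 3, seed = 1), "exceeds")
})
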