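test_that("score_pcl5 handles boundary and rule-edge item vectors", {
  z <- score_pcl5(rep(0L, 20))
  expect_equal(z$total, 0L)
  expect_equal(z$group, "TEC")
  expect_equal(z$numbing, 0L)

  s <- score_pcl5(rep(4L, 20))
  expect_equal(s$total, 80L)
  expect_equal(s$group, "pPTSD")
  expect_true(all(s$cluster_flags))
  expect_equal(s$numbing, 12L)

  # three clusters endorsed but total 28 <= 33: still a control
  mid <- score_pcl5(c(rep(2L, 14), rep(0L, 6)))
  expect_equal(mid$total, 28L)
  expect_equal(mid$group, "TEC")
  expect_true(mid$cluster_flags[["intrusion"]])
  expect_true(mid$cluster_flags[["cogmood"]])
  expect_false(mid$cluster_flags[["arousal"]])

  # total 40 but both avoidance items below 2: avoidance cluster fails
  v <- c(4L, 4L, 0L, 0L, 0L, 1L, 1L, 4L, 4L, 0L, 0L, 4L, 4L, 0L,
         4L, 4L, 2L, 2L, 2L, 0L)
  expect_equal(sum(v), 40L)
  r <- score_pcl5(v)
  expect_equal(r$group, "TEC")
  expect_false(r$cluster_flags[["avoidance"]])
  expect_true(r$cluster_flags[["intrusion"]])
  expect_true(r$cluster_flags[["cogmood"]])
  expect_true(r$cluster_flags[["arousal"]])
})

test_that("score_pcl5 rejects malformed responses, naming the offender", {
  expect_error(score_pcl5(rep(1L, 19)), "exactly 20")
  expect_error(score_pcl5(c(rep(1L, 7), 5L, rep(1L, 12))), "item 8")
  expect_error(score_pcl5(c(rep(0L, 11), -1L, rep(0L, 8))), "item 12")
  expect_error(score_pcl5(c(rep(0L, 4), 1.5, rep(0L, 15))), "item 5")
})

test_that("score_pcl5 agrees with a brute-force rule implementation", {
  # a quick spot-check; the full 10,000-vector comparison runs with the
  # acceptance checks
  set.seed(42)
  n <- 1000
  for (i in seq_len(n)) {
    items <- sample(0:4, 20, replace = TRUE,
                    prob = c(0.35, 0.2, 0.2, 0.15, 0.1))
    got <- score_pcl5(items)
    want <- brute_force_pcl5(items)
    if (got$total != want$total || got$group != want$group ||
        got$numbing != want$numbing) {
      fail(sprintf("disagreement on vector %s", paste(items, collapse = ",")))
    }
  }
  succeed()
})

test_that("diagnosis is monotone in severity", {
  set.seed(7)
  for (rep in 1:300) {
    items <- sample(0:4, 20, replace = TRUE)
    before <- score_pcl5(items)$group
    j <- sample(1:20, 1)
    if (items[j] < 4) {
      items[j] <- items[j] + 1L
      after <- score_pcl5(items)$group
      expect_false(before == "pPTSD" && after == "TEC")
    }
  }
})

test_that("score_pcl5_table scores row-wise and keeps ids", {
  q <- data.frame(participant_id = c("a", "b"))
  for (j in 1:20) q[[sprintf("pcl5_%02d", j)]] <- c(0L, 4L)
  tab <- score_pcl5_table(q)
  expect_equal(tab$group, c("TEC", "pPTSD"))
  expect_equal(tab$numbing, c(0L, 12L))
  expect_error(score_pcl5_table(q[, -3]), "pcl5_02")
})

test_that("numbing z-scores centre and scale as specified", {
  # population-SD convention (default): two points at +/-1 population SD
  z <- numbing_z_scores(c(0, 12))
  expect_equal(z, c(-1, 1), tolerance = 1e-12)
  # sample-SD convention: the same two points land at +/-1/sqrt(2)
  zs2 <- numbing_z_scores(c(0, 12), type = "sample")
  expect_equal(zs2, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(1)
  x <- sample(0:12, 40, replace = TRUE)
  z <- numbing_z_scores(x)
  expect_lt(abs(mean(z)), 1e-12)
  n <- length(x)
  expect_equal(sd(z) * sqrt((n - 1) / n), 1, tolerance = 1e-12)
  zs <- numbing_z_scores(x, type = "sample")
  expect_equal(sd(zs), 1, tolerance = 1e-12)
  expect_error(numbing_z_scores(c(5, 5, 5)), "constant")
  expect_error(numbing_z_scores(3), "at least 2")
})

test_that("outlier rule counts >3 SD deviations and excludes at 3+", {
  norms <- fixture_norms(n_images = 8)
  exact <- fixture_exact_ratings(norms)
  v <- flag_outliers(exact, norms)
  expect_equal(v$deviation_count, 0L)
  expect_false(v$excluded)

  # exactly 2 gross deviations: "more than 2 occasions" not met
  two <- exact
  s <- norms$valence_sd / 8
  two$rating[1:2] <- pmin(1, two$rating[1:2] + 10 * s[1:2])
  v2 <- flag_outliers(two, norms)
  expect_equal(v2$deviation_count, 2L)
  expect_false(v2$excluded)

  three <- exact
  three$rating[1:3] <- pmin(1, three$rating[1:3] + 4 * s[1:3])
  v3 <- flag_outliers(three, norms)
  expect_equal(v3$deviation_count, 3L)
  expect_true(v3$excluded)

  # rule is invariant to image ordering
  perm <- three[sample(nrow(three)), ]
  expect_equal(flag_outliers(perm, norms), v3)

  bad <- exact
  bad$image_id[1] <- "nonexistent"
  expect_error(flag_outliers(bad, norms), "nonexistent")
})

test_that("positive-image filter retains the negative-to-neutral block", {
  norms <- generate_norms(n_images = 35, n_positive = 5, seed = 5)
  kept <- filter_positive_images(norms)
  expect_equal(nrow(kept), 35)
  expect_equal(attr(kept, "n_removed"), 5)
  expect_true(all(kept$valence_mean <= 5))

  all_neg <- generate_norms(n_images = 10, n_positive = 0, seed = 5)
  kept2 <- filter_positive_images(all_neg)
  expect_equal(kept2$image_id, all_neg$image_id)
  expect_equal(attr(kept2, "n_removed"), 0)

  pos_only <- data.frame(image_id = "p", valence_mean = 6, valence_sd = 1)
  expect_warning(out <- filter_positive_images(pos_only), "nothing retained")
  expect_equal(nrow(out), 0)
})
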