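#' Generate a stimulus-norm table
#'
#' Builds normative valence statistics for a negative-to-neutral image set
#' plus an optional block of positive filler images, mirroring the design
#' of the rating task: `n_images` means increase strictly from 1.33 (most
#' negative) to 5.0 (neutral) on the 1-9 source scale — an even grid with
#' a small monotonicity-preserving jitter on interior points — and
#' `n_positive` filler means spread over 5.63-7.09. Normative SDs are
#' drawn uniformly from `sd_range`.
#'
#' @param n_images number of analysed (negative-to-neutral) images,
#'   at least 2.
#' @param n_positive number of positive filler images (filtered out
#'   before modelling).
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @param jitter_frac jitter amplitude as a fraction of the grid gap,
#'   in \[0, 0.45\]; 0 gives the exact even grid.
#' @param sd_range length-2 numeric range for the normative SDs.
#' @return data frame with columns `image_id`, `valence_mean`,
#'   `valence_sd`, ordered by increasing mean.
#' @export
generate_norms <- function(n_images = 35, n_positive = 5, seed = 1,
                           jitter_frac = 0.3, sd_range = c(0.8, 1.6)) {
  stopifnot(n_images >= 2, n_positive >= 0,
            jitter_frac >= 0, jitter_frac < 0.5,
            length(sd_range) == 2, sd_range[1] > 0, sd_range[2] >= sd_range[1])
  set.seed(seed)
  means <- seq(1.33, 5.0, length.out = n_images)
  if (n_images > 2 && jitter_frac > 0) {
    gap <- means[2] - means[1]
    idx <- 2:(n_images - 1)
    means[idx] <- means[idx] + stats::runif(length(idx), -1, 1) * jitter_frac * gap
  }
  if (n_positive > 0) {
    pos <- if (n_positive == 1) 6.36 else seq(5.63, 7.09, length.out = n_positive)
    means <- c(means, pos)
  }
  n <- length(means)
  data.frame(
    image_id = sprintf("img_%02d", seq_len(n)),
    valence_mean = means,
    valence_sd = stats::runif(n, sd_range[1], sd_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic participant generator
#'
#' Collects the ground-truth parameters of the forward model. Defaults
#' describe two groups whose 5-PL curves differ only in the group-level
#' Hill slope (TEC 1.2 vs pPTSD 1.45, the neighbourhood of the reported
#' group effect), with an emotional-numbing coefficient of 0.1 on the
#' slope, additive Gaussian rating noise of SD 0.05 on the VAS scale,
#' and PCL-5 totals and numbing subscale scores centred on the study's
#' sample statistics (TEC 17.81/2.95, pPTSD 46.52/7.94).
#'
#' @param n_per_group participants per group.
#' @param n_images number of analysed images (passed to norms generation
#'   by the pipeline; kept here for the record).
#' @param mu_b named numeric, true group-level Hill-slope means for
#'   `TEC` and `pPTSD`.
#' @param alpha1,alpha2 true beta shapes for the lower asymptote `a`
#'   (mean `alpha1/(alpha1+alpha2)`, kept close to 0).
#' @param mu_c,mu_d,mu_g true group-level means of the remaining curve
#'   parameters (shared across groups).
#' @param sd_b,sd_c,sd_d,sd_g true between-participant SDs.
#' @param noise_sd additive rating noise SD on the VAS \[0,1\] scale.
#' @param en_slope_coeff true effect of the z-scored emotional-numbing
#'   score on the participant slope (`B_i = en_slope_coeff * z_i + b_i`).
#' @param pcl_total_mean,pcl_total_sd named numeric per group: PCL-5
#'   total score distribution (TEC capped at 33, pPTSD floored at 34).
#' @param numbing_mean,numbing_sd named numeric per group: emotional
#'   numbing subscale distribution (0-12).
#' @param age_mean,age_sd named numeric per group.
#' @param seed integer RNG seed.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 40,
                             n_images = 35,
                             mu_b = c(TEC = 1.2, pPTSD = 1.45),
                             alpha1 = 2, alpha2 = 10,
                             mu_c = 3.0, mu_d = 0.55, mu_g = 1.5,
                             sd_b = 0.2, sd_c = 0.3, sd_d = 0.05, sd_g = 0.2,
                             noise_sd = 0.05,
                             en_slope_coeff = 0.1,
                             pcl_total_mean = c(TEC = 17.81, pPTSD = 46.52),
                             pcl_total_sd = c(TEC = 10.14, pPTSD = 9.72),
                             numbing_mean = c(TEC = 2.95, pPTSD = 7.94),
                             numbing_sd = c(TEC = 2.63, pPTSD = 2.49),
                             age_mean = c(TEC = 41.5, pPTSD = 36.1),
                             age_sd = c(TEC = 13.3, pPTSD = 10.9),
                             seed = 1) {
  cfg <- list(n_per_group = as.integer(n_per_group), n_images = as.integer(n_images),
              mu_b = mu_b, alpha1 = alpha1, alpha2 = alpha2,
              mu_c = mu_c, mu_d = mu_d, mu_g = mu_g,
              sd_b = sd_b, sd_c = sd_c, sd_d = sd_d, sd_g = sd_g,
              noise_sd = noise_sd, en_slope_coeff = en_slope_coeff,
              pcl_total_mean = pcl_total_mean, pcl_total_sd = pcl_total_sd,
              numbing_mean = numbing_mean, numbing_sd = numbing_sd,
              age_mean = age_mean, age_sd = age_sd,
              seed = as.integer(seed))
  sds <- c(cfg$sd_b, cfg$sd_c, cfg$sd_d, cfg$sd_g, cfg$noise_sd)
  if (any(sds <= 0)) stop("all SDs must be > 0", call. = FALSE)
  if (cfg$n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (!all(c("TEC", "pPTSD") %in% names(cfg$mu_b))) {
    stop("mu_b must be named for both groups (TEC, pPTSD)", call. = FALSE)
  }
  if (any(cfg$mu_b < 0.5)) stop("group slope means must be >= 0.5", call. = FALSE)
  if (cfg$mu_c <= 0.5 || cfg$mu_c >= 5) stop("mu_c must lie in (0.5, 5)", call. = FALSE)
  if (cfg$alpha1 <= 0 || cfg$alpha2 <= 0) stop("beta shapes must be positive", call. = FALSE)
  # curves must stay inside the VAS scale: the upper asymptote cannot
  # plausibly exceed 1 once between-participant spread is added
  if (cfg$mu_d + 3 * cfg$sd_d > 1) {
    stop("mu_d + 3*sd_d exceeds 1: configuration implies ratings outside [0, 1]",
         call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# truncated-normal draws by inverse-CDF (vectorised, exact)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# spread `amount` points over `slots` (item indices), each capped at 4
distribute_points <- function(items, slots, amount) {
  while (amount > 0L) {
    open <- slots[items[slots] < 4L]
    if (!length(open)) break
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    items[pick] <- items[pick] + 1L
    amount <- amount - 1L
  }
  items
}

# construct one PCL-5 item vector with a given target total and numbing
# subscale, guaranteed to satisfy (pPTSD) or fail (TEC) the screening rule
make_pcl5_items <- function(group, total, numbing) {
  items <- integer(20)
  numbing <- max(0L, min(12L, as.integer(numbing)))
  total <- as.integer(total)
  if (group == "TEC") total <- max(numbing, min(33L, total))
  if (group == "pPTSD") total <- min(80L, max(34L, total, numbing))
  # numbing items 12-14: as even a split as possible, remainder random
  base <- numbing %/% 3L
  rem <- numbing %% 3L
  nb <- rep(base, 3L)
  if (rem > 0L) {
    bump <- sample(1:3, rem)
    nb[bump] <- nb[bump] + 1L
  }
  items[12:14] <- nb
  if (group == "pPTSD") {
    # enforce cluster endorsement: 1 intrusion, 1 avoidance, 2 cognition/
    # mood (items 12-14 count toward it), 2 arousal, each at >= 2
    items[sample(1:5, 1L)] <- 2L
    items[sample(6:7, 1L)] <- 2L
    short <- 2L - sum(items[8:14] >= 2L)
    if (short > 0L) {
      pool <- setdiff(8:11, which(items >= 2L))
      items[sample(pool, short)] <- 2L
    }
    items[sample(15:20, 2L)] <- 2L
  }
  # top up the remaining mass outside the numbing items so the subscale
  # stays exact; item totals are capped at 4
  free <- setdiff(1:20, 12:14)
  remaining <- total - sum(items)
  if (remaining > 0L) items <- distribute_points(items, free, remaining)
  items
}

#' Generate synthetic participants: ratings, questionnaires and truth
#'
#' Simulates the full study structure forward: per-participant 5-PL curve
#' parameters drawn from group-level truncated distributions, PCL-5 item
#' vectors constructed to satisfy (pPTSD) or fail (TEC) the screening
#' rule with group-appropriate totals and emotional-numbing subscales,
#' the participant Hill slope composed as
#' `B_i = en_slope_coeff * numbing_z_i + b_i` (numbing z-scored over the
#' pooled sample), and VAS ratings
#' `clamp(five_pl(x) + Normal(0, noise_sd), 0, 1)` for every image in
#' the norm table (positive fillers are rated with the same curve and
#' filtered before modelling).
#'
#' @param cfg a [generator_config()].
#' @param norms a stimulus-norm table from [generate_norms()].
#' @return list with elements `ratings` (participant_id, image_id,
#'   rating), `questionnaires` (participant_id, pcl5_01..pcl5_20, age,
#'   sex), and `truth` (participant_id, group, a, b, c, d, g, B,
#'   numbing, en_z, age) — the ground-truth table is for recovery tests
#'   only and must not feed the inference stages.
#' @export
generate_participants <- function(cfg, norms) {
  stopifnot(inherits(cfg, "generator_config"),
            all(c("image_id", "valence_mean", "valence_sd") %in% names(norms)))
  set.seed(cfg$seed)
  groups <- c("TEC", "pPTSD")
  n <- cfg$n_per_group
  ids <- c(sprintf("tec_%04d", seq_len(n)), sprintf("ptsd_%04d", seq_len(n)))
  grp <- rep(groups, each = n)

  # questionnaires first: the numbing z-score enters the true slope
  totals <- numeric(2 * n); numbing <- integer(2 * n); age <- numeric(2 * n)
  items_mat <- matrix(0L, nrow = 2 * n, ncol = 20)
  for (i in seq_len(2 * n)) {
    g <- grp[i]
    t_i <- round(stats::rnorm(1, cfg$pcl_total_mean[[g]], cfg$pcl_total_sd[[g]]))
    nb_i <- round(stats::rnorm(1, cfg$numbing_mean[[g]], cfg$numbing_sd[[g]]))
    nb_i <- max(0L, min(12L, as.integer(nb_i)))
    items <- make_pcl5_items(g, t_i, nb_i)
    items_mat[i, ] <- items
    totals[i] <- sum(items)
    numbing[i] <- sum(items[12:14])
    age[i] <- round(max(18, min(80, stats::rnorm(1, cfg$age_mean[[g]], cfg$age_sd[[g]]))))
  }
  en_z <- numbing_z_scores(numbing)

  # participant-level curve parameters from the group-level truncated laws
  a_i <- stats::rbeta(2 * n, cfg$alpha1, cfg$alpha2)
  b_i <- rtruncnorm(2 * n, cfg$mu_b[grp], cfg$sd_b, lower = 0.5)
  c_i <- rtruncnorm(2 * n, cfg$mu_c, cfg$sd_c, lower = 0.5, upper = 5)
  d_i <- rtruncnorm(2 * n, cfg$mu_d, cfg$sd_d, lower = 0.5)
  g_i <- rtruncnorm(2 * n, cfg$mu_g, cfg$sd_g, lower = 0.8)
  B_i <- cfg$en_slope_coeff * en_z + b_i

  x <- norms$valence_mean
  n_img <- length(x)
  mu <- matrix(0, nrow = 2 * n, ncol = n_img)
  for (i in seq_len(2 * n)) {
    mu[i, ] <- five_pl(x, a_i[i], B_i[i], c_i[i], d_i[i], g_i[i])
  }
  y <- mu + stats::rnorm(length(mu), 0, cfg$noise_sd)
  y <- pmin(pmax(y, 0), 1)  # y first: pmax/pmin keep the dims of arg 1

  ratings <- data.frame(
    participant_id = rep(ids, each = n_img),
    image_id = rep(norms$image_id, times = 2 * n),
    rating = as.vector(t(y)),
    stringsAsFactors = FALSE
  )
  questionnaires <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (j in 1:20) questionnaires[[sprintf("pcl5_%02d", j)]] <- items_mat[, j]
  questionnaires$age <- age
  questionnaires$sex <- sample(c("male", "female"), 2 * n, replace = TRUE)
  truth <- data.frame(
    participant_id = ids, group = grp,
    a = a_i, b = b_i, c = c_i, d = d_i, g = g_i, B = B_i,
    numbing = numbing, en_z = en_z, age = age,
    stringsAsFactors = FALSE
  )
  list(ratings = ratings, questionnaires = questionnaires, truth = truth)
}

#' Inject rating outliers for screening-rule tests
#'
#' Moves `n_images_each` ratings of `n_participants` randomly chosen
#' participants to values deviating from the rescaled norm by more than 3
#' normative SDs (the images with the smallest normative SD are used so
#' the displaced rating always fits inside \[0,1\]). All other records
#' are returned unchanged.
#'
#' @param ratings rating table (participant_id, image_id, rating).
#' @param norms stimulus-norm table on the 1-9 source scale.
#' @param n_participants number of participants to perturb.
#' @param n_images_each number of ratings moved per chosen participant.
#' @param seed integer RNG seed.
#' @return list with `ratings` (the perturbed table) and
#'   `participant_ids` (who was perturbed).
#' @export
inject_outliers <- function(ratings, norms, n_participants, n_images_each = 3,
                            seed = 1) {
  stopifnot(n_images_each >= 1)
  ids <- unique(ratings$participant_id)
  if (n_participants > length(ids)) {
    stop("n_participants exceeds the number of participants", call. = FALSE)
  }
  if (n_participants == 0L) {
    return(list(ratings = ratings, participant_ids = character(0)))
  }
  set.seed(seed)
  chosen <- sample(ids, n_participants)
  for (pid in chosen) {
    rows <- which(ratings$participant_id == pid)
    imgs <- ratings$image_id[rows]
    ord <- order(norms$valence_sd[match(imgs, norms$image_id)])
    take <- rows[ord[seq_len(min(n_images_each, length(rows)))]]
    for (r in take) {
      ni <- match(ratings$image_id[r], norms$image_id)
      m <- rescale_norm_mean(norms$valence_mean[ni])
      s <- rescale_norm_sd(norms$valence_sd[ni])
      dev <- 3.4 * s
      ratings$rating[r] <- if (m + dev <= 1) m + dev else m - dev
      if (ratings$rating[r] < 0 || ratings$rating[r] > 1) {
        stop("cannot place a >3 SD deviation inside [0,1] for image ",
             ratings$image_id[r], call. = FALSE)
      }
    }
  }
  list(ratings = ratings, participant_ids = sort(chosen))
}
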