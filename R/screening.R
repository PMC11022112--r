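#' Score a PCL-5 questionnaire and assign a screening group
#'
#' Applies the probable-PTSD screening rule to a 20-item PCL-5 response:
#' total severity above 33 together with DSM-5-style symptom-cluster
#' endorsement — at least 1 intrusion item (1-5), 1 avoidance item (6-7),
#' 2 negative-alterations-in-cognition-and-mood items (8-14) and 2
#' arousal/reactivity items (15-20), each endorsed at a rating of 2 or
#' more. Participants failing the rule are labelled trauma-exposed
#' controls (TEC). The emotional-numbing subscale is the sum of items
#' 12-14 (8-factor model), range 0-12.
#'
#' @param items integer vector of exactly 20 item responses, each in 0-4
#'   (1-based item numbering, published item order).
#' @param participant_id optional identifier carried into the result.
#' @return a list of class `pcl5_diagnosis` with elements
#'   `participant_id`, `total` (0-80), `group` (`"pPTSD"` or `"TEC"`),
#'   `cluster_flags` (named logical: intrusion, avoidance, cogmood,
#'   arousal) and `numbing` (0-12).
#' @examples
#' score_pcl5(rep(4L, 20))$group # "pPTSD"
#' @seealso [score_pcl5_table()] for a whole questionnaire table.
#' @export
score_pcl5 <- function(items, participant_id = NA_character_) {
  if (length(items) != 20L) {
    stop("PCL-5 requires exactly 20 items, got ", length(items), call. = FALSE)
  }
  items <- as.numeric(items)
  bad <- which(!is.finite(items) | items < 0 | items > 4 | items != round(items))
  if (length(bad)) {
    stop("invalid PCL-5 response at item ", bad[1L],
         " (must be an integer in 0-4)", call. = FALSE)
  }
  endorsed <- items >= 2
  flags <- c(
    intrusion = sum(endorsed[1:5]) >= 1L,
    avoidance = sum(endorsed[6:7]) >= 1L,
    cogmood   = sum(endorsed[8:14]) >= 2L,
    arousal   = sum(endorsed[15:20]) >= 2L
  )
  total <- as.integer(sum(items))
  structure(list(
    participant_id = participant_id,
    total = total,
    group = if (total > 33L && all(flags)) "pPTSD" else "TEC",
    cluster_flags = flags,
    numbing = as.integer(sum(items[12:14]))
  ), class = "pcl5_diagnosis")
}

#' @export
print.pcl5_diagnosis <- function(x, ...) {
  cat(sprintf("PCL-5: id=%s total=%d group=%s numbing=%d clusters=%s\n",
              x$participant_id, x$total, x$group, x$numbing,
              paste(substr(names(x$cluster_flags)[x$cluster_flags], 1, 3),
                    collapse = "+")))
  invisible(x)
}

#' Score a table of PCL-5 questionnaires
#'
#' @param questionnaires data frame with a `participant_id` column and
#'   item columns `pcl5_01` ... `pcl5_20` (extra columns are ignored).
#' @return data frame with one row per participant: `participant_id`,
#'   `total`, `group`, the four cluster flags (`intrusion`, `avoidance`,
#'   `cogmood`, `arousal`) and `numbing`.
#' @export
score_pcl5_table <- function(questionnaires) {
  cols <- sprintf("pcl5_%02d", 1:20)
  missing_cols <- setdiff(c("participant_id", cols), names(questionnaires))
  if (length(missing_cols)) {
    stop("questionnaire table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(questionnaires)), function(i) {
    r <- score_pcl5(as.numeric(questionnaires[i, cols]),
                    participant_id = as.character(questionnaires$participant_id[i]))
    data.frame(participant_id = r$participant_id, total = r$total,
               group = r$group,
               intrusion = r$cluster_flags[["intrusion"]],
               avoidance = r$cluster_flags[["avoidance"]],
               cogmood = r$cluster_flags[["cogmood"]],
               arousal = r$cluster_flags[["arousal"]],
               numbing = r$numbing, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' z-transform emotional-numbing scores
#'
#' Centres and scales a vector of emotional-numbing subscale scores to
#' sample mean 0 and SD 1, as done before entering the covariate into the
#' slope-regression model. The default scaling uses the population-SD
#' convention (divisor `n`); the alternative uses the sample SD (divisor
#' `n - 1`). The choice only rescales the regression coefficient globally.
#'
#' @param scores numeric vector with at least 2 distinct values.
#' @param type `"population"` (default) or `"sample"` SD convention.
#' @return numeric vector of z-scores with mean 0.
#' @export
numbing_z_scores <- function(scores, type = c("population", "sample")) {
  type <- match.arg(type)
  scores <- as.numeric(scores)
  if (length(scores) < 2L || !all(is.finite(scores))) {
    stop("need at least 2 finite scores", call. = FALSE)
  }
  s <- stats::sd(scores)
  if (s == 0) stop("scores are constant; z-transform undefined", call. = FALSE)
  n <- length(scores)
  if (type == "population") s <- s * sqrt((n - 1) / n)
  (scores - mean(scores)) / s
}

# Map NAPS-scale norms (1-9) onto the VAS scale [0,1]: order-preserving
# affine map m -> (m-1)/8, so SDs scale by 1/8.
rescale_norm_mean <- function(m) (m - 1) / 8
rescale_norm_sd <- function(s) s / 8

#' Flag rating outliers against stimulus norms
#'
#' Applies the exclusion rule used before modelling: a participant whose
#' VAS rating deviates from the normative valence by more than 3
#' normative SDs on more than 2 images is excluded. Norms live on the
#' 1-9 source scale and are mapped onto the VAS \[0,1\] scale by the
#' affine map `m -> (m - 1) / 8` (SDs scale by 1/8) before the rule is
#' applied; the rule is equivariant under this order-preserving map.
#'
#' @param ratings data frame with columns `participant_id`, `image_id`,
#'   `rating` (in \[0,1\]).
#' @param norms data frame with columns `image_id`, `valence_mean`,
#'   `valence_sd` (1-9 source scale).
#' @param sd_limit deviation threshold in normative SDs (default 3).
#' @param max_occasions largest tolerated number of deviating images
#'   (default 2; exclusion requires strictly more).
#' @return data frame with one row per participant: `participant_id`,
#'   `deviation_count`, `excluded`.
#' @export
flag_outliers <- function(ratings, norms, sd_limit = 3, max_occasions = 2) {
  stopifnot(all(c("participant_id", "image_id", "rating") %in% names(ratings)),
            all(c("image_id", "valence_mean", "valence_sd") %in% names(norms)))
  if (any(ratings$rating < 0 | ratings$rating > 1)) {
    stop("ratings must lie in [0, 1]", call. = FALSE)
  }
  idx <- match(ratings$image_id, norms$image_id)
  if (anyNA(idx)) {
    stop("no norm for rated image(s): ",
         paste(unique(ratings$image_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  m <- rescale_norm_mean(norms$valence_mean[idx])
  s <- rescale_norm_sd(norms$valence_sd[idx])
  deviates <- abs(ratings$rating - m) > sd_limit * s
  counts <- tapply(deviates, ratings$participant_id, sum)
  out <- data.frame(participant_id = names(counts),
                    deviation_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$excluded <- out$deviation_count > max_occasions
  out[order(out$participant_id), , drop = FALSE]
}

#' Drop positive images from a stimulus-norm table
#'
#' Positive images (normative valence above neutral) are shown only to
#' reduce negativity bias during rating and are removed before
#' modelling. Neutral is 5 on the 1-9 source scale.
#'
#' @param norms data frame with columns `image_id`, `valence_mean`,
#'   `valence_sd`.
#' @param threshold retain images with `valence_mean <= threshold`
#'   (default 5).
#' @return the retained norms, with attribute `n_removed` giving the
#'   number of images dropped; warns if nothing is retained.
#' @export
filter_positive_images <- function(norms, threshold = 5) {
  keep <- norms$valence_mean <= threshold
  out <- norms[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("all images exceed the valence threshold; nothing retained")
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}
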