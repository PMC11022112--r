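#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `generator` (synthetic mode) or `data` (data mode)
#' must be supplied. In synthetic mode the global `seed` is mandatory
#' and per-stage seeds are derived from it deterministically.
#'
#' @param out_dir output directory (created if needed).
#' @param generator a [generator_config()] for synthetic mode, or NULL.
#' @param data list with file paths `ratings`, `norms`, `questionnaires`
#'   for data mode, or NULL.
#' @param sampler a [sampler_config()]; its seed is overridden by the
#'   derived stage seed.
#' @param models which rating models to fit per group.
#' @param fit_en fit the pooled emotional-numbing slope model.
#' @param en_extras additional EN variants: any of `"age"`,
#'   `"age_interaction"`.
#' @param compare_params group-level parameters to contrast.
#' @param mass HPD mass for comparisons.
#' @param priors optional prior overrides passed to the builders.
#' @param seed global integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       generator = NULL,
                       data = NULL,
                       sampler = sampler_config(),
                       models = c("fivepl", "linear"),
                       fit_en = TRUE,
                       en_extras = character(0),
                       compare_params = c("mu_a", "mu_b", "mu_c", "mu_d", "mu_g"),
                       mass = 0.89,
                       priors = NULL,
                       seed = 1) {
  if (is.null(generator) == is.null(data)) {
    stop("exactly one of `generator` (synthetic mode) or `data` (data mode) ",
         "must be given", call. = FALSE)
  }
  if (!is.null(generator) && !inherits(generator, "generator_config")) {
    stop("`generator` must be a generator_config()", call. = FALSE)
  }
  if (!is.null(data)) {
    need <- c("ratings", "norms", "questionnaires")
    if (!all(need %in% names(data))) {
      stop("`data` must name paths: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  models <- match.arg(models, c("fivepl", "linear"), several.ok = TRUE)
  structure(list(out_dir = out_dir, generator = generator, data = data,
                 sampler = sampler, models = models, fit_en = fit_en,
                 en_extras = en_extras, compare_params = compare_params,
                 mass = mass, priors = priors, seed = as.integer(seed)),
            class = "run_config")
}

log_line <- function(con, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) data generation or loading, (2) questionnaire
#' scoring and group assignment, (3) outlier exclusion and the
#' positive-image filter, (4) per-group 5-PL and linear fits, (5) group
#' comparison of the five curve parameters (TEC − pPTSD), (6) the pooled
#' emotional-numbing slope model (plus optional age variants), (7) LOO
#' model-comparison tables per group. Every stage persists its outputs
#' under `cfg$out_dir` so stages can be re-run and inspected
#' independently; a manifest records the config, derived seeds and
#' checksums of every output file. Warnings (convergence, Pareto-k) are
#' collected into `log.jsonl`.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress sampler progress output.
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  for (sub in c("data", "screening", "fits", "comparisons")) {
    dir.create(file.path(out, sub), recursive = TRUE, showWarnings = FALSE)
  }
  logcon <- file(file.path(out, "log.jsonl"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  seeds <- derive_seeds(cfg$seed, 10)
  outputs <- character(0)
  manifest <- list(package_version = as.character(utils::packageVersion("valtrans")),
                   seed = cfg$seed, stage_seeds = seeds, status = "running",
                   stages = list())
  keep <- function(path) { outputs <<- c(outputs, path); path }
  warn_log <- function(stage) {
    function(w) {
      log_line(logcon, stage, warning = conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  }
  finish <- function(status, error = NULL) {
    manifest$status <<- status
    if (!is.null(error)) manifest$error <<- error
    sums <- tools::md5sum(outputs[file.exists(outputs)])
    manifest$checksums <<- as.list(sums)
    names(manifest$checksums) <<- substring(names(sums), nchar(out) + 2)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  result <- tryCatch({
    # stage 1: data
    if (!is.null(cfg$generator)) {
      norms <- generate_norms(n_images = cfg$generator$n_images, seed = seeds[1])
      gen <- cfg$generator
      gen$seed <- seeds[2]
      sim <- generate_participants(gen, norms)
      ratings <- sim$ratings; questionnaires <- sim$questionnaires
      utils::write.csv(sim$truth, keep(file.path(out, "data", "truth.csv")),
                       row.names = FALSE)
    } else {
      ratings <- utils::read.csv(cfg$data$ratings)
      norms <- utils::read.csv(cfg$data$norms)
      questionnaires <- utils::read.csv(cfg$data$questionnaires)
    }
    utils::write.csv(norms, keep(file.path(out, "data", "norms.csv")),
                     row.names = FALSE)
    utils::write.csv(ratings, keep(file.path(out, "data", "ratings.csv")),
                     row.names = FALSE)
    utils::write.csv(questionnaires,
                     keep(file.path(out, "data", "questionnaires.csv")),
                     row.names = FALSE)
    log_line(logcon, "data", n_ratings = nrow(ratings),
             n_participants = length(unique(ratings$participant_id)))

    # stage 2: screening
    diagnoses <- score_pcl5_table(questionnaires)
    utils::write.csv(diagnoses,
                     keep(file.path(out, "screening", "diagnoses.csv")),
                     row.names = FALSE)
    verdicts <- flag_outliers(ratings, norms)
    utils::write.csv(verdicts,
                     keep(file.path(out, "screening", "outliers.csv")),
                     row.names = FALSE)
    excluded <- verdicts$participant_id[verdicts$excluded]
    log_line(logcon, "screening", n_excluded = length(excluded),
             n_pptsd = sum(diagnoses$group == "pPTSD"),
             n_tec = sum(diagnoses$group == "TEC"))

    # stage 3: positive-image filter + exclusions
    norms_neg <- filter_positive_images(norms)
    analysis <- ratings[!(ratings$participant_id %in% excluded) &
                          ratings$image_id %in% norms_neg$image_id, ]
    diagnoses <- diagnoses[!(diagnoses$participant_id %in% excluded), ]
    questionnaires <- questionnaires[!(questionnaires$participant_id %in% excluded), ]
    log_line(logcon, "filter", n_images_removed = attr(norms_neg, "n_removed"),
             n_analysis_rows = nrow(analysis))
    manifest$stages$filter <- list(images_removed = attr(norms_neg, "n_removed"),
                                   participants_excluded = length(excluded))

    # stage 4: per-group fits
    groups <- c("TEC", "pPTSD")
    fits <- list()
    fit_i <- 0L
    for (grp in groups) {
      ids <- diagnoses$participant_id[diagnoses$group == grp]
      sub <- analysis[analysis$participant_id %in% ids, ]
      for (mk in cfg$models) {
        fit_i <- fit_i + 1L
        spec <- if (mk == "fivepl") {
          build_5pl_model(sub, norms_neg, priors = cfg$priors)
        } else {
          build_linear_model(sub, norms_neg, priors = cfg$priors)
        }
        scfg <- cfg$sampler
        scfg$seed <- derive_seeds(seeds[3], fit_i, salt = 7L)[fit_i]
        fit <- withCallingHandlers(
          fit_model(spec, scfg, quiet = quiet),
          warning = warn_log(paste0("fit_", grp, "_", mk)))
        fits[[paste(grp, mk, sep = "_")]] <- fit
        fdir <- file.path(out, "fits", paste(grp, mk, sep = "_"))
        write_fit(fit, fdir)
        for (f in list.files(fdir, full.names = TRUE)) keep(f)
        log_line(logcon, paste0("fit_", grp, "_", mk),
                 max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
                 min_ess = min(fit$diagnostics$ess_bulk, na.rm = TRUE))
      }
    }

    # stage 5: group comparison (TEC - pPTSD)
    if ("fivepl" %in% cfg$models) {
      cmp <- compare_groups(fits[["TEC_fivepl"]], fits[["pPTSD_fivepl"]],
                            cfg$compare_params, mass = cfg$mass,
                            seed = seeds[4])
      utils::write.csv(cmp,
                       keep(file.path(out, "comparisons", "group_comparison.csv")),
                       row.names = FALSE)
      log_line(logcon, "compare_groups",
               robust = paste(cmp$parameter[cmp$robust], collapse = ","))
    }

    # stage 6: pooled EN model (+ age variants)
    if (isTRUE(cfg$fit_en)) {
      pids <- sort(unique(analysis$participant_id))
      nz <- numbing_z_scores(diagnoses$numbing[match(pids, diagnoses$participant_id)])
      en_rows <- list()
      variants <- c("none", cfg$en_extras)
      for (v in variants) {
        az <- NULL
        if (v != "none") {
          az <- numbing_z_scores(
            questionnaires$age[match(pids, questionnaires$participant_id)])
        }
        spec <- build_en_model(analysis, norms_neg, participant_index = pids,
                               numbing_z = nz, extra = v, age_z = az,
                               priors = cfg$priors)
        scfg <- cfg$sampler
        v_i <- match(v, variants)
        scfg$seed <- derive_seeds(seeds[5], v_i, salt = 13L)[v_i]
        fit <- withCallingHandlers(
          fit_model(spec, scfg, quiet = quiet),
          warning = warn_log(paste0("fit_en_", v)))
        fdir <- file.path(out, "fits", paste0("pooled_", spec$kind))
        write_fit(fit, fdir)
        for (f in list.files(fdir, full.names = TRUE)) keep(f)
        coefs <- intersect(c("EN", "AGE", "INT"), dimnames(fit$draws)[[3]])
        for (cf in coefs) {
          dd <- extract_draws(fit, cf)
          h <- hpd(dd, cfg$mass)
          en_rows[[paste(v, cf)]] <- data.frame(
            variant = v, coefficient = cf, mean = mean(dd), sd = stats::sd(dd),
            hpd_low = h[1], hpd_high = h[2], robust = (h[1] > 0 || h[2] < 0))
        }
      }
      en_tab <- do.call(rbind, en_rows)
      utils::write.csv(en_tab,
                       keep(file.path(out, "comparisons", "en_association.csv")),
                       row.names = FALSE)
      log_line(logcon, "en_model", robust = paste(
        sprintf("%s:%s", en_tab$variant[en_tab$robust],
                en_tab$coefficient[en_tab$robust]), collapse = ","))
    }

    # stage 7: LOO tables per group
    if (all(c("fivepl", "linear") %in% cfg$models)) {
      for (grp in groups) {
        loos <- list(compute_loo(fits[[paste0(grp, "_fivepl")]], "5-PL"),
                     compute_loo(fits[[paste0(grp, "_linear")]], "Linear"))
        tab <- withCallingHandlers(compare_models(loos, seed = seeds[6]),
                                   warning = warn_log(paste0("loo_", grp)))
        write_comparison_csv(tab,
          keep(file.path(out, "comparisons", paste0("loo_", grp, ".csv"))))
        log_line(logcon, paste0("loo_", grp), best = tab$model[1],
                 weight_best = tab$weight[1])
      }
    }
    "complete"
  }, error = function(e) {
    finish("failed", conditionMessage(e))
    stop(e)
  })
  finish(result)
  invisible(manifest)
}
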