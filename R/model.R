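#' Prior constants of the hierarchical models
#'
#' Returns the full prior block of a model as a table, one row per
#' parameter: distribution family, location, scale and truncation
#' bounds. These are the constants used verbatim by the model builders;
#' any of them can be overridden through the builders' `priors`
#' argument. Group-level rows (`alpha1`, `alpha2`, `mu_*`) are fixed
#' constants; participant-level rows (`a`, `b`, `c`, `d`, `g`) have
#' hierarchical locations (`NA` here) supplied by their group-level
#' mean, with the participant-level SD fixed at 1 as printed.
#'
#' The lower asymptote `a` follows `Beta(alpha1, alpha2)`; `alpha2`'s
#' prior is an untruncated `Normal(10, 1)` with a hard positivity guard
#' at evaluation time (a beta shape must be positive; the prior mass
#' below 0 is ~8e-24, so behaviour is unchanged). The observation noise
#' `sigma` is `Half-Normal(0.2)`, shared across participants.
#'
#' @param kind one of `"fivepl"`, `"linear"`, `"fivepl_en"`,
#'   `"fivepl_en_age"`, `"fivepl_en_age_interaction"`.
#' @return data frame with columns `parameter`, `dist`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @export
default_priors <- function(kind = c("fivepl", "linear", "fivepl_en",
                                    "fivepl_en_age",
                                    "fivepl_en_age_interaction")) {
  kind <- match.arg(kind)
  row <- function(parameter, dist, mean, sd, lower, upper) {
    data.frame(parameter = parameter, dist = dist, mean = mean, sd = sd,
               lower = lower, upper = upper, stringsAsFactors = FALSE)
  }
  sigma <- row("sigma", "half-normal", 0, 0.2, 0, Inf)
  if (kind == "linear") {
    tab <- rbind(
      row("mu_a", "normal", 0, 0.2, 0, Inf),
      row("mu_b", "normal", 0, 0.5, 0, Inf),
      row("a", "normal", NA, 1, 0, Inf),
      row("b", "normal", NA, 1, 0, Inf),
      sigma
    )
    return(tab)
  }
  tab <- rbind(
    row("alpha1", "normal", 2, 1, 1, Inf),
    row("alpha2", "normal", 10, 1, -Inf, Inf),
    row("mu_b", "normal", 2, 1, 1, Inf),
    row("mu_c", "normal", 2, 1, 0.5, Inf),
    row("mu_d", "normal", 2, 1, 0, Inf),
    row("mu_g", "normal", 4, 1, 1, Inf),
    row("a", "beta", NA, NA, 0, 1),
    row("b", "normal", NA, 1, 0.5, Inf),
    row("c", "normal", NA, 1, 0.5, 5),
    row("d", "normal", NA, 1, 0.5, Inf),
    row("g", "normal", NA, 1, 0.8, Inf),
    sigma
  )
  if (kind %in% c("fivepl_en", "fivepl_en_age", "fivepl_en_age_interaction")) {
    tab <- rbind(tab, row("EN", "normal", 0, 1, -Inf, Inf))
  }
  if (kind %in% c("fivepl_en_age", "fivepl_en_age_interaction")) {
    tab <- rbind(tab, row("AGE", "normal", 0, 1, -Inf, Inf))
  }
  if (kind == "fivepl_en_age_interaction") {
    tab <- rbind(tab, row("INT", "normal", 0, 1, -Inf, Inf))
  }
  tab
}

apply_prior_overrides <- function(tab, priors) {
  if (is.null(priors)) return(tab)
  for (nm in names(priors)) {
    i <- which(tab$parameter == nm)
    if (!length(i)) stop("unknown prior parameter: ", nm, call. = FALSE)
    ov <- priors[[nm]]
    for (f in intersect(names(ov), c("mean", "sd", "lower", "upper"))) {
      tab[[f]][i] <- as.numeric(ov[[f]])
    }
  }
  tab
}

prior_row <- function(spec, parameter) {
  i <- which(spec$priors$parameter == parameter)
  if (!length(i)) stop("model has no prior for ", parameter, call. = FALSE)
  spec$priors[i, , drop = FALSE]
}

# shared data assembly/validation for all builders
bind_model_data <- function(ratings, norms, participant_index = NULL) {
  stopifnot(all(c("participant_id", "image_id", "rating") %in% names(ratings)),
            all(c("image_id", "valence_mean") %in% names(norms)))
  idx <- match(ratings$image_id, norms$image_id)
  if (anyNA(idx)) {
    stop("no norm for rated image(s): ",
         paste(unique(ratings$image_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  x <- norms$valence_mean[idx]
  if (any(x <= 0)) stop("norm valence must be strictly positive", call. = FALSE)
  y <- ratings$rating
  if (any(y < 0 | y > 1)) stop("ratings must lie in [0, 1]", call. = FALSE)
  participant_ids <- participant_index %||% sort(unique(ratings$participant_id))
  pid <- match(ratings$participant_id, participant_ids)
  if (anyNA(pid)) {
    stop("participant index lacks: ",
         paste(unique(ratings$participant_id[is.na(pid)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(participant_ids) < 2L) stop("need at least 2 participants", call. = FALSE)
  list(x = x, y = y, pid = pid, participant_ids = participant_ids)
}

new_model_spec <- function(kind, data, priors, covariates = list(),
                           options = list()) {
  structure(list(kind = kind, data = data, priors = priors,
                 covariates = covariates,
                 options = utils::modifyList(
                   list(estimate_participant_sd = FALSE), options)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': %d observations, %d participants\n",
              x$kind, length(x$data$y), length(x$data$participant_ids)))
  invisible(x)
}

#' Build the hierarchical 5-PL rating model
#'
#' Assembles the hierarchical five-parameter logistic model of VAS
#' ratings: participant-level curve parameters `a_i ~ Beta(alpha1,
#' alpha2)`, `b_i ~ Normal(mu_b, 1)` truncated at 0.5, `c_i ~
#' Normal(mu_c, 1)` truncated to \[0.5, 5\], `d_i ~ Normal(mu_d, 1)`
#' truncated at 0.5, `g_i ~ Normal(mu_g, 1)` truncated at 0.8, with
#' group-level truncated-normal priors on the means (see
#' [default_priors()]), and likelihood
#' `y ~ Normal(five_pl(x; a_i, b_i, c_i, d_i, g_i), sigma)` with
#' `sigma ~ Half-Normal(0.2)` shared across participants.
#'
#' @param ratings data frame (`participant_id`, `image_id`, `rating`)
#'   with positive images already filtered out.
#' @param norms stimulus-norm table supplying the regressor
#'   `valence_mean` (1-9 source scale).
#' @param participant_index optional character vector fixing the
#'   participant ordering; defaults to sorted unique ids.
#' @param priors named list of overrides for rows of [default_priors()],
#'   e.g. `list(mu_b = list(mean = 3))`.
#' @param options list; `estimate_participant_sd = TRUE` replaces the
#'   fixed participant-level SD of 1 by estimated half-normal(1) SDs.
#' @return a `model_spec` object.
#' @export
build_5pl_model <- function(ratings, norms, participant_index = NULL,
                            priors = NULL, options = list()) {
  data <- bind_model_data(ratings, norms, participant_index)
  tab <- apply_prior_overrides(default_priors("fivepl"), priors)
  new_model_spec("fivepl", data, tab, options = options)
}

#' Build the hierarchical linear comparison model
#'
#' The linear benchmark `f(x) = b x + a` with group-level priors
#' `mu_a ~ Normal(0, 0.2)` truncated at 0 and `mu_b ~ Normal(0, 0.5)`
#' truncated at 0, and the same random-participant structure as the
#' 5-PL model (participant-level `a_i`, `b_i` around the group means
#' with SD fixed at 1, truncated at 0), so that the LOO comparison
#' between the two models is like-for-like.
#'
#' @inheritParams build_5pl_model
#' @return a `model_spec` object.
#' @export
build_linear_model <- function(ratings, norms, participant_index = NULL,
                               priors = NULL, options = list()) {
  data <- bind_model_data(ratings, norms, participant_index)
  tab <- apply_prior_overrides(default_priors("linear"), priors)
  new_model_spec("linear", data, tab, options = options)
}

#' Build the emotional-numbing slope-regression model
#'
#' Identical to [build_5pl_model()] except that the Hill slope entering
#' the curve for participant `i` is
#' `B_i = numbing_z_i * EN + b_i` — a fixed-slope random-intercept
#' regression of the slope on the z-scored emotional-numbing score,
#' with `EN ~ Normal(0, 1)`. `extra = "age"` adds `age_z_i * AGE`;
#' `extra = "age_interaction"` additionally adds
#' `numbing_z_i * age_z_i * INT`, each coefficient with a
#' `Normal(0, 1)` prior.
#'
#' @inheritParams build_5pl_model
#' @param numbing_z numeric vector, one z-scored emotional-numbing value
#'   per participant (same order as `participant_index`), mean ~0.
#' @param extra `"none"`, `"age"` or `"age_interaction"`.
#' @param age_z numeric vector of z-scored ages per participant
#'   (required when `extra != "none"`).
#' @return a `model_spec` object.
#' @export
build_en_model <- function(ratings, norms, participant_index = NULL,
                           numbing_z, extra = c("none", "age", "age_interaction"),
                           age_z = NULL, priors = NULL, options = list()) {
  extra <- match.arg(extra)
  data <- bind_model_data(ratings, norms, participant_index)
  P <- length(data$participant_ids)
  if (length(numbing_z) != P) {
    stop("numbing_z must have one value per participant (", P, ")", call. = FALSE)
  }
  if (abs(mean(numbing_z)) > 0.05) {
    warning("numbing_z does not appear to be centred (mean ",
            signif(mean(numbing_z), 3), ")")
  }
  covariates <- list(numbing_z = as.numeric(numbing_z))
  kind <- "fivepl_en"
  if (extra != "none") {
    if (is.null(age_z) || length(age_z) != P) {
      stop("age_z must have one value per participant (", P, ")", call. = FALSE)
    }
    covariates$age_z <- as.numeric(age_z)
    kind <- if (extra == "age") "fivepl_en_age" else "fivepl_en_age_interaction"
  }
  tab <- apply_prior_overrides(default_priors(kind), priors)
  new_model_spec(kind, data, tab, covariates = covariates, options = options)
}

# --- JAGS translation ---------------------------------------------------

jags_trunc <- function(lower, upper) {
  if (is.finite(lower) && is.finite(upper)) sprintf(" T(%g, %g)", lower, upper)
  else if (is.finite(lower)) sprintf(" T(%g, )", lower)
  else if (is.finite(upper)) sprintf(" T(, %g)", upper)
  else ""
}

jags_normal_line <- function(node, row, mean_expr = NULL, lower = NULL) {
  m <- mean_expr %||% sprintf("%g", row$mean)
  lo <- lower %||% row$lower
  sprintf("  %s ~ dnorm(%s, %g)%s", node, m, 1 / row$sd^2, jags_trunc(lo, row$upper))
}

slope_expr <- function(spec) {
  switch(spec$kind,
    fivepl = "b[i]",
    fivepl_en = "en_z[i] * EN + b[i]",
    fivepl_en_age = "en_z[i] * EN + age_z[i] * AGE + b[i]",
    fivepl_en_age_interaction =
      "en_z[i] * EN + age_z[i] * AGE + en_z[i] * age_z[i] * INT + b[i]",
    stop("no slope expression for kind ", spec$kind))
}

jags_model_code <- function(spec) {
  pr <- function(p) prior_row(spec, p)
  est_sd <- isTRUE(spec$options$estimate_participant_sd)
  lines <- c("model {")
  sig <- pr("sigma")
  lines <- c(lines,
    sprintf("  sigma ~ dnorm(0, %g) T(1.0E-4, )", 1 / sig$sd^2),
    "  tau_y <- pow(sigma, -2)")
  if (spec$kind == "linear") {
    lines <- c(lines,
      jags_normal_line("mu_a", pr("mu_a")),
      jags_normal_line("mu_b", pr("mu_b")))
    sd_nodes <- c(a = "1", b = "1")
    if (est_sd) {
      lines <- c(lines,
        "  sd_a ~ dnorm(0, 1) T(0.01, )",
        "  sd_b ~ dnorm(0, 1) T(0.01, )")
      sd_nodes <- c(a = "sd_a", b = "sd_b")
    }
    ra <- pr("a"); rb <- pr("b")
    lines <- c(lines,
      "  for (i in 1:P) {",
      sprintf("    a[i] ~ dnorm(mu_a, pow(%s, -2))%s", sd_nodes["a"],
              jags_trunc(ra$lower, ra$upper)),
      sprintf("    b[i] ~ dnorm(mu_b, pow(%s, -2))%s", sd_nodes["b"],
              jags_trunc(rb$lower, rb$upper)),
      "  }",
      "  for (n in 1:N) {",
      "    mu[n] <- b[pid[n]] * x[n] + a[pid[n]]",
      "    y[n] ~ dnorm(mu[n], tau_y)",
      "  }",
      "}")
    return(paste(lines, collapse = "\n"))
  }
  a1 <- pr("alpha1"); a2 <- pr("alpha2")
  lines <- c(lines,
    jags_normal_line("alpha1", a1),
    # alpha2 is printed untruncated; the positivity guard for the beta
    # shape is a hard bound just above 0 (prior mass below it ~8e-24)
    sprintf("  alpha2 ~ dnorm(%g, %g) T(1.0E-3, %s)", a2$mean, 1 / a2$sd^2,
            if (is.finite(a2$upper)) sprintf("%g", a2$upper) else ""),
    jags_normal_line("mu_b", pr("mu_b")),
    jags_normal_line("mu_c", pr("mu_c")),
    jags_normal_line("mu_d", pr("mu_d")),
    jags_normal_line("mu_g", pr("mu_g")))
  if (spec$kind != "fivepl") lines <- c(lines, jags_normal_line("EN", pr("EN")))
  if (spec$kind %in% c("fivepl_en_age", "fivepl_en_age_interaction")) {
    lines <- c(lines, jags_normal_line("AGE", pr("AGE")))
  }
  if (spec$kind == "fivepl_en_age_interaction") {
    lines <- c(lines, jags_normal_line("INT", pr("INT")))
  }
  sd_nodes <- c(b = "1", c = "1", d = "1", g = "1")
  if (est_sd) {
    for (p in c("b", "c", "d", "g")) {
      lines <- c(lines, sprintf("  sd_%s ~ dnorm(0, 1) T(0.01, )", p))
      sd_nodes[p] <- sprintf("sd_%s", p)
    }
  }
  rb <- pr("b"); rc <- pr("c"); rd <- pr("d"); rg <- pr("g")
  lines <- c(lines,
    "  for (i in 1:P) {",
    "    a[i] ~ dbeta(alpha1, alpha2)",
    sprintf("    b[i] ~ dnorm(mu_b, pow(%s, -2))%s", sd_nodes["b"],
            jags_trunc(rb$lower, rb$upper)),
    sprintf("    c[i] ~ dnorm(mu_c, pow(%s, -2))%s", sd_nodes["c"],
            jags_trunc(rc$lower, rc$upper)),
    sprintf("    d[i] ~ dnorm(mu_d, pow(%s, -2))%s", sd_nodes["d"],
            jags_trunc(rd$lower, rd$upper)),
    sprintf("    g[i] ~ dnorm(mu_g, pow(%s, -2))%s", sd_nodes["g"],
            jags_trunc(rg$lower, rg$upper)))
  if (spec$kind == "fivepl") {
    lines <- c(lines, "    B[i] <- b[i]")
  } else {
    lines <- c(lines, sprintf("    B[i] <- %s", slope_expr(spec)))
  }
  lines <- c(lines,
    "  }",
    "  for (n in 1:N) {",
    "    mu[n] <- d[pid[n]] + (a[pid[n]] - d[pid[n]]) / pow(1 + pow(x[n] / c[pid[n]], B[pid[n]]), g[pid[n]])",
    "    y[n] ~ dnorm(mu[n], tau_y)",
    "  }",
    "}")
  paste(lines, collapse = "\n")
}

jags_data_list <- function(spec) {
  out <- list(N = length(spec$data$y), P = length(spec$data$participant_ids),
              x = spec$data$x, y = spec$data$y, pid = spec$data$pid)
  if (!is.null(spec$covariates$numbing_z)) out$en_z <- spec$covariates$numbing_z
  if (!is.null(spec$covariates$age_z)) out$age_z <- spec$covariates$age_z
  out
}

jags_inits <- function(spec, chain_seed) {
  P <- length(spec$data$participant_ids)
  inits <- if (spec$kind == "linear") {
    list(mu_a = 0.2, mu_b = 0.1, a = rep(0.2, P), b = rep(0.1, P), sigma = 0.1)
  } else {
    # start at the prior centres (data-sane where the prior centre would
    # put the curve outside the rating scale)
    list(alpha1 = 2, alpha2 = 10, mu_b = 2, mu_c = 2, mu_d = 0.7,
         mu_g = 4, a = rep(0.15, P), b = rep(2, P), c = rep(2, P),
         d = rep(0.7, P), g = rep(4, P), sigma = 0.1)
  }
  if (spec$kind != "linear" && spec$kind != "fivepl") inits$EN <- 0
  if (spec$kind %in% c("fivepl_en_age", "fivepl_en_age_interaction")) inits$AGE <- 0
  if (spec$kind == "fivepl_en_age_interaction") inits$INT <- 0
  if (isTRUE(spec$options$estimate_participant_sd)) {
    sds <- if (spec$kind == "linear") c("sd_a", "sd_b")
           else c("sd_b", "sd_c", "sd_d", "sd_g")
    for (s in sds) inits[[s]] <- 0.3
  }
  inits$.RNG.name <- "base::Mersenne-Twister"
  inits$.RNG.seed <- chain_seed
  inits
}

jags_monitors <- function(spec) {
  base <- if (spec$kind == "linear") c("mu_a", "mu_b", "a", "b", "sigma")
          else c("alpha1", "alpha2", "mu_b", "mu_c", "mu_d", "mu_g",
                 "a", "b", "c", "d", "g", "sigma")
  if (spec$kind %in% c("fivepl_en", "fivepl_en_age",
                       "fivepl_en_age_interaction")) base <- c(base, "EN")
  if (spec$kind %in% c("fivepl_en_age", "fivepl_en_age_interaction")) {
    base <- c(base, "AGE")
  }
  if (spec$kind == "fivepl_en_age_interaction") base <- c(base, "INT")
  if (isTRUE(spec$options$estimate_participant_sd)) {
    base <- c(base, if (spec$kind == "linear") c("sd_a", "sd_b")
                    else c("sd_b", "sd_c", "sd_d", "sd_g"))
  }
  base
}

# --- direct log-density evaluation -------------------------------------

log_dtnorm <- function(x, mean, sd, lower, upper) {
  if (any(x < lower | x > upper)) return(-Inf)
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  sum(stats::dnorm(x, mean, sd, log = TRUE)) - length(x) * log(z)
}

#' Joint log-density of a model at a parameter point
#'
#' Evaluates log prior + log likelihood of a `model_spec` at a named
#' parameter point, returning `-Inf` outside any truncation bound
#' (including the positivity guard on `alpha2`). Intended for tests and
#' debugging; sampling goes through [fit_model()].
#'
#' @param spec a `model_spec`.
#' @param params named list: group-level scalars plus participant-level
#'   vectors (`a`, `b`, `c`, `d`, `g` for the 5-PL family; `a`, `b` for
#'   the linear model) and `sigma`; `EN`/`AGE`/`INT` where applicable.
#' @return scalar log-density.
#' @export
model_log_density <- function(spec, params) {
  p <- params
  pr <- function(nm) prior_row(spec, nm)
  ld <- 0
  add <- function(ld, v) if (!is.finite(v)) -Inf else ld + v
  if (p$sigma <= 0) return(-Inf)
  sig <- pr("sigma")
  ld <- add(ld, stats::dnorm(p$sigma, 0, sig$sd, log = TRUE) + log(2))
  P <- length(spec$data$participant_ids)
  if (spec$kind == "linear") {
    for (nm in c("mu_a", "mu_b")) {
      r <- pr(nm)
      ld <- add(ld, log_dtnorm(p[[nm]], r$mean, r$sd, r$lower, r$upper))
    }
    ra <- pr("a"); rb <- pr("b")
    ld <- add(ld, log_dtnorm(p$a, p$mu_a, ra$sd, ra$lower, ra$upper))
    ld <- add(ld, log_dtnorm(p$b, p$mu_b, rb$sd, rb$lower, rb$upper))
    if (!is.finite(ld)) return(-Inf)
    mu <- p$b[spec$data$pid] * spec$data$x + p$a[spec$data$pid]
    return(ld + sum(stats::dnorm(spec$data$y, mu, p$sigma, log = TRUE)))
  }
  for (nm in c("alpha1", "mu_b", "mu_c", "mu_d", "mu_g")) {
    r <- pr(nm)
    ld <- add(ld, log_dtnorm(p[[nm]], r$mean, r$sd, r$lower, r$upper))
  }
  # positivity guard: the printed prior is untruncated but a beta shape
  # must be positive
  if (p$alpha2 <= 0) return(-Inf)
  r2 <- pr("alpha2")
  ld <- add(ld, log_dtnorm(p$alpha2, r2$mean, r2$sd, r2$lower, r2$upper))
  if (any(p$a <= 0 | p$a >= 1)) return(-Inf)
  ld <- add(ld, sum(stats::dbeta(p$a, p$alpha1, p$alpha2, log = TRUE)))
  for (nm in c("b", "c", "d", "g")) {
    r <- pr(nm)
    ld <- add(ld, log_dtnorm(p[[nm]], p[[paste0("mu_", nm)]], r$sd,
                             r$lower, r$upper))
  }
  for (nm in c("EN", "AGE", "INT")) {
    if (!is.null(p[[nm]])) {
      r <- pr(nm)
      ld <- add(ld, log_dtnorm(p[[nm]], r$mean, r$sd, r$lower, r$upper))
    }
  }
  if (!is.finite(ld)) return(-Inf)
  B <- p$b
  if (!is.null(spec$covariates$numbing_z)) {
    B <- B + spec$covariates$numbing_z * p$EN
  }
  if (!is.null(spec$covariates$age_z) && !is.null(p$AGE)) {
    B <- B + spec$covariates$age_z * p$AGE
  }
  if (!is.null(p$INT)) {
    B <- B + spec$covariates$numbing_z * spec$covariates$age_z * p$INT
  }
  i <- spec$data$pid
  mu <- p$d[i] + (p$a[i] - p$d[i]) /
    (1 + (spec$data$x / p$c[i])^B[i])^p$g[i]
  ld + sum(stats::dnorm(spec$data$y, mu, p$sigma, log = TRUE))
}

# --- serialization ------------------------------------------------------

#' Serialize or restore a model specification
#'
#' `model_spec_to_json()` writes the complete specification — kind,
#' prior table, options, covariates and data bindings — to JSON at full
#' numeric precision; `model_spec_from_json()` restores it losslessly.
#'
#' @param spec a `model_spec`.
#' @param path file path.
#' @return `model_spec_from_json()` returns the restored `model_spec`;
#'   `model_spec_to_json()` returns `path` invisibly.
#' @export
model_spec_to_json <- function(spec, path) {
  obj <- list(kind = spec$kind, priors = spec$priors,
              options = spec$options, covariates = spec$covariates,
              data = spec$data)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "string", pretty = TRUE)
  invisible(path)
}

#' @rdname model_spec_to_json
#' @export
model_spec_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  priors <- as.data.frame(obj$priors, stringsAsFactors = FALSE)
  for (f in c("mean", "sd", "lower", "upper")) {
    priors[[f]] <- suppressWarnings(as.numeric(priors[[f]]))
  }
  covs <- obj$covariates
  if (length(covs) == 0) covs <- list()
  data <- obj$data
  data$pid <- as.integer(data$pid)
  new_model_spec(obj$kind, data, priors, covariates = covs,
                 options = obj$options)
}
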