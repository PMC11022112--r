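# Unconstrained-space target (log posterior + analytic gradient) for the
# hierarchical models, used by the NUTS engine. Bounded parameters are
# mapped to the real line (log / scaled-logit transforms with Jacobian
# corrections); participant-level truncated-normal priors carry their
# mean-dependent normalization terms so the hierarchy is exact.

# block metadata: name, size, lower, upper (transform inferred from
# bounds); nc marks participant layers sampled as non-centered N(0,1)
# deviates when the participant-level SDs are estimated
target_blocks <- function(spec) {
  P <- length(spec$data$participant_ids)
  pr <- function(p) prior_row(spec, p)
  blk <- function(name, size, lower, upper, nc = FALSE) {
    if (nc) { lower <- -Inf; upper <- Inf }
    data.frame(name = name, size = size, lower = lower, upper = upper,
               nc = nc, stringsAsFactors = FALSE)
  }
  est_sd <- isTRUE(spec$options$estimate_participant_sd)
  if (spec$kind == "linear") {
    b <- rbind(
      blk("mu_a", 1, pr("mu_a")$lower, pr("mu_a")$upper),
      blk("mu_b", 1, pr("mu_b")$lower, pr("mu_b")$upper),
      blk("sigma", 1, 0, Inf),
      if (est_sd) rbind(blk("sd_a", 1, 0, Inf), blk("sd_b", 1, 0, Inf)),
      blk("a", P, pr("a")$lower, pr("a")$upper, nc = est_sd),
      blk("b", P, pr("b")$lower, pr("b")$upper, nc = est_sd)
    )
    return(b)
  }
  b <- rbind(
    blk("alpha1", 1, pr("alpha1")$lower, pr("alpha1")$upper),
    # positivity guard on the beta shape (printed prior is untruncated)
    blk("alpha2", 1, 0, pr("alpha2")$upper),
    blk("mu_b", 1, pr("mu_b")$lower, pr("mu_b")$upper),
    blk("mu_c", 1, pr("mu_c")$lower, pr("mu_c")$upper),
    blk("mu_d", 1, pr("mu_d")$lower, pr("mu_d")$upper),
    blk("mu_g", 1, pr("mu_g")$lower, pr("mu_g")$upper),
    blk("sigma", 1, 0, Inf)
  )
  if (spec$kind != "fivepl") b <- rbind(b, blk("EN", 1, -Inf, Inf))
  if (spec$kind %in% c("fivepl_en_age", "fivepl_en_age_interaction")) {
    b <- rbind(b, blk("AGE", 1, -Inf, Inf))
  }
  if (spec$kind == "fivepl_en_age_interaction") b <- rbind(b, blk("INT", 1, -Inf, Inf))
  if (est_sd) {
    b <- rbind(b, blk("sd_b", 1, 0, Inf), blk("sd_c", 1, 0, Inf),
               blk("sd_d", 1, 0, Inf), blk("sd_g", 1, 0, Inf))
  }
  rbind(b,
        blk("a", P, 0, 1),
        blk("b", P, pr("b")$lower, pr("b")$upper, nc = est_sd),
        blk("c", P, pr("c")$lower, pr("c")$upper, nc = est_sd),
        blk("d", P, pr("d")$lower, pr("d")$upper, nc = est_sd),
        blk("g", P, pr("g")$lower, pr("g")$upper, nc = est_sd))
}

unconstrain_block <- function(v, lower, upper) {
  if (is.finite(lower) && is.finite(upper)) {
    stats::qlogis((v - lower) / (upper - lower))
  } else if (is.finite(lower)) log(v - lower)
  else if (is.finite(upper)) log(upper - v)
  else v
}

# gradient pieces of a truncated-normal layer v_i ~ TN(mu, s, L, U):
# returns lp contribution and gradients wrt v, mu and s
tn_layer <- function(v, mu, s, L, U) {
  r <- (v - mu) / s
  lp <- -sum(r^2) / 2 - length(v) * log(s)
  g_v <- -r / s
  g_mu <- sum(r) / s
  g_s <- sum(r^2) / s - length(v) / s
  if (is.finite(L) || is.finite(U)) {
    zL <- if (is.finite(L)) (L - mu) / s else -Inf
    zU <- if (is.finite(U)) (U - mu) / s else Inf
    Z <- stats::pnorm(zU) - stats::pnorm(zL)
    phL <- if (is.finite(L)) stats::dnorm(zL) else 0
    phU <- if (is.finite(U)) stats::dnorm(zU) else 0
    n <- length(v)
    lp <- lp - n * log(Z)
    g_mu <- g_mu + n * (phU - phL) / (s * Z)            # d(-logZ)/dmu
    g_s <- g_s + n * (phU * zL_safe(zU) - phL * zL_safe(zL)) / (s * Z)
  }
  list(lp = lp, g_v = g_v, g_mu = g_mu, g_s = g_s)
}
zL_safe <- function(z) if (is.finite(z)) z else 0

# exact non-centered map for a truncated-normal layer: eta ~ N(0,1) on the
# real line, v = F^{-1}(Phi(eta); mu, s, L, U). Used when participant-level
# SDs are estimated (removes the centered funnel); returns the value and
# its partial derivatives wrt eta, mu and s.
tn_nc_map <- function(eta, mu, s, L, U) {
  zL <- if (is.finite(L)) (L - mu) / s else -Inf
  zU <- if (is.finite(U)) (U - mu) / s else Inf
  PL <- stats::pnorm(zL); PU <- stats::pnorm(zU)
  W <- PU - PL
  Ph <- stats::pnorm(eta); ph <- stats::dnorm(eta)
  p <- pmin(pmax(PL + Ph * W, 1e-15), 1 - 1e-15)
  z <- stats::qnorm(p)
  fz <- pmax(stats::dnorm(z), 1e-300)
  phL <- if (is.finite(zL)) stats::dnorm(zL) else 0
  phU <- if (is.finite(zU)) stats::dnorm(zU) else 0
  dp_dmu <- (-phL * (1 - Ph) - phU * Ph) / s
  dp_ds <- (-phL * zL_safe(zL) * (1 - Ph) - phU * zL_safe(zU) * Ph) / s
  list(v = mu + s * z,
       d_eta = s * W * ph / fz,
       d_mu = 1 + s * dp_dmu / fz,
       d_s = z + s * dp_ds / fz)
}

# full constrained-space log posterior and gradient for a model_spec
make_target <- function(spec) {
  blocks <- target_blocks(spec)
  D <- sum(blocks$size)
  idx <- vector("list", nrow(blocks))
  pos <- 0L
  for (i in seq_len(nrow(blocks))) {
    idx[[i]] <- pos + seq_len(blocks$size[i])
    pos <- pos + blocks$size[i]
  }
  names(idx) <- blocks$name
  x <- spec$data$x; y <- spec$data$y; pid <- spec$data$pid
  N <- length(y); P <- length(spec$data$participant_ids)
  lx <- log(x)
  en <- spec$covariates$numbing_z
  az <- spec$covariates$age_z
  est_sd <- isTRUE(spec$options$estimate_participant_sd)
  pr <- function(p) prior_row(spec, p)
  pr_b <- pr("b"); pr_a <- pr("a")
  if (spec$kind != "linear") {
    pr_c <- pr("c"); pr_d <- pr("d"); pr_g <- pr("g")
  }
  group_kernels <- if (spec$kind == "linear") c("mu_a", "mu_b")
                   else c("alpha1", "alpha2", "mu_b", "mu_c", "mu_d", "mu_g")
  gk <- lapply(setNames(group_kernels, group_kernels), pr)
  sig_sd <- pr("sigma")$sd
  coef_names <- intersect(c("EN", "AGE", "INT"), blocks$name)
  ck <- lapply(setNames(coef_names, coef_names), pr)

  lp_grad_constrained <- function(v) {
    g <- lapply(v, function(z) numeric(length(z)))
    lp <- 0
    for (nm in group_kernels) {
      r <- gk[[nm]]
      lp <- lp - (v[[nm]] - r$mean)^2 / (2 * r$sd^2)
      g[[nm]] <- -(v[[nm]] - r$mean) / r$sd^2
    }
    for (nm in coef_names) {
      r <- ck[[nm]]
      lp <- lp - (v[[nm]] - r$mean)^2 / (2 * r$sd^2)
      g[[nm]] <- -(v[[nm]] - r$mean) / r$sd^2
    }
    lp <- lp - v$sigma^2 / (2 * sig_sd^2)
    g$sigma <- -v$sigma / sig_sd^2
    if (est_sd) {
      for (nm in grep("^sd_", blocks$name, value = TRUE)) {
        lp <- lp - v[[nm]]^2 / 2
        g[[nm]] <- -v[[nm]]
      }
    }
    if (spec$kind == "linear") {
      if (est_sd) {
        # non-centered: v$a, v$b hold standard-normal deviates
        ma <- tn_nc_map(v$a, v$mu_a, v$sd_a, pr_a$lower, pr_a$upper)
        mb <- tn_nc_map(v$b, v$mu_b, v$sd_b, pr_b$lower, pr_b$upper)
        lp <- lp - (sum(v$a^2) + sum(v$b^2)) / 2
        g$a <- g$a - v$a
        g$b <- g$b - v$b
        lik <- .linear_lik_grad(y, x, pid, ma$v, mb$v, v$sigma)
        lp <- lp + lik$lp
        g$sigma <- g$sigma + lik$gsigma
        g$a <- g$a + lik$ga * ma$d_eta
        g$b <- g$b + lik$gb * mb$d_eta
        g$mu_a <- g$mu_a + sum(lik$ga * ma$d_mu)
        g$mu_b <- g$mu_b + sum(lik$gb * mb$d_mu)
        g$sd_a <- g$sd_a + sum(lik$ga * ma$d_s)
        g$sd_b <- g$sd_b + sum(lik$gb * mb$d_s)
        return(list(lp = lp, g = g))
      }
      la <- tn_layer(v$a, v$mu_a, pr_a$sd, pr_a$lower, pr_a$upper)
      lb <- tn_layer(v$b, v$mu_b, pr_b$sd, pr_b$lower, pr_b$upper)
      lp <- lp + la$lp + lb$lp
      g$a <- g$a + la$g_v; g$mu_a <- g$mu_a + la$g_mu
      g$b <- g$b + lb$g_v; g$mu_b <- g$mu_b + lb$g_mu
      lik <- .linear_lik_grad(y, x, pid, v$a, v$b, v$sigma)
      lp <- lp + lik$lp
      g$sigma <- g$sigma + lik$gsigma
      g$a <- g$a + lik$ga
      g$b <- g$b + lik$gb
      return(list(lp = lp, g = g))
    }
    # beta layer for a
    a1 <- v$alpha1; a2 <- v$alpha2
    lp <- lp + (a1 - 1) * sum(log(v$a)) + (a2 - 1) * sum(log1p(-v$a)) -
      P * lbeta(a1, a2)
    g$a <- g$a + (a1 - 1) / v$a - (a2 - 1) / (1 - v$a)
    dig <- digamma(a1 + a2)
    g$alpha1 <- g$alpha1 + sum(log(v$a)) - P * (digamma(a1) - dig)
    g$alpha2 <- g$alpha2 + sum(log1p(-v$a)) - P * (digamma(a2) - dig)
    # participant layers: centered truncated normals as printed, or
    # exact non-centered deviates when the SDs are estimated
    if (est_sd) {
      maps <- list(
        b = tn_nc_map(v$b, v$mu_b, v$sd_b, pr_b$lower, pr_b$upper),
        c = tn_nc_map(v$c, v$mu_c, v$sd_c, pr_c$lower, pr_c$upper),
        d = tn_nc_map(v$d, v$mu_d, v$sd_d, pr_d$lower, pr_d$upper),
        g = tn_nc_map(v$g, v$mu_g, v$sd_g, pr_g$lower, pr_g$upper))
      pv <- lapply(maps, `[[`, "v")
      for (nm in c("b", "c", "d", "g")) {
        lp <- lp - sum(v[[nm]]^2) / 2
        g[[nm]] <- g[[nm]] - v[[nm]]
      }
    } else {
      lyb <- tn_layer(v$b, v$mu_b, pr_b$sd, pr_b$lower, pr_b$upper)
      lyc <- tn_layer(v$c, v$mu_c, pr_c$sd, pr_c$lower, pr_c$upper)
      lyd <- tn_layer(v$d, v$mu_d, pr_d$sd, pr_d$lower, pr_d$upper)
      lyg <- tn_layer(v$g, v$mu_g, pr_g$sd, pr_g$lower, pr_g$upper)
      lp <- lp + lyb$lp + lyc$lp + lyd$lp + lyg$lp
      g$b <- g$b + lyb$g_v; g$mu_b <- g$mu_b + lyb$g_mu
      g$c <- g$c + lyc$g_v; g$mu_c <- g$mu_c + lyc$g_mu
      g$d <- g$d + lyd$g_v; g$mu_d <- g$mu_d + lyd$g_mu
      g$g <- g$g + lyg$g_v; g$mu_g <- g$mu_g + lyg$g_mu
      pv <- list(b = v$b, c = v$c, d = v$d, g = v$g)
    }
    # likelihood through the 5-PL mean (compiled kernel)
    B <- pv$b
    if (!is.null(en)) B <- B + en * v$EN
    if (!is.null(az) && !is.null(v$AGE)) B <- B + az * v$AGE
    if (!is.null(v$INT)) B <- B + en * az * v$INT
    lik <- .fivepl_lik_grad(y, lx, pid, v$a, B, pv$c, pv$d, pv$g, v$sigma)
    lp <- lp + lik$lp
    if (!is.finite(lp)) return(list(lp = -Inf, g = g))
    g$sigma <- g$sigma + lik$gsigma
    g$a <- g$a + lik$ga
    if (est_sd) {
      lg <- list(b = lik$gB, c = lik$gc, d = lik$gd, g = lik$gg)
      for (nm in c("b", "c", "d", "g")) {
        g[[nm]] <- g[[nm]] + lg[[nm]] * maps[[nm]]$d_eta
        g[[paste0("mu_", nm)]] <- g[[paste0("mu_", nm)]] +
          sum(lg[[nm]] * maps[[nm]]$d_mu)
        g[[paste0("sd_", nm)]] <- g[[paste0("sd_", nm)]] +
          sum(lg[[nm]] * maps[[nm]]$d_s)
      }
    } else {
      g$d <- g$d + lik$gd
      g$b <- g$b + lik$gB
      g$c <- g$c + lik$gc
      g$g <- g$g + lik$gg
    }
    if (!is.null(en)) g$EN <- g$EN + sum(en * lik$gB)
    if (!is.null(az) && !is.null(v$AGE)) g$AGE <- g$AGE + sum(az * lik$gB)
    if (!is.null(v$INT)) g$INT <- g$INT + sum(en * az * lik$gB)
    list(lp = lp, g = g)
  }

  # vectorized transform bookkeeping over the full parameter vector
  lo_vec <- rep(blocks$lower, blocks$size)
  hi_vec <- rep(blocks$upper, blocks$size)
  m_lb <- is.finite(lo_vec) & !is.finite(hi_vec)
  m_int <- is.finite(lo_vec) & is.finite(hi_vec)
  width <- hi_vec[m_int] - lo_vec[m_int]
  transform_all <- function(u) {
    v <- u
    dv <- rep(1, D)
    dlogJ <- numeric(D)
    logJ <- 0
    if (any(m_lb)) {
      e <- exp(u[m_lb])
      v[m_lb] <- lo_vec[m_lb] + e
      dv[m_lb] <- e
      dlogJ[m_lb] <- 1
      logJ <- logJ + sum(u[m_lb])
    }
    if (any(m_int)) {
      s <- stats::plogis(u[m_int])
      v[m_int] <- lo_vec[m_int] + width * s
      dv[m_int] <- width * s * (1 - s)
      dlogJ[m_int] <- 1 - 2 * s
      logJ <- logJ + sum(log(width) + log(s) + log1p(-s))
    }
    list(v = v, dv = dv, dlogJ = dlogJ, logJ = logJ)
  }

  lp_grad <- function(u) {
    tr <- transform_all(u)
    if (any(!is.finite(tr$v))) {
      return(list(lp = -Inf, grad = rep(0, D)))
    }
    v <- lapply(idx, function(j) tr$v[j])
    res <- lp_grad_constrained(v)
    if (!is.finite(res$lp)) return(list(lp = -Inf, grad = rep(0, D)))
    list(lp = res$lp + tr$logJ,
         grad = unlist(res$g, use.names = FALSE) * tr$dv + tr$dlogJ)
  }

  # pooled least-squares curve fit: one set of curve parameters for all
  # observations, used to start every chain inside the data-supported
  # region (the posterior of the 5-PL family is ridge-shaped; chains
  # started at the prior centres can fail to reach the dominant basin)
  ls_init_values <- local({
    cache <- NULL
    function() {
      if (!is.null(cache)) return(cache)
      ini <- jags_inits(spec, 1L)
      if (spec$kind == "linear") {
        fitlm <- stats::lm.fit(cbind(1, x), y)
        co <- fitlm$coefficients
        ini$mu_a <- min(max(co[1], 0.01), 1)
        ini$mu_b <- min(max(co[2], 0.01), 2)
        ini$a <- rep(ini$mu_a, P); ini$b <- rep(ini$mu_b, P)
      } else {
        sse <- function(p) sum((y - five_pl(x, p[1], p[2], p[3], p[4], p[5]))^2)
        o <- stats::optim(c(0.1, 2, 2.5, 0.6, 1.5), sse, method = "L-BFGS-B",
                          lower = c(1e-3, 0.51, 0.51, 0.51, 0.81),
                          upper = c(0.999, 8, 4.99, 1.5, 8),
                          control = list(maxit = 500))
        q <- o$par
        ini$a <- rep(q[1], P); ini$b <- rep(q[2], P); ini$c <- rep(q[3], P)
        ini$d <- rep(q[4], P); ini$g <- rep(q[5], P)
        ini$mu_b <- max(q[2], 1.01); ini$mu_c <- max(q[3], 0.51)
        ini$mu_d <- max(q[4], 0.01); ini$mu_g <- max(q[5], 1.01)
        ini$alpha2 <- 10
        ini$alpha1 <- min(max(10 * q[1] / (1 - q[1]), 1.01), 8)
      }
      ini$sigma <- max(0.02, stats::sd(y) / 4)
      cache <<- ini
      ini
    }
  })

  init_u <- function(jitter_sd = 0, mode = c("ls", "prior")) {
    mode <- match.arg(mode)
    ini <- if (mode == "ls") ls_init_values() else jags_inits(spec, 1L)
    u <- numeric(D)
    for (i in seq_len(nrow(blocks))) {
      nm <- blocks$name[i]
      if (isTRUE(blocks$nc[i])) next  # non-centered deviates start at 0
      val <- ini[[nm]]
      if (is.null(val)) val <- 0
      u[idx[[i]]] <- unconstrain_block(rep(val, length.out = blocks$size[i]),
                                       blocks$lower[i], blocks$upper[i])
    }
    if (jitter_sd > 0) u <- u + stats::rnorm(D, 0, jitter_sd)
    u
  }

  flat_names <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    if (blocks$size[i] == 1) blocks$name[i]
    else sprintf("%s[%d]", blocks$name[i], seq_len(blocks$size[i]))
  }))

  constrain_all <- function(u) {
    out <- transform_all(u)$v
    if (est_sd) {
      # map the non-centered deviates back to participant parameters
      if (spec$kind == "linear") {
        layers <- list(a = pr_a, b = pr_b)
        mus <- c(a = "mu_a", b = "mu_b"); sds <- c(a = "sd_a", b = "sd_b")
      } else {
        layers <- list(b = pr_b, c = pr_c, d = pr_d, g = pr_g)
        mus <- c(b = "mu_b", c = "mu_c", d = "mu_d", g = "mu_g")
        sds <- c(b = "sd_b", c = "sd_c", d = "sd_d", g = "sd_g")
      }
      for (nm in names(layers)) {
        r <- layers[[nm]]
        out[idx[[match(nm, blocks$name)]]] <-
          tn_nc_map(out[idx[[match(nm, blocks$name)]]],
                    out[idx[[match(mus[[nm]], blocks$name)]]],
                    out[idx[[match(sds[[nm]], blocks$name)]]],
                    r$lower, r$upper)$v
      }
    }
    out
  }

  list(dim = D, blocks = blocks, idx = idx, lp_grad = lp_grad,
       init_u = init_u, constrain = constrain_all, flat_names = flat_names)
}
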