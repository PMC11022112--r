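# No-U-Turn sampler with dual-averaging step-size adaptation and
# windowed mass-matrix estimation (slice-sampling tree variant,
# divergence threshold 1000 on the joint log density). The metric is
# dense by default: the 5-PL posterior carries strong within-participant
# correlations that a diagonal metric cannot absorb, forcing very deep
# trajectories; a dense metric estimated in the warmup windows keeps
# tree depths small. "diag" remains available for large dimensions.

nuts_chain <- function(target, n_warmup, n_draws, seed,
                       target_accept = 0.8, max_treedepth = 10,
                       init_jitter = 0.2, init_mode = "ls",
                       metric = c("dense", "diag")) {
  metric <- match.arg(metric)
  set.seed(seed)
  D <- target$dim
  lpg <- target$lp_grad
  u <- target$init_u(jitter_sd = init_jitter, mode = init_mode)
  cur <- lpg(u)
  tries <- 0
  while (!is.finite(cur$lp) && tries < 20) {
    u <- target$init_u(jitter_sd = init_jitter, mode = init_mode)
    cur <- lpg(u)
    tries <- tries + 1
  }
  if (!is.finite(cur$lp)) {
    stop("non-finite log density at the initial point", call. = FALSE)
  }

  # metric state: velocity(p) = M^{-1} p where M^{-1} is the estimated
  # posterior covariance; momenta are N(0, M)
  inv_diag <- rep(1, D)     # diagonal of M^{-1}
  dense_cov <- NULL         # M^{-1} (dense case)
  dense_mom_L <- NULL       # draws p = solve(chol(M^{-1}), z)
  velocity <- function(p) {
    if (is.null(dense_cov)) inv_diag * p else drop(dense_cov %*% p)
  }
  kinetic <- function(p) sum(p * velocity(p)) / 2
  draw_momentum <- function() {
    z <- stats::rnorm(D)
    if (is.null(dense_cov)) z / sqrt(inv_diag)
    else backsolve(dense_mom_L, z, upper.tri = TRUE, transpose = FALSE)
  }
  set_dense <- function(S) {
    # regularized covariance -> M^{-1}; keep a chol factor of it for
    # momentum draws (p = A^{-1} z with S = A' A gives cov S^{-1})
    A <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(A)) {
      S <- S + diag(1e-8 + 1e-6 * mean(diag(S)), D)
      A <- tryCatch(chol(S), error = function(e) NULL)
    }
    if (is.null(A)) return(FALSE)
    dense_cov <<- S
    dense_mom_L <<- A
    TRUE
  }

  # states carry their velocity (v = M^{-1} p) so the dense matvec is
  # computed once per leapfrog; kinetic energy is then sum(p * v) / 2
  leapfrog <- function(u, p, grad, eps) {
    p <- p + eps / 2 * grad
    u <- u + eps * velocity(p)
    new <- lpg(u)
    p <- p + eps / 2 * new$grad
    list(u = u, p = p, v = velocity(p), lp = new$lp, grad = new$grad)
  }

  # crude reasonable step size: halve/double until acceptance crosses 1/2
  find_eps <- function(u, cur) {
    eps <- 0.1
    p <- draw_momentum()
    H0 <- cur$lp - kinetic(p)
    st <- leapfrog(u, p, cur$grad, eps)
    dH <- (st$lp - sum(st$p * st$v) / 2) - H0
    if (!is.finite(dH)) dH <- -Inf
    dir <- if (dH > log(0.5)) 1 else -1
    for (k in 1:40) {
      eps <- eps * 2^dir
      st <- leapfrog(u, p, cur$grad, eps)
      dH <- (st$lp - sum(st$p * st$v) / 2) - H0
      if (!is.finite(dH)) dH <- -Inf
      if ((dir == 1 && dH <= log(0.5)) || (dir == -1 && dH > log(0.5))) break
    }
    eps
  }

  eps <- find_eps(u, cur)
  # dual averaging state
  da_mu <- log(10 * eps); da_H <- 0; da_leps_bar <- log(eps); da_n <- 0
  da_gamma <- 0.05; da_t0 <- 10; da_kappa <- 0.75
  da_reset <- function(eps0) {
    da_mu <<- log(10 * eps0); da_H <<- 0; da_leps_bar <<- log(eps0); da_n <<- 0
  }
  da_update <- function(accept) {
    da_n <<- da_n + 1
    da_H <<- (1 - 1 / (da_n + da_t0)) * da_H +
      (target_accept - accept) / (da_n + da_t0)
    leps <- da_mu - sqrt(da_n) / da_gamma * da_H
    w <- da_n^(-da_kappa)
    da_leps_bar <<- w * leps + (1 - w) * da_leps_bar
    exp(leps)
  }

  # adaptation windows (Stan-like: initial step-size buffer, doubling
  # variance windows, terminal step-size buffer)
  init_buf <- min(75L, max(5L, round(0.15 * n_warmup)))
  term_buf <- min(50L, max(5L, round(0.10 * n_warmup)))
  windows <- integer(0)
  if (n_warmup > init_buf + term_buf + 10L) {
    w <- max(25L, round(0.1 * n_warmup))
    pos <- init_buf
    repeat {
      nxt <- pos + w
      if (nxt + 2L * w + term_buf > n_warmup) {
        nxt <- n_warmup - term_buf
        windows <- c(windows, nxt)
        break
      }
      windows <- c(windows, nxt)
      pos <- nxt
      w <- 2L * w
    }
  }
  wbuf <- matrix(NA_real_, nrow = max(c(windows, 0)) + 1L, ncol = D)
  wn <- 0

  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, nrow = n_draws, ncol = D)
  stats <- data.frame(accept_stat = numeric(n_draws),
                      treedepth = integer(n_draws),
                      divergent = logical(n_draws),
                      energy = numeric(n_draws),
                      n_leapfrog = integer(n_draws))
  divergences_warmup <- 0L

  for (it in seq_len(total)) {
    p0 <- draw_momentum()
    v0 <- velocity(p0)
    K0 <- sum(p0 * v0) / 2
    H0 <- cur$lp - K0
    log_slice <- H0 + log(stats::runif(1))
    state_minus <- list(u = u, p = p0, v = v0, lp = cur$lp, grad = cur$grad)
    state_plus <- state_minus
    u_prop <- u; cur_prop <- cur
    n_keep <- 1L; depth <- 0L; running <- TRUE
    div <- FALSE; acc_sum <- 0; acc_n <- 0L; n_leap <- 0L

    build <- function(state, dir, depth) {
      if (depth == 0L) {
        st <- leapfrog(state$u, state$p, state$grad, dir * eps)
        n_leap <<- n_leap + 1L
        H <- if (is.finite(st$lp)) st$lp - sum(st$p * st$v) / 2 else -Inf
        dH <- H - H0
        acc_sum <<- acc_sum + min(1, exp(min(0, dH))); acc_n <<- acc_n + 1L
        divergent <- !is.finite(H) || (log_slice - H) > 1000
        list(minus = st, plus = st,
             prop = st, n = as.integer(is.finite(H) && log_slice <= H),
             stop = divergent, div = divergent)
      } else {
        t1 <- build(state, dir, depth - 1L)
        if (t1$stop) return(t1)
        from <- if (dir == 1) t1$plus else t1$minus
        t2 <- build(from, dir, depth - 1L)
        if (dir == 1) { minus <- t1$minus; plus <- t2$plus }
        else { minus <- t2$minus; plus <- t1$plus }
        n <- t1$n + t2$n
        prop <- if (n > 0 && stats::runif(1) < t2$n / n) t2$prop else t1$prop
        du <- plus$u - minus$u
        uturn <- sum(du * minus$v) < 0 || sum(du * plus$v) < 0
        list(minus = minus, plus = plus, prop = prop, n = n,
             stop = t2$stop || uturn, div = t1$div || t2$div)
      }
    }

    while (running && depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      sub <- build(if (dir == 1) state_plus else state_minus, dir, depth)
      if (dir == 1) state_plus <- sub$plus else state_minus <- sub$minus
      div <- div || sub$div
      if (!sub$stop && sub$n > 0 &&
          stats::runif(1) < sub$n / n_keep) {
        u_prop <- sub$prop$u
        cur_prop <- list(lp = sub$prop$lp, grad = sub$prop$grad)
      }
      n_keep <- n_keep + sub$n
      du <- state_plus$u - state_minus$u
      uturn <- sum(du * state_minus$v) < 0 || sum(du * state_plus$v) < 0
      running <- !sub$stop && !uturn
      depth <- depth + 1L
    }
    u <- u_prop; cur <- cur_prop
    accept <- if (acc_n > 0) acc_sum / acc_n else 0

    if (it <= n_warmup) {
      if (div) divergences_warmup <- divergences_warmup + 1L
      eps <- da_update(accept)
      if (length(windows) && it > init_buf && it <= (n_warmup - term_buf)) {
        wn <- wn + 1
        wbuf[wn, ] <- u
      }
      if (length(windows) && it == windows[1]) {
        if (wn > 4) {
          X <- wbuf[seq_len(wn), , drop = FALSE]
          if (metric == "dense" && wn >= 10) {
            S <- stats::cov(X)
            wgt <- wn / (wn + 5)
            S <- wgt * S + (1 - wgt) * diag(pmax(diag(S), 1e-8))
            S <- S + diag(1e-8, D)
            if (set_dense(S)) inv_diag <- rep(NA_real_, D)
          } else {
            vr <- apply(X, 2, stats::var)
            inv_diag <- (wn / (wn + 5)) * pmax(vr, 1e-10) +
              (5 / (wn + 5)) * 1e-3
            dense_cov <- NULL; dense_mom_L <- NULL
          }
          wn <- 0
          eps <- find_eps(u, cur)
          da_reset(eps)
        }
        windows <- windows[-1]
      }
      if (it == n_warmup) eps <- exp(da_leps_bar)
    } else {
      j <- it - n_warmup
      draws[j, ] <- target$constrain(u)
      stats$accept_stat[j] <- accept
      stats$treedepth[j] <- depth
      stats$divergent[j] <- div
      stats$energy[j] <- -(cur$lp - K0)
      stats$n_leapfrog[j] <- n_leap
    }
  }
  colnames(draws) <- target$flat_names
  list(draws = draws, stats = stats, eps = eps,
       divergences_warmup = divergences_warmup)
}
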