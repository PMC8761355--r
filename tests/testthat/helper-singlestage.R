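# Independent single-stage hierarchical sampler used as an oracle for the
# proposal-recursive method. Deliberately coded from scratch: its own
# density evaluations, random-walk Metropolis updates on transformed scales
# (no stage-1 recycling, no KDE), and its own conjugate group updates.

single_stage_sampler <- function(trajectories, raster, hyper, n_iter,
                                 seed, sd0 = 5) {
  ids <- names(trajectories)
  grp_of <- vapply(trajectories, function(t) t$treatment, character(1))
  groups <- sort(unique(grp_of))
  dat <- lapply(trajectories, function(tr) {
    pos <- tr$positions
    d <- diff(pos)
    n <- nrow(pos)
    t_idx <- 3:n
    gaps <- diff(tr$days)
    ok <- gaps[t_idx - 1L] == 1L & gaps[t_idx - 2L] == 1L
    el <- t_idx[ok]
    cat_idx <- match(feature_at(raster, pos[el - 1L, , drop = FALSE]),
                     landscape_categories())
    list(dc = d[el - 1L, , drop = FALSE], dp = d[el - 2L, , drop = FALSE],
         cat = cat_idx, n = length(el))
  })

  lf0 <- lapply(dat, function(d)
    dnorm(d$dc[, 1], 0, sd0, log = TRUE) +
      dnorm(d$dc[, 2], 0, sd0, log = TRUE))
  lf1_of <- function(d, g, th, s1) {
    mx <- g * (cos(th) * d$dp[, 1] - sin(th) * d$dp[, 2])
    my <- g * (sin(th) * d$dp[, 1] + cos(th) * d$dp[, 2])
    dnorm(d$dc[, 1], mx, s1, log = TRUE) + dnorm(d$dc[, 2], my, s1, log = TRUE)
  }
  move_loglik <- function(d, z, g, th, s1) {
    if (!any(z == 1)) return(0)
    sum(lf1_of(d, g, th, s1)[z == 1])
  }

  set.seed(seed)
  # initial states
  st <- lapply(ids, function(id) {
    d <- dat[[id]]
    len <- sqrt(rowSums(d$dc^2))
    list(z = as.integer(len > 10), beta = rep(0, 4), lg = 0, th = pi,
         ls = log(20))
  })
  names(st) <- ids
  gs <- list()
  for (g in groups)
    gs[[g]] <- list(mu_beta = rep(0, 4), Sigma_beta = diag(4), mu_lg = 0,
                    s2_lg = 1, mu_th = pi, s2_th = 1, mu_ls = log(20),
                    s2_ls = 1)

  out_mu_lg <- matrix(NA_real_, n_iter, length(groups),
                      dimnames = list(NULL, groups))
  step_lg <- 0.4; step_th <- 0.3; step_ls <- 0.2

  for (k in seq_len(n_iter)) {
    for (id in ids) {
      d <- dat[[id]]; s <- st[[id]]; G <- gs[[grp_of[[id]]]]
      gam <- plogis(s$lg); s1 <- exp(s$ls)
      # latent states + probit auxiliaries
      eta <- s$beta[d$cat]
      a <- pnorm(eta, log.p = TRUE) + lf1_of(d, gam, s$th, s1)
      b <- pnorm(-eta, log.p = TRUE) + lf0[[id]]
      pz <- 1 / (1 + exp(b - a))
      s$z <- as.integer(runif(d$n) < pz)
      Fm <- pnorm(-eta)
      u <- runif(d$n)
      qv <- ifelse(s$z == 1, Fm + u * (1 - Fm), u * Fm)
      v <- eta + qnorm(pmin(pmax(qv, 1e-300), 1 - 1e-16))
      # beta given v (conjugate, correlated prior)
      X <- diag(4)[d$cat, , drop = FALSE]
      Sinv <- solve(G$Sigma_beta)
      A <- crossprod(X) + Sinv
      bb <- crossprod(X, v) + Sinv %*% G$mu_beta
      V <- solve(A)
      s$beta <- drop(V %*% bb + t(chol(V)) %*% rnorm(4))
      # gamma on the logit scale (random walk)
      prop <- s$lg + rnorm(1, 0, step_lg)
      lr <- move_loglik(d, s$z, plogis(prop), s$th, s1) -
        move_loglik(d, s$z, gam, s$th, s1) +
        dnorm(prop, G$mu_lg, sqrt(G$s2_lg), log = TRUE) -
        dnorm(s$lg, G$mu_lg, sqrt(G$s2_lg), log = TRUE)
      if (log(runif(1)) < lr) { s$lg <- prop; gam <- plogis(prop) }
      # theta (random walk on the natural scale)
      prop <- s$th + rnorm(1, 0, step_th)
      lr <- move_loglik(d, s$z, gam, prop, s1) -
        move_loglik(d, s$z, gam, s$th, s1) +
        dnorm(prop, G$mu_th, sqrt(G$s2_th), log = TRUE) -
        dnorm(s$th, G$mu_th, sqrt(G$s2_th), log = TRUE)
      if (log(runif(1)) < lr) s$th <- prop
      # log sigma1 (random walk)
      prop <- s$ls + rnorm(1, 0, step_ls)
      lr <- move_loglik(d, s$z, gam, s$th, exp(prop)) -
        move_loglik(d, s$z, gam, s$th, exp(s$ls)) +
        dnorm(prop, G$mu_ls, sqrt(G$s2_ls), log = TRUE) -
        dnorm(s$ls, G$mu_ls, sqrt(G$s2_ls), log = TRUE)
      if (log(runif(1)) < lr) s$ls <- prop
      st[[id]] <- s
    }
    for (g in groups) {
      mem <- st[grp_of == g]
      n <- length(mem)
      G <- gs[[g]]
      B <- t(vapply(mem, function(s) s$beta, numeric(4)))
      lg <- vapply(mem, function(s) s$lg, 0)
      th <- vapply(mem, function(s) s$th, 0)
      ls <- vapply(mem, function(s) s$ls, 0)
      # covariance given previous mean, then mean given covariance
      SS <- crossprod(sweep(B, 2, G$mu_beta))
      W <- rWishart(1, hyper$wishart_nu + n,
                    solve(hyper$wishart_S * hyper$wishart_nu + SS))[, , 1]
      G$Sigma_beta <- solve(W)
      Sinv <- W
      S0inv <- solve(hyper$Sigma_beta_pop)
      V <- solve(n * Sinv + S0inv)
      m <- V %*% (Sinv %*% colSums(B) + S0inv %*% hyper$mu_beta_pop)
      G$mu_beta <- drop(m + t(chol(V)) %*% rnorm(4))
      upd <- function(x, mu_prev, m0, v0, ig) {
        s2 <- 1 / rgamma(1, ig[["q"]] + n / 2,
                         rate = ig[["r"]] + sum((x - mu_prev)^2) / 2)
        vv <- 1 / (n / s2 + 1 / v0)
        mm <- vv * (sum(x) / s2 + m0 / v0)
        c(rnorm(1, mm, sqrt(vv)), s2)
      }
      r <- upd(lg, G$mu_lg, hyper$mu_logit_gamma_pop,
               hyper$var_logit_gamma_pop, hyper$ig_logit_gamma)
      G$mu_lg <- r[1]; G$s2_lg <- r[2]
      r <- upd(th, G$mu_th, hyper$mu_theta_pop, hyper$var_theta_pop,
               hyper$ig_theta)
      G$mu_th <- r[1]; G$s2_th <- r[2]
      r <- upd(ls, G$mu_ls, hyper$mu_log_sigma1_pop,
               hyper$var_log_sigma1_pop, hyper$ig_log_sigma1)
      G$mu_ls <- r[1]; G$s2_ls <- r[2]
      gs[[g]] <- G
    }
    out_mu_lg[k, ] <- vapply(groups, function(g) gs[[g]]$mu_lg, 0)
  }
  out_mu_lg
}
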