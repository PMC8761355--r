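# Stage 2: hierarchical model fit by recycling each individual's stage-1
# draws as Metropolis-Hastings proposals. The proposal density is the
# Gaussian kernel density estimate of the stage-1 pool, the process density
# is the treatment-level normal on the transformed scale (with a change of
# variables correction for gamma and sigma1^2), and treatment-level
# means/variances get conjugate Gibbs updates.

#' Gaussian KDE log-density of a stage-1 proposal pool
#'
#' Exact Gaussian-mixture evaluation: log( (1/n) sum_k phi((x - pool_k)/h) / h )
#' with the normal-reference (Silverman) plug-in bandwidth, floored at 1e-6
#' of the pool range to avoid degeneracy. Computed by log-sum-exp so the
#' result is finite (if astronomically negative) arbitrarily far from the
#' pool.
#'
#' @param pool Numeric vector of stage-1 draws (length >= 2).
#' @param x Evaluation point(s).
#' @param bw Optional bandwidth override.
#' @return Log proposal density at `x`.
#' @export
kde_logpdf <- function(pool, x, bw = NULL) {
  n <- length(pool)
  if (n < 2L) stop("`pool` must contain at least 2 draws")
  if (is.null(bw)) bw <- kde_bandwidth(pool)
  vapply(x, function(xi) {
    t2 <- -0.5 * ((xi - pool) / bw)^2
    m <- max(t2)
    m + log(sum(exp(t2 - m))) - log(n) - log(bw) - 0.5 * log(2 * pi)
  }, 0)
}

# Silverman normal-reference bandwidth with a range-based floor.
kde_bandwidth <- function(pool) {
  rng <- diff(range(pool))
  if (rng == 0)
    stop("degenerate pool (all values identical); cannot form a KDE ",
         "bandwidth -- supply `bw` to impose a floor")
  max(stats::bw.nrd0(pool), 1e-6 * rng)
}

#' Draw a proposal from a stage-1 pool
#'
#' Uniform random selection of one stored stage-1 sample (the
#' proposal-recursive step). Uses the current RNG stream.
#'
#' @param pool Numeric vector of stage-1 draws.
#' @return One element of `pool`.
#' @export
propose_from_stage1 <- function(pool) {
  if (length(pool) == 0L) stop("empty proposal pool")
  pool[sample.int(length(pool), 1L)]
}

#' Individual-level process log-density with change-of-variables correction
#'
#' The hierarchy places normals on transformed scales (logit(gamma), theta,
#' log(sigma1)), while the samplers carry natural-scale values; evaluating
#' the process density at a natural-scale value therefore needs the Jacobian:
#' gamma gets -log(gamma (1 - gamma)), sigma1^2 gets -log(2 sigma1^2) (from
#' d log sigma1 / d sigma1^2), theta needs none. Out-of-support values return
#' -Inf rather than erroring, so Metropolis steps simply reject them.
#'
#' @param param_name One of `"gamma"`, `"theta"`, `"sigma1_sq"`.
#' @param value Natural-scale value.
#' @param treatment A [treatment_params()].
#' @return Log-density (scalar; `-Inf` outside the support).
#' @export
process_log_density <- function(param_name, value, treatment) {
  switch(param_name,
    gamma = {
      if (!is.finite(value) || value <= 0 || value >= 1) return(-Inf)
      stats::dnorm(stats::qlogis(value), treatment$mu_logit_gamma,
                   sqrt(treatment$var_logit_gamma), log = TRUE) -
        log(value * (1 - value))
    },
    theta = {
      if (!is.finite(value)) return(-Inf)
      stats::dnorm(value, treatment$mu_theta, sqrt(treatment$var_theta),
                   log = TRUE)
    },
    sigma1_sq = {
      if (!is.finite(value) || value <= 0) return(-Inf)
      stats::dnorm(log(sqrt(value)), treatment$mu_log_sigma1,
                   sqrt(treatment$var_log_sigma1), log = TRUE) -
        log(2 * value)
    },
    stop("unknown parameter name: ", param_name))
}

#' Conditional log-density of one probit coefficient
#'
#' Under beta ~ N(mu, Sigma), the univariate conditional of component l
#' given the other current-iteration components, via the standard
#' multivariate-normal partition: mean mu_l + Sigma_l,-l Sigma_-l,-l^-1
#' (beta_-l - mu_-l), variance Sigma_ll - Sigma_l,-l Sigma_-l,-l^-1
#' Sigma_-l,l.
#'
#' @param beta Full current coefficient vector (component l at its value of
#'   interest).
#' @param l Component index.
#' @param mu_beta Group mean vector.
#' @param Sigma_beta Group covariance (positive definite).
#' @return Log conditional density (scalar).
#' @export
conditional_beta_logpdf <- function(beta, l, mu_beta, Sigma_beta) {
  cm <- beta_conditional_moments(beta, l, mu_beta, Sigma_beta)
  stats::dnorm(beta[l], cm$mean, sqrt(cm$var), log = TRUE)
}

beta_conditional_moments <- function(beta, l, mu_beta, Sigma_beta) {
  o <- setdiff(seq_along(beta), l)
  Soo <- Sigma_beta[o, o, drop = FALSE]
  Sol <- Sigma_beta[o, l]
  R <- tryCatch(chol(Soo), error = function(e)
    stop("`Sigma_beta` must be positive definite"))
  w <- backsolve(R, backsolve(R, Sol, transpose = TRUE))  # Soo^-1 Sol
  m <- mu_beta[l] + sum(w * (beta[o] - mu_beta[o]))
  v <- Sigma_beta[l, l] - sum(Sol * w)
  if (v <= 0) stop("`Sigma_beta` must be positive definite")
  list(mean = m, var = v)
}

#' Fit the hierarchical model by proposal-recursive MCMC
#'
#' Each iteration: for every individual, one-at-a-time Metropolis updates of
#' gamma, theta and sigma1^2 (acceptance ratio = integrated-likelihood ratio
#' x process-density ratio x reversed KDE proposal ratio) followed by each
#' beta coefficient in turn (likelihood x conditional-normal process ratio x
#' KDE ratio); then conjugate Gibbs updates of every treatment group's means,
#' variances and beta covariance. The individual likelihood integrates over
#' the latent states (two-component mixture), except for encamped-only
#' individuals whose states are pinned to 0. Deterministic given `seed`.
#'
#' @param stage1 Named list of [fit_stage1()] results, one per individual.
#' @param trajectories Named list of [trajectory()] objects (same names).
#' @param raster A [categorical_raster()].
#' @param hyper A [hyper_priors()].
#' @param n_iter Number of iterations (default 50,000).
#' @param seed Integer seed.
#' @param burn_frac Fraction of iterations flagged as burn-in for downstream
#'   summaries (default 0.1).
#' @param constants A [model_constants()].
#' @return An object of class `stage2_fit` with 3-d draw arrays `individual`
#'   (iteration x parameter x individual) and `group` (iteration x parameter
#'   x group), plus burn-in count, acceptance rates and metadata.
#' @export
fit_stage2 <- function(stage1, trajectories, raster, hyper = hyper_priors(),
                       n_iter = 50000L, seed = 1L, burn_frac = 0.1,
                       constants = model_constants()) {
  ids <- names(trajectories)
  missing_fit <- setdiff(ids, names(stage1))
  if (length(missing_fit))
    stop("no stage-1 samples for individual(s): ",
         paste(missing_fit, collapse = ", "))
  stage1 <- stage1[ids]
  cats <- landscape_categories()
  p <- length(cats)
  par_names <- c(paste0("beta.", cats), "gamma", "theta", "sigma1_sq")

  # per-individual data, pools and bandwidths
  dat <- lapply(trajectories, step_data, raster = raster,
                constants = constants)
  pools <- lapply(stage1, function(f) {
    pl <- lapply(par_names, function(pn) f$draws[, pn])
    names(pl) <- par_names
    pl
  })
  bws <- lapply(pools, function(pl) vapply(pl, kde_bandwidth, 0))

  groups <- sort(unique(vapply(trajectories, function(t) t$treatment,
                               character(1))))
  grp_of <- vapply(trajectories, function(t) t$treatment, character(1))
  gp_names <- c(paste0("mu_beta.", cats),
                paste0("Sigma_beta.", rep(seq_len(p), p), ".",
                       rep(seq_len(p), each = p)),
                "mu_logit_gamma", "var_logit_gamma", "mu_theta", "var_theta",
                "mu_log_sigma1", "var_log_sigma1")

  n_ind <- length(ids)
  ind_draws <- array(NA_real_, c(n_iter, length(par_names), n_ind),
                     dimnames = list(NULL, par_names, ids))
  grp_draws <- array(NA_real_, c(n_iter, length(gp_names), length(groups)),
                     dimnames = list(NULL, gp_names, groups))
  acc_counts <- matrix(0, length(par_names), n_ind,
                       dimnames = list(par_names, ids))

  # current individual states initialised at stage-1 posterior means
  cur <- lapply(stage1, function(f) {
    m <- colMeans(f$draws)
    list(beta = unname(m[1:p]),
         gamma = min(max(m["gamma"], 1e-6), 1 - 1e-6),
         theta = m["theta"], s2 = m["sigma1_sq"])
  })
  # empirical group-level start
  gcur <- list()
  for (g in groups) {
    members <- which(grp_of == g)
    B <- t(vapply(cur[members], function(s) s$beta, numeric(p)))
    lg <- vapply(cur[members], function(s) stats::qlogis(s$gamma), 0)
    th <- vapply(cur[members], function(s) s$theta, 0)
    ls <- vapply(cur[members], function(s) log(sqrt(s$s2)), 0)
    svar <- function(x) max(if (length(x) > 1) stats::var(x) else 0, 0.1)
    Sg <- if (length(members) > 1) stats::cov(B) else diag(0, p)
    gcur[[g]] <- list(mu_beta = colMeans(B),
                      Sigma_beta = Sg + diag(0.1, p),
                      mu_lg = mean(lg), s2_lg = svar(lg),
                      mu_th = mean(th), s2_th = svar(th),
                      mu_ls = mean(ls), s2_ls = svar(ls))
  }

  with_seed(seed, {
    # per-individual likelihood caches
    cache <- vector("list", n_ind)
    for (i in seq_len(n_ind)) cache[[i]] <- make_lik_cache(dat[[i]], cur[[i]])
    kde_cur <- lapply(seq_len(n_ind), function(i)
      vapply(par_names, function(pn)
        kde_logpdf(pools[[i]][[pn]], cur_value(cur[[i]], pn),
                   bws[[i]][[pn]]), 0))

    for (k in seq_len(n_iter)) {
      for (i in seq_len(n_ind)) {
        g <- gcur[[grp_of[i]]]
        tp <- treatment_from_state(g)
        st <- cur[[i]]; ch <- cache[[i]]; kc <- kde_cur[[i]]
        enc <- dat[[i]]$encamped_only

        for (pn in c("gamma", "theta", "sigma1_sq")) {
          prop <- propose_from_stage1(pools[[i]][[pn]])
          kde_prop <- kde_logpdf(pools[[i]][[pn]], prop, bws[[i]][[pn]])
          up <- scalar_update_ratio(dat[[i]], st, ch, pn, prop, tp,
                                    kc[[pn]], kde_prop)
          if (is.finite(up$lr) && log(stats::runif(1)) < up$lr) {
            st <- set_value(st, pn, prop)
            kc[[pn]] <- kde_prop
            if (!enc) {
              ch$lf1 <- up$new_lf1
              ch$loglik <- up$new_loglik
            }
            acc_counts[pn, i] <- acc_counts[pn, i] + 1
          }
        }

        for (l in seq_len(p)) {
          pn <- par_names[l]
          prop <- propose_from_stage1(pools[[i]][[pn]])
          kde_prop <- kde_logpdf(pools[[i]][[pn]], prop, bws[[i]][[pn]])
          up <- beta_update_ratio(dat[[i]], st, ch, l, prop, g,
                                  kc[[pn]], kde_prop)
          if (is.finite(up$lr) && log(stats::runif(1)) < up$lr) {
            st$beta <- up$beta_new
            ch$eta <- up$new_eta; ch$lp1 <- up$new_lp1; ch$lp0 <- up$new_lp0
            ch$loglik <- up$new_loglik
            kc[[pn]] <- kde_prop
            acc_counts[pn, i] <- acc_counts[pn, i] + 1
          }
        }

        cur[[i]] <- st; cache[[i]] <- ch; kde_cur[[i]] <- kc
        ind_draws[k, , i] <- c(st$beta, st$gamma, st$theta, st$s2)
      }

      for (g in groups) {
        members <- which(grp_of == g)
        gcur[[g]] <- gibbs_update_treatment(cur[members], hyper,
                                            prev = gcur[[g]])
        gs <- gcur[[g]]
        grp_draws[k, , g] <- c(gs$mu_beta, as.vector(gs$Sigma_beta),
                               gs$mu_lg, gs$s2_lg, gs$mu_th, gs$s2_th,
                               gs$mu_ls, gs$s2_ls)
      }
    }
  })

  structure(list(individual = ind_draws, group = grp_draws,
                 groups = groups, individual_ids = ids,
                 group_of = grp_of,
                 encamped_only = vapply(dat, function(d) d$encamped_only,
                                        logical(1)),
                 n_iter = n_iter, burn = floor(burn_frac * n_iter),
                 seed = seed, hyper = hyper,
                 acceptance = acc_counts / n_iter),
            class = "stage2_fit")
}

#' @export
print.stage2_fit <- function(x, ...) {
  cat(sprintf(paste0("<stage2_fit> %d individuals in %d groups; %d ",
                     "iterations (%d burn-in)\n"),
              length(x$individual_ids), length(x$groups), x$n_iter, x$burn))
  cat("mean acceptance rates by parameter:\n")
  print(round(rowMeans(x$acceptance), 3))
  invisible(x)
}

# --- internal helpers ------------------------------------------------------

cur_value <- function(st, pn) {
  switch(pn, gamma = st$gamma, theta = st$theta, sigma1_sq = st$s2,
         beta.tree = st$beta[1L], beta.pavement = st$beta[2L],
         beta.grass = st$beta[3L], beta.building = st$beta[4L],
         stop("bad name"))
}

set_value <- function(st, pn, v) {
  if (pn == "gamma") st$gamma <- v
  else if (pn == "theta") st$theta <- v
  else st$s2 <- v
  st
}

treatment_from_state <- function(g) {
  list(mu_beta = g$mu_beta, Sigma_beta = g$Sigma_beta,
       mu_logit_gamma = g$mu_lg, var_logit_gamma = g$s2_lg,
       mu_theta = g$mu_th, var_theta = g$s2_th,
       mu_log_sigma1 = g$mu_ls, var_log_sigma1 = g$s2_ls)
}

# likelihood cache for one individual at its current parameters
make_lik_cache <- function(d, st) {
  eta <- st$beta[d$cat]
  lp1 <- stats::pnorm(eta, log.p = TRUE)
  lp0 <- stats::pnorm(-eta, log.p = TRUE)
  lf1 <- bvn_logpdf(d$dcur, movement_mean(d$dprev, st$gamma, st$theta),
                    sqrt(st$s2))
  ll <- if (d$encamped_only) sum(lp0)
        else mix_loglik(lp1, lp0, lf1, d$lf0)
  list(eta = eta, lp1 = lp1, lp0 = lp0, lf1 = lf1, loglik = ll)
}

# log acceptance ratio for one recursive scalar update: integrated
# likelihood ratio x process-density ratio x reversed KDE proposal ratio.
# `ch` is the make_lik_cache() state at the current parameters; `kde_cur`
# the cached KDE log-density at the current value. Encamped-only
# individuals have a likelihood that is flat in gamma/theta/sigma1^2.
scalar_update_ratio <- function(d, st, ch, pn, prop, tp, kde_cur, kde_prop) {
  lr <- process_log_density(pn, prop, tp) -
    process_log_density(pn, cur_value(st, pn), tp) +
    kde_cur - kde_prop
  new_lf1 <- NULL
  new_loglik <- ch$loglik
  if (!d$encamped_only) {
    new_lf1 <- lf1_for(d, st, pn, prop)
    new_loglik <- mix_loglik(ch$lp1, ch$lp0, new_lf1, d$lf0)
    lr <- lr + new_loglik - ch$loglik
  }
  list(lr = lr, new_lf1 = new_lf1, new_loglik = new_loglik)
}

# log acceptance ratio for one beta coefficient: integrated likelihood
# ratio x conditional-normal process ratio (given the other current
# coefficients) x reversed KDE ratio.
beta_update_ratio <- function(d, st, ch, l, prop, g, kde_cur, kde_prop) {
  beta_new <- st$beta
  beta_new[l] <- prop
  lr <- conditional_beta_logpdf(beta_new, l, g$mu_beta, g$Sigma_beta) -
    conditional_beta_logpdf(st$beta, l, g$mu_beta, g$Sigma_beta) +
    kde_cur - kde_prop
  chg <- d$cat == l
  new_eta <- ch$eta
  new_eta[chg] <- prop
  new_lp1 <- ch$lp1; new_lp0 <- ch$lp0
  new_lp1[chg] <- stats::pnorm(new_eta[chg], log.p = TRUE)
  new_lp0[chg] <- stats::pnorm(-new_eta[chg], log.p = TRUE)
  new_loglik <- if (d$encamped_only) sum(new_lp0)
                else mix_loglik(new_lp1, new_lp0, ch$lf1, d$lf0)
  list(lr = lr + new_loglik - ch$loglik, beta_new = beta_new,
       new_eta = new_eta, new_lp1 = new_lp1, new_lp0 = new_lp0,
       new_loglik = new_loglik)
}

# movement-state log-density vector after changing one scalar parameter
lf1_for <- function(d, st, pn, value) {
  g <- if (pn == "gamma") value else st$gamma
  th <- if (pn == "theta") value else st$theta
  s2 <- if (pn == "sigma1_sq") value else st$s2
  bvn_logpdf(d$dcur, movement_mean(d$dprev, g, th), sqrt(s2))
}

# integrated (state-marginalised) log-likelihood:
# sum_t log( p_t f1_t + (1 - p_t) f0_t ), computed in log space
mix_loglik <- function(lp1, lp0, lf1, lf0) {
  if (length(lp1) == 0L) return(0)
  a <- lp1 + lf1
  b <- lp0 + lf0
  m <- pmax(a, b)
  sum(m + log1p(exp(pmin(a, b) - m)))
}

#' Conjugate Gibbs update of one treatment group's parameters
#'
#' Given the group's current individual-level parameters, draws the
#' treatment-level means (normal-normal), variances (inverse-gamma, on the
#' transformed scales) and the coefficient covariance -- inverse-Wishart by
#' default, or independent diagonal inverse-gamma variances when the
#' hyperpriors request `beta_cov_model = "diag"`. Uses the current RNG
#' stream.
#'
#' @param members List of per-individual states, each with elements `beta`,
#'   `gamma`, `theta`, `s2` (natural scales).
#' @param hyper A [hyper_priors()].
#' @param prev Previous iteration's group-level state (same shape as the
#'   return value); the variance updates condition on its means, preserving
#'   the systematic Gibbs scan. When `NULL` (initialisation) the empirical
#'   means of `members` stand in.
#' @return List of updated group-level parameters (`mu_beta`, `Sigma_beta`,
#'   `mu_lg`, `s2_lg`, `mu_th`, `s2_th`, `mu_ls`, `s2_ls`).
#' @export
gibbs_update_treatment <- function(members, hyper = hyper_priors(),
                                   prev = NULL) {
  if (length(members) < 1L) stop("group must contain at least one individual")
  p <- length(members[[1L]]$beta)
  B <- t(vapply(members, function(s) s$beta, numeric(p)))
  n <- nrow(B)

  draw_mu <- function(x, s2, m0, v0) {
    v <- 1 / (n / s2 + 1 / v0)
    stats::rnorm(1, v * (sum(x) / s2 + m0 / v0), sqrt(v))
  }
  draw_s2 <- function(x, mu, q, r)
    1 / stats::rgamma(1, shape = q + n / 2, rate = r + sum((x - mu)^2) / 2)

  lg <- vapply(members, function(s) stats::qlogis(s$gamma), 0)
  th <- vapply(members, function(s) s$theta, 0)
  ls <- vapply(members, function(s) log(sqrt(s$s2)), 0)

  # means conditioned on for the variance draws (Gibbs scan: variances given
  # last iteration's means, then means given the new variances)
  mu_beta_c <- if (is.null(prev)) colMeans(B) else prev$mu_beta
  mu_lg_c <- if (is.null(prev)) mean(lg) else prev$mu_lg
  mu_th_c <- if (is.null(prev)) mean(th) else prev$mu_th
  mu_ls_c <- if (is.null(prev)) mean(ls) else prev$mu_ls

  mu0 <- hyper$mu_beta_pop
  Sig0inv <- chol2inv(chol(hyper$Sigma_beta_pop))
  if (hyper$beta_cov_model == "wishart") {
    SS <- crossprod(sweep(B, 2L, mu_beta_c))
    scale_post <- hyper$wishart_S * hyper$wishart_nu + SS
    W <- stats::rWishart(1L, df = hyper$wishart_nu + n,
                         Sigma = chol2inv(chol(scale_post)))[, , 1L]
    Sigma <- chol2inv(chol(W))
  } else {
    q <- hyper$ig_beta["q"]; r <- hyper$ig_beta["r"]
    vars <- vapply(seq_len(p), function(l)
      1 / stats::rgamma(1, shape = q + n / 2,
                        rate = r + sum((B[, l] - mu_beta_c[l])^2) / 2), 0)
    Sigma <- diag(vars, p)
  }
  Sinv <- chol2inv(chol(Sigma))
  V <- chol2inv(chol(n * Sinv + Sig0inv))
  mvec <- V %*% (Sinv %*% colSums(B) + Sig0inv %*% mu0)
  Rv <- chol(V)
  mu_beta <- drop(mvec) + drop(crossprod(Rv, stats::rnorm(p)))

  s2_lg <- draw_s2(lg, mu_lg_c, hyper$ig_logit_gamma["q"],
                   hyper$ig_logit_gamma["r"])
  mu_lg <- draw_mu(lg, s2_lg, hyper$mu_logit_gamma_pop,
                   hyper$var_logit_gamma_pop)
  s2_th <- draw_s2(th, mu_th_c, hyper$ig_theta["q"], hyper$ig_theta["r"])
  mu_th <- draw_mu(th, s2_th, hyper$mu_theta_pop, hyper$var_theta_pop)
  s2_ls <- draw_s2(ls, mu_ls_c, hyper$ig_log_sigma1["q"],
                   hyper$ig_log_sigma1["r"])
  mu_ls <- draw_mu(ls, s2_ls, hyper$mu_log_sigma1_pop,
                   hyper$var_log_sigma1_pop)

  list(mu_beta = mu_beta, Sigma_beta = Sigma,
       mu_lg = mu_lg, s2_lg = s2_lg, mu_th = mu_th, s2_th = s2_th,
       mu_ls = mu_ls, s2_ls = s2_ls)
}
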