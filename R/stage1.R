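# Stage 1: independent per-individual samplers. Probit data augmentation
# makes the coefficient update conjugate (Albert-Chib); gamma and theta use
# their priors as Metropolis-Hastings proposals (no tuning needed) and
# sigma1^2 has a conjugate inverse-gamma Gibbs update.

#' Is a trajectory encamped-only?
#'
#' A trajectory with no displacement longer than the encamped threshold
#' (default 10 m) cannot separate the two behavioural states: the movement
#' variance would collapse below sigma0^2. Such individuals have every step
#' forced into the encamped state so all remaining parameters stay
#' identifiable.
#'
#' @param series A [displacement_series()].
#' @param constants A [model_constants()].
#' @return Logical flag.
#' @export
detect_encamped_only <- function(series, constants = model_constants()) {
  if (!inherits(series, "displacement_series"))
    stop("`series` must be a displacement_series")
  len <- sqrt(rowSums(series$deltas^2))
  all(len <= constants$encamped_threshold)
}

# Precompute per-individual step arrays used by both fitting stages:
# current/previous displacements, landscape category (integer code) at each
# step's starting position, for the likelihood-eligible steps only.
step_data <- function(traj, raster, constants = model_constants()) {
  series <- displacement_series(traj)
  el <- series$eligible
  n <- length(el)
  if (n > 0L) {
    dcur <- series$deltas[el - 1L, , drop = FALSE]
    dprev <- series$deltas[el - 2L, , drop = FALSE]
    cat_idx <- match(feature_at(raster, traj$positions[el - 1L, , drop = FALSE]),
                     landscape_categories())
  } else {
    dcur <- dprev <- matrix(numeric(0), 0L, 2L)
    cat_idx <- integer(0)
  }
  list(individual_id = traj$individual_id, treatment = traj$treatment,
       series = series, dcur = dcur, dprev = dprev, cat = cat_idx, n = n,
       encamped_only = detect_encamped_only(series, constants),
       lf0 = if (n > 0L) bvn_logpdf(dcur, matrix(0, n, 2L), constants$sigma0)
             else numeric(0))
}

#' Draw the latent states and probit auxiliaries
#'
#' Full-conditional update: z_t is Bernoulli with probability
#' p_t f1(delta_t) / (p_t f1 + (1 - p_t) f0), where f1/f0 are the movement
#' and encamped displacement densities and p_t = Phi(x_t' beta); v_t is
#' truncated normal(x_t' beta, 1), positive iff z_t = 1. Uses the current R
#' RNG stream.
#'
#' @param series A [displacement_series()].
#' @param design One-hot design matrix, one row per eligible step.
#' @param params An [individual_params()].
#' @param constants A [model_constants()].
#' @return List with `z` (integer), `v` (numeric) and `prob` (the analytic
#'   full-conditional movement probabilities).
#' @export
update_latent_states <- function(series, design, params,
                                 constants = model_constants()) {
  el <- series$eligible
  n <- length(el)
  dcur <- series$deltas[el - 1L, , drop = FALSE]
  dprev <- series$deltas[el - 2L, , drop = FALSE]
  cat_idx <- max.col(design)
  lf0 <- bvn_logpdf(dcur, matrix(0, n, 2L), constants$sigma0)
  st <- draw_states(dcur, dprev, cat_idx, lf0, params$beta, params$gamma,
                    params$theta, params$sigma1_sq)
  st
}

# Vectorised core of the latent-state update.
draw_states <- function(dcur, dprev, cat_idx, lf0, beta, gamma, theta,
                        sigma1_sq) {
  n <- length(cat_idx)
  eta <- beta[cat_idx]
  mu1 <- movement_mean(dprev, gamma, theta)
  lf1 <- bvn_logpdf(dcur, mu1, sqrt(sigma1_sq))
  la <- stats::pnorm(eta, log.p = TRUE) + lf1
  lb <- stats::pnorm(-eta, log.p = TRUE) + lf0
  prob <- stats::plogis(la - lb)
  z <- as.integer(stats::runif(n) < prob)
  v <- draw_probit_aux(eta, z)
  list(z = z, v = v, prob = prob)
}

# Truncated-normal draw for the probit auxiliary: v ~ N(eta, 1) truncated to
# (0, Inf) if z = 1 and (-Inf, 0] otherwise.
draw_probit_aux <- function(eta, z) {
  n <- length(eta)
  Fm <- stats::pnorm(-eta)          # P(v <= 0)
  u <- stats::runif(n)
  q <- ifelse(z == 1L, Fm + u * (1 - Fm), u * Fm)
  q <- pmin(pmax(q, 1e-300), 1 - 1e-16)
  eta + stats::qnorm(q)
}

#' Conjugate Gibbs draw for the probit coefficients
#'
#' Normal-linear update of Albert--Chib type: with auxiliaries v ~ N(X beta,
#' I) and prior beta ~ N(mu_beta, var_beta I), the full conditional is
#' N(A^-1 b, A^-1) with A = X'X + I/var_beta and b = X'v + mu_beta/var_beta.
#' With no data rows the draw comes from the prior. Uses the current RNG
#' stream.
#'
#' @param v Auxiliary values (length n).
#' @param design n x p design matrix.
#' @param mu_beta Prior mean (length p).
#' @param var_beta Prior variance (spherical).
#' @return List with the `draw` and the conditional `mean` and `cov`.
#' @export
update_beta_gibbs <- function(v, design, mu_beta = rep(0, 4), var_beta = 1) {
  p <- length(mu_beta)
  if (length(v) > 0 && nrow(design) != length(v))
    stop("`v` must align with the design rows")
  A <- diag(1 / var_beta, p)
  b <- mu_beta / var_beta
  if (length(v) > 0) {
    A <- A + crossprod(design)
    b <- b + drop(crossprod(design, v))
  }
  R <- chol(A)
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  draw <- m + backsolve(R, stats::rnorm(p))
  list(draw = draw, mean = m, cov = chol2inv(R))
}

#' Conjugate Gibbs draw for the movement-state variance
#'
#' With movement-state residuals r_t = delta_t - gamma M(theta) delta_(t-1)
#' and prior sigma1^2 ~ IG(q1, r1) (shape--scale), the full conditional is
#' IG(q1 + m/2, r1 + SSR/2) where m counts scalar residual components (two
#' per movement step) and SSR is their sum of squares. Uses the current RNG
#' stream.
#'
#' @param residuals Numeric matrix (movement steps x 2) or vector of scalar
#'   residual components; may be empty (prior draw).
#' @param q1,r1 Prior shape and scale.
#' @return List with the `draw` and posterior `shape`/`scale`.
#' @export
update_sigma1_gibbs <- function(residuals, q1 = 1, r1 = 0.1) {
  ssr <- sum(residuals^2)
  m <- length(residuals)
  shape <- q1 + m / 2
  scale <- r1 + ssr / 2
  list(draw = 1 / stats::rgamma(1, shape = shape, rate = scale),
       shape = shape, scale = scale)
}

#' Prior-as-proposal Metropolis updates for gamma and theta
#'
#' Proposes gamma* from its Beta prior and theta* from its wrapped-Cauchy
#' prior; because proposal and prior cancel, the acceptance probability is
#' min(1, likelihood ratio) over the movement-state steps only (encamped
#' terms do not involve gamma or theta). Parameters are updated one at a
#' time, gamma first. Uses the current RNG stream.
#'
#' @param gamma,theta Current values.
#' @param dcur,dprev Displacement matrices restricted to eligible steps.
#' @param movement Logical vector marking movement-state steps.
#' @param sigma1_sq Current movement variance.
#' @param priors A [stage1_priors()].
#' @return List with updated `gamma`, `theta` and acceptance flags.
#' @export
update_gamma_theta_mh <- function(gamma, theta, dcur, dprev, movement,
                                  sigma1_sq, priors = stage1_priors()) {
  s1 <- sqrt(sigma1_sq)
  dc <- dcur[movement, , drop = FALSE]
  dp <- dprev[movement, , drop = FALSE]
  loglik <- function(g, th) {
    if (nrow(dc) == 0L) return(0)
    sum(bvn_logpdf(dc, movement_mean(dp, g, th), s1))
  }
  ll_cur <- loglik(gamma, theta)
  g_star <- stats::rbeta(1, priors$gamma_a, priors$gamma_b)
  acc_g <- log(stats::runif(1)) < loglik(g_star, theta) - ll_cur
  if (acc_g) {
    gamma <- g_star
    ll_cur <- loglik(gamma, theta)
  }
  t_star <- rwrappedcauchy(1, priors$theta_mu, priors$theta_rho)
  acc_t <- log(stats::runif(1)) < loglik(gamma, t_star) - ll_cur
  if (acc_t) theta <- t_star
  list(gamma = gamma, theta = theta, accept_gamma = acc_g,
       accept_theta = acc_t)
}

#' Fit the first-stage model to one individual
#'
#' Systematic-scan MCMC cycling (z, v) -> beta -> gamma -> theta -> sigma1^2
#' each iteration. Encamped-only trajectories (see [detect_encamped_only()])
#' have z fixed at 0 throughout; beta is still updated from the (all
#' negative) auxiliaries while gamma, theta and sigma1^2 sample their priors.
#' All iterations are stored; burn-in and thinning are deferred to
#' second-stage use. Deterministic given `seed`.
#'
#' @param traj A [trajectory()].
#' @param raster A [categorical_raster()] supplying the covariate at each
#'   step's starting position.
#' @param priors A [stage1_priors()].
#' @param n_iter Number of iterations (default 100,000).
#' @param seed Integer seed.
#' @param constants A [model_constants()].
#' @param store_states Keep the full latent-state draw matrix? (Off by
#'   default: it is n_iter x steps and only the per-step posterior state
#'   probabilities, always stored, are needed downstream.)
#' @return An object of class `stage1_fit`: `draws` is an n_iter x 7 matrix
#'   (columns beta.tree, beta.pavement, beta.grass, beta.building, gamma,
#'   theta, sigma1_sq), plus state probabilities, acceptance rates and the
#'   encamped-only flag.
#' @export
fit_stage1 <- function(traj, raster, priors = stage1_priors(),
                       n_iter = 100000L, seed = 1L,
                       constants = model_constants(),
                       store_states = FALSE) {
  if (n_iter < 1L) stop("`n_iter` must be at least 1")
  if (length(traj$days) < 3L) stop("trajectory has fewer than 3 relocations")
  sd_ <- step_data(traj, raster, constants)
  n <- sd_$n
  enc <- sd_$encamped_only

  draws <- matrix(NA_real_, n_iter, 7L)
  colnames(draws) <- c(paste0("beta.", landscape_categories()),
                       "gamma", "theta", "sigma1_sq")
  z_draws <- if (store_states) matrix(0L, n_iter, n) else NULL
  z_sum <- numeric(n)
  acc <- c(gamma = 0, theta = 0)

  with_seed(seed, {
    state <- stage1_init(sd_, constants)
    for (k in seq_len(n_iter)) {
      state <- stage1_sweep(sd_, state, priors, constants)
      acc <- acc + c(state$accept_gamma, state$accept_theta)
      draws[k, ] <- c(state$beta, state$gamma, state$theta, state$sigma1_sq)
      if (store_states) z_draws[k, ] <- state$z
      z_sum <- z_sum + state$z
    }
  })
  structure(list(individual_id = traj$individual_id,
                 treatment = traj$treatment,
                 draws = draws, z_draws = z_draws,
                 state_prob = if (n > 0L) z_sum / n_iter else numeric(0),
                 encamped_only = enc, n_iter = n_iter, seed = seed,
                 n_steps = n, acceptance = acc / n_iter,
                 priors = priors),
            class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("<stage1_fit> %s [%s]: %d iterations, %d eligible steps%s\n",
              x$individual_id, x$treatment, x$n_iter, x$n_steps,
              if (x$encamped_only) " (encamped-only)" else ""))
  cat("posterior means:\n")
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

# --- single-iteration kernel ----------------------------------------------

# moment-matching initial state: states from the step-length threshold,
# beta = 0, gamma = 0.5, theta = pi, sigma1^2 from the large steps' spread
# (floored at 2 sigma0^2)
stage1_init <- function(d, constants = model_constants()) {
  len <- sqrt(rowSums(d$dcur^2))
  big <- len > constants$encamped_threshold
  list(z = if (d$encamped_only) integer(d$n) else as.integer(big),
       beta = rep(0, 4L), gamma = 0.5, theta = pi,
       sigma1_sq = max(2 * constants$sigma0^2,
                       if (any(big)) stats::var(as.vector(d$dcur[big, ]))
                       else 0),
       accept_gamma = FALSE, accept_theta = FALSE)
}

# one systematic scan of the stage-1 sampler: (z, v) -> beta -> gamma ->
# theta -> sigma1^2. `d` is a step_data() list, `state` the current state.
# Uses the current RNG stream.
stage1_sweep <- function(d, state, priors = stage1_priors(),
                         constants = model_constants()) {
  n <- d$n
  enc <- d$encamped_only
  counts <- tabulate(d$cat, 4L)
  varb <- priors$var_beta; mub <- priors$mu_beta
  z <- state$z
  eta <- state$beta[d$cat]
  if (!enc && n > 0L) {
    mu1 <- movement_mean(d$dprev, state$gamma, state$theta)
    lf1 <- bvn_logpdf(d$dcur, mu1, sqrt(state$sigma1_sq))
    la <- stats::pnorm(eta, log.p = TRUE) + lf1
    lb <- stats::pnorm(-eta, log.p = TRUE) + d$lf0
    z <- as.integer(stats::runif(n) < stats::plogis(la - lb))
  }
  v <- draw_probit_aux(eta, z)
  # one-hot design: the posterior precision of beta is diagonal
  prec <- counts + 1 / varb
  vsum <- unname(vapply(1:4, function(cc) sum(v[d$cat == cc]), 0))
  beta <- stats::rnorm(4L, (vsum + mub / varb) / prec, sqrt(1 / prec))
  if (!enc) {
    mv <- z == 1L
    up <- update_gamma_theta_mh(state$gamma, state$theta, d$dcur, d$dprev,
                                mv, state$sigma1_sq, priors)
    gamma <- up$gamma; theta <- up$theta
    acc_g <- up$accept_gamma; acc_t <- up$accept_theta
    res <- d$dcur[mv, , drop = FALSE] -
      movement_mean(d$dprev[mv, , drop = FALSE], gamma, theta)
    sigma1_sq <- update_sigma1_gibbs(res, priors$sigma1_q,
                                     priors$sigma1_r)$draw
  } else {
    gamma <- stats::rbeta(1, priors$gamma_a, priors$gamma_b)
    theta <- rwrappedcauchy(1, priors$theta_mu, priors$theta_rho)
    sigma1_sq <- update_sigma1_gibbs(numeric(0), priors$sigma1_q,
                                     priors$sigma1_r)$draw
    acc_g <- acc_t <- TRUE
  }
  list(z = z, v = v, beta = beta, gamma = gamma, theta = theta,
       sigma1_sq = sigma1_sq, accept_gamma = acc_g, accept_theta = acc_t)
}
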