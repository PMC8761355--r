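test_that("KDE log-density is an exact Gaussian mixture", {
  pool <- c(-1.5, 1.5)
  bw <- 0.4
  # symmetric pool gives a symmetric density
  for (x in c(0.3, 1.1, 2.7))
    expect_equal(kde_logpdf(pool, x, bw), kde_logpdf(pool, -x, bw),
                 tolerance = 1e-12)
  # matches a directly coded mixture formula
  set.seed(2)
  pool2 <- rnorm(200, 3, 2)
  bw2 <- statewalk:::kde_bandwidth(pool2)
  xs <- runif(100, -5, 12)
  direct <- sapply(xs, function(x)
    log(mean(dnorm(x, mean = pool2, sd = bw2))))
  expect_equal(kde_logpdf(pool2, xs), direct, tolerance = 1e-10)
  # integrates to one by quadrature
  grid <- seq(min(pool2) - 10 * bw2, max(pool2) + 10 * bw2,
              length.out = 4001)
  mass <- sum(exp(kde_logpdf(pool2, grid))) * diff(grid[1:2])
  expect_lt(abs(mass - 1), 1e-3)
  expect_error(kde_logpdf(rep(2, 50), 1), "degenerate")
  expect_error(kde_logpdf(numeric(1), 1), "at least 2")
})

test_that("stage-1 proposals are uniform draws from the pool", {
  pool <- c(0.2, 0.5, 0.9)
  set.seed(3)
  draws <- replicate(30000, propose_from_stage1(pool))
  expect_true(all(draws %in% pool))
  tab <- table(factor(draws, levels = pool))
  expect_gt(chisq.test(tab)$p.value, 0.001)
  set.seed(11); a <- replicate(50, propose_from_stage1(pool))
  set.seed(11); b <- replicate(50, propose_from_stage1(pool))
  expect_identical(a, b)
  expect_error(propose_from_stage1(numeric(0)), "empty")
})

test_that("process density applies the change-of-variables correction", {
  tp <- treatment_params(rep(0, 4), diag(4), mu_logit_gamma = 0,
                         var_logit_gamma = 1, mu_theta = pi,
                         var_theta = 1.3, mu_log_sigma1 = log(20),
                         var_log_sigma1 = 0.5)
  # logit'(1/2) = 4, so the Jacobian adds log 4
  expect_equal(process_log_density("gamma", 0.5, tp),
               dnorm(0, 0, 1, log = TRUE) + log(4), tolerance = 1e-12)
  # integrates to one over (0,1)
  mass <- integrate(function(g)
    exp(sapply(g, process_log_density, param_name = "gamma",
               treatment = tp)), 0, 1, rel.tol = 1e-9)$value
  expect_lt(abs(mass - 1), 1e-4)
  # theta is a plain normal
  expect_equal(process_log_density("theta", 2.2, tp),
               dnorm(2.2, pi, sqrt(1.3), log = TRUE))
  # sigma1^2 density integrates to one on (0, Inf)
  mass2 <- integrate(function(v)
    exp(sapply(v, process_log_density, param_name = "sigma1_sq",
               treatment = tp)), 0, Inf, rel.tol = 1e-9)$value
  expect_lt(abs(mass2 - 1), 1e-4)
  # out-of-support values reject rather than error
  expect_identical(process_log_density("gamma", 1.2, tp), -Inf)
  expect_identical(process_log_density("sigma1_sq", -3, tp), -Inf)
})

test_that("conditional beta density matches the multivariate normal partition", {
  mu <- c(0.5, -0.2, 0.1, 0.8)
  # diagonal covariance: conditional equals marginal
  Sd <- diag(c(1, 2, 0.5, 1.5))
  b <- c(0.3, 0.4, -0.1, 0.2)
  expect_equal(conditional_beta_logpdf(b, 2, mu, Sd),
               dnorm(b[2], mu[2], sqrt(2), log = TRUE), tolerance = 1e-12)
  # bivariate correlation case against the joint/marginal ratio
  rho <- 0.6; s1 <- 0.7; s2 <- 1.3
  S2 <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
  bb <- c(0.9, -0.4); mu2 <- c(0.1, 0.3)
  got <- conditional_beta_logpdf(bb, 1, mu2, S2)
  cm <- mu2[1] + rho * (s1 / s2) * (bb[2] - mu2[2])
  cv <- s1^2 * (1 - rho^2)
  expect_equal(got, dnorm(bb[1], cm, sqrt(cv), log = TRUE),
               tolerance = 1e-12)
  # and against joint minus marginal computed directly
  ld_joint <- -log(2 * pi) - 0.5 * log(det(S2)) -
    0.5 * drop(t(bb - mu2) %*% solve(S2) %*% (bb - mu2))
  ld_marg <- dnorm(bb[2], mu2[2], s2, log = TRUE)
  expect_equal(got, ld_joint - ld_marg, tolerance = 1e-12)
  # conditional variance never exceeds the marginal
  set.seed(8)
  for (k in 1:10) {
    A <- matrix(rnorm(16), 4)
    S <- crossprod(A) + diag(0.1, 4)
    for (l in 1:4)
      expect_lte(statewalk:::beta_conditional_moments(b, l, mu, S)$var,
                 S[l, l] + 1e-12)
  }
  expect_error(conditional_beta_logpdf(b, 1, mu, matrix(0, 4, 4)),
               "positive definite")
})

test_that("recursive MH acceptance ratios recompose from their factors", {
  # tiny individual: T = 5 relocations -> 3 likelihood-eligible data factors
  s <- sim_individual(T_steps = 5, seed = 9)
  d <- statewalk:::step_data(s$traj, s$raster)
  expect_equal(d$n, 3L)
  st <- list(beta = c(0.2, -0.1, 0.3, 0), gamma = 0.55, theta = 3,
             s2 = 500)
  ch <- statewalk:::make_lik_cache(d, st)
  tp <- default_truth()$resident
  g <- list(mu_beta = tp$mu_beta, Sigma_beta = tp$Sigma_beta)

  pool <- rbeta(300, 2, 2)
  bw <- statewalk:::kde_bandwidth(pool)
  prop <- 0.7
  kde_cur <- kde_logpdf(pool, st$gamma, bw)
  kde_prop <- kde_logpdf(pool, prop, bw)
  up <- statewalk:::scalar_update_ratio(d, st, ch, "gamma", prop, tp,
                                        kde_cur, kde_prop)
  # independent recomputation of the three factors
  loglik <- function(gam) {
    tot <- 0
    for (k in 1:d$n) {
      p <- pnorm(st$beta[d$cat[k]])
      f1 <- exp(sum(dnorm(d$dcur[k, ],
                          gam * propagation_matrix(st$theta) %*% d$dprev[k, ],
                          sqrt(st$s2), log = TRUE)))
      f0 <- exp(sum(dnorm(d$dcur[k, ], 0, 5, log = TRUE)))
      tot <- tot + log(p * f1 + (1 - p) * f0)
    }
    tot
  }
  oracle <- (loglik(prop) - loglik(st$gamma)) +
    (process_log_density("gamma", prop, tp) -
       process_log_density("gamma", st$gamma, tp)) +
    (kde_cur - kde_prop)
  expect_equal(up$lr, oracle, tolerance = 1e-10)

  # identical proposal always accepted (ratio exactly 1)
  up0 <- statewalk:::scalar_update_ratio(d, st, ch, "gamma", st$gamma, tp,
                                         kde_cur, kde_cur)
  expect_equal(up0$lr, 0, tolerance = 1e-12)

  # beta coefficient ratio against brute force
  bpool <- rnorm(300, 0, 1)
  bbw <- statewalk:::kde_bandwidth(bpool)
  bprop <- 0.9
  kc <- kde_logpdf(bpool, st$beta[1], bbw)
  kp <- kde_logpdf(bpool, bprop, bbw)
  upb <- statewalk:::beta_update_ratio(d, st, ch, 1L, bprop, g, kc, kp)
  loglik_b <- function(beta) {
    tot <- 0
    for (k in 1:d$n) {
      p <- pnorm(beta[d$cat[k]])
      f1 <- exp(sum(dnorm(d$dcur[k, ],
                          st$gamma * propagation_matrix(st$theta) %*%
                            d$dprev[k, ], sqrt(st$s2), log = TRUE)))
      f0 <- exp(sum(dnorm(d$dcur[k, ], 0, 5, log = TRUE)))
      tot <- tot + log(p * f1 + (1 - p) * f0)
    }
    tot
  }
  bnew <- st$beta; bnew[1] <- bprop
  oracle_b <- (loglik_b(bnew) - loglik_b(st$beta)) +
    (conditional_beta_logpdf(bnew, 1, g$mu_beta, g$Sigma_beta) -
       conditional_beta_logpdf(st$beta, 1, g$mu_beta, g$Sigma_beta)) +
    (kc - kp)
  expect_equal(upb$lr, oracle_b, tolerance = 1e-10)
})

test_that("a flat likelihood and flat proposal reduce the gamma ratio to the process ratio", {
  # encamped-only individual: likelihood flat in gamma; feed equal KDE terms
  set.seed(21)
  lens <- runif(12, 0, 6); ang <- cumsum(runif(12, 0, 2))
  tr <- toy_trajectory(cbind(lens * cos(ang), lens * sin(ang)),
                       start = c(150, 150))
  r <- uniform_raster("grass", 60, 5)
  d <- statewalk:::step_data(tr, r)
  expect_true(d$encamped_only)
  st <- list(beta = rep(0, 4), gamma = 0.4, theta = pi, s2 = 300)
  ch <- statewalk:::make_lik_cache(d, st)
  tp <- default_truth()$resident
  up <- statewalk:::scalar_update_ratio(d, st, ch, "gamma", 0.8, tp, 0, 0)
  expect_equal(up$lr,
               process_log_density("gamma", 0.8, tp) -
                 process_log_density("gamma", 0.4, tp), tolerance = 1e-12)
})

test_that("treatment-level Gibbs updates match the conjugate closed forms", {
  hyper <- hyper_priors()
  members <- list(list(beta = c(0.4, -0.3, 0.2, 0.1), gamma = 0.62,
                       theta = 3.0, s2 = 600),
                  list(beta = c(0.1, 0.2, -0.2, 0), gamma = 0.55,
                       theta = 3.3, s2 = 450),
                  list(beta = c(0.3, 0, 0.1, -0.1), gamma = 0.70,
                       theta = 2.9, s2 = 700))
  prev <- list(mu_beta = rep(0.2, 4), Sigma_beta = diag(0.2, 4),
               mu_lg = 0.4, s2_lg = 0.3, mu_th = 3, s2_th = 0.2,
               mu_ls = log(25), s2_ls = 0.1)
  set.seed(31)
  reps <- replicate(6000, gibbs_update_treatment(members, hyper, prev),
                    simplify = FALSE)
  lg <- vapply(members, function(m) qlogis(m$gamma), 0)
  n <- 3
  # scalar normal-normal closed form, averaging over the drawn variances
  s2_draws <- vapply(reps, function(r) r$s2_lg, 0)
  mu_draws <- vapply(reps, function(r) r$mu_lg, 0)
  vpost <- 1 / (n / s2_draws + 1 / hyper$var_logit_gamma_pop)
  mpost <- vpost * (sum(lg) / s2_draws +
                      hyper$mu_logit_gamma_pop / hyper$var_logit_gamma_pop)
  expect_lt(abs(mean(mu_draws) - mean(mpost)),
            4 * sd(mu_draws) / sqrt(length(mu_draws)) + 1e-3)
  # variance draw: IG(q + n/2, r + SS/2) with SS about prev$mu_lg
  ss <- sum((lg - prev$mu_lg)^2)
  q <- hyper$ig_logit_gamma["q"] + n / 2
  r <- hyper$ig_logit_gamma["r"] + ss / 2
  med_theory <- unname(r / qgamma(0.5, shape = q))
  expect_lt(abs(median(s2_draws) - med_theory) / med_theory, 0.1)
  # every covariance draw positive definite
  pd <- vapply(reps[1:500], function(rr)
    all(eigen(rr$Sigma_beta, symmetric = TRUE,
              only.values = TRUE)$values > 0), logical(1))
  expect_true(all(pd))
})

test_that("with one individual and a near-flat prior the group mean tracks it", {
  hyper <- hyper_priors(var_logit_gamma_pop = 1e6)
  m <- list(list(beta = rep(0, 4), gamma = 0.62, theta = pi, s2 = 600))
  prev <- list(mu_beta = rep(0, 4), Sigma_beta = diag(4),
               mu_lg = qlogis(0.62), s2_lg = 0.2, mu_th = pi, s2_th = 0.2,
               mu_ls = log(25), s2_ls = 0.1)
  set.seed(7)
  mu <- replicate(10000, gibbs_update_treatment(m, hyper, prev)$mu_lg)
  expect_lt(abs(mean(mu) - qlogis(0.62)), 0.05)
})

test_that("the diagonal beta-covariance variant stays diagonal", {
  hyper <- hyper_priors(beta_cov_model = "diag")
  members <- list(list(beta = c(0.4, -0.3, 0.2, 0.1), gamma = 0.6,
                       theta = 3, s2 = 500),
                  list(beta = c(0.2, 0.1, -0.1, 0), gamma = 0.5,
                       theta = 3, s2 = 400))
  set.seed(5)
  up <- gibbs_update_treatment(members, hyper)
  offdiag <- up$Sigma_beta[upper.tri(up$Sigma_beta)]
  expect_true(all(offdiag == 0))
  expect_true(all(diag(up$Sigma_beta) > 0))
})

test_that("the hierarchical sampler runs deterministically with sound acceptance", {
  r <- tiny_raster(80, 5, seed = 2)
  cfg <- study_config(n_individuals = c(3, 3), length_range = c(25, 40),
                      truth = default_truth()[c("resident",
                                                "forest_to_urban")],
                      raster = r, seed = 101)
  study <- simulate_study(cfg)
  s1 <- lapply(study$trajectories, function(tr)
    fit_stage1(tr, r, n_iter = 800, seed = derive_seed(5, tr$individual_id)))
  f2a <- fit_stage2(s1, study$trajectories, r, n_iter = 400, seed = 9)
  f2b <- fit_stage2(s1, study$trajectories, r, n_iter = 400, seed = 9)
  expect_identical(f2a$individual, f2b$individual)
  expect_identical(f2a$group, f2b$group)
  # acceptance rates strictly inside (0,1) on a nondegenerate problem
  expect_true(all(f2a$acceptance > 0 & f2a$acceptance < 1))
  # burn-in convention
  expect_equal(f2a$burn, 40)
  # missing stage-1 fit errors with the individual named
  expect_error(fit_stage2(s1[-1], study$trajectories, r, n_iter = 10,
                          seed = 1),
               names(study$trajectories)[1])
})

test_that("with a flat likelihood the recursive kernel samples the process distribution", {
  # an encamped-only individual's likelihood is flat in gamma, so its
  # stage-2 chain (at fixed treatment parameters) must be stationary for
  # the group's process distribution: logit(gamma) ~ N(mu, s2)
  set.seed(71)
  ang <- cumsum(runif(25, 0, 2 * pi)); lens <- runif(25, 0, 8)
  tr <- toy_trajectory(cbind(lens * cos(ang), lens * sin(ang)),
                       start = c(500, 500), id = "enc")
  r <- uniform_raster("grass", 100, 10)
  d <- statewalk:::step_data(tr, r)
  expect_true(d$encamped_only)
  s1 <- fit_stage1(tr, r, n_iter = 4000, seed = 9)
  pool <- s1$draws[, "gamma"]
  bw <- statewalk:::kde_bandwidth(pool)
  tp <- list(mu_logit_gamma = 0.3, var_logit_gamma = 0.4)

  st <- list(beta = rep(0, 4), gamma = 0.5, theta = pi, s2 = 100)
  ch <- statewalk:::make_lik_cache(d, st)
  n_iter <- 20000
  out <- numeric(n_iter)
  kde_cur <- kde_logpdf(pool, st$gamma, bw)
  set.seed(13)
  for (k in seq_len(n_iter)) {
    prop <- propose_from_stage1(pool)
    kde_prop <- kde_logpdf(pool, prop, bw)
    up <- statewalk:::scalar_update_ratio(d, st, ch, "gamma", prop, tp,
                                          kde_cur, kde_prop)
    if (is.finite(up$lr) && log(runif(1)) < up$lr) {
      st$gamma <- prop
      kde_cur <- kde_prop
    }
    out[k] <- st$gamma
  }
  lg <- qlogis(out[2001:n_iter])
  expect_lt(abs(mean(lg) - 0.3), 0.06)
  expect_lt(abs(sd(lg) - sqrt(0.4)) / sqrt(0.4), 0.06)
})
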