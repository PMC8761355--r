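test_that("encamped-only detection uses the 10 m threshold inclusively", {
  mk <- function(lens) {
    ang <- seq_along(lens) * 0.7
    toy_trajectory(cbind(lens * cos(ang), lens * sin(ang)))
  }
  expect_true(detect_encamped_only(displacement_series(mk(c(3, 9.9, 7, 2)))))
  expect_false(detect_encamped_only(displacement_series(mk(c(3, 10.5, 7)))))
  # exactly 10.0 m everywhere still counts as encamped (<= convention)
  ten <- toy_trajectory(matrix(c(6, 8, -6, 8, 8, -6), ncol = 2, byrow = TRUE))
  expect_true(detect_encamped_only(displacement_series(ten)))
})

test_that("latent-state full conditional matches the analytic probability", {
  cons <- model_constants()
  # symmetric case: f1 = f0 and p = 0.5 gives exactly 1/2
  pars <- individual_params(rep(0, 4), gamma = 0.5, theta = pi,
                            sigma1_sq = 25)
  d0 <- matrix(c(0, 0, 0, 0, 0, 0), ncol = 2, byrow = TRUE)
  tr <- toy_trajectory(d0)
  ser <- displacement_series(tr)
  design <- design_row(rep("grass", 2))
  set.seed(1)
  st <- update_latent_states(ser, design, pars, cons)
  # with delta_prev = 0 the movement mean is 0 too, so f1 = f0 at delta = 0
  expect_equal(unname(st$prob), rep(0.5, 2))

  # an extreme displacement makes movement certain
  d1 <- matrix(c(1, 1, 200, 0, 2, 1), ncol = 2, byrow = TRUE)
  p2 <- individual_params(rep(0, 4), 0.5, pi, 40^2)
  st2 <- update_latent_states(displacement_series(toy_trajectory(d1)),
                              design, p2, cons)
  expect_gt(st2$prob[1], 1 - 1e-6)

  # Monte Carlo frequency against the closed form (moderate contrast case)
  p3 <- individual_params(c(0.3, 0, 0, 0), 0.4, pi / 2, 900)
  d3 <- matrix(c(4, -2, 12, 6, 0, 0), ncol = 2, byrow = TRUE)
  ser3 <- displacement_series(toy_trajectory(d3))
  des3 <- design_row(rep("tree", 2))
  n_mc <- 20000
  set.seed(42)
  zf <- replicate(n_mc, update_latent_states(ser3, des3, p3, cons)$z[1])
  p_true <- update_latent_states(ser3, des3, p3, cons)$prob[1]
  expect_lt(abs(mean(zf) - p_true), 3 * sqrt(p_true * (1 - p_true) / n_mc))

  # auxiliaries have the sign their state demands
  set.seed(7)
  st3 <- update_latent_states(ser3, des3, p3, cons)
  expect_true(all((st3$v > 0) == (st3$z == 1)))
})

test_that("beta Gibbs update matches the closed-form normal-linear model", {
  # no data: the draw comes from the prior
  set.seed(5)
  draws <- replicate(4000, update_beta_gibbs(numeric(0),
                                             matrix(0, 0, 4))$draw[2])
  expect_lt(abs(mean(draws)), 3 / sqrt(4000))
  expect_lt(abs(sd(draws) - 1), 0.05)

  # 5-row toy against the textbook posterior
  X <- design_row(c("tree", "tree", "grass", "pavement", "building"))
  v <- c(0.4, -1.2, 0.7, 2.1, -0.3)
  up <- update_beta_gibbs(v, X, mu_beta = rep(0, 4), var_beta = 1)
  A <- crossprod(X) + diag(4)
  expect_equal(up$mean, unname(drop(solve(A, crossprod(X, v)))),
               tolerance = 1e-10)
  expect_equal(up$cov, unname(solve(A)), tolerance = 1e-10)

  # replicated data concentrate the draw at the least-squares solution
  Xr <- X[rep(1:5, 2e4), ]
  vr <- rep(v, 2e4)
  set.seed(9)
  d <- update_beta_gibbs(vr, Xr)$draw
  ls <- drop(solve(crossprod(Xr), crossprod(Xr, vr)))
  expect_lt(max(abs(d - ls)), 0.05)
})

test_that("sigma1^2 Gibbs update has the conjugate inverse-gamma form", {
  # no movement steps: prior draw from IG(1, 0.1)
  set.seed(11)
  pri <- replicate(20000, update_sigma1_gibbs(numeric(0))$draw)
  # IG(1, 0.1): P(X <= x) = exp(-0.1/x); compare at the median
  med_theory <- 0.1 / log(2)
  expect_lt(abs(median(pri) - med_theory) / med_theory, 0.05)

  # 3-step toy: shape and scale match the hand computation
  res <- matrix(c(3, -4, 1, 2, -2, 0.5), ncol = 2, byrow = TRUE)
  up <- update_sigma1_gibbs(res, q1 = 1, r1 = 0.1)
  expect_equal(up$shape, 1 + 3)
  expect_equal(up$scale, 0.1 + sum(res^2) / 2)

  # doubling the residuals stochastically increases the draws
  set.seed(13)
  a <- replicate(5000, update_sigma1_gibbs(res)$draw)
  b <- replicate(5000, update_sigma1_gibbs(2 * res)$draw)
  expect_gt(mean(b), mean(a))
})

test_that("prior-as-proposal updates recover the prior under a flat likelihood", {
  # no movement steps: every proposal accepted, gamma marginal is Beta(1,1)
  d <- matrix(rnorm(20), ncol = 2)
  set.seed(17)
  g <- numeric(3000)
  acc <- logical(3000)
  cur_g <- 0.5; cur_t <- pi
  for (k in seq_len(3000)) {
    up <- update_gamma_theta_mh(cur_g, cur_t, d, d, rep(FALSE, 10), 100)
    acc[k] <- up$accept_gamma && up$accept_theta
    cur_g <- up$gamma; cur_t <- up$theta
    g[k] <- cur_g
  }
  expect_true(all(acc))
  ks <- suppressWarnings(ks.test(g, punif))
  expect_gt(ks$p.value, 0.01)
})

test_that("stage-1 sampler recovers known parameters on a long trajectory", {
  s <- sim_individual(T_steps = 300, beta = c(0.3, -0.2, 0.5, 0),
                      gamma = 0.6, theta = pi, sigma1_sq = 625, seed = 31)
  fit <- fit_stage1(s$traj, s$raster, n_iter = 4000, seed = 101)
  keep <- 401:4000
  for (pn in colnames(fit$draws)) {
    truth <- switch(pn, gamma = 0.6, theta = pi, sigma1_sq = 625,
                    beta.tree = 0.3, beta.pavement = -0.2,
                    beta.grass = 0.5, beta.building = 0)
    dr <- fit$draws[keep, pn]
    expect_lt(abs(mean(dr) - truth), 3 * sd(dr))
  }
})

test_that("stage-1 fits are bit-identical given the same seed", {
  s <- sim_individual(T_steps = 40, seed = 3)
  a <- fit_stage1(s$traj, s$raster, n_iter = 300, seed = 77,
                  store_states = TRUE)
  b <- fit_stage1(s$traj, s$raster, n_iter = 300, seed = 77,
                  store_states = TRUE)
  expect_identical(a$draws, b$draws)
  expect_identical(a$z_draws, b$z_draws)
})

test_that("encamped-only individuals keep z at zero and sample the prior", {
  set.seed(41)
  ang <- cumsum(runif(30, 0, 2 * pi))
  lens <- runif(30, 0, 8)
  tr <- toy_trajectory(cbind(lens * cos(ang), lens * sin(ang)),
                       start = c(150, 150))
  r <- uniform_raster("building", 60, 5)
  fit <- fit_stage1(tr, r, n_iter = 5000, seed = 19, store_states = TRUE)
  expect_true(fit$encamped_only)
  expect_true(all(fit$z_draws == 0L))
  ks <- suppressWarnings(ks.test(fit$draws[, "gamma"], punif))
  expect_gt(ks$p.value, 0.01)
  # theta draws stay on the circle, sigma1^2 stays positive
  expect_true(all(fit$draws[, "theta"] >= 0 & fit$draws[, "theta"] < 2 * pi))
  expect_true(all(fit$draws[, "sigma1_sq"] > 0))
})

test_that("sampler transitions agree with forward simulation (successive-conditional check)", {
  # Compare prior-predictive moments of the sampler-updated parameters with
  # pure forward draws on a tiny instance: repeatedly (a) draw params from
  # their priors, (b) simulate a T=10 trajectory, (c) apply one sampler
  # sweep. If the transition kernels target the right conditionals, the
  # swept parameters remain prior-distributed.
  r <- uniform_raster("grass", 300, 10)
  priors <- stage1_priors()
  n_rep <- 800
  g_sweep <- numeric(n_rep); prec_sweep <- numeric(n_rep)
  set.seed(53)
  for (k in seq_len(n_rep)) {
    pars <- individual_params(rnorm(4, 0, 1),
                              rbeta(1, 1, 1) * 0.998 + 0.001,
                              rwrappedcauchy(1, 0, 0.1),
                              1 / rgamma(1, shape = 1, rate = 0.1))
    tr <- simulate_trajectory(pars, r, 10, c(1500, 1500),
                              seed = sample.int(1e6, 1))
    d <- statewalk:::step_data(tr, r)
    st <- list(z = attr(tr, "states")[d$series$eligible - 2L],
               beta = pars$beta, gamma = pars$gamma, theta = pars$theta,
               sigma1_sq = pars$sigma1_sq)
    sw <- statewalk:::stage1_sweep(d, st, priors)
    g_sweep[k] <- sw$gamma
    prec_sweep[k] <- 1 / sw$sigma1_sq
  }
  # gamma ~ Beta(1,1): mean 1/2, var 1/12
  expect_lt(abs(mean(g_sweep) - 0.5),
            3 * sqrt(1 / 12 / length(g_sweep)))
  # precision ~ Gamma(1, rate 0.1): mean 10, var 100
  expect_lt(abs(mean(prec_sweep) - 10),
            3 * sqrt(100 / length(prec_sweep)))
})
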