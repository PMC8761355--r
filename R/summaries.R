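# Derived quantities and hypothesis tests: back-transformation of
# treatment-level parameters to natural scales by Monte Carlo integration,
# pairwise posterior-probability comparisons, individual-heterogeneity
# sample variances, and chain diagnostics.

#' Back-transform one treatment-level draw to natural scales
#'
#' For a single MCMC draw of the group-level parameters, draws `n_mc`
#' pseudo-individuals from the group's distributions and averages the
#' inverse transforms: mu_gamma = mean inverse-logit, mu_sigma1 = mean
#' exp(log sigma1) in metres, and mu_p per landscape feature = mean
#' Phi(beta_k) with beta ~ N(mu_beta, Sigma_beta). This integrates the
#' individual heterogeneity into the group-level mean rather than plugging
#' in Phi(mu). Uses the current RNG stream.
#'
#' @param tp A [treatment_params()] (or compatible list).
#' @param n_mc Pseudo-individuals per MCMC draw (>= 1).
#' @param plugin If `TRUE`, skip the integration and deterministically
#'   transform the means.
#' @return Named numeric: `mu_gamma`, `mu_sigma1`, `mu_theta`, and
#'   `mu_p.<feature>` for the four features.
#' @export
back_transform_treatment <- function(tp, n_mc = 1000, plugin = FALSE) {
  cats <- landscape_categories()
  if (plugin) {
    out <- c(stats::plogis(tp$mu_logit_gamma), exp(tp$mu_log_sigma1),
             tp$mu_theta, stats::pnorm(tp$mu_beta))
  } else {
    if (n_mc < 1L) stop("`n_mc` must be at least 1")
    mu_g <- mean(stats::plogis(stats::rnorm(n_mc, tp$mu_logit_gamma,
                                            sqrt(tp$var_logit_gamma))))
    mu_s <- mean(exp(stats::rnorm(n_mc, tp$mu_log_sigma1,
                                  sqrt(tp$var_log_sigma1))))
    L <- chol(tp$Sigma_beta)
    Bdraw <- matrix(stats::rnorm(n_mc * length(tp$mu_beta)), n_mc) %*% L
    Bdraw <- sweep(Bdraw, 2L, tp$mu_beta, "+")
    out <- c(mu_g, mu_s, tp$mu_theta, colMeans(stats::pnorm(Bdraw)))
  }
  names(out) <- c("mu_gamma", "mu_sigma1", "mu_theta", paste0("mu_p.", cats))
  out
}

#' Derived-quantity draws from a second-stage fit
#'
#' Applies [back_transform_treatment()] to every retained (post-burn-in)
#' iteration of each treatment group, and computes the per-iteration
#' individual-heterogeneity sample variances: the (n-1)-denominator variance
#' across the group's individuals of gamma_i, theta_i, sigma_1i (metres) and
#' the per-feature movement probabilities Phi(beta_ik). Deterministic given
#' `seed`.
#'
#' @param fit A [fit_stage2()] result.
#' @param n_mc Monte Carlo integration size per iteration.
#' @param seed Integer seed for the integration draws.
#' @param plugin Use deterministic plug-in transforms instead of Monte Carlo
#'   integration.
#' @return Object of class `derived_draws`: 3-d array `draws` (retained
#'   iteration x quantity x group); quantities are the back-transformed
#'   means plus `het_gamma`, `het_theta`, `het_sigma1`, `het_p.<feature>`.
#' @export
derived_quantities <- function(fit, n_mc = 1000, seed = 1L, plugin = FALSE) {
  if (!inherits(fit, "stage2_fit")) stop("`fit` must be a stage2_fit")
  keep <- (fit$burn + 1L):fit$n_iter
  cats <- landscape_categories()
  p <- length(cats)
  qnames <- c("mu_gamma", "mu_sigma1", "mu_theta", paste0("mu_p.", cats),
              "het_gamma", "het_theta", "het_sigma1", paste0("het_p.", cats))
  out <- array(NA_real_, c(length(keep), length(qnames), length(fit$groups)),
               dimnames = list(NULL, qnames, fit$groups))
  rowvar <- function(m) {
    if (ncol(m) < 2L) stop("heterogeneity requires at least 2 individuals")
    apply(m, 1L, stats::var)
  }
  with_seed(seed, {
    for (g in fit$groups) {
      G <- fit$group[keep, , g]
      members <- which(fit$group_of == g)
      for (r in seq_along(keep)) {
        tp <- list(
          mu_beta = G[r, paste0("mu_beta.", cats)],
          Sigma_beta = matrix(G[r, grep("^Sigma_beta\\.", colnames(G))], p, p),
          mu_logit_gamma = G[r, "mu_logit_gamma"],
          var_logit_gamma = G[r, "var_logit_gamma"],
          mu_theta = G[r, "mu_theta"], var_theta = G[r, "var_theta"],
          mu_log_sigma1 = G[r, "mu_log_sigma1"],
          var_log_sigma1 = G[r, "var_log_sigma1"])
        out[r, 1:(3 + p), g] <- back_transform_treatment(tp, n_mc, plugin)
      }
      if (length(members) >= 2L) {
        gi <- fit$individual[keep, "gamma", members, drop = FALSE][, 1L, ]
        th <- fit$individual[keep, "theta", members, drop = FALSE][, 1L, ]
        s1 <- sqrt(fit$individual[keep, "sigma1_sq", members,
                                  drop = FALSE][, 1L, ])
        out[, "het_gamma", g] <- rowvar(gi)
        out[, "het_theta", g] <- rowvar(th)
        out[, "het_sigma1", g] <- rowvar(s1)
        for (k in seq_len(p)) {
          pk <- stats::pnorm(fit$individual[keep, paste0("beta.", cats[k]),
                                            members, drop = FALSE][, 1L, ])
          out[, paste0("het_p.", cats[k]), g] <- rowvar(pk)
        }
      }
    }
  })
  structure(list(draws = out, groups = fit$groups, n_mc = n_mc,
                 plugin = plugin),
            class = "derived_draws")
}

#' Posterior probability that one chain exceeds another
#'
#' The hypothesis-testing statistic: the fraction of MCMC iterations in
#' which `draws_a > draws_b`, ties counted half. Two identical chains give
#' exactly 0.5, and P(a > b) + P(b > a) = 1 always.
#'
#' @param draws_a,draws_b Aligned draw vectors of equal length.
#' @return Proportion in [0, 1].
#' @export
posterior_probability_greater <- function(draws_a, draws_b) {
  if (length(draws_a) != length(draws_b))
    stop("draw vectors must have equal length")
  mean((draws_a > draws_b) + 0.5 * (draws_a == draws_b))
}

#' Posterior summary of a pairwise difference
#'
#' Summarises the derived quantity a - b: posterior mean difference,
#' equal-tailed credible interval, and the posterior probability that a
#' exceeds b.
#'
#' @param draws_a,draws_b Aligned draw vectors.
#' @param ci_level Credible level (default 0.95).
#' @return Named list: `mean_diff`, `lower`, `upper`, `prob_greater`.
#' @export
difference_summary <- function(draws_a, draws_b, ci_level = 0.95) {
  if (length(draws_a) != length(draws_b))
    stop("draw vectors must have equal length")
  d <- draws_a - draws_b
  s <- summarize_draws(d, ci_level)
  list(mean_diff = s[["mean"]], lower = s[["lower"]], upper = s[["upper"]],
       prob_greater = posterior_probability_greater(draws_a, draws_b))
}

#' Per-iteration individual-heterogeneity variance
#'
#' Sample variance ((n-1) denominator) across a group's individuals of their
#' current parameter values, one variance per MCMC iteration.
#'
#' @param draw_matrix Iterations x individuals matrix of aligned draws.
#' @return Numeric vector of variance draws.
#' @export
individual_heterogeneity <- function(draw_matrix) {
  draw_matrix <- as.matrix(draw_matrix)
  if (ncol(draw_matrix) < 2L)
    stop("heterogeneity requires at least 2 individuals")
  apply(draw_matrix, 1L, stats::var)
}

#' Mean and equal-tailed credible interval
#'
#' @param draws Nonempty numeric vector.
#' @param ci_level Credible level (default 0.95 gives the 2.5/97.5
#'   percentiles).
#' @return Named numeric `c(mean, lower, upper)`.
#' @export
summarize_draws <- function(draws, ci_level = 0.95) {
  if (length(draws) == 0L) stop("empty draw vector")
  a <- (1 - ci_level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), names = FALSE)
  c(mean = mean(draws), lower = q[1L], upper = q[2L])
}

#' Effective sample size and split-chain convergence diagnostic
#'
#' Automated stand-in for visual trace inspection: for each column of a draw
#' matrix, the effective sample size (Geyer initial-positive-sequence
#' truncation of the autocorrelation sum, capped at the number of draws) and
#' the split-chain R-hat (chain halved, between/within variance ratio).
#' Parameters with R-hat > 1.1 are flagged.
#'
#' @param draws Numeric matrix (iterations x parameters) or vector.
#' @return `data.frame` with columns `parameter`, `ess`, `rhat`, `flagged`.
#' @export
trace_diagnostics <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 100L)
    stop("at least 100 post-burn-in draws are required for diagnostics")
  if (is.null(colnames(draws)))
    colnames(draws) <- paste0("par", seq_len(ncol(draws)))
  res <- data.frame(parameter = colnames(draws),
                    ess = NA_real_, rhat = NA_real_)
  for (j in seq_len(ncol(draws))) {
    x <- draws[, j]
    res$ess[j] <- ess_geyer(x)
    res$rhat[j] <- split_rhat(x)
  }
  res$flagged <- !is.na(res$rhat) & res$rhat > 1.1
  res
}

ess_geyer <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  lag_max <- min(n - 1L, 2000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  tau <- 1
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2L
  }
  min(n, n / tau)
}

split_rhat <- function(x) {
  n <- length(x)
  half <- floor(n / 2)
  chains <- cbind(x[seq_len(half)], x[(n - half + 1L):n])
  m <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}
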