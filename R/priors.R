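#' Stage-1 (individual model) temporary priors
#'
#' Semi-informative priors used only while fitting each individual on its
#' own, chosen to match each parameter's support so every first-stage update
#' is either conjugate or a prior-as-proposal Metropolis step needing no
#' tuning: beta ~ N(0, I), gamma ~ Beta(1, 1), theta ~ wrapped-Cauchy(0, 0.1)
#' (near-uniform on the circle), sigma1^2 ~ IG(1, 0.1). The inverse gamma is
#' in the shape--scale convention: density proportional to
#' (s2)^-(q+1) exp(-r/s2).
#'
#' @param mu_beta Prior mean for beta (length 4).
#' @param var_beta Prior variance of each beta coefficient (spherical).
#' @param gamma_a,gamma_b Beta prior shapes for gamma.
#' @param theta_mu,theta_rho Wrapped-Cauchy location/concentration for theta.
#' @param sigma1_q,sigma1_r Inverse-gamma shape/scale for sigma1^2.
#' @return An object of class `stage1_priors`.
#' @export
stage1_priors <- function(mu_beta = rep(0, 4), var_beta = 1,
                          gamma_a = 1, gamma_b = 1,
                          theta_mu = 0, theta_rho = 0.1,
                          sigma1_q = 1, sigma1_r = 0.1) {
  structure(list(mu_beta = mu_beta, var_beta = var_beta,
                 gamma_a = gamma_a, gamma_b = gamma_b,
                 theta_mu = theta_mu, theta_rho = theta_rho,
                 sigma1_q = sigma1_q, sigma1_r = sigma1_r),
            class = "stage1_priors")
}

#' Hyperpriors of the full hierarchical model
#'
#' Defaults: treatment mean coefficients mu_beta_j ~ N(0, I); mu_logit(gamma)
#' ~ N(logit(0.7), 1.5) (regularised away from 0 so the movement state stays
#' distinct from the encamped state); mu_theta ~ N(pi, pi^2/4) (mass mostly
#' inside [0, 2*pi)); mu_log(sigma1) ~ N(log(20), 100) (2*20 m = a 40 m
#' nightly kernel, a typical movement distance for small brown treesnakes).
#' Group variances get diffuse inverse-gamma priors. The package's IG
#' convention is shape--scale (density proportional to
#' (s2)^-(q+1) exp(-r/s2)); the default scales are the reciprocals of the
#' conventional rate-style pairs -- IG(0.001, scale 0.001) for the
#' logit(gamma) and log(sigma1) variances, IG(2.5, scale 2) for the theta
#' variance -- i.e. diffuse priors whose mass stays within reasonable
#' bounds of each transformation (a scale of 1000 would instead pin the
#' variances near 10^3 and destroy the hierarchy). The beta covariance is
#' either a full inverse Wishart (default, `beta_cov_model = "wishart"`,
#' prior precision ~ Wish((S*nu)^-1, nu) with S = I, nu = 6) or independent
#' diagonal IG(0.01, scale 0.1) variances (`beta_cov_model = "diag"`).
#'
#' @param n_beta Number of landscape categories (coefficients).
#' @param beta_cov_model `"wishart"` (full covariance) or `"diag"`.
#' @param wishart_S,wishart_nu Inverse-Wishart scale matrix and df.
#' @param ... Override any default element by name.
#' @return An object of class `hyper_priors`.
#' @export
hyper_priors <- function(n_beta = 4, beta_cov_model = c("wishart", "diag"),
                         wishart_S = diag(n_beta), wishart_nu = n_beta + 2,
                         ...) {
  beta_cov_model <- match.arg(beta_cov_model)
  hp <- list(
    mu_beta_pop = rep(0, n_beta),
    Sigma_beta_pop = diag(n_beta),
    mu_logit_gamma_pop = stats::qlogis(0.7), var_logit_gamma_pop = 1.5,
    mu_theta_pop = pi, var_theta_pop = pi^2 / 4,
    mu_log_sigma1_pop = log(20), var_log_sigma1_pop = 100,
    ig_beta = c(q = 0.01, r = 1 / 10),          # diag variant only
    ig_logit_gamma = c(q = 0.001, r = 1 / 1000),
    ig_theta = c(q = 2.5, r = 1 / 0.5),
    ig_log_sigma1 = c(q = 0.001, r = 1 / 1000),
    wishart_S = wishart_S, wishart_nu = wishart_nu,
    beta_cov_model = beta_cov_model,
    stage1 = stage1_priors(mu_beta = rep(0, n_beta))
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(hp))
  if (length(bad)) stop("unknown hyperprior fields: ", paste(bad, collapse = ", "))
  hp[names(dots)] <- dots
  structure(hp, class = "hyper_priors")
}

#' Wrapped-Cauchy density
#'
#' Circular density f(x) = (1 - rho^2) / (2*pi*(1 + rho^2 - 2*rho*cos(x -
#' mu))) on [0, 2*pi).
#'
#' @param x Angle(s) in radians.
#' @param mu Location (radians).
#' @param rho Concentration in [0, 1).
#' @param log Return log-density?
#' @return Density values.
#' @export
dwrappedcauchy <- function(x, mu = 0, rho = 0.1, log = FALSE) {
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)")
  d <- (1 - rho^2) / (2 * pi * (1 + rho^2 - 2 * rho * cos(x - mu)))
  if (log) base::log(d) else d
}

#' Wrapped-Cauchy random draws
#'
#' Inverse-CDF sampling of the underlying Cauchy followed by wrapping onto
#' [0, 2*pi).
#'
#' @param n Number of draws.
#' @param mu Location (radians).
#' @param rho Concentration in [0, 1).
#' @return Numeric vector of angles in [0, 2*pi).
#' @export
rwrappedcauchy <- function(n, mu = 0, rho = 0.1) {
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)")
  if (rho == 0) return(stats::runif(n, 0, 2 * pi))
  scale <- -log(rho)   # wrapped Cauchy(mu, rho) = wrap of Cauchy(mu, -log rho)
  (mu + stats::rcauchy(n, 0, scale)) %% (2 * pi)
}
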