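#' Landscape category levels
#'
#' Fixed ordering of the four landscape categories used throughout the
#' package: probit design rows, raster codes (1--4) and coefficient names all
#' follow this order.
#'
#' @return Character vector `c("tree", "pavement", "grass", "building")`.
#' @export
landscape_categories <- function() c("tree", "pavement", "grass", "building")

#' Treatment group labels
#'
#' The three translocation treatment groups of the study design: residents
#' (never moved), snakes translocated from forest into an urban area, and
#' snakes translocated between urban areas.
#'
#' @return Character vector of the three valid treatment labels.
#' @export
treatment_levels <- function() c("resident", "forest_to_urban", "urban_to_urban")

#' Fixed model constants
#'
#' The encamped-state kernel is fixed across all individuals: displacements in
#' the encamped state are N(0, sigma0^2 I). `sigma0 = 5` m corresponds to a
#' "95% movement kernel" (the 2-sigma reporting convention, see
#' [kernel_radius()]) of 10 m, roughly one tree canopy plus GPS error.
#' Trajectories whose every displacement is `<= encamped_threshold` metres are
#' treated as encamped-only for identifiability (see
#' [detect_encamped_only()]).
#'
#' @param sigma0 Encamped-state standard deviation in metres (> 0).
#' @param encamped_threshold Step length in metres at or below which all steps
#'   of a trajectory may be forced into the encamped state.
#' @return An object of class `model_constants`.
#' @export
model_constants <- function(sigma0 = 5, encamped_threshold = 10) {
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("`sigma0` must be a positive finite number")
  if (!is.finite(encamped_threshold) || encamped_threshold < 0)
    stop("`encamped_threshold` must be nonnegative and finite")
  structure(list(sigma0 = sigma0, encamped_threshold = encamped_threshold),
            class = "model_constants")
}

#' Construct a trajectory
#'
#' One individual's ordered daily relocations. Days must be strictly
#' increasing integers; positions are planar projected coordinates in metres
#' (x east, y north). At least 3 relocations are required for any likelihood
#' evaluation, because the autoregression on the previous displacement makes
#' t = 3 the first usable term.
#'
#' @param individual_id Character label.
#' @param treatment One of [treatment_levels()].
#' @param days Integer vector of day indices, strictly increasing.
#' @param positions Numeric matrix with one row per day and columns (x, y).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(individual_id, treatment, days, positions) {
  treatment <- match.arg(treatment, treatment_levels())
  days <- as.integer(days)
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    stop("`positions` must have two columns (x, y)")
  if (length(days) != nrow(positions))
    stop("`days` and `positions` must have matching lengths")
  if (any(diff(days) <= 0L))
    stop("`days` must be strictly increasing")
  if (!all(is.finite(positions)))
    stop("`positions` must be finite")
  structure(list(individual_id = as.character(individual_id),
                 treatment = treatment, days = days, positions = positions),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s [%s]: %d relocations, days %d..%d\n",
              x$individual_id, x$treatment, length(x$days),
              min(x$days), max(x$days)))
  invisible(x)
}

#' Displacement series of a trajectory
#'
#' Converts relocations s_t to successive displacements delta_t = s_t -
#' s_(t-1) and identifies the likelihood-eligible steps: a step t (3 <= t <=
#' T) enters the likelihood only when days t-2, t-1, t are consecutive, so
#' both delta_t and delta_(t-1) are genuine nightly displacements. The first
#' displacement delta_2 is always treated as a fixed initial condition and
#' never modelled.
#'
#' @param traj A [trajectory()].
#' @return An object of class `displacement_series` with elements `deltas`
#'   ((T-1) x 2 matrix, row r giving delta for relocation index r+1) and
#'   `eligible` (integer vector of eligible relocation indices t).
#' @export
displacement_series <- function(traj) {
  if (!inherits(traj, "trajectory")) stop("`traj` must be a trajectory")
  n <- length(traj$days)
  if (n < 3L)
    stop("at least 3 relocations are required for a displacement series")
  deltas <- diff(traj$positions)
  gaps <- diff(traj$days)          # length n-1; gaps[r] = day(r+1) - day(r)
  t_idx <- 3:n
  ok <- gaps[t_idx - 1L] == 1L & gaps[t_idx - 2L] == 1L
  structure(list(deltas = deltas, eligible = t_idx[ok],
                 n_relocations = n),
            class = "displacement_series")
}

#' Individual-level movement parameters
#'
#' @param beta Probit coefficient vector, one entry per landscape category.
#' @param gamma Autoregression coefficient in (0, 1): how strongly a
#'   movement-state displacement adheres to the rotated previous displacement.
#' @param theta Turning angle in radians, canonicalised to [0, 2*pi).
#' @param sigma1_sq Movement-state variance in m^2 (> 0).
#' @return An object of class `individual_params`.
#' @export
individual_params <- function(beta, gamma, theta, sigma1_sq) {
  beta <- as.numeric(beta)
  if (!all(is.finite(beta))) stop("`beta` must be finite")
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1)
    stop("`gamma` must lie in (0, 1)")
  if (!is.finite(sigma1_sq) || sigma1_sq <= 0)
    stop("`sigma1_sq` must be positive")
  if (!is.finite(theta)) stop("`theta` must be finite")
  theta <- theta %% (2 * pi)
  structure(list(beta = beta, gamma = gamma, theta = theta,
                 sigma1_sq = sigma1_sq),
            class = "individual_params")
}

#' Treatment-level (group) parameters on transformed scales
#'
#' Group means and variances of the individual-level process model: beta_i ~
#' N(mu_beta, Sigma_beta); logit(gamma_i), theta_i and log(sigma_1i) each
#' normal with the given mean/variance.
#'
#' @param mu_beta Mean coefficient vector (length 4).
#' @param Sigma_beta 4x4 symmetric positive-definite covariance.
#' @param mu_logit_gamma,var_logit_gamma Mean/variance of logit(gamma).
#' @param mu_theta,var_theta Mean/variance of theta (radians).
#' @param mu_log_sigma1,var_log_sigma1 Mean/variance of log(sigma_1).
#' @return An object of class `treatment_params`.
#' @export
treatment_params <- function(mu_beta, Sigma_beta, mu_logit_gamma,
                             var_logit_gamma, mu_theta, var_theta,
                             mu_log_sigma1, var_log_sigma1) {
  mu_beta <- as.numeric(mu_beta)
  Sigma_beta <- as.matrix(Sigma_beta)
  if (nrow(Sigma_beta) != length(mu_beta) ||
      ncol(Sigma_beta) != length(mu_beta))
    stop("`Sigma_beta` dimensions must match `mu_beta`")
  ev <- eigen(Sigma_beta, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("`Sigma_beta` must be positive definite")
  for (v in c(var_logit_gamma, var_theta, var_log_sigma1))
    if (!is.finite(v) || v <= 0) stop("all variances must be positive")
  structure(list(mu_beta = mu_beta, Sigma_beta = Sigma_beta,
                 mu_logit_gamma = mu_logit_gamma,
                 var_logit_gamma = var_logit_gamma,
                 mu_theta = mu_theta, var_theta = var_theta,
                 mu_log_sigma1 = mu_log_sigma1,
                 var_log_sigma1 = var_log_sigma1),
            class = "treatment_params")
}

#' Propagation (rotation) matrix
#'
#' The 2x2 rotation matrix M(theta) applied to the previous displacement to
#' form the mean direction of the next movement-state displacement. With
#' gamma = 1 and theta = pi/2 the walk makes 90-degree turns every night.
#'
#' @param theta Turning angle in radians.
#' @return 2x2 rotation matrix `[[cos, -sin], [sin, cos]]`.
#' @export
propagation_matrix <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("`theta` must be a single finite number")
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Log-density of one displacement under a given behavioural state
#'
#' The data model is a two-component normal mixture: in the movement state
#' (state = 1) delta_t ~ N(gamma * M(theta) * delta_(t-1), sigma1^2 I); in the
#' encamped state (state = 0) delta_t ~ N(0, sigma0^2 I).
#'
#' @param delta_t Displacement at step t (length-2 numeric).
#' @param delta_prev Previous displacement (length-2 numeric).
#' @param state 0 (encamped) or 1 (movement).
#' @param params An [individual_params()].
#' @param constants A [model_constants()].
#' @return Log-density (scalar).
#' @export
step_log_density <- function(delta_t, delta_prev, state, params,
                             constants = model_constants()) {
  if (!all(is.finite(delta_t)) || !all(is.finite(delta_prev)))
    stop("displacements must be finite")
  if (params$sigma1_sq <= 0) stop("`sigma1_sq` must be positive")
  if (state == 1) {
    mu <- params$gamma * propagation_matrix(params$theta) %*% delta_prev
    s <- sqrt(params$sigma1_sq)
  } else {
    mu <- c(0, 0)
    s <- constants$sigma0
  }
  sum(stats::dnorm(delta_t, mean = as.numeric(mu), sd = s, log = TRUE))
}

#' Probit movement probability
#'
#' The nightly probability of being in the movement state is Phi(x' beta),
#' where x is the one-hot design row for the landscape category occupied at
#' the start of the step.
#'
#' @param design_row Indicator vector (same length as `beta`).
#' @param beta Probit coefficient vector.
#' @return Probability in (0, 1) (0/1 only in the infinite-predictor limit).
#' @export
movement_probability <- function(design_row, beta) {
  if (length(design_row) != length(beta))
    stop("`design_row` and `beta` must have the same length")
  stats::pnorm(sum(design_row * beta))
}

#' 95% movement-kernel radius
#'
#' Reporting convention: twice the state standard deviation is quoted as the
#' radius containing ~95% of nightly displacements ("95% movement kernel").
#' For sigma0 = 5 this gives the 10 m encamped kernel. Note the convention is
#' the per-coordinate 2-sigma rule; the radial bivariate mass inside 2 sigma
#' is ~86.5%, but the literal 2*sigma convention is what gets reported.
#'
#' @param sigma State standard deviation in metres (>= 0).
#' @return `2 * sigma` in metres.
#' @export
kernel_radius <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma < 0))
    stop("`sigma` must be nonnegative and finite")
  2 * sigma
}

#' Complete-data log-likelihood for one individual
#'
#' Sums, over the likelihood-eligible steps t = 3..T, the state-conditional
#' displacement log-density plus the Bernoulli(Phi(x' beta)) log-mass of the
#' latent state, with x the design row at the step's starting position. Steps
#' spanning day gaps are excluded (see [displacement_series()]).
#'
#' @param series A [displacement_series()].
#' @param params An [individual_params()].
#' @param states Binary vector of latent states, one per eligible step.
#' @param design Matrix of one-hot design rows, one per eligible step.
#' @param constants A [model_constants()].
#' @return Log-likelihood (0 for an empty eligible set).
#' @export
individual_log_likelihood <- function(series, params, states, design,
                                      constants = model_constants()) {
  el <- series$eligible
  if (length(el) == 0L) return(0)
  if (is.null(design) || nrow(design) != length(el))
    stop(sprintf("`design` must have one row per eligible step (%d needed)",
                 length(el)))
  if (length(states) != length(el))
    stop("`states` must align with the eligible steps")
  dcur <- series$deltas[el - 1L, , drop = FALSE]
  dprev <- series$deltas[el - 2L, , drop = FALSE]
  ll <- 0
  for (k in seq_along(el)) {
    p <- movement_probability(design[k, ], params$beta)
    ll <- ll + step_log_density(dcur[k, ], dprev[k, ], states[k], params,
                                constants) +
      ifelse(states[k] == 1, log(p), log1p(-p))
  }
  ll
}

# Vectorised movement-state mean of eligible displacements:
# gamma * M(theta) %*% delta_prev for each row. Internal workhorse shared by
# the samplers and the simulator.
movement_mean <- function(dprev, gamma, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(gamma * (ct * dprev[, 1L] - st * dprev[, 2L]),
        gamma * (st * dprev[, 1L] + ct * dprev[, 2L]))
}

# Row-wise isotropic bivariate normal log-density with sd s.
bvn_logpdf <- function(x, mu, s) {
  stats::dnorm(x[, 1L], mu[, 1L], s, log = TRUE) +
    stats::dnorm(x[, 2L], mu[, 2L], s, log = TRUE)
}
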