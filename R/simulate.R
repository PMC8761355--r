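#' Default treatment-level truth for synthetic studies
#'
#' The generator's default study conditions. Group mean movement scales are
#' set at 23, 31 and 34 m (residents smallest; translocated snakes ~35--47%
#' larger), mean movement probabilities fall in the 0.24--0.52 band via
#' probit-scale means per landscape feature, turning-angle means sit at pi
#' (course reversals dominate), and autocorrelation means rise modestly
#' across groups. Between-individual variances are moderate: sd 0.3 on the
#' probit, 0.5 on logit(gamma), ~0.3 rad on theta, and 0.25 on log(sigma1)
#' (so individual scales span roughly half to double the group mean).
#'
#' @return Named list of [treatment_params()], one per treatment group.
#' @export
default_truth <- function() {
  mk <- function(p_move, gamma, sigma1) {
    treatment_params(
      mu_beta = stats::qnorm(p_move), Sigma_beta = diag(0.09, 4),
      mu_logit_gamma = stats::qlogis(gamma), var_logit_gamma = 0.25,
      mu_theta = pi, var_theta = 0.1,
      mu_log_sigma1 = log(sigma1), var_log_sigma1 = 0.0625)
  }
  list(
    resident        = mk(c(0.47, 0.41, 0.38, 0.45), 0.50, 23),
    forest_to_urban = mk(c(0.40, 0.52, 0.33, 0.39), 0.60, 31),
    urban_to_urban  = mk(c(0.45, 0.27, 0.33, 0.25), 0.65, 34)
  )
}

#' Synthetic study configuration
#'
#' Bundles everything [simulate_study()] needs: truth parameters per group,
#' group sizes, trajectory length range, landscape, constants and seed.
#' Defaults mirror the field study design: groups of 29/32/23 individuals
#' (resident / forest-to-urban / urban-to-urban) and trajectory lengths
#' drawn uniformly from 5--77 relocations.
#'
#' @param truth Named list of [treatment_params()] keyed by treatment label.
#' @param n_individuals Integer vector of individuals per group (recycled to
#'   the number of groups).
#' @param length_range Length-2 integer, min/max relocations per trajectory.
#' @param raster A [categorical_raster()]; default a 600x600 cell, 0.7 m
#'   synthetic landscape with equal category proportions.
#' @param constants A [model_constants()].
#' @param start Either `"center"` (all trajectories start at the raster
#'   centre) or a length-2 coordinate.
#' @param seed Integer master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(truth = default_truth(),
                         n_individuals = c(29, 32, 23),
                         length_range = c(5, 77),
                         raster = NULL,
                         constants = model_constants(),
                         start = "center",
                         seed = 1L) {
  if (is.null(raster))
    raster <- generate_synthetic_raster(600, 600, cell_size = 0.7,
                                        seed = seed)
  if (length(length_range) != 2L || length_range[1] < 3L ||
      length_range[2] < length_range[1])
    stop("`length_range` must be (min, max) with min >= 3")
  n_individuals <- rep_len(as.integer(n_individuals), length(truth))
  if (any(n_individuals < 1L)) stop("need at least 1 individual per group")
  if (is.null(names(truth)) || !all(names(truth) %in% treatment_levels()))
    stop("`truth` must be named by treatment labels")
  structure(list(truth = truth, n_individuals = n_individuals,
                 length_range = as.integer(length_range), raster = raster,
                 constants = constants, start = start, seed = seed),
            class = "study_config")
}

#' Draw one individual's parameters from its treatment distribution
#'
#' beta ~ N(mu_beta, Sigma_beta); logit(gamma) ~ normal then inverse-logit;
#' theta ~ normal then wrapped to [0, 2*pi); log(sigma1) ~ normal then
#' exponentiated and squared to the variance sigma1^2.
#'
#' @param treatment A [treatment_params()].
#' @param seed Integer seed.
#' @return An [individual_params()].
#' @export
draw_individual_params <- function(treatment, seed) {
  with_seed(seed, {
    L <- tryCatch(chol(treatment$Sigma_beta),
                  error = function(e) stop("`Sigma_beta` must be positive definite"))
    beta <- treatment$mu_beta +
      drop(crossprod(L, stats::rnorm(length(treatment$mu_beta))))
    g <- stats::plogis(stats::rnorm(1, treatment$mu_logit_gamma,
                                    sqrt(treatment$var_logit_gamma)))
    th <- stats::rnorm(1, treatment$mu_theta, sqrt(treatment$var_theta)) %% (2 * pi)
    s1 <- exp(stats::rnorm(1, treatment$mu_log_sigma1,
                           sqrt(treatment$var_log_sigma1)))
    individual_params(beta = beta, gamma = g, theta = th, sigma1_sq = s1^2)
  })
}

#' Simulate one trajectory from the two-state model
#'
#' Runs the data model generatively on a landscape: delta_2 is drawn from the
#' encamped kernel as the unconditioned initial displacement; for each t >= 3
#' the movement probability is Phi(x' beta) with x the design row of the
#' category at s_(t-1), the state z_t is Bernoulli, and delta_t comes from
#' the state's normal. Positions reflect at the raster boundary so every step
#' keeps covariate support; the stored displacements are the realised
#' (post-reflection) ones.
#'
#' @param params An [individual_params()].
#' @param raster A [categorical_raster()].
#' @param T_steps Number of relocations (>= 3).
#' @param start Length-2 start coordinate inside the raster.
#' @param constants A [model_constants()].
#' @param seed Integer seed.
#' @param individual_id,treatment Labels attached to the result.
#' @return A [trajectory()] with attribute `states` (integer vector of true
#'   z_t for t = 3..T).
#' @export
simulate_trajectory <- function(params, raster, T_steps, start,
                                constants = model_constants(), seed = 1L,
                                individual_id = "sim", treatment = "resident") {
  if (T_steps < 3L) stop("`T_steps` must be at least 3")
  ext <- raster_extent(raster)
  if (start[1] < ext["xmin"] || start[1] >= ext["xmax"] ||
      start[2] < ext["ymin"] || start[2] >= ext["ymax"])
    stop("`start` lies outside the raster extent")
  sigma0 <- constants$sigma0
  sigma1 <- sqrt(params$sigma1_sq)
  ct <- cos(params$theta); st <- sin(params$theta); g <- params$gamma
  with_seed(seed, {
    pos <- matrix(NA_real_, T_steps, 2L)
    pos[1L, ] <- start
    delta_prev <- stats::rnorm(2L, 0, sigma0)
    pos[2L, ] <- reflect_into(pos[1L, ] + delta_prev, ext)
    delta_prev <- pos[2L, ] - pos[1L, ]
    z <- integer(T_steps - 2L)
    for (t in 3:T_steps) {
      x <- design_row(feature_at(raster, pos[t - 1L, ]))
      p <- movement_probability(x, params$beta)
      zt <- as.integer(stats::runif(1) < p)
      if (zt == 1L) {
        mu <- g * c(ct * delta_prev[1L] - st * delta_prev[2L],
                    st * delta_prev[1L] + ct * delta_prev[2L])
        delta <- mu + stats::rnorm(2L, 0, sigma1)
      } else {
        delta <- stats::rnorm(2L, 0, sigma0)
      }
      pos[t, ] <- reflect_into(pos[t - 1L, ] + delta, ext)
      delta_prev <- pos[t, ] - pos[t - 1L, ]
      z[t - 2L] <- zt
    }
    out <- trajectory(individual_id, treatment, seq_len(T_steps), pos)
    attr(out, "states") <- z
    out
  })
}

# Reflect a point into the (half-open) extent by mirroring at the edges.
reflect_into <- function(p, ext) {
  span <- c(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"])
  lo <- c(ext["xmin"], ext["ymin"])
  q <- (p - lo) %% (2 * span)
  q <- ifelse(q > span, 2 * span - q, q)
  # keep strictly inside the half-open extent
  q <- pmin(q, span * (1 - 1e-12))
  unname(lo + q)
}

#' Simulate a full multi-group study with known truth
#'
#' Draws each individual's parameters from its group's truth distribution,
#' simulates its trajectory, and records everything in a truth ledger for
#' parameter-recovery testing. Per-individual seeds derive from the master
#' seed and individual label ([derive_seed()]), so results do not depend on
#' the order individuals are simulated in.
#'
#' @param config A [study_config()].
#' @return An object of class `simulated_study`: list with `trajectories`
#'   (named list of [trajectory()], each carrying its true `states`
#'   attribute), `truth` (list with `individual` named list of
#'   [individual_params()] and `treatment` the truth [treatment_params()]),
#'   `raster`, `constants` and `config`.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "study_config")) stop("`config` must be a study_config")
  if (is.null(config$raster)) stop("`config` has no raster")
  ext <- raster_extent(config$raster)
  start <- if (identical(config$start, "center"))
    c((ext["xmin"] + ext["xmax"]) / 2, (ext["ymin"] + ext["ymax"]) / 2)
  else config$start
  groups <- names(config$truth)
  trajectories <- list()
  ind_truth <- list()
  for (j in seq_along(groups)) {
    grp <- groups[j]
    for (i in seq_len(config$n_individuals[j])) {
      id <- sprintf("%s_%02d", grp, i)
      sd_i <- derive_seed(config$seed, id)
      pars <- draw_individual_params(config$truth[[grp]], seed = sd_i)
      T_i <- with_seed(derive_seed(sd_i, "length"),
                       sample(config$length_range[1]:config$length_range[2], 1L))
      trajectories[[id]] <- simulate_trajectory(
        pars, config$raster, T_i, start, config$constants,
        seed = derive_seed(sd_i, "path"), individual_id = id, treatment = grp)
      ind_truth[[id]] <- pars
    }
  }
  structure(list(trajectories = trajectories,
                 truth = list(individual = ind_truth,
                              treatment = config$truth),
                 raster = config$raster, constants = config$constants,
                 config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  tr <- vapply(x$trajectories, function(t) t$treatment, character(1))
  cat(sprintf("<simulated_study> %d trajectories in %d groups\n",
              length(x$trajectories), length(unique(tr))))
  print(table(tr))
  invisible(x)
}
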