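#' Fit the full two-state movement model
#'
#' The package's main entry point: runs the complete two-stage
#' proposal-recursive analysis. Stage 1 fits each individual's two-state
#' correlated random walk independently (probit data augmentation, conjugate
#' and prior-as-proposal updates); stage 2 recycles those draws as proposals
#' in the hierarchical model, estimating treatment-level means, variances
#' and the coefficient covariance; derived quantities (natural-scale group
#' means by Monte Carlo integration, individual-heterogeneity variances) are
#' then computed from the retained draws. Per-individual stage-1 seeds are
#' derived from the master seed and the individual's label, so results do
#' not depend on processing order.
#'
#' @param data A named list of [trajectory()] objects or a
#'   `simulated_study` (whose raster is used when `raster` is `NULL`).
#' @param raster A [categorical_raster()].
#' @param hyper A [hyper_priors()].
#' @param stage1_iter,stage2_iter Iteration counts (defaults 100,000 and
#'   50,000).
#' @param burn_frac Stage-2 burn-in fraction (default 0.1).
#' @param n_mc Monte Carlo integration size per retained iteration.
#' @param seed Master integer seed.
#' @param constants A [model_constants()].
#' @param verbose Print progress?
#' @return An object of class `movefit`.
#' @export
fit_movement <- function(data, raster = NULL, hyper = hyper_priors(),
                         stage1_iter = 100000L, stage2_iter = 50000L,
                         burn_frac = 0.1, n_mc = 1000L, seed = 1L,
                         constants = model_constants(), verbose = FALSE) {
  if (inherits(data, "simulated_study")) {
    if (is.null(raster)) raster <- data$raster
    data <- data$trajectories
  }
  if (is.null(raster)) stop("a landscape raster is required")
  if (is.null(names(data)) || any(names(data) == ""))
    names(data) <- vapply(data, function(t) t$individual_id, character(1))

  stage1 <- list()
  for (id in names(data)) {
    if (verbose) message("stage 1: ", id)
    stage1[[id]] <- fit_stage1(data[[id]], raster, priors = hyper$stage1,
                               n_iter = stage1_iter,
                               seed = derive_seed(seed, id),
                               constants = constants)
  }
  if (verbose) message("stage 2")
  stage2 <- fit_stage2(stage1, data, raster, hyper = hyper,
                       n_iter = stage2_iter, seed = derive_seed(seed, "stage2"),
                       burn_frac = burn_frac, constants = constants)
  if (verbose) message("derived quantities")
  derived <- derived_quantities(stage2, n_mc = n_mc,
                                seed = derive_seed(seed, "derived"))
  structure(list(stage1 = stage1, stage2 = stage2, derived = derived,
                 data = data, raster = raster, constants = constants,
                 hyper = hyper, seed = seed,
                 call = match.call()),
            class = "movefit")
}

#' @export
print.movefit <- function(x, ...) {
  cat("Two-state correlated random walk, hierarchical fit\n")
  cat(sprintf("  %d individuals, %d treatment groups\n",
              length(x$data), length(x$stage2$groups)))
  cat(sprintf("  stage 1: %d iterations/individual; stage 2: %d (%d burn-in)\n",
              x$stage1[[1L]]$n_iter, x$stage2$n_iter, x$stage2$burn))
  enc <- sum(x$stage2$encamped_only)
  if (enc > 0) cat(sprintf("  %d encamped-only individual(s)\n", enc))
  cat("\nTreatment-level posterior means (natural scales):\n")
  print(round(t(apply(x$derived$draws, c(2L, 3L), mean)), 3))
  invisible(x)
}

#' Summarise a fitted movement model
#'
#' @param object A [fit_movement()] result.
#' @param ci_level Credible level for intervals.
#' @param ... Unused.
#' @return A `summary.movefit` object: per-group derived-quantity summaries
#'   and all pairwise treatment comparisons with posterior probabilities.
#' @export
summary.movefit <- function(object, ci_level = 0.95, ...) {
  dq <- object$derived$draws
  qn <- dimnames(dq)[[2L]]
  groups <- dimnames(dq)[[3L]]
  tabs <- list()
  for (g in groups) {
    s <- t(apply(dq[, , g], 2L, summarize_draws, ci_level = ci_level))
    tabs[[g]] <- data.frame(quantity = qn, s, row.names = NULL)
  }
  structure(list(group_summaries = tabs,
                 comparisons = hypothesis_tests(object, ci_level = ci_level),
                 ci_level = ci_level),
            class = "summary.movefit")
}

#' @export
print.summary.movefit <- function(x, ...) {
  for (g in names(x$group_summaries)) {
    cat("==", g, "==\n")
    print(x$group_summaries[[g]], digits = 3)
  }
  cat("\nPairwise treatment comparisons (posterior mean difference,",
      "P(first > second)):\n")
  print(x$comparisons, digits = 3)
  invisible(x)
}

#' Pairwise treatment-group hypothesis tests
#'
#' For every derived quantity and every ordered pair of treatment groups,
#' the posterior mean difference, its credible interval, and the posterior
#' probability that the first group's parameter exceeds the second's.
#'
#' @param fit A [fit_movement()] result (or a `derived_draws` object).
#' @param ci_level Credible level.
#' @return A `data.frame` with one row per (quantity, group pair).
#' @export
hypothesis_tests <- function(fit, ci_level = 0.95) {
  dq <- if (inherits(fit, "movefit")) fit$derived$draws
        else if (inherits(fit, "derived_draws")) fit$draws
        else stop("`fit` must be a movefit or derived_draws")
  groups <- dimnames(dq)[[3L]]
  qn <- dimnames(dq)[[2L]]
  rows <- list()
  for (q in qn) {
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        ds <- difference_summary(dq[, q, a], dq[, q, b], ci_level)
        rows[[length(rows) + 1L]] <- data.frame(
          quantity = q, group_a = groups[a], group_b = groups[b],
          mean_diff = ds$mean_diff, lower = ds$lower, upper = ds$upper,
          prob_greater = ds$prob_greater)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
coef.movefit <- function(object, level = c("treatment", "individual"), ...) {
  level <- match.arg(level)
  if (level == "treatment") {
    keep <- (object$stage2$burn + 1L):object$stage2$n_iter
    t(apply(object$stage2$group[keep, , , drop = FALSE], c(2L, 3L), mean))
  } else {
    keep <- (object$stage2$burn + 1L):object$stage2$n_iter
    t(apply(object$stage2$individual[keep, , , drop = FALSE], c(2L, 3L), mean))
  }
}

#' @export
plot.movefit <- function(x, parameters = c("mu_logit_gamma", "mu_theta",
                                           "mu_log_sigma1"), ...) {
  groups <- x$stage2$groups
  old <- graphics::par(mfrow = c(length(parameters), 1),
                       mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (pn in parameters) {
    graphics::matplot(x$stage2$group[, pn, ], type = "l", lty = 1,
                      ylab = pn, xlab = "iteration",
                      main = paste("trace:", pn), ...)
    graphics::abline(v = x$stage2$burn, lty = 2)
    graphics::legend("topright", legend = groups, lty = 1,
                     col = seq_along(groups), bty = "n", cex = 0.7)
  }
  invisible(x)
}

#' Simulate trajectories from a fitted model
#'
#' Draws new individuals from the posterior-mean treatment-level
#' distributions and simulates their trajectories on the fitted landscape --
#' a posterior-predictive check of path morphology.
#'
#' @param object A [fit_movement()] result.
#' @param nsim Trajectories per treatment group.
#' @param seed Integer seed.
#' @param T_steps Relocations per simulated trajectory.
#' @param ... Unused.
#' @return A named list of [trajectory()] objects.
#' @export
simulate.movefit <- function(object, nsim = 1, seed = 1L, T_steps = 30L, ...) {
  cm <- coef(object, "treatment")
  cats <- landscape_categories()
  ext <- raster_extent(object$raster)
  start <- c((ext["xmin"] + ext["xmax"]) / 2, (ext["ymin"] + ext["ymax"]) / 2)
  out <- list()
  for (g in rownames(cm)) {
    tp <- treatment_params(
      mu_beta = cm[g, paste0("mu_beta.", cats)],
      Sigma_beta = make_pd(matrix(cm[g, grep("^Sigma_beta\\.",
                                             colnames(cm))], 4L, 4L)),
      mu_logit_gamma = cm[g, "mu_logit_gamma"],
      var_logit_gamma = cm[g, "var_logit_gamma"],
      mu_theta = cm[g, "mu_theta"], var_theta = cm[g, "var_theta"],
      mu_log_sigma1 = cm[g, "mu_log_sigma1"],
      var_log_sigma1 = cm[g, "var_log_sigma1"])
    for (i in seq_len(nsim)) {
      id <- sprintf("ppc_%s_%02d", g, i)
      sd_i <- derive_seed(seed, id)
      pars <- draw_individual_params(tp, seed = sd_i)
      out[[id]] <- simulate_trajectory(pars, object$raster, T_steps, start,
                                       object$constants,
                                       seed = derive_seed(sd_i, "path"),
                                       individual_id = id, treatment = g)
    }
  }
  out
}

# symmetrise and ridge a posterior-mean covariance so it is usable as a
# generating covariance
make_pd <- function(S) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-8)
  ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
}
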