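# Delimited-text interchange: trajectory tables, long-format draw tables,
# truth ledgers and YAML run configuration.

#' Write trajectories to a delimited table
#'
#' Schema: `individual_id, treatment, day, x, y`, one row per relocation,
#' ordered by individual then day (byte-stable given identical input).
#'
#' @param trajectories Named list of [trajectory()] (or a
#'   `simulated_study`, whose trajectories are taken).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "simulated_study"))
    trajectories <- trajectories$trajectories
  tabs <- lapply(trajectories[order(names(trajectories))], function(tr)
    data.table::data.table(individual_id = tr$individual_id,
                           treatment = tr$treatment, day = tr$days,
                           x = tr$positions[, 1L], y = tr$positions[, 2L]))
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Read trajectories from a delimited table
#'
#' Expects the [write_trajectories()] schema. Rows are grouped by individual
#' and sorted by day; nonconsecutive days are kept (they simply remove the
#' affected steps from the likelihood). Duplicate (individual, day) pairs,
#' non-numeric coordinates and unknown treatment labels are errors.
#'
#' @param path CSV path.
#' @return Named list of [trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character =
                                                    c("individual_id",
                                                      "treatment")))
  need <- c("individual_id", "treatment", "day", "x", "y")
  if (!all(need %in% names(dt)))
    stop("trajectory table must have columns: ", paste(need, collapse = ", "))
  for (col in c("day", "x", "y")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("non-numeric value in column `%s` at data row %d",
                   col, if (is.na(bad)) 1L else bad))
    }
  }
  bad_tr <- setdiff(unique(dt$treatment), treatment_levels())
  if (length(bad_tr))
    stop("unknown treatment label(s): ", paste(bad_tr, collapse = ", "))
  dup <- duplicated(dt[, c("individual_id", "day")])
  if (any(dup)) {
    d <- dt[which(dup)[1L], ]
    stop(sprintf("duplicate relocation for individual %s on day %d",
                 d$individual_id, as.integer(d$day)))
  }
  out <- list()
  for (id in unique(dt$individual_id)) {
    sub <- dt[dt$individual_id == id, ]
    sub <- sub[order(sub$day), ]
    out[[id]] <- trajectory(id, sub$treatment[1L], sub$day,
                            cbind(sub$x, sub$y))
  }
  out
}

#' Write MCMC draws in long format
#'
#' Long (tidy) schema: `stage, level, group, individual_id, parameter,
#' iteration, value`, lossless at full floating precision and byte-stable
#' for identical samples. Accepts a single [fit_stage1()] result or a
#' [fit_stage2()] result.
#'
#' @param samples A `stage1_fit` or `stage2_fit`.
#' @param path Output CSV path.
#' @param include_states For stage-1 fits, also write the latent-state draws
#'   (rows `parameter = "z<step>"`); requires the fit to have been run with
#'   `store_states = TRUE`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(samples, path, include_states = FALSE) {
  if (inherits(samples, "stage1_fit")) {
    d <- samples$draws
    dt <- data.table::data.table(
      stage = 1L, level = "individual", group = samples$treatment,
      individual_id = samples$individual_id,
      parameter = rep(colnames(d), each = nrow(d)),
      iteration = rep(seq_len(nrow(d)), ncol(d)),
      value = sprintf("%.17g", as.vector(d)))
    if (include_states) {
      if (is.null(samples$z_draws))
        stop("fit was run without `store_states = TRUE`; no state draws")
      z <- samples$z_draws
      dt <- rbind(dt, data.table::data.table(
        stage = 1L, level = "individual", group = samples$treatment,
        individual_id = samples$individual_id,
        parameter = rep(sprintf("z%d", seq_len(ncol(z))), each = nrow(z)),
        iteration = rep(seq_len(nrow(z)), ncol(z)),
        value = sprintf("%.17g", as.numeric(z))))
    }
  } else if (inherits(samples, "stage2_fit")) {
    parts <- list()
    for (id in samples$individual_ids) {
      d <- samples$individual[, , id]
      parts[[length(parts) + 1L]] <- data.table::data.table(
        stage = 2L, level = "individual",
        group = samples$group_of[[id]], individual_id = id,
        parameter = rep(colnames(d), each = nrow(d)),
        iteration = rep(seq_len(nrow(d)), ncol(d)),
        value = sprintf("%.17g", as.vector(d)))
    }
    for (g in samples$groups) {
      d <- samples$group[, , g]
      parts[[length(parts) + 1L]] <- data.table::data.table(
        stage = 2L, level = "treatment", group = g, individual_id = NA,
        parameter = rep(colnames(d), each = nrow(d)),
        iteration = rep(seq_len(nrow(d)), ncol(d)),
        value = sprintf("%.17g", as.vector(d)))
    }
    dt <- data.table::rbindlist(parts)
  } else stop("`samples` must be a stage1_fit or stage2_fit")
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a long-format draw table
#'
#' @param path CSV path written by [write_draws()].
#' @return A `data.frame` in the long draw schema.
#' @export
read_draws <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  need <- c("stage", "level", "group", "individual_id", "parameter",
            "iteration", "value")
  if (!all(need %in% names(dt)))
    stop("draw table must have columns: ", paste(need, collapse = ", "))
  dt$value <- as.numeric(dt$value)
  dt
}

# reshape a long stage-1 draw table back into the matrix the samplers use
draws_matrix_from_long <- function(df) {
  pars <- unique(df$parameter)
  its <- sort(unique(df$iteration))
  m <- matrix(NA_real_, length(its), length(pars),
              dimnames = list(NULL, pars))
  for (pn in pars) {
    sub <- df[df$parameter == pn, ]
    m[sub$iteration, pn] <- sub$value
  }
  m
}

#' Write the truth ledger of a simulated study
#'
#' Long schema: `level, group, individual_id, parameter, value` covering
#' every individual's true parameters and every group's treatment-level
#' truth.
#'
#' @param study A `simulated_study`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(study, path) {
  cats <- landscape_categories()
  parts <- list()
  for (id in sort(names(study$truth$individual))) {
    pr <- study$truth$individual[[id]]
    grp <- study$trajectories[[id]]$treatment
    parts[[length(parts) + 1L]] <- data.table::data.table(
      level = "individual", group = grp, individual_id = id,
      parameter = c(paste0("beta.", cats), "gamma", "theta", "sigma1_sq"),
      value = c(pr$beta, pr$gamma, pr$theta, pr$sigma1_sq))
  }
  for (g in names(study$truth$treatment)) {
    tp <- study$truth$treatment[[g]]
    parts[[length(parts) + 1L]] <- data.table::data.table(
      level = "treatment", group = g, individual_id = NA,
      parameter = c(paste0("mu_beta.", cats),
                    paste0("Sigma_beta.", rep(1:4, 4), ".", rep(1:4, each = 4)),
                    "mu_logit_gamma", "var_logit_gamma", "mu_theta",
                    "var_theta", "mu_log_sigma1", "var_log_sigma1"),
      value = c(tp$mu_beta, as.vector(tp$Sigma_beta), tp$mu_logit_gamma,
                tp$var_logit_gamma, tp$mu_theta, tp$var_theta,
                tp$mu_log_sigma1, tp$var_log_sigma1))
  }
  data.table::fwrite(data.table::rbindlist(parts), path)
  invisible(path)
}

#' Read a truth ledger
#'
#' @param path CSV path written by [write_truth()].
#' @return A `data.frame` in the truth-ledger schema.
#' @export
read_truth <- function(path) data.table::fread(path, data.table = FALSE)

#' Read a YAML run configuration
#'
#' Recognised keys (all optional, shown with defaults): `seed` (1),
#' `stage1_iterations` (100000), `stage2_iterations` (50000),
#' `burn_in_fraction` (0.1), `n_mc` (1000), `ci_level` (0.95), `paths:`
#' (`trajectories`, `raster`, `output_dir`), `simulation:` (`n_individuals`,
#' `length_range`, `raster_cols`, `raster_rows`, `cell_size`), and `priors:`
#' overrides passed to [hyper_priors()] (e.g. `beta_cov_model: diag`).
#'
#' @param path YAML file path.
#' @return A `run_config` list with all defaults filled in.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- list(seed = 1L, stage1_iterations = 100000L,
              stage2_iterations = 50000L, burn_in_fraction = 0.1,
              n_mc = 1000L, ci_level = 0.95,
              paths = list(trajectories = "trajectories.csv",
                           raster = "landscape.asc",
                           output_dir = "output"),
              simulation = list(n_individuals = c(29L, 32L, 23L),
                                length_range = c(5L, 77L),
                                raster_cols = 600L, raster_rows = 600L,
                                cell_size = 0.7),
              priors = list())
  for (k in names(raw)) {
    if (k %in% c("paths", "simulation") && is.list(raw[[k]]))
      cfg[[k]][names(raw[[k]])] <- raw[[k]]
    else cfg[[k]] <- raw[[k]]
  }
  cfg$hyper <- do.call(hyper_priors, cfg$priors)
  class(cfg) <- "run_config"
  cfg
}
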