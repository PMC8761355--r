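# Shared fixtures, all built in code at test time.

# small mixed landscape
tiny_raster <- function(n = 40, cell = 2, seed = 11) {
  generate_synthetic_raster(n, n, cell_size = cell, seed = seed)
}

# landscape that is a single category everywhere
uniform_raster <- function(category = "grass", n = 60, cell = 5) {
  code <- match(category, landscape_categories())
  categorical_raster(matrix(code, n, n), cell_size = cell)
}

# a short hand-built trajectory with known displacements
toy_trajectory <- function(deltas, start = c(100, 100), days = NULL,
                           treatment = "resident", id = "toy") {
  pos <- rbind(start, start + apply(deltas, 2L, cumsum))
  if (is.null(days)) days <- seq_len(nrow(pos))
  trajectory(id, treatment, days, pos)
}

# standard simulated individual for recovery-style tests
sim_individual <- function(T_steps = 120, beta = c(0.3, -0.2, 0.5, 0),
                           gamma = 0.6, theta = pi, sigma1_sq = 625,
                           seed = 5, raster = NULL) {
  if (is.null(raster)) raster <- tiny_raster(60, 5, seed = 2)
  pars <- individual_params(beta, gamma, theta, sigma1_sq)
  ext <- raster_extent(raster)
  tr <- simulate_trajectory(pars, raster, T_steps,
                            c(mean(ext[1:2]), mean(ext[3:4])),
                            seed = seed)
  list(traj = tr, params = pars, raster = raster)
}

# equal-tailed interval coverage helper
ci_covers <- function(draws, truth, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), names = FALSE)
  truth >= q[1] && truth <= q[2]
}
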