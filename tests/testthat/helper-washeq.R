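# Shared fixtures, built in code at test time.

# compact trial scenario for fast tests
small_scenario <- function(...) {
  trial_scenario(n_blocks = 20L, compounds_per_cluster = 8L, ...)
}

# simulate and join the estimated wealth index onto observations
simulate_with_wealth <- function(scenario = small_scenario(), seed = 1L) {
  sim <- simulate_trial(scenario, seed = seed)
  w <- wealth_index(sim$assets)
  obs <- merge(sim$observations,
               w[, c("compound_id", "rank", "tertile")],
               by = "compound_id", sort = FALSE)
  list(obs = obs, sim = sim, wealth = w)
}

# independent data with prevalence p(r) = base * exp(slope * r),
# ranks uniform, observations grouped into blocks
make_loglinear_data <- function(n, base = 0.08, slope = -0.8,
                                n_blocks = 100, seed = 1) {
  set.seed(seed)
  r <- runif(n)
  data.frame(
    y = rbinom(n, 1, base * exp(slope * r)),
    r = r,
    block = sample(sprintf("b%03d", seq_len(n_blocks)), n, replace = TRUE)
  )
}

# a degenerate spline_curve whose PD is identically zero: real fitted
# basis, zeroed coefficients
zero_pd_curve <- function() {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 10L), seed = 42)$obs
  cv <- fit_wealth_spline(d, "pd")
  cv$coef[] <- 0
  cv$vcov[] <- 0
  diag(cv$vcov) <- 1e-12
  cv$grid$est[] <- 0
  cv
}

# tiny raster fixture on a shared 3 x 3 grid
toy_layers <- function(pop = matrix(c(100, 200, 0,
                                      50, 400, 300,
                                      10, 0, 250), 3, 3, byrow = TRUE)) {
  wealth <- grid_layer(matrix(1:9, 3, 3), role = "wealth")
  population <- grid_layer(pop, role = "population")
  urban <- grid_layer(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3,
                             byrow = TRUE), role = "urban-mask")
  district <- grid_layer(matrix(c(1, 1, 2, 1, 1, 2, 2, 2, 2), 3, 3,
                                byrow = TRUE), role = "district-id")
  list(wealth = wealth, population = population, urban = urban,
       district = district)
}
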