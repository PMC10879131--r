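#' Simulate a cluster-randomized WASH trial
#'
#' Generates the full design hierarchy block -> cluster -> compound ->
#' child -> observation.  Each compound draws a latent wealth factor once;
#' household assets are generated from it per the scenario's asset
#' specification (binary assets by thresholding `loading * latent + noise`
#' at zero, continuous assets affine in the latent).  Each observation's
#' 7-day diarrhea indicator is Bernoulli with the scenario cell
#' probability for its (arm, season, true wealth tertile), where the true
#' tertile cuts the latent wealth distribution at its empirical terciles.
#' Season is drawn per observation with probability `monsoon_fraction` and
#' a calendar date consistent with the drawn season is attached (survey
#' rounds 1 and 2 map to 2014 and 2015 with the trial's monsoon windows).
#'
#' @param scenario A [trial_scenario()].
#' @param seed Integer seed; identical (scenario, seed) pairs give
#'   identical output.
#' @return A list with components
#'   \describe{
#'     \item{observations}{data frame, one row per child-visit:
#'       `child_id`, `compound_id`, `cluster_id`, `block_id`,
#'       `assignment` (control/wsh/wshn), `arm` (control/intervention),
#'       `round`, `date`, `season`, `diarrhea`.}
#'     \item{assets}{data frame, one row per compound: `compound_id` plus
#'       one column per asset (binary 0/1 or continuous; NA = missing).}
#'     \item{truth}{data frame per compound with the generating
#'       `latent_wealth`, `true_rank` and `true_tertile`, for recovery
#'       tests.}
#'   }
#' @export
#' @examples
#' sim <- simulate_trial(trial_scenario(n_blocks = 4), seed = 1)
#' table(sim$observations$arm)
simulate_trial <- function(scenario, seed = 1L) {
  if (!inherits(scenario, "trial_scenario"))
    stop("`scenario` must be a trial_scenario object")
  set.seed(as.integer(seed))
  sc <- scenario
  n_per_block <- sum(sc$allocation)

  # cluster frame: arm assignment within each matched block
  assignment <- rep(
    rep(c("control", "wsh", "wshn"), times = sc$allocation),
    times = sc$n_blocks
  )
  cluster <- data.frame(
    cluster_id = sprintf("c%04d", seq_len(sc$n_blocks * n_per_block)),
    block_id = sprintf("b%03d", rep(seq_len(sc$n_blocks), each = n_per_block)),
    assignment = assignment,
    arm = ifelse(assignment == "control", "control", "intervention"),
    stringsAsFactors = FALSE
  )

  # compounds, one index child each
  n_comp <- nrow(cluster) * sc$compounds_per_cluster
  compound <- data.frame(
    compound_id = sprintf("h%05d", seq_len(n_comp)),
    cluster_id = rep(cluster$cluster_id, each = sc$compounds_per_cluster),
    stringsAsFactors = FALSE
  )
  compound$block_id <- cluster$block_id[match(compound$cluster_id, cluster$cluster_id)]
  compound$assignment <- cluster$assignment[match(compound$cluster_id, cluster$cluster_id)]
  compound$arm <- cluster$arm[match(compound$cluster_id, cluster$cluster_id)]

  # latent wealth, drawn once per compound; true tertile from empirical ranks
  latent <- rnorm(n_comp, 0, sc$wealth_latent_sd)
  wr <- rank_and_tertiles(data.frame(compound_id = compound$compound_id,
                                     score = latent))
  truth <- data.frame(
    compound_id = compound$compound_id,
    latent_wealth = latent,
    true_rank = wr$rank,
    true_tertile = wr$tertile,
    stringsAsFactors = FALSE
  )

  assets <- .simulate_assets(sc$asset_spec, latent, compound$compound_id)

  # cluster-level random intercept on the logit scale (default off)
  cl_re <- if (sc$cluster_re_sd > 0)
    setNames(rnorm(nrow(cluster), 0, sc$cluster_re_sd), cluster$cluster_id)
  else setNames(rep(0, nrow(cluster)), cluster$cluster_id)

  # observations: child = index child of the compound
  m <- sc$measurements_per_child
  obs <- compound[rep(seq_len(n_comp), each = m),
                  c("compound_id", "cluster_id", "block_id", "assignment", "arm")]
  obs$child_id <- sub("^h", "k", obs$compound_id)
  obs$round <- rep(seq_len(m), times = n_comp)
  obs$season <- ifelse(runif(nrow(obs)) < sc$monsoon_fraction,
                       "monsoon", "dry")
  obs$date <- .season_consistent_date(obs$round, obs$season)
  tert <- as.character(truth$true_tertile[match(obs$compound_id,
                                                truth$compound_id)])
  p <- sc$cell_prevalence[cbind(obs$arm, obs$season, tert)]
  if (sc$cluster_re_sd > 0) {
    eta <- qlogis_safe(p) + cl_re[obs$cluster_id]
    p <- 1 / (1 + exp(-eta))
  }
  obs$diarrhea <- rbinom(nrow(obs), 1L, p)
  rownames(obs) <- NULL
  obs <- obs[, c("child_id", "compound_id", "cluster_id", "block_id",
                 "assignment", "arm", "round", "date", "season", "diarrhea")]

  list(observations = obs, assets = assets, truth = truth)
}

# logit that tolerates p = 0 or 1 by clamping
qlogis_safe <- function(p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

.simulate_assets <- function(spec, latent, compound_id) {
  out <- data.frame(compound_id = compound_id, stringsAsFactors = FALSE)
  n <- length(latent)
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    noise <- if (s$noise > 0) rnorm(n, 0, s$noise) else rep(0, n)
    val <- s$loading * latent + noise
    x <- if (s$type == "binary") as.numeric(val > 0) else val
    if (s$missing > 0) x[runif(n) < s$missing] <- NA
    out[[s$name]] <- x
  }
  out
}

# rounds 1/2 -> study years 2014/2015; dates drawn uniformly inside (monsoon)
# or outside (dry) that year's trial monsoon window, so label_season() with
# the built-in calendar reproduces the drawn season
.season_consistent_date <- function(round, season) {
  year <- ifelse(round %% 2L == 1L, 2014L, 2015L)
  cal <- trial_season_calendar()
  out <- rep(as.Date(NA), length(round))
  for (yr in unique(year)) {
    days <- seq(as.Date(sprintf("%d-01-01", yr)),
                as.Date(sprintf("%d-12-31", yr)), by = "day")
    row <- cal[cal$year == yr, ]
    inside <- days >= row$start & days <= row$end
    idx <- which(year == yr)
    mon <- season[idx] == "monsoon"
    pick_in <- days[inside]
    pick_out <- days[!inside]
    out[idx[mon]] <- sample(pick_in, sum(mon), replace = TRUE)
    out[idx[!mon]] <- sample(pick_out, sum(!mon), replace = TRUE)
  }
  out
}
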