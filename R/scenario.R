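#' Default cell prevalence table for the synthetic trial
#'
#' Seven-day diarrhea prevalence for each (arm, season, wealth tertile)
#' cell of the default scenario.  Values follow the reported trial strata:
#' control monsoon prevalences of 10.3%/8.5%/6.1% across tertiles
#' (averaging 8.3%), control dry at roughly half the monsoon level, and a
#' flat intervention prevalence (4.6% monsoon, 4.0% dry) reflecting the
#' absence of a wealth gradient and of a seasonal surge under intervention.
#'
#' @return A 3-d numeric array with dimensions `arm` (control,
#'   intervention), `season` (dry, monsoon) and `tertile` (T1, T2, T3;
#'   T1 = lowest socioeconomic position).
#' @export
#' @examples
#' default_cell_prevalence()["control", "monsoon", "T1"]  # 0.103
default_cell_prevalence <- function() {
  arr <- array(
    NA_real_, dim = c(2L, 2L, 3L),
    dimnames = list(
      arm     = c("control", "intervention"),
      season  = c("dry", "monsoon"),
      tertile = c("T1", "T2", "T3")
    )
  )
  arr["control", "monsoon", ] <- c(0.103, 0.085, 0.061)
  arr["control", "dry",     ] <- c(0.052, 0.043, 0.031)
  arr["intervention", "monsoon", ] <- c(0.046, 0.046, 0.046)
  arr["intervention", "dry",     ] <- c(0.040, 0.040, 0.040)
  arr
}

#' Default asset specification for the synthetic asset table
#'
#' One row per asset: name, type (binary/continuous), loading on the
#' latent wealth factor, noise scale, and missingness fraction.  The list
#' mirrors the asset block of a rural Bangladesh household survey (land,
#' housing materials, electricity, durable goods); `chouki` (a low wooden
#' stool) loads negatively, as squat furniture is associated with manual
#' labour.  Two screening probes are included on purpose: `radio` is
#' constant (zero variance) and `clock` carries 12% missingness, so the
#' default pipeline exercises the variable-exclusion rules.  `own_latrine`
#' and `store_water` are WASH-related and named in the default exclusion
#' list.
#'
#' @return A data frame with columns `name`, `type`, `loading`, `noise`,
#'   `missing`.
#' @export
default_asset_spec <- function() {
  spec <- rbind(
    data.frame(name = "land_acres",     type = "continuous", loading = 0.70, noise = 0.70, missing = 0.02),
    data.frame(name = "improved_wall",  type = "binary",     loading = 0.80, noise = 0.60, missing = 0.00),
    data.frame(name = "improved_floor", type = "binary",     loading = 0.70, noise = 0.70, missing = 0.00),
    data.frame(name = "electricity",    type = "binary",     loading = 0.90, noise = 0.50, missing = 0.00),
    data.frame(name = "refrigerator",   type = "binary",     loading = 0.80, noise = 0.60, missing = 0.00),
    data.frame(name = "bicycle",        type = "binary",     loading = 0.40, noise = 0.90, missing = 0.01),
    data.frame(name = "motorcycle",     type = "binary",     loading = 0.60, noise = 0.80, missing = 0.00),
    data.frame(name = "sewing_machine", type = "binary",     loading = 0.50, noise = 0.90, missing = 0.00),
    data.frame(name = "television",     type = "binary",     loading = 0.85, noise = 0.55, missing = 0.00),
    data.frame(name = "wardrobe",       type = "binary",     loading = 0.70, noise = 0.70, missing = 0.01),
    data.frame(name = "table",          type = "binary",     loading = 0.60, noise = 0.80, missing = 0.00),
    data.frame(name = "chair",          type = "binary",     loading = 0.60, noise = 0.80, missing = 0.00),
    data.frame(name = "khat",           type = "binary",     loading = 0.80, noise = 0.60, missing = 0.00),
    data.frame(name = "chouki",         type = "binary",     loading = -0.40, noise = 0.90, missing = 0.00),
    data.frame(name = "mobile",         type = "binary",     loading = 0.50, noise = 0.90, missing = 0.00),
    data.frame(name = "radio",          type = "binary",     loading = 0.00, noise = 0.00, missing = 0.00),
    data.frame(name = "clock",          type = "binary",     loading = 0.40, noise = 0.90, missing = 0.12),
    data.frame(name = "own_latrine",    type = "binary",     loading = 0.50, noise = 0.90, missing = 0.00),
    data.frame(name = "store_water",    type = "binary",     loading = 0.30, noise = 1.00, missing = 0.00)
  )
  rownames(spec) <- NULL
  spec
}

#' Asset names excluded from the wealth index by default
#'
#' WASH-related assets are excluded from wealth-index construction (per
#' UNICEF guidance for WASH studies) so the index is not confounded with
#' the intervention's own targets.
#'
#' @return Character vector of asset names.
#' @export
default_wash_exclusions <- function() c("own_latrine", "store_water")

#' Describe a synthetic cluster-randomized trial
#'
#' Bundles the design constants of the emulated trial: 90 matched blocks
#' of 4 clusters allocated 2:1:1 to control, combined WSH and WSH+N (the
#' latter two pooled as "intervention"), 12 study compounds per cluster,
#' one index child per compound with 2 diarrhea measurements, and the
#' (arm, season, tertile) cell prevalences of
#' [default_cell_prevalence()].
#'
#' @param n_blocks Number of matched randomization blocks.
#' @param allocation Integer vector `c(control, wsh, wshn)` of clusters
#'   per block by assignment; the last two form the intervention arm.
#' @param compounds_per_cluster Compounds (households) per cluster; one
#'   index child per compound.
#' @param measurements_per_child Repeated diarrhea measurements per child.
#' @param cell_prevalence 3-d array `arm x season x tertile` of outcome
#'   probabilities, as from [default_cell_prevalence()].
#' @param wealth_latent_sd Standard deviation of the latent compound
#'   wealth factor.
#' @param asset_spec Data frame as from [default_asset_spec()].
#' @param monsoon_fraction Probability that a measurement falls in the
#'   monsoon season (default 0.473, the trial's marginal split).
#' @param cluster_re_sd Optional SD of a cluster-level random intercept on
#'   the logit scale (default 0 = off; the trial papers do not report a
#'   within-cluster correlation).
#' @return An object of class `trial_scenario`.
#' @export
trial_scenario <- function(n_blocks = 90L,
                           allocation = c(control = 2L, wsh = 1L, wshn = 1L),
                           compounds_per_cluster = 12L,
                           measurements_per_child = 2L,
                           cell_prevalence = default_cell_prevalence(),
                           wealth_latent_sd = 1,
                           asset_spec = default_asset_spec(),
                           monsoon_fraction = 0.473,
                           cluster_re_sd = 0) {
  stopifnot(n_blocks >= 1, compounds_per_cluster >= 1,
            measurements_per_child >= 1)
  if (length(allocation) != 3L || any(allocation < 1) ||
      any(allocation != round(allocation)))
    stop("`allocation` must be three positive integers (control, wsh, wshn)")
  if (!is.array(cell_prevalence) ||
      !identical(dim(cell_prevalence), c(2L, 2L, 3L)))
    stop("`cell_prevalence` must be a 2 x 2 x 3 array (arm x season x tertile)")
  if (anyNA(cell_prevalence))
    stop("all (arm, season, tertile) cell probabilities must be supplied")
  if (any(cell_prevalence < 0 | cell_prevalence > 1))
    stop("cell probabilities must lie in [0, 1]")
  if (monsoon_fraction < 0 || monsoon_fraction > 1)
    stop("`monsoon_fraction` must lie in [0, 1]")
  if (wealth_latent_sd <= 0) stop("`wealth_latent_sd` must be positive")
  req <- c("name", "type", "loading", "noise", "missing")
  if (!all(req %in% names(asset_spec)))
    stop("`asset_spec` needs columns: ", paste(req, collapse = ", "))
  if (any(asset_spec$missing < 0 | asset_spec$missing >= 1))
    stop("asset missingness fractions must lie in [0, 1)")
  if (!all(asset_spec$type %in% c("binary", "continuous")))
    stop("asset types must be 'binary' or 'continuous'")
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      allocation = setNames(as.integer(allocation),
                            c("control", "wsh", "wshn")),
      compounds_per_cluster = as.integer(compounds_per_cluster),
      measurements_per_child = as.integer(measurements_per_child),
      cell_prevalence = cell_prevalence,
      wealth_latent_sd = wealth_latent_sd,
      asset_spec = asset_spec,
      monsoon_fraction = monsoon_fraction,
      cluster_re_sd = cluster_re_sd
    ),
    class = "trial_scenario"
  )
}

#' @export
print.trial_scenario <- function(x, ...) {
  nclus <- x$n_blocks * sum(x$allocation)
  nobs <- x$n_blocks * sum(x$allocation) * x$compounds_per_cluster *
    x$measurements_per_child
  cat("Synthetic cluster-randomized WASH trial scenario\n")
  cat(sprintf("  %d blocks x %d clusters (allocation %s) = %d clusters\n",
              x$n_blocks, sum(x$allocation),
              paste(x$allocation, collapse = ":"), nclus))
  cat(sprintf("  %d compounds/cluster, %d measurements/child -> %d observations\n",
              x$compounds_per_cluster, x$measurements_per_child, nobs))
  cat(sprintf("  monsoon fraction %.3f; %d assets; cluster RE sd %.2f\n",
              x$monsoon_fraction, nrow(x$asset_spec), x$cluster_re_sd))
  invisible(x)
}

#' Describe a synthetic raster landscape
#'
#' Parameters of the gridded fixture layers (wealth surface, population,
#' urban mask, district partition) used to exercise the burden-projection
#' stage without national data downloads.
#'
#' @param nrow,ncol Grid dimensions (cells).
#' @param cellsize Cell edge length in map units.
#' @param origin Numeric `c(xmin, ymin)` of the lower-left corner.
#' @param wealth_corr_length Correlation length (in cells) of the smooth
#'   wealth surface; the surface is white noise smoothed with a moving
#'   average of this half-width.
#' @param pop_mean,pop_dispersion Mean and negative-binomial dispersion
#'   (size) of people per cell.
#' @param urban_fraction Fraction of cells flagged urban.
#' @param n_districts Number of contiguous districts partitioning the grid.
#' @return An object of class `raster_scenario`.
#' @export
raster_scenario <- function(nrow = 40L, ncol = 40L, cellsize = 1,
                            origin = c(0, 0),
                            wealth_corr_length = 4,
                            pop_mean = 250, pop_dispersion = 1.5,
                            urban_fraction = 0.1,
                            n_districts = 8L) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0, n_districts >= 1,
            pop_mean >= 0, pop_dispersion > 0, wealth_corr_length >= 0)
  if (urban_fraction < 0 || urban_fraction > 1)
    stop("`urban_fraction` must lie in [0, 1]")
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         cellsize = cellsize, origin = origin,
         wealth_corr_length = wealth_corr_length,
         pop_mean = pop_mean, pop_dispersion = pop_dispersion,
         urban_fraction = urban_fraction,
         n_districts = as.integer(n_districts)),
    class = "raster_scenario"
  )
}

#' @export
print.raster_scenario <- function(x, ...) {
  cat(sprintf("Synthetic raster scenario: %d x %d grid, %d districts, urban fraction %.2f\n",
              x$nrow, x$ncol, x$n_districts, x$urban_fraction))
  invisible(x)
}
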