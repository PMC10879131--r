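#' Default pipeline configuration
#'
#' Returns the configuration list for a full synthetic end-to-end run at
#' the default study conditions.  Every block can be overridden via
#' `run_pipeline(config = modifyList(default_config(), list(...)))` or a
#' YAML file with the same structure.
#'
#' @param seed Integer seed recorded in the manifest and used for every
#'   random draw.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    mode = "synthetic",
    seed = as.integer(seed),
    scenario = list(),          # overrides to trial_scenario()
    raster_scenario = list(),   # overrides to raster_scenario()
    paths = list(),             # user-data mode: observations, assets, rasters
    wealth = list(missing_threshold = 0.10, variance_floor = 0.01,
                  anchor = "electricity"),
    spline = list(k = 10, season_filter = "monsoon"),
    projection = list(enabled = TRUE, min_children = 2, weeks_per_month = 4,
                      frac_0_14 = 0.31, frac_u3_of_0_14 = 3 / 14)
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data simulation (or loading), wealth
#' index construction, inequality indices per arm, stratum effects
#' (wealth tertile, season, joint) with additive and multiplicative
#' interaction tests, the penalized-spline PD curve over wealth rank, and
#' (if enabled) the gridded burden projection.  Every stage's tabular
#' output is written as CSV under `outdir`, rasters as ESRI ASCII grids,
#' and a JSON manifest records the configuration, seed and an MD5 hash of
#' every output file, so identical (config, seed) runs are byte-identical.
#'
#' @param config Configuration list (see [default_config()]) or path to
#'   a YAML file with the same structure.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`wealth`, `inequality`, `effects`, `interactions`, `curve`,
#'   `projection`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("washeq_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_config(), config)
  .validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  out_files <- character()
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    out_files <<- c(out_files, p)
    p
  }

  # -- stage 1: data -------------------------------------------------------
  if (config$mode == "synthetic") {
    scn <- do.call(trial_scenario, config$scenario)
    sim <- simulate_trial(scn, seed = seed)
    obs <- sim$observations
    assets <- sim$assets
  } else {
    obs <- read.csv(config$paths$observations, stringsAsFactors = FALSE)
    assets <- read.csv(config$paths$assets, stringsAsFactors = FALSE)
  }
  emit(obs, "observations.csv")
  emit(assets, "assets.csv")

  # -- stage 2: wealth index ----------------------------------------------
  w <- config$wealth
  wres <- wealth_index(assets, missing_threshold = w$missing_threshold,
                       variance_floor = w$variance_floor,
                       anchor = w$anchor)
  emit(wres, "wealth.csv")
  emit(data.frame(asset = names(attr(wres, "loadings")),
                  loading = as.numeric(attr(wres, "loadings"))),
       "loadings.csv")
  obs <- merge(obs, wres[, c("compound_id", "rank", "tertile")],
               by = "compound_id", sort = FALSE)

  # -- stage 3: inequality indices ----------------------------------------
  ineq <- arm_inequality(obs)
  emit(ineq, "inequality.csv")

  # -- stage 4: stratum effects + interaction tests -----------------------
  effects <- list(
    overall = estimate_stratum_effects(obs),
    tertile = estimate_stratum_effects(obs, by = "tertile"),
    season = estimate_stratum_effects(obs, by = "season"),
    joint = estimate_stratum_effects(obs, by = c("tertile", "season"))
  )
  emit(effects$overall, "effects_overall.csv")
  emit(effects$tertile, "effects_tertile.csv")
  emit(effects$season, "effects_season.csv")
  emit(effects$joint, "effects_joint.csv")
  inter <- do.call(rbind, lapply(
    list(list(m = "tertile"), list(m = "season"),
         list(m = c("tertile", "season"))),
    function(s) do.call(rbind, lapply(c("additive", "multiplicative"),
      function(sc) {
        t <- interaction_test(obs, s$m, scale = sc)
        data.frame(modifiers = paste(t$modifiers, collapse = " x "),
                   scale = t$scale, statistic = t$statistic,
                   df1 = t$df1, df2 = t$df2, p_value = t$p_value,
                   flag = t$flag)
      }))))
  emit(inter, "interactions.csv")

  # -- stage 5: spline PD curve -------------------------------------------
  curve <- fit_wealth_spline(obs, quantity = "pd",
                             season_filter = config$spline$season_filter,
                             k = config$spline$k)
  emit(curve$grid, "spline_curve.csv")
  curve_path <- file.path(outdir, "spline_curve.rds")
  saveRDS(curve, curve_path)
  out_files <- c(out_files, curve_path)

  # -- stage 6: burden projection -----------------------------------------
  projection <- NULL
  if (isTRUE(config$projection$enabled)) {
    pj <- config$projection
    if (config$mode == "synthetic") {
      rscn <- do.call(raster_scenario, config$raster_scenario)
      layers <- simulate_rasters(rscn, seed = seed + 1L)
    } else {
      layers <- lapply(config$paths$rasters, read_asc)
    }
    children <- children_under3_layer(layers$population,
                                      frac_0_14 = pj$frac_0_14,
                                      frac_u3_of_0_14 = pj$frac_u3_of_0_14)
    mask <- build_mask(layers$urban, children,
                       min_children = pj$min_children)
    rankl <- wealth_rank_layer(layers$wealth, mask)
    projection <- project_cases(curve, rankl, children, mask,
                                districts = layers$district,
                                weeks_per_month = pj$weeks_per_month)
    for (nm in names(layers)) {
      p <- file.path(outdir, paste0(nm, ".asc"))
      write_asc(layers[[nm]], p); out_files <- c(out_files, p)
    }
    p <- file.path(outdir, "cases.asc")
    write_asc(projection$cases, p); out_files <- c(out_files, p)
    emit(projection$district, "district.csv")
    emit(projection$national, "national.csv")
  }

  # -- manifest ------------------------------------------------------------
  manifest <- list(
    package = "washeq",
    seed = seed,
    mode = config$mode,
    config = config,
    outputs = lapply(setNames(nm = basename(out_files)), function(f)
      unname(tools::md5sum(file.path(outdir, f))))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(observations = obs, wealth = wres, inequality = ineq,
                 effects = effects, interactions = inter, curve = curve,
                 projection = projection, manifest = manifest,
                 outdir = outdir))
}

.validate_config <- function(config) {
  if (!config$mode %in% c("synthetic", "user-data"))
    stop("mode must be 'synthetic' or 'user-data'")
  if (config$mode == "user-data") {
    need <- c("observations", "assets")
    miss <- setdiff(need, names(config$paths))
    if (length(miss) > 0)
      stop("user-data mode needs paths: ", paste(miss, collapse = ", "))
    for (p in unlist(config$paths))
      if (!file.exists(p)) stop("input path does not exist: ", p)
    if (isTRUE(config$projection$enabled) &&
        is.null(config$paths$rasters))
      stop("projection enabled but no raster inputs configured")
  }
  invisible(TRUE)
}
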