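#' A lightweight in-memory raster layer
#'
#' A 2-d value grid with an affine georeference (lower-left origin and
#' square cell size) and an explicit nodata convention: missing cells are
#' `NA` in memory and written as the `nodata` sentinel on disk.  All
#' layers entering a projection must share shape and georeference exactly
#' (checked, never silently resampled).
#'
#' @param values Numeric matrix (row 1 = northernmost row, as stored in
#'   ESRI ASCII grids).
#' @param xmin,ymin Coordinates of the lower-left corner.
#' @param cellsize Cell edge length in map units.
#' @param nodata Sentinel value used on disk for missing cells.
#' @param role Optional semantic role label (e.g. `"wealth"`,
#'   `"population"`, `"urban-mask"`, `"district-id"`, `"cases"`).
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                       nodata = -9999, role = NA_character_) {
  values <- as.matrix(values)
  if (length(values) == 0) stop("zero-area grid")
  storage.mode(values) <- "double"
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cellsize = cellsize, nodata = nodata, role = role),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("grid_layer%s: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              if (is.na(x$role)) "" else paste0(" [", x$role, "]"),
              nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymin))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: min %g, mean %g, max %g; %d NA cells\n",
                min(v), mean(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

# shared-grid guard: shape and georeference must match exactly
check_same_grid <- function(...) {
  layers <- list(...)
  ref <- layers[[1]]
  for (l in layers[-1]) {
    if (!identical(dim(l$values), dim(ref$values)) ||
        !isTRUE(all.equal(c(l$xmin, l$ymin, l$cellsize),
                          c(ref$xmin, ref$ymin, ref$cellsize))))
      stop("layers do not share grid shape and georeference")
  }
  invisible(TRUE)
}

#' Write / read a grid layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by the value
#' rows, north to south.
#'
#' @param layer A [grid_layer()].
#' @param path File path (conventionally `.asc`).
#' @return `write_asc` invisibly returns `path`; `read_asc` returns a
#'   `grid_layer`.
#' @export
write_asc <- function(layer, path) {
  stopifnot(inherits(layer, "grid_layer"))
  v <- layer$values
  v[is.na(v)] <- layer$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", layer$xmin),
    sprintf("yllcorner %.10g", layer$ymin),
    sprintf("cellsize %.10g", layer$cellsize),
    sprintf("NODATA_value %.10g", layer$nodata)
  )
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE,
                                               digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  ncols <- as.integer(val(1)); nrows <- as.integer(val(2))
  xll <- val(3); yll <- val(4); cs <- val(5); nodata <- val(6)
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  stopifnot(nrow(m) == nrows, ncol(m) == ncols)
  m[m == nodata] <- NA
  grid_layer(m, xmin = xll, ymin = yll, cellsize = cs, nodata = nodata)
}

#' Simulate the raster fixture layers
#'
#' Generates four layers sharing one grid: a smooth wealth surface
#' (white noise smoothed by a moving average of half-width
#' `wealth_corr_length`), a nonnegative negative-binomial population
#' layer, a binary urban mask occupying approximately the requested
#' fraction of cells (the top quantile of a second smooth surface, so
#' urban areas are spatially coherent), and a district partition by
#' nearest seed point (Voronoi on the grid), contiguous and covering
#' every cell.
#'
#' @param scenario A [raster_scenario()].
#' @param seed Integer seed.
#' @return Named list of `grid_layer`s: `wealth`, `population`, `urban`,
#'   `district`.
#' @export
simulate_rasters <- function(scenario, seed = 1L) {
  if (!inherits(scenario, "raster_scenario"))
    stop("`scenario` must be a raster_scenario object")
  set.seed(as.integer(seed))
  nr <- scenario$nrow; nc <- scenario$ncol
  gl <- function(m, role) grid_layer(m, xmin = scenario$origin[1],
                                     ymin = scenario$origin[2],
                                     cellsize = scenario$cellsize,
                                     role = role)
  wealth <- smooth_surface(nr, nc, scenario$wealth_corr_length)
  pop <- matrix(rnbinom(nr * nc, size = scenario$pop_dispersion,
                        mu = scenario$pop_mean), nr, nc)
  urban <- matrix(0, nr, nc)
  if (scenario$urban_fraction > 0) {
    u <- smooth_surface(nr, nc, max(1, scenario$wealth_corr_length))
    thr <- quantile(u, 1 - scenario$urban_fraction, names = FALSE)
    urban[u >= thr] <- 1
  }
  # districts: nearest seed point in cell coordinates
  k <- scenario$n_districts
  sr <- runif(k, 0.5, nr + 0.5); sc_ <- runif(k, 0.5, nc + 0.5)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dist2 <- array(NA_real_, c(nr, nc, k))
  for (j in seq_len(k))
    dist2[, , j] <- (rows - sr[j])^2 + (cols - sc_[j])^2
  district <- apply(dist2, c(1, 2), which.min)
  list(wealth = gl(wealth, "wealth"),
       population = gl(pop, "population"),
       urban = gl(urban, "urban-mask"),
       district = gl(district, "district-id"))
}

# moving-average smoothing of white noise; half-width L cells (L = 0
# returns the white noise unchanged), rescaled to unit variance
smooth_surface <- function(nr, nc, L) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  L <- as.integer(round(L))
  if (L <= 0) return(z)
  w <- 2L * L + 1L
  # separable box filter with edge renormalization via padding by counts
  sm_rows <- apply(z, 2, function(col) box_mean(col, L))
  sm <- t(apply(sm_rows, 1, function(row) box_mean(row, L)))
  (sm - mean(sm)) / sd(sm)
}

box_mean <- function(x, L) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - L, 1)
  hi <- pmin(seq_len(n) + L, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
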