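test_that("children layer applies the demographic multipliers", {
  pop <- grid_layer(matrix(c(0, 1000), 1, 2))
  ch <- children_under3_layer(pop)
  expect_equal(ch$values[1, 1], 0)
  expect_equal(ch$values[1, 2], 1000 * 0.31 * 3 / 14, tolerance = 1e-12)
  ch21 <- children_under3_layer(pop, frac_u3_of_0_14 = 0.21)
  expect_equal(ch21$values[1, 2], 65.1, tolerance = 1e-10)
  expect_equal(round(3 / 14, 2), 0.21)
  neg <- grid_layer(matrix(-1, 1, 1))
  expect_error(children_under3_layer(neg), "negative")
})

test_that("wealth rank layer is the mid-rank ECDF over included cells", {
  w <- grid_layer(matrix(c(5, 7, 9), 1, 3))
  r <- wealth_rank_layer(w)
  expect_equal(as.vector(r$values), c(1 / 6, 1 / 2, 5 / 6))

  tie <- wealth_rank_layer(grid_layer(matrix(4, 2, 2)))
  expect_true(all(tie$values == 0.5))

  # 100-cell brute-force ECDF oracle
  set.seed(31)
  vals <- matrix(rnorm(100), 10, 10)
  rr <- wealth_rank_layer(grid_layer(vals))
  oracle <- (vapply(vals, function(v)
    sum(vals < v) + (sum(vals == v) + 1) / 2, numeric(1)) - 0.5) / 100
  expect_equal(as.vector(rr$values), as.vector(oracle), tolerance = 1e-12)

  # masked cells get nodata and are excluded from the ranking
  m <- grid_layer(matrix(c(1, 0, 1), 1, 3))
  rm_ <- wealth_rank_layer(w, m)
  expect_true(is.na(rm_$values[1, 2]))
  expect_equal(as.vector(rm_$values[1, c(1, 3)]), c(0.25, 0.75))
  expect_error(wealth_rank_layer(w, grid_layer(matrix(c(1, 0, 0), 1, 3))),
               "fewer than 2")
})

test_that("mask rule: urban excluded; <= 2 children excluded; > 2 included", {
  urban <- grid_layer(matrix(c(1, 0, 0, 0), 1, 4))
  children <- grid_layer(matrix(c(100, 2.0, 2.01, 0), 1, 4))
  m <- build_mask(urban, children)
  expect_equal(as.vector(m$values), c(0, 0, 1, 0))
})

test_that("a zero PD curve projects zero cases everywhere", {
  lay <- toy_layers()
  ch <- children_under3_layer(lay$population)
  mask <- build_mask(lay$urban, ch)
  rk <- wealth_rank_layer(lay$wealth, mask)
  res <- project_cases(zero_pd_curve(), rk, ch, mask,
                       districts = lay$district)
  expect_true(all(res$cases$values[!is.na(res$cases$values)] == 0))
  expect_equal(res$national$cases, 0)
})

test_that("3x3 toy projection matches a hand-computed brute-force sum", {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 30L), seed = 32)$obs
  curve <- fit_wealth_spline(d, "pd")
  lay <- toy_layers()
  ch <- children_under3_layer(lay$population)
  mask <- build_mask(lay$urban, ch)
  rk <- wealth_rank_layer(lay$wealth, mask)
  res <- project_cases(curve, rk, ch, mask, districts = lay$district)

  # oracle: loop over cells by hand
  total <- 0; dist_tot <- c(`1` = 0, `2` = 0)
  for (i in 1:3) for (j in 1:3) {
    if (is.na(mask$values[i, j]) || mask$values[i, j] != 1) next
    pd <- predict(curve, rk$values[i, j])$est
    cell <- ch$values[i, j] * pd * 4
    expect_equal(res$cases$values[i, j], cell, tolerance = 1e-10)
    total <- total + cell
    key <- as.character(lay$district$values[i, j])
    dist_tot[key] <- dist_tot[key] + cell
  }
  expect_equal(res$national$cases, total, tolerance = 1e-10)
  got <- setNames(res$district$cases, res$district$district)
  expect_equal(got[names(dist_tot)], dist_tot, tolerance = 1e-10,
               ignore_attr = TRUE)
  # rate definition: 1000 * cases / children
  expect_equal(res$national$rate_per_1000,
               1000 * total / res$national$children, tolerance = 1e-10)
})

test_that("single-cell district SE equals the pointwise delta-method SE", {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 30L), seed = 33)$obs
  curve <- fit_wealth_spline(d, "pd")
  rk <- grid_layer(matrix(0.4, 1, 1))
  ch <- grid_layer(matrix(120, 1, 1))
  mask <- grid_layer(matrix(1, 1, 1))
  dist <- grid_layer(matrix(1, 1, 1))
  agg <- aggregate_uncertainty(curve, rk, ch, mask, districts = dist)
  ptw <- predict(curve, 0.4)
  expect_equal(agg$district$se, 120 * 4 * ptw$se, tolerance = 1e-10)
})

test_that("two identical districts get identical CIs", {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 30L), seed = 34)$obs
  curve <- fit_wealth_spline(d, "pd")
  rk <- grid_layer(matrix(c(0.2, 0.7, 0.2, 0.7), 1, 4))
  ch <- grid_layer(matrix(c(80, 120, 80, 120), 1, 4))
  mask <- grid_layer(matrix(1, 1, 4))
  dist <- grid_layer(matrix(c(1, 1, 2, 2), 1, 4))
  agg <- aggregate_uncertainty(curve, rk, ch, mask, districts = dist)
  expect_equal(agg$district$se[1], agg$district$se[2], tolerance = 1e-12)
  expect_equal(agg$district$cases_lo[1], agg$district$cases_lo[2],
               tolerance = 1e-12)
})

test_that("delta-method district SE >= independent-cells SE", {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 30L), seed = 35)$obs
  curve <- fit_wealth_spline(d, "pd")
  lay <- toy_layers()
  ch <- children_under3_layer(lay$population)
  mask <- build_mask(lay$urban, ch)
  rk <- wealth_rank_layer(lay$wealth, mask)
  full <- aggregate_uncertainty(curve, rk, ch, mask,
                                districts = lay$district)
  naive <- aggregate_uncertainty(curve, rk, ch, mask,
                                 districts = lay$district, naive = TRUE)
  expect_true(all(full$district$se >= naive$district$se - 1e-12))
})

test_that("projection invariants: additivity, scale equivariance, masks", {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 30L), seed = 36)$obs
  curve <- fit_wealth_spline(d, "pd")
  lay <- simulate_rasters(raster_scenario(nrow = 15, ncol = 15,
                                          n_districts = 4), seed = 37)
  ch <- children_under3_layer(lay$population)
  mask <- build_mask(lay$urban, ch)
  rk <- wealth_rank_layer(lay$wealth, mask)
  res <- project_cases(curve, rk, ch, mask, districts = lay$district)

  # additivity to 1e-6 relative
  expect_equal(sum(res$district$cases), res$national$cases,
               tolerance = 1e-6)
  inc <- !is.na(res$cases$values)
  expect_equal(sum(res$cases$values[inc]), res$national$cases,
               tolerance = 1e-6)

  # doubling children doubles cases, leaves rates unchanged
  ch2 <- ch; ch2$values <- ch$values * 2
  res2 <- project_cases(curve, rk, ch2, mask, districts = lay$district)
  expect_equal(res2$national$cases, 2 * res$national$cases,
               tolerance = 1e-8)
  expect_equal(res2$national$rate_per_1000, res$national$rate_per_1000,
               tolerance = 1e-8)

  # enlarging the mask never increases a district total (PD >= 0 here)
  if (all(res$cases$values[inc] >= 0)) {
    mask2 <- mask
    on <- which(mask2$values == 1)
    mask2$values[on[seq_len(floor(length(on) / 3))]] <- 0
    res3 <- project_cases(curve, rk, ch, mask2, districts = lay$district)
    merged <- merge(res$district, res3$district, by = "district")
    expect_true(all(merged$cases.y <= merged$cases.x + 1e-9))
  }
})

test_that("rank values outside the curve support are clamped with warning", {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 30L), seed = 38)$obs
  d <- d[d$rank > 0.2 & d$rank < 0.8, ]
  curve <- fit_wealth_spline(d, "pd")
  expect_warning(p <- predict(curve, c(0, 1)), "clamped")
  inb <- predict(curve, curve$support)
  expect_equal(p$est, inb$est, tolerance = 1e-12)
})

test_that("Spearman comparison of wealth measures", {
  expect_equal(compare_wealth_layers(1:10, 1:10), 1)
  expect_equal(compare_wealth_layers(1:10, 10:1), -1)
  set.seed(39)
  x <- rnorm(50); y <- x + rnorm(50)
  rx <- rank(x); ry <- rank(y)
  oracle <- cor(rx, ry)                 # ranked Pearson
  expect_equal(compare_wealth_layers(x, y), oracle, tolerance = 1e-12)
  expect_error(compare_wealth_layers(1:2, 1:2), "3 complete pairs")
})

test_that("ESRI ASCII grid round trip preserves values and georeference", {
  g <- grid_layer(matrix(c(1.5, NA, -2, 4), 2, 2), xmin = 10, ymin = -5,
                  cellsize = 0.5)
  p <- tempfile(fileext = ".asc")
  write_asc(g, p)
  g2 <- read_asc(p)
  expect_equal(g2$values, g$values, tolerance = 1e-9)
  expect_equal(c(g2$xmin, g2$ymin, g2$cellsize),
               c(g$xmin, g$ymin, g$cellsize))
  expect_error(grid_layer(matrix(numeric(0), 0, 0)), "zero-area")
})

test_that("layers with mismatched grids are rejected", {
  a <- grid_layer(matrix(0, 2, 2))
  b <- grid_layer(matrix(0, 3, 3))
  c_ <- grid_layer(matrix(0, 2, 2), xmin = 1)
  expect_error(build_mask(a, b), "share grid")
  expect_error(build_mask(a, c_), "share grid")
})
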