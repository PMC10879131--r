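#' Children-under-3 layer from a total population layer
#'
#' Children under 3 per cell = population x (share aged 0-14) x (share of
#' the 0-14 band under 3 assuming a uniform age distribution).  Defaults
#' are the World Bank 0-14 share for rural Bangladesh (0.31) and the
#' exact 3/14; set `frac_u3_of_0_14 = 0.21` to use the rounded published
#' multiplier instead.
#'
#' @param population `grid_layer` of people per cell (nonnegative).
#' @param frac_0_14 Share of the population aged 0-14.
#' @param frac_u3_of_0_14 Share of the 0-14 band that is under 3.
#' @return `grid_layer` of children under 3 per cell.
#' @export
#' @examples
#' pop <- grid_layer(matrix(1000, 1, 1))
#' children_under3_layer(pop)$values           # 66.43
#' children_under3_layer(pop, frac_u3_of_0_14 = 0.21)$values  # 65.1
children_under3_layer <- function(population, frac_0_14 = 0.31,
                                  frac_u3_of_0_14 = 3 / 14) {
  stopifnot(inherits(population, "grid_layer"))
  if (any(population$values < 0, na.rm = TRUE))
    stop("population layer has negative cells")
  out <- population
  out$values <- population$values * frac_0_14 * frac_u3_of_0_14
  out$role <- "children"
  out
}

#' Relative wealth rank layer
#'
#' Mid-rank empirical CDF of the wealth surface over the included cells
#' only: rank = (mid-rank - 0.5) / n, in (0, 1), ties averaged.  Masked
#' or excluded cells become nodata.
#'
#' @param wealth `grid_layer` of wealth scores.
#' @param mask Optional `grid_layer`: cells with value 1 are included.
#'   `NULL` ranks every finite cell (national-scope ranking).
#' @return `grid_layer` of ranks with role `"wealth-rank"`.
#' @export
wealth_rank_layer <- function(wealth, mask = NULL) {
  stopifnot(inherits(wealth, "grid_layer"))
  inc <- is.finite(wealth$values)
  if (!is.null(mask)) {
    check_same_grid(wealth, mask)
    inc <- inc & !is.na(mask$values) & mask$values == 1
  }
  n <- sum(inc)
  if (n < 2) stop("fewer than 2 included cells; cannot rank")
  out <- wealth
  out$values[] <- NA_real_
  out$values[inc] <- (rank(wealth$values[inc],
                           ties.method = "average") - 0.5) / n
  out$role <- "wealth-rank"
  out
}

#' Rural inclusion mask
#'
#' A cell enters the projection iff it is not urban and holds strictly
#' more than `min_children` children under 3 (cells with <= 2 children
#' are excluded by default, matching the published masking rule).
#'
#' @param urban `grid_layer`, 1 = urban.
#' @param children `grid_layer` of children under 3 per cell.
#' @param min_children Exclusive lower bound on children per included
#'   cell (default 2).
#' @return Binary `grid_layer` (1 = included) with role `"mask"`.
#' @export
build_mask <- function(urban, children, min_children = 2) {
  stopifnot(inherits(urban, "grid_layer"), inherits(children, "grid_layer"))
  check_same_grid(urban, children)
  out <- urban
  u <- urban$values; ch <- children$values
  out$values[] <- as.numeric(!is.na(u) & u == 0 &
                               !is.na(ch) & ch > min_children)
  out$role <- "mask"
  out
}

#' Project prevented diarrhea cases onto the grid
#'
#' For each included cell, prevented cases per month =
#' children x PD(rank) x weeks_per_month, with the prevalence difference
#' evaluated from the fitted spline curve at the cell's wealth rank
#' (clamped to the curve's fitted support).  Negative PD cells (possible
#' harm) are retained in the totals and counted in the diagnostics.
#' District and national rates are 1000 x sum(cases) / sum(children) per
#' month.
#'
#' @param curve A `spline_curve` with `quantity = "pd"` (monsoon fit for
#'   the headline projection; a year-round fit for the sensitivity mode).
#' @param rank `grid_layer` of wealth ranks.
#' @param children `grid_layer` of children under 3.
#' @param mask Binary `grid_layer` of included cells.
#' @param districts Optional `grid_layer` of district ids; when given,
#'   district totals and delta-method CIs are computed via
#'   [aggregate_uncertainty()].
#' @param weeks_per_month Conversion from 7-day prevalence to monthly
#'   cases (default 4, per the published formula).
#' @return An object of class `projection_result`: `cases` layer,
#'   `district` table (id, children, cases, rate per 1000 with CI),
#'   `national` one-row table, and `diagnostics` (cells included,
#'   negative-PD cells).
#' @export
project_cases <- function(curve, rank, children, mask, districts = NULL,
                          weeks_per_month = 4) {
  stopifnot(inherits(curve, "spline_curve"))
  if (curve$quantity != "pd")
    stop("projection needs a prevalence-difference (pd) curve")
  check_same_grid(rank, children, mask)
  if (!is.null(districts)) check_same_grid(rank, districts)
  inc <- !is.na(mask$values) & mask$values == 1 &
    is.finite(rank$values) & is.finite(children$values)
  cases <- rank
  cases$values[] <- 0
  cases$values[is.na(mask$values) | mask$values != 1] <- NA_real_
  pd <- rep(NA_real_, sum(inc))
  if (any(inc)) {
    pred <- predict(curve, rank$values[inc])
    pd <- pred$est
    cases$values[inc] <- children$values[inc] * pd * weeks_per_month
  }
  cases$role <- "cases"

  nat_children <- sum(children$values[inc])
  nat_cases <- sum(cases$values[inc])
  agg <- aggregate_uncertainty(curve, rank, children, mask,
                               districts = districts,
                               weeks_per_month = weeks_per_month)
  structure(
    list(cases = cases,
         district = agg$district,
         national = agg$national,
         diagnostics = list(
           n_included = sum(inc),
           n_negative_pd = sum(pd < 0, na.rm = TRUE),
           children_total = nat_children,
           cases_total = nat_cases)),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat("Projected diarrhea cases prevented per month\n")
  cat(sprintf("  %d included cells (%d with negative PD), %.0f children\n",
              x$diagnostics$n_included, x$diagnostics$n_negative_pd,
              x$diagnostics$children_total))
  n <- x$national
  cat(sprintf("  national: %.1f cases (%.1f per 1000 children; 95%% CI %.1f, %.1f)\n",
              n$cases, n$rate_per_1000, n$rate_lo, n$rate_hi))
  if (!is.null(x$district))
    cat(sprintf("  %d districts aggregated\n", nrow(x$district)))
  invisible(x)
}

#' District and national uncertainty for projected cases
#'
#' Delta-method propagation of the spline coefficient covariance through
#' the projection: a district total is
#' `T_d = w * sum_c N_c x(r_c)' beta`, so `SE(T_d) = sqrt(a' V a)` with
#' `a = w * sum_c N_c x(r_c)` - cells within (and across) districts are
#' fully correlated through the shared coefficients.  A naive mode
#' (`naive = TRUE`) instead sums per-cell SEs in quadrature as if cells
#' were independent, for sensitivity comparison only.
#'
#' @inheritParams project_cases
#' @param naive Use the independent-cells SE instead of the delta method.
#' @return List with `district` (data frame: district, children, cases,
#'   se, rate_per_1000, rate_lo, rate_hi; `NULL` when no district layer)
#'   and `national` (one-row data frame with the same columns).
#' @export
aggregate_uncertainty <- function(curve, rank, children, mask,
                                  districts = NULL, weeks_per_month = 4,
                                  naive = FALSE) {
  stopifnot(inherits(curve, "spline_curve"))
  check_same_grid(rank, children, mask)
  V <- curve$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("coefficient covariance is not positive semidefinite")
  inc <- which(!is.na(mask$values) & mask$values == 1 &
                 is.finite(rank$values) & is.finite(children$values))
  if (length(inc) == 0) stop("no included cells")
  pred <- predict(curve, rank$values[inc])
  X <- attr(pred, "X")
  N <- children$values[inc]
  w <- weeks_per_month
  cell_cases <- N * pred$est * w

  total_row <- function(sel) {
    a <- drop(w * crossprod(X[sel, , drop = FALSE], N[sel]))
    se <- if (naive) {
      sqrt(sum((N[sel] * w * pred$se[sel])^2))
    } else {
      sqrt(drop(t(a) %*% V %*% a))
    }
    cases <- sum(cell_cases[sel])
    ch <- sum(N[sel])
    z <- qnorm(0.975)
    data.frame(children = ch, cases = cases, se = se,
               cases_lo = cases - z * se, cases_hi = cases + z * se,
               rate_per_1000 = 1000 * cases / ch,
               rate_lo = 1000 * (cases - z * se) / ch,
               rate_hi = 1000 * (cases + z * se) / ch)
  }

  national <- total_row(seq_along(inc))
  district <- NULL
  if (!is.null(districts)) {
    check_same_grid(rank, districts)
    did <- districts$values[inc]
    ids <- sort(unique(did))
    district <- do.call(rbind, lapply(ids, function(i)
      cbind(data.frame(district = i), total_row(which(did == i)))))
    rownames(district) <- NULL
  }
  list(district = district, national = national)
}

#' Spearman rank correlation between two wealth measures
#'
#' Used to compare trial-measured wealth at cluster locations with a
#' modelled wealth surface; mid-rank handling of ties.
#'
#' @param x,y Paired numeric vectors (>= 3 pairs).
#' @return Spearman correlation coefficient.
#' @export
compare_wealth_layers <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  cor(x[ok], y[ok], method = "spearman")
}
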