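#' Screen asset variables before wealth-index construction
#'
#' Drops (a) named WASH-related assets, which would confound an index used
#' to study a WASH intervention, (b) columns with a missingness fraction
#' at or above `missing_threshold`, and (c) near-constant columns: for
#' continuous assets a variance below `variance_floor`, for binary assets
#' a minority-class share below `variance_floor`.  Each removal is
#' recorded with its reason in the `"screen_log"` attribute.
#'
#' @param assets Data frame with a `compound_id` column and one column per
#'   asset (binary 0/1 or continuous; NA allowed).
#' @param missing_threshold Columns with missing fraction >= this are
#'   dropped (default 0.10).
#' @param variance_floor Minimum variance (continuous) or minority-class
#'   share (binary) to keep a column (default 0.01).
#' @param excluded_names Asset names to drop outright (default the
#'   WASH-related set, [default_wash_exclusions()]).
#' @return The screened asset table (same column order, minus removals),
#'   with attribute `screen_log`: data frame (column, reason).
#' @export
screen_assets <- function(assets,
                          missing_threshold = 0.10,
                          variance_floor = 0.01,
                          excluded_names = default_wash_exclusions()) {
  stopifnot(is.data.frame(assets), "compound_id" %in% names(assets))
  if (missing_threshold <= 0 || missing_threshold > 1)
    stop("`missing_threshold` must lie in (0, 1]")
  cols <- setdiff(names(assets), "compound_id")
  log <- data.frame(column = character(), reason = character(),
                    stringsAsFactors = FALSE)
  keep <- character()
  for (cl in cols) {
    x <- assets[[cl]]
    if (cl %in% excluded_names) {
      log <- rbind(log, data.frame(column = cl, reason = "wash-related exclusion"))
      next
    }
    if (mean(is.na(x)) >= missing_threshold) {
      log <- rbind(log, data.frame(column = cl, reason = "high missingness"))
      next
    }
    xo <- x[!is.na(x)]
    low_var <- if (is_binary_column(xo)) {
      min(mean(xo == 1), mean(xo == 0)) < variance_floor
    } else {
      var(xo) < variance_floor
    }
    if (length(xo) == 0 || low_var) {
      log <- rbind(log, data.frame(column = cl, reason = "near-zero variation"))
      next
    }
    keep <- c(keep, cl)
  }
  if (length(keep) == 0)
    stop("screening removed every asset column; asset table unusable")
  out <- assets[, c("compound_id", keep), drop = FALSE]
  attr(out, "screen_log") <- log
  out
}

is_binary_column <- function(x) all(x %in% c(0, 1))

#' Impute missing asset values
#'
#' Continuous assets: missing values replaced by the column mean.  Binary
#' assets: missing values form their own level, encoded as the original
#' column with NA -> 0 plus a companion `<name>_missing` indicator, so no
#' information is invented for absent binary responses.  The output has no
#' missing cells.
#'
#' @param assets Screened asset table (see [screen_assets()]).
#' @return Imputed asset table.
#' @export
impute_assets <- function(assets) {
  stopifnot(is.data.frame(assets), "compound_id" %in% names(assets))
  out <- assets["compound_id"]
  for (cl in setdiff(names(assets), "compound_id")) {
    x <- assets[[cl]]
    if (all(is.na(x))) stop("asset column entirely missing: ", cl)
    if (!anyNA(x)) {
      out[[cl]] <- x
    } else if (is_binary_column(x[!is.na(x)])) {
      miss <- as.numeric(is.na(x))
      x[is.na(x)] <- 0
      out[[cl]] <- x
      out[[paste0(cl, "_missing")]] <- miss
    } else {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      out[[cl]] <- x
    }
  }
  out
}

#' First-principal-component wealth scores
#'
#' Standardizes every asset column to mean 0 / variance 1 and projects
#' onto the first principal component of the correlation matrix.  The
#' sign is oriented so that the loading on an anchor asset (default
#' household electricity, a canonical wealth marker) is positive, i.e.
#' higher score = wealthier.
#'
#' @param assets Imputed, screened asset table.
#' @param anchor Asset column used to orient the score sign.  If absent
#'   from the table the component is oriented so the mean loading is
#'   positive, with a warning.
#' @return Data frame (`compound_id`, `score`) with attribute `loadings`
#'   (named numeric vector) and `var_explained`.
#' @export
pca_scores <- function(assets, anchor = "electricity") {
  stopifnot(is.data.frame(assets), "compound_id" %in% names(assets))
  x <- as.matrix(assets[, setdiff(names(assets), "compound_id"), drop = FALSE])
  if (ncol(x) < 2) stop("need at least 2 asset columns for PCA")
  if (nrow(x) < 3) stop("need at least 3 compounds for PCA")
  if (anyNA(x)) stop("asset table has missing cells; run impute_assets() first")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  if (pc$sdev[1] <= .Machine$double.eps^0.5)
    stop("degenerate asset table: leading eigenvalue is zero")
  load1 <- pc$rotation[, 1]
  score <- pc$x[, 1]
  flip <- if (anchor %in% names(load1)) {
    sign(load1[[anchor]])
  } else {
    warning("anchor asset '", anchor,
            "' not present; orienting by mean loading")
    sign(mean(load1))
  }
  if (flip == 0) flip <- 1
  load1 <- flip * load1
  score <- flip * score
  out <- data.frame(compound_id = assets$compound_id, score = score,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "loadings") <- load1
  attr(out, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}

#' @importFrom stats prcomp
NULL

#' Wealth rank and tertiles from scores
#'
#' Ranks compounds in the cumulative distribution of the wealth score:
#' `rank = (r - 0.5) / n` with `r` the mid-rank (ties receive their
#' average rank), so ranks lie strictly inside (0, 1) with 0 = lowest
#' socioeconomic position.  Tertiles cut the rank at 1/3 and 2/3 with
#' ties going to the lower tertile.
#'
#' @param scores Data frame (`compound_id`, `score`), or a bare numeric
#'   vector of scores.
#' @return Data frame (`compound_id`, `score`, `rank`, `tertile`) with
#'   `tertile` a factor T1 < T2 < T3 (T1 = lowest wealth).
#' @export
#' @examples
#' rank_and_tertiles(c(10, 20, 30))$rank  # 1/6, 1/2, 5/6
rank_and_tertiles <- function(scores) {
  if (is.numeric(scores))
    scores <- data.frame(compound_id = as.character(seq_along(scores)),
                         score = scores)
  stopifnot(is.data.frame(scores), all(c("compound_id", "score") %in% names(scores)))
  s <- scores$score
  if (length(s) == 0) stop("empty score vector")
  if (any(!is.finite(s))) stop("scores must be finite")
  r <- rank(s, ties.method = "average")
  wrank <- (r - 0.5) / length(s)
  tert <- factor(
    ifelse(wrank <= 1 / 3, "T1", ifelse(wrank <= 2 / 3, "T2", "T3")),
    levels = c("T1", "T2", "T3"), ordered = TRUE
  )
  data.frame(compound_id = scores$compound_id, score = s,
             rank = wrank, tertile = tert, stringsAsFactors = FALSE)
}

#' Build the wealth index end to end
#'
#' Convenience wrapper: screen, impute, PCA, rank and tertile in one call.
#'
#' @inheritParams screen_assets
#' @inheritParams pca_scores
#' @return As [rank_and_tertiles()], with the PCA `loadings` and the
#'   `screen_log` carried as attributes.
#' @export
wealth_index <- function(assets,
                         missing_threshold = 0.10,
                         variance_floor = 0.01,
                         excluded_names = default_wash_exclusions(),
                         anchor = "electricity") {
  screened <- screen_assets(assets, missing_threshold, variance_floor,
                            excluded_names)
  sc <- pca_scores(impute_assets(screened), anchor = anchor)
  out <- rank_and_tertiles(sc)
  attr(out, "loadings") <- attr(sc, "loadings")
  attr(out, "var_explained") <- attr(sc, "var_explained")
  attr(out, "screen_log") <- attr(screened, "screen_log")
  out
}
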