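# Block-clustered sandwich covariance for a fitted glm/lm
cluster_vcov <- function(fit, cluster) {
  sandwich::vcovCL(fit, cluster = cluster, type = "HC0")
}

# sqrt that treats numerically tiny negative variances as exact zeros
safe_sqrt <- function(x) sqrt(pmax(x, 0))

#' Relative and Slope Index of Inequality over wealth rank
#'
#' Fits a log-link binomial GLM of the binary outcome on the continuous
#' wealth rank (0 = lowest socioeconomic position, 1 = highest) within
#' one arm.  Writing the fitted prevalence as
#' `v(r) = exp(b0 + b1 r)`, the Relative Index of Inequality is
#' `RII = v(0) / v(1) = exp(-b1)` (bottom-to-top ratio) and the Slope
#' Index of Inequality is `SII = v(0) - v(1)` (bottom-to-top difference,
#' proportion scale).  RII = 1 and SII = 0 indicate no inequality;
#' RII > 1 / SII > 0 indicate the outcome is concentrated among the
#' lowest socioeconomic position.  95% confidence intervals use
#' block-clustered sandwich covariance: the RII interval is formed on the
#' log scale, the SII interval by the delta method.
#'
#' @param outcome Binary (0/1) outcome vector.
#' @param rank Wealth ranks in \[0, 1\].
#' @param block Randomization-block ids for clustering.
#' @param arm Optional arm label stored on the result.
#' @return An object of class `inequality_result`: list with `arm`,
#'   `rii`, `rii_ci`, `sii`, `sii_ci`, `coef` (b0, b1), `vcov`, `n`.
#' @export
fit_rii_sii <- function(outcome, rank, block, arm = NA_character_) {
  stopifnot(length(outcome) == length(rank),
            length(outcome) == length(block))
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (any(rank < 0 | rank > 1)) stop("ranks must lie in [0, 1]")
  if (length(unique(rank)) < 2) stop("need >= 2 distinct ranks")
  if (sum(outcome) == 0)
    stop("all outcomes are zero: RII undefined on the log scale")
  dat <- data.frame(y = outcome, r = rank)
  fit <- glm(y ~ r, family = binomial(link = "log"), data = dat,
             start = c(log(mean(outcome)), 0))
  if (!fit$converged)
    stop("log-binomial fit did not converge (deviance ",
         format(fit$deviance), ")")
  b <- coef(fit)
  V <- cluster_vcov(fit, block)
  z <- qnorm(0.975)

  # RII = exp(-b1): CI on the log scale
  se_log_rii <- safe_sqrt(V[2, 2])
  rii <- exp(-b[[2]])
  rii_ci <- exp(-b[[2]] + c(-1, 1) * z * se_log_rii)

  # SII = exp(b0) - exp(b0 + b1): delta method
  v0 <- exp(b[[1]]); v1 <- exp(b[[1]] + b[[2]])
  grad <- c(v0 - v1, -v1)
  se_sii <- safe_sqrt(drop(t(grad) %*% V %*% grad))
  sii <- v0 - v1
  sii_ci <- sii + c(-1, 1) * z * se_sii

  structure(
    list(arm = arm, rii = rii, rii_ci = sort(rii_ci),
         sii = sii, sii_ci = sii_ci,
         coef = b, vcov = V, n = length(outcome)),
    class = "inequality_result"
  )
}

#' @export
print.inequality_result <- function(x, ...) {
  cat(sprintf("Inequality indices%s (n = %d)\n",
              if (is.na(x$arm)) "" else paste0(" [", x$arm, "]"), x$n))
  cat(sprintf("  RII %.2f (95%% CI %.2f, %.2f)\n",
              x$rii, x$rii_ci[1], x$rii_ci[2]))
  cat(sprintf("  SII %.3f (95%% CI %.3f, %.3f)\n",
              x$sii, x$sii_ci[1], x$sii_ci[2]))
  invisible(x)
}

#' Inequality indices for both trial arms
#'
#' @param observations Observation table with columns `diarrhea`, `arm`,
#'   `block_id` and a wealth `rank` column (join wealth records first).
#' @return Data frame, one row per arm: RII/SII with 95% CIs.
#' @export
arm_inequality <- function(observations) {
  need <- c("diarrhea", "arm", "block_id", "rank")
  stopifnot(all(need %in% names(observations)))
  do.call(rbind, lapply(split(observations, observations$arm), function(d) {
    r <- fit_rii_sii(d$diarrhea, d$rank, d$block_id, arm = d$arm[1])
    data.frame(arm = r$arm, rii = r$rii, rii_lo = r$rii_ci[1],
               rii_hi = r$rii_ci[2], sii = r$sii, sii_lo = r$sii_ci[1],
               sii_hi = r$sii_ci[2], n = r$n, row.names = NULL)
  }))
}
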