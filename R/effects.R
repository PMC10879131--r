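# Identity-link binomial fit with linear-probability fallback.
# The identity link can step outside (0,1) during IRLS; when it fails the
# linear-probability model gives the same estimand (cell means and their
# differences) and the block-clustered sandwich covariance stays valid.
fit_identity_binomial <- function(formula, data) {
  lpm <- lm(formula, data = data)
  start <- coef(lpm)
  fit <- tryCatch({
    g <- suppressWarnings(
      glm(formula, family = binomial(link = "identity"), data = data,
          start = start)
    )
    if (!g$converged) stop("identity-link IRLS did not converge")
    g
  }, error = function(e) NULL)
  if (is.null(fit)) list(fit = lpm, flag = "lpm-fallback")
  else list(fit = fit, flag = "")
}

# Log-link binomial fit with modified-Poisson fallback (log link, robust
# errors) when the log-binomial likelihood fails to converge.
fit_log_binomial <- function(formula, data) {
  y <- model.response(stats::model.frame(formula, data))
  start <- c(log(max(mean(y), 1e-8)),
             rep(0, ncol(model.matrix(formula, data)) - 1))
  fit <- tryCatch({
    g <- suppressWarnings(
      glm(formula, family = binomial(link = "log"), data = data,
          start = start)
    )
    if (!g$converged) stop("log-binomial IRLS did not converge")
    g
  }, error = function(e) NULL)
  if (is.null(fit)) {
    g <- glm(formula, family = stats::poisson(link = "log"), data = data)
    list(fit = g, flag = "poisson-fallback")
  } else list(fit = fit, flag = "")
}

#' Stratum-level intervention effects
#'
#' For each stratum defined by the `by` columns (or the whole sample when
#' `by` is empty), estimates arm prevalences, the prevalence difference
#' PD = prevalence(control) - prevalence(intervention) from an
#' identity-link binomial GLM, and the prevalence ratio
#' PR = prevalence(control) / prevalence(intervention) from a log-link
#' binomial GLM.  All 95% confidence intervals are delta-method linear
#' combinations of the regression coefficients with block-clustered
#' sandwich covariance, so repeated measurements and cluster correlation
#' are absorbed at the randomization-block level.
#'
#' Degenerate strata are flagged rather than dropped: zero events in both
#' arms gives PD 0 with a `degenerate` flag and an undefined PR; an
#' identity-link convergence failure falls back to the linear-probability
#' model (`lpm-fallback`), a log-link failure to a modified Poisson fit
#' (`poisson-fallback`).
#'
#' @param observations Data frame with columns `diarrhea` (0/1), `arm`
#'   (`"control"`/`"intervention"`), `block_id`, plus any `by` columns.
#' @param by Character vector of stratifying columns (e.g. `"tertile"`,
#'   `"season"`, `c("tertile", "season")`); `NULL` for the overall effect.
#' @return Data frame, one row per stratum: the `by` labels, arm sizes,
#'   `prev_control`, `prev_intervention` with CIs, `pd`, `pd_se`,
#'   `pd_lo`, `pd_hi`, `pr`, `pr_lo`, `pr_hi`, `flag`.
#' @export
estimate_stratum_effects <- function(observations, by = NULL) {
  need <- c("diarrhea", "arm", "block_id", by)
  stopifnot(all(need %in% names(observations)))
  if (!all(observations$arm %in% c("control", "intervention")))
    stop("arm must be 'control' or 'intervention'")
  strata <- if (length(by) == 0) list(overall = observations)
            else split(observations, observations[by], drop = TRUE, sep = " / ")
  out <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    res <- .one_stratum_effect(d)
    lab <- if (length(by) > 0) {
      vals <- strsplit(nm, " / ", fixed = TRUE)[[1]]
      setNames(as.data.frame(as.list(vals), stringsAsFactors = FALSE), by)
    } else data.frame(stratum = "overall", stringsAsFactors = FALSE)
    cbind(lab, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.one_stratum_effect <- function(d) {
  z <- qnorm(0.975)
  d$ctrl <- as.numeric(d$arm == "control")
  n0 <- sum(d$ctrl == 1); n1 <- sum(d$ctrl == 0)
  if (n0 == 0 || n1 == 0) stop("stratum missing one arm")
  ev0 <- sum(d$diarrhea[d$ctrl == 1]); ev1 <- sum(d$diarrhea[d$ctrl == 0])
  empty <- data.frame(
    n_control = n0, n_intervention = n1,
    prev_control = ev0 / n0, prev_control_lo = NA, prev_control_hi = NA,
    prev_intervention = ev1 / n1, prev_intervention_lo = NA,
    prev_intervention_hi = NA,
    pd = ev0 / n0 - ev1 / n1, pd_se = NA, pd_lo = NA, pd_hi = NA,
    pr = NA, pr_lo = NA, pr_hi = NA, flag = "", stringsAsFactors = FALSE
  )
  if (ev0 == 0 && ev1 == 0) {
    empty$pd <- 0; empty$flag <- "degenerate:no-events"
    return(empty)
  }
  flags <- character()

  ident <- fit_identity_binomial(diarrhea ~ ctrl, d)
  if (nzchar(ident$flag)) flags <- c(flags, ident$flag)
  b <- coef(ident$fit)
  V <- cluster_vcov(ident$fit, d$block_id)
  p1 <- b[[1]]; p0 <- b[[1]] + b[[2]]
  se_p1 <- safe_sqrt(V[1, 1])
  se_p0 <- safe_sqrt(V[1, 1] + V[2, 2] + 2 * V[1, 2])
  se_pd <- safe_sqrt(V[2, 2])
  empty$prev_control <- p0
  empty$prev_control_lo <- p0 - z * se_p0
  empty$prev_control_hi <- p0 + z * se_p0
  empty$prev_intervention <- p1
  empty$prev_intervention_lo <- p1 - z * se_p1
  empty$prev_intervention_hi <- p1 + z * se_p1
  empty$pd <- b[[2]]; empty$pd_se <- se_pd
  empty$pd_lo <- b[[2]] - z * se_pd
  empty$pd_hi <- b[[2]] + z * se_pd

  if (ev0 > 0 && ev1 > 0) {
    lg <- fit_log_binomial(diarrhea ~ ctrl, d)
    if (nzchar(lg$flag)) flags <- c(flags, lg$flag)
    bl <- coef(lg$fit)
    Vl <- cluster_vcov(lg$fit, d$block_id)
    empty$pr <- exp(bl[[2]])
    empty$pr_lo <- exp(bl[[2]] - z * safe_sqrt(Vl[2, 2]))
    empty$pr_hi <- exp(bl[[2]] + z * safe_sqrt(Vl[2, 2]))
  } else {
    flags <- c(flags, "degenerate:pr-undefined")
  }
  empty$flag <- paste(flags, collapse = ";")
  empty
}

#' Wald-type F test for effect modification
#'
#' Compares the models with and without the arm-by-modifier interaction
#' through a joint Wald-type F test on the interaction coefficients,
#' using block-clustered sandwich covariance.  The additive scale uses
#' the identity-link binomial model (linear-probability fallback), the
#' multiplicative scale the log-link binomial model.  With several
#' modifiers the tested coefficients are the highest-order interaction
#' terms involving the arm and all modifiers (i.e. whether modification
#' by one modifier itself differs across the other).  The denominator
#' degrees of freedom are `number of blocks - number of model
#' parameters`, a small-sample cluster correction.
#'
#' @param observations As in [estimate_stratum_effects()].
#' @param modifiers Character vector of modifier columns (factors or
#'   character), length 1 or 2.
#' @param scale `"additive"` or `"multiplicative"`.
#' @return An object of class `interaction_test`: list with `modifiers`,
#'   `scale`, `statistic` (F), `df1`, `df2`, `p_value`, `flag`.
#' @export
interaction_test <- function(observations,
                             modifiers,
                             scale = c("additive", "multiplicative")) {
  scale <- match.arg(scale)
  stopifnot(length(modifiers) %in% 1:2,
            all(c("diarrhea", "arm", "block_id", modifiers) %in%
                  names(observations)))
  d <- observations
  d$ctrl <- as.numeric(d$arm == "control")
  for (m in modifiers) {
    d[[m]] <- factor(d[[m]])
    if (nlevels(d[[m]]) < 2) stop("modifier has < 2 levels: ", m)
  }
  rhs <- paste(c("ctrl", modifiers), collapse = " * ")
  form <- as.formula(paste("diarrhea ~", rhs))
  fitted <- if (scale == "additive") fit_identity_binomial(form, d)
            else fit_log_binomial(form, d)
  fit <- fitted$fit
  b <- coef(fit)
  if (anyNA(b)) stop("model matrix rank-deficient; check modifier levels")
  V <- cluster_vcov(fit, d$block_id)

  # highest-order interaction terms: ctrl x all modifiers
  pat <- paste0("^ctrl:", paste(sapply(modifiers, function(m)
    paste0(m, "[^:]*")), collapse = ":"), "$")
  sel <- grepl(pat, names(b))
  if (!any(sel)) stop("no interaction coefficients found for ",
                      paste(modifiers, collapse = ", "))
  q <- sum(sel)
  bq <- b[sel]
  Vq <- V[sel, sel, drop = FALSE]
  Vq_inv <- tryCatch(solve(Vq), error = function(e)
    stop("singular interaction covariance: ", conditionMessage(e)))
  Fstat <- drop(t(bq) %*% Vq_inv %*% bq) / q
  n_blocks <- length(unique(d$block_id))
  df2 <- n_blocks - length(b)
  if (df2 <= 0) stop("fewer blocks than model parameters; F df undefined")
  structure(
    list(modifiers = modifiers, scale = scale, statistic = Fstat,
         df1 = q, df2 = df2,
         p_value = pf(Fstat, q, df2, lower.tail = FALSE),
         flag = fitted$flag),
    class = "interaction_test"
  )
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf("Wald-type F test of %s interaction [%s]\n",
              x$scale, paste(x$modifiers, collapse = " x ")))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g%s\n", x$df1, x$df2,
              x$statistic, x$p_value,
              if (nzchar(x$flag)) paste0("  (", x$flag, ")") else ""))
  invisible(x)
}
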