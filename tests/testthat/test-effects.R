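test_that("identical arms give PD = 0 and PR = 1", {
  y <- rep(c(0, 1, 0, 0, 1), 40)
  d <- data.frame(
    diarrhea = c(y, y),
    arm = rep(c("control", "intervention"), each = length(y)),
    block_id = rep_len(sprintf("b%02d", 1:10), 2 * length(y))
  )
  eff <- estimate_stratum_effects(d)
  expect_equal(eff$pd, 0, tolerance = 1e-10)
  expect_equal(eff$pr, 1, tolerance = 1e-8)
})

test_that("stratum PD equals the difference of stratum prevalences", {
  d <- simulate_with_wealth(seed = 21)$obs
  eff <- estimate_stratum_effects(d, by = c("tertile", "season"))
  for (i in seq_len(nrow(eff))) {
    sub <- d[d$tertile == eff$tertile[i] & d$season == eff$season[i], ]
    p0 <- mean(sub$diarrhea[sub$arm == "control"])
    p1 <- mean(sub$diarrhea[sub$arm == "intervention"])
    expect_equal(eff$pd[i], p0 - p1, tolerance = 1e-10)
    expect_equal(eff$prev_control[i], p0, tolerance = 1e-10)
    expect_equal(eff$prev_intervention[i], p1, tolerance = 1e-10)
    expect_equal(eff$pr[i], p0 / p1, tolerance = 1e-6)
  }
})

test_that("degenerate strata are flagged, not dropped", {
  d <- data.frame(
    diarrhea = rep(0, 80),
    arm = rep(c("control", "intervention"), 40),
    block_id = rep_len(sprintf("b%d", 1:8), 80)
  )
  eff <- estimate_stratum_effects(d)
  expect_equal(eff$pd, 0)
  expect_match(eff$flag, "degenerate:no-events")
  expect_true(is.na(eff$pr))

  # events only in control: PD defined, PR undefined
  d$diarrhea[d$arm == "control"][1:6] <- 1
  eff2 <- estimate_stratum_effects(d)
  expect_gt(eff2$pd, 0)
  expect_match(eff2$flag, "pr-undefined")
})

test_that("block-clustered sandwich SE agrees with a jackknife over blocks", {
  set.seed(22)
  B <- 20; m <- 60
  blocks <- rep(sprintf("b%02d", 1:B), each = m)
  re <- rnorm(B, 0, 0.03)[rep(1:B, each = m)]
  arm <- rep_len(c("control", "intervention"), B * m)
  p <- pmin(pmax(0.08 + re + ifelse(arm == "control", 0.03, 0), 0.01), 0.99)
  d <- data.frame(diarrhea = rbinom(B * m, 1, p), arm = arm,
                  block_id = blocks)
  eff <- estimate_stratum_effects(d)

  # oracle: leave-one-block-out jackknife of the difference in means
  pd_b <- vapply(unique(blocks), function(b) {
    sub <- d[d$block_id != b, ]
    mean(sub$diarrhea[sub$arm == "control"]) -
      mean(sub$diarrhea[sub$arm == "intervention"])
  }, numeric(1))
  se_jack <- sqrt((B - 1) / B * sum((pd_b - mean(pd_b))^2))
  expect_lt(abs(eff$pd_se - se_jack) / se_jack, 0.15)
})

test_that("Wald-type F detects a strong seasonal interaction", {
  sc <- trial_scenario(n_blocks = 90L, compounds_per_cluster = 20L)
  # PD 4pp in monsoon, 0 in dry
  cp <- default_cell_prevalence()
  cp["control", "dry", ] <- 0.05
  cp["intervention", "dry", ] <- 0.05
  cp["control", "monsoon", ] <- 0.09
  cp["intervention", "monsoon", ] <- 0.05
  sc <- trial_scenario(n_blocks = 90L, compounds_per_cluster = 20L,
                       cell_prevalence = cp)
  obs <- simulate_trial(sc, seed = 23)$observations
  t_add <- interaction_test(obs, "season", "additive")
  expect_lt(t_add$p_value, 0.001)
  t_mul <- interaction_test(obs, "season", "multiplicative")
  expect_lt(t_mul$p_value, 0.05)
  expect_equal(t_add$df1, 1L)
  expect_equal(t_add$df2, 90L - 4L)
})

test_that("joint two-modifier test targets the highest-order terms", {
  d <- simulate_with_wealth(seed = 24)$obs
  t2 <- interaction_test(d, c("tertile", "season"), "additive")
  expect_equal(t2$df1, 2L)             # (3-1) x (2-1) coefficients
  expect_true(t2$p_value >= 0 && t2$p_value <= 1)
  expect_error(interaction_test(d, "arm"), "diarrhea|levels|modifier")
})

test_that("spline: constant truth yields a flat PD curve within its band", {
  set.seed(25)
  n <- 20000
  d <- data.frame(
    rank = runif(n),
    arm = rep(c("control", "intervention"), length.out = n),
    block_id = sample(sprintf("b%02d", 1:40), n, replace = TRUE)
  )
  d$diarrhea <- rbinom(n, 1, ifelse(d$arm == "control", 0.09, 0.05))
  cv <- fit_wealth_spline(d, "pd")
  expect_true(all(cv$grid$lo <= 0.04 & 0.04 <= cv$grid$hi))
  expect_lt(max(abs(cv$grid$est - 0.04)), 0.025)
  # bands contain the fitted value everywhere
  expect_true(all(cv$grid$lo <= cv$grid$est & cv$grid$est <= cv$grid$hi))
})

test_that("spline with penalty -> infinity degenerates to a straight line", {
  d <- simulate_with_wealth(seed = 26)$obs
  cv <- fit_wealth_spline(d, "pd", sp = rep(1e9, 3))
  curv <- diff(cv$grid$est, differences = 2)
  expect_lt(max(abs(curv)), 1e-6)
})

test_that("arm-shuffled null gives a PD curve covering zero", {
  set.seed(27)
  d <- simulate_with_wealth(trial_scenario(n_blocks = 60L), seed = 27)$obs
  d$arm <- sample(d$arm)                      # break the randomization
  cv <- fit_wealth_spline(d, "pd")
  expect_true(mean(cv$grid$lo <= 0 & 0 <= cv$grid$hi) >= 0.95)
  expect_lt(max(abs(cv$grid$est)), 0.03)
})

test_that("control-arm prevalence curve preserves a monotone gradient", {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 90L), seed = 28)$obs
  cv <- fit_wealth_spline(d, "pd")
  g <- cv$grid
  expect_gt(g$prev_control[1], g$prev_control[nrow(g)])
})

test_that("PD and PR curves agree with stratum GLMs in level", {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 90L), seed = 29)$obs
  eff <- estimate_stratum_effects(d)
  cv <- fit_wealth_spline(d, "pd")
  mean_pd <- mean(cv$grid$est)
  expect_lt(abs(mean_pd - eff$pd), 0.02)
  pr <- fit_wealth_spline(d, "pr")
  expect_true(all(pr$grid$est > 0))
})

test_that("season filter restricts the spline fit", {
  d <- simulate_with_wealth(trial_scenario(n_blocks = 60L), seed = 30)$obs
  cvm <- fit_wealth_spline(d, "pd", season_filter = "monsoon")
  cvd <- fit_wealth_spline(d, "pd", season_filter = "dry")
  # generating PDs: monsoon low tertile 5.7pp vs dry ~1.2pp
  expect_gt(mean(cvm$grid$est), mean(cvd$grid$est))
  expect_error(fit_wealth_spline(d, "pd", season_filter = "winter"),
               "no observations")
})
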