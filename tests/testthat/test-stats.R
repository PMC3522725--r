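test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(2)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(9, 0.5)
    a <- one_way_anova(list(a = x, b = y))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(unname(a$statistic), unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate variance and malformed groups raise errors", {
  const <- list(a = c(1, 1, 1), b = c(2, 2, 2))
  expect_error(one_way_anova(const), "degenerate-variance")
  expect_error(snk(const), "degenerate-variance")
  expect_error(one_way_anova(list(a = 1:5)), ">= 2 groups")
  expect_error(one_way_anova(list(a = 1:5, b = 3)), "n >= 2")
  expect_error(dunnett(list(a = 1:5, b = 1:5), "nope"), "not present")
})

test_that("ANOVA agrees with base R aov on a multi-group fixture", {
  set.seed(33)
  df <- data.frame(value = rnorm(40), group = rep(letters[1:4], each = 10))
  ours <- one_way_anova(df)
  ref <- summary(stats::aov(value ~ group, df))[[1]]
  expect_equal(unname(ours$statistic), ref[["F value"]][1], tolerance = 1e-8)
  expect_equal(ours$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-8)
})

test_that("Dunnett with one treatment reduces to the two-sample t critical value", {
  lam <- sqrt(7 / (7 + 9))
  # tolerance matches the documented quadrature accuracy (~3e-4 absolute)
  expect_equal(mtquant:::dunnett_critical(lam, 14, 0.05), qt(0.975, 14),
               tolerance = 5e-4)
})

test_that("Dunnett critical values match the mvtnorm oracle", {
  skip_if_not_installed("mvtnorm")
  cases <- list(list(n = rep(9, 8), n0 = 9),
                list(n = c(4, 6, 12), n0 = 8),
                list(n = rep(5, 3), n0 = 5))
  for (cs in cases) {
    lam <- sqrt(cs$n / (cs$n + cs$n0))
    df <- sum(cs$n) + cs$n0 - length(cs$n) - 1
    R <- outer(lam, lam); diag(R) <- 1
    set.seed(1)
    oracle <- mvtnorm::qmvt(0.95, tail = "both.tails", df = df, corr = R,
                            algorithm = mvtnorm::GenzBretz(abseps = 1e-5))$quantile
    expect_equal(mtquant:::dunnett_critical(lam, df, 0.05), oracle,
                 tolerance = 2e-3)
  }
})

test_that("Dunnett: identical treatment not flagged; flags monotone in alpha; never less conservative than plain t", {
  set.seed(6)
  g <- list(vehicle = rnorm(9), t1 = rnorm(9, 3), t2 = rnorm(9))
  g$t3 <- g$vehicle                       # identical to control
  d <- dunnett(g, "vehicle", alpha = 0.05)
  expect_false(d$comparisons$significant[d$comparisons$group == "t3"])
  expect_true(d$comparisons$significant[d$comparisons$group == "t1"])
  d01 <- dunnett(g, "vehicle", alpha = 0.01)
  expect_true(all(d01$comparisons$significant <= d$comparisons$significant))
  expect_true(all(d$comparisons$p_value >= 0 & d$comparisons$p_value <= 1))
  # adjusted p >= per-comparison pooled-t p on random data
  for (rep in 1:10) {
    g2 <- split(rnorm(45), rep(1:5, 9))
    names(g2) <- c("vehicle", paste0("t", 1:4))
    dd <- dunnett(g2, "vehicle")
    gm <- mtquant:::group_moments(mtquant:::as_groups(g2))
    praw <- 2 * pt(abs(dd$comparisons$statistic), gm$df_within, lower.tail = FALSE)
    expect_true(all(dd$comparisons$p_value >= praw - 1e-12))
  }
})

test_that("SNK: two groups match the span-2 studentized range; absorption protects inner pairs", {
  set.seed(13)
  x <- rnorm(8); y <- rnorm(8, 1)
  s <- snk(list(a = x, b = y), alpha = 0.05)
  gm <- mtquant:::group_moments(mtquant:::as_groups(list(a = x, b = y)))
  q <- abs(diff(vapply(list(x, y), mean, numeric(1)))) / sqrt(gm$mse / 8)
  expect_equal(unname(s$comparisons$statistic), q, tolerance = 1e-10)
  expect_equal(s$comparisons$significant,
               ptukey(q, 2, gm$df_within, lower.tail = FALSE) < 0.05)
  # when the full range is not significant, nothing inside may be flagged
  for (rep in 1:20) {
    g <- split(rnorm(24, sd = 5), rep(1:4, 6))
    names(g) <- letters[1:4]
    res <- snk(g)
    full <- res$comparisons[res$comparisons$span == 4, ]
    if (!full$significant)
      expect_false(any(res$comparisons$significant))
  }
})

test_that("viability percent: arithmetic, control pins at 100, scale invariance", {
  g <- list(control = c(0.5, 0.5), zinc = c(0.25, 0.25))
  v <- viability_percent(g, "control")
  expect_equal(v$mean_percent[v$group == "zinc"], 50)
  expect_equal(v$mean_percent[v$group == "control"], 100)
  g2 <- lapply(g, function(x) x * 37)
  expect_equal(viability_percent(g2, "control")$mean_percent, v$mean_percent)
  expect_error(viability_percent(list(control = c(-1, -1), t = c(1, 2)), "control"),
               "> 0")
})

test_that("viability recovers a true survival fraction of 0.6 within 5 points", {
  set.seed(25)
  est <- vapply(1:20, function(r) {
    g <- list(control = rnorm(18, 0.50, 0.05), zinc = rnorm(18, 0.30, 0.05))
    v <- viability_percent(g, "control")
    v$mean_percent[v$group == "zinc"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 60), 5)
})

test_that("shape classification covers all flag patterns", {
  cls <- mtquant:::classify_shape
  expect_equal(cls(c(FALSE, FALSE, FALSE)), "flat")
  expect_equal(cls(c(FALSE, TRUE, TRUE)), "monotone")
  expect_equal(cls(c(TRUE, FALSE, TRUE)), "bimodal")
  expect_equal(cls(c(FALSE, TRUE, FALSE)), "bimodal")   # interior peak
  expect_equal(cls(c(TRUE, TRUE, TRUE)), "monotone")
})

test_that("dose-response summary wires normalization, Dunnett and shape together", {
  fx <- make_plate_table(plate_params(shape = "bimodal"), seed = 42)
  drs <- dose_response_summary(fx$plate)
  expect_s3_class(drs, "dose_response_summary")
  expect_equal(drs$table$condition[1], "vehicle")
  expect_true(all(diff(drs$table$concentration_M) > 0))
  expect_true(is.na(drs$table$significant[1]))
  expect_error(dose_response_summary(fx$plate, control_label = "missing"),
               "not present")
})
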