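sinusoid_trace <- function(fs = 500, dur = 12) {
  t <- seq(0, dur, by = 1 / fs)
  tibble::tibble(time_s = t, pressure_mmhg = 50 + 50 * sin(2 * pi * t))
}

test_that("dP/dt_max of an analytic sinusoid is 100*pi within 0.5%", {
  res <- dpdt_max(sinusoid_trace())
  expect_lt(abs(res$dpdt_mean - 100 * pi) / (100 * pi), 0.005)
  expect_gte(res$n_beats, 8) # 12 s window at 1 Hz, boundary beats trimmed
})

test_that("degenerate traces are rejected", {
  t <- seq(0, 12, by = 1 / 500)
  flat <- tibble::tibble(time_s = t, pressure_mmhg = rep(50, length(t)))
  expect_error(dpdt_max(flat), "beats")
  short <- sinusoid_trace(dur = 5)
  expect_error(dpdt_max(short), "10 s")
  slow <- sinusoid_trace(fs = 50)
  expect_error(dpdt_max(slow), "100 Hz")
})

test_that("a single 5x outlier beat does not move the retained mean", {
  p <- plan_config(hemo = list(ectopy_rate = 0))$hemo
  rec <- generate_pressure_traces("target", p, seed = 21)
  clean <- dpdt_max(rec$baseline)
  # inject one ectopic beat by scaling a mid-trace systole
  tr <- rec$baseline
  sel <- tr$time_s >= 6 * 60 / p$hr_bpm & tr$time_s < 6 * 60 / p$hr_bpm + p$systole_s
  tr$pressure_mmhg[sel] <- 10 + 5 * (tr$pressure_mmhg[sel] - 10)
  dirty <- dpdt_max(tr)
  expect_false(all(dirty$beats$retained))
  expect_lt(abs(dirty$dpdt_mean / clean$dpdt_mean - 1), 0.01)
})

test_that("AHR is the percent change of dP/dt_max", {
  expect_identical(compute_ahr(800, 1000), 25)
  expect_identical(compute_ahr(950, 950), 0)
  expect_identical(compute_ahr(800, 760), -5)
  expect_error(compute_ahr(0, 500), "positive")
  expect_error(compute_ahr(-10, 500), "positive")
})

test_that("identical groups give zero difference and p = 1", {
  rec <- tibble::tibble(
    ahr = rep(c(12, 15, 18, 21), 2),
    group = rep(c("target", "nontarget"), each = 4),
    class = rep(c("target", "nontarget_viable"), each = 4)
  )
  cmp <- compare_groups(rec)
  g <- glance(cmp)
  expect_equal(g$mean_difference, 0)
  expect_equal(g$p_value, 1)
  expect_equal(g$fisher_p_value, 1)
})

test_that("Fisher p equals exact hypergeometric enumeration", {
  # 2x2 table [[10, 0], [5, 5]]
  rec <- tibble::tibble(
    ahr = c(rep(20, 10), rep(20, 5), rep(5, 5)),
    group = rep(c("target", "nontarget"), c(10, 10)),
    class = rep(c("target", "nontarget_viable"), c(10, 10))
  )
  cmp <- compare_groups(rec, ahr_cut = 10)
  expect_equal(unname(cmp$table[1, ]), c(10, 0))
  # enumeration oracle: fixed margins, sum the probabilities of all tables
  # at most as likely as the observed one
  x_obs <- 10
  xs <- max(0, 15 - 10):min(10, 15)
  probs <- stats::dhyper(xs, 10, 10, 15)
  p_exact <- sum(probs[probs <= stats::dhyper(x_obs, 10, 10, 15) * (1 + 1e-7)])
  expect_equal(cmp$fisher$p.value, p_exact, tolerance = 1e-12)
})

test_that("power at the study effect size matches the noncentral oracle", {
  # independent oracle: exact noncentral-t power at n = 20 vs 20,
  # delta = 12.6, sds 8.8 / 8.6 (Welch df via Satterthwaite)
  se <- sqrt(8.8^2 / 20 + 8.6^2 / 20)
  df <- se^4 / ((8.8^2 / 20)^2 / 19 + (8.6^2 / 20)^2 / 19)
  ncp <- 12.6 / se
  crit <- stats::qt(1 - 0.001 / 2, df)
  power_exact <- 1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  set.seed(1)
  hits <- replicate(200, {
    x <- rnorm(20, 25.5, 8.8); y <- rnorm(20, 12.9, 8.6)
    stats::t.test(x, y)$p.value < 0.001
  })
  expect_lt(abs(mean(hits) - power_exact), 3 * sqrt(power_exact * (1 - power_exact) / 200))
  # the comparison is overwhelmingly significant at the conventional level
  set.seed(2)
  hits05 <- replicate(200, {
    x <- rnorm(20, 25.5, 8.8); y <- rnorm(20, 12.9, 8.6)
    stats::t.test(x, y)$p.value < 0.05
  })
  expect_gt(mean(hits05), 0.97)
})

test_that("AHR is invariant to a common pressure scale", {
  p <- plan_config()$hemo
  rec <- generate_pressure_traces("target", p, seed = 31)
  ahr1 <- compute_ahr(dpdt_max(rec$baseline)$dpdt_mean,
                      dpdt_max(rec$paced)$dpdt_mean)
  scale_k <- function(tr, k) dplyr::mutate(tr, pressure_mmhg = pressure_mmhg * k)
  ahr2 <- compute_ahr(dpdt_max(scale_k(rec$baseline, 2.5))$dpdt_mean,
                      dpdt_max(scale_k(rec$paced, 2.5))$dpdt_mean)
  expect_equal(ahr1, ahr2, tolerance = 1e-9)
})

test_that("captureless records are dropped and empty groups error", {
  rec <- tibble::tibble(
    ahr = c(25, 28, NA, 10, 12),
    group = c("target", "target", "nontarget", "nontarget", "nontarget"),
    class = c("target", "target", "scarred", "nontarget_viable", "nontarget_viable"),
    capture = c(TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  cmp <- compare_groups(rec)
  expect_identical(as.integer(cmp$nontarget[["n"]]), 2L)
  expect_error(compare_groups(rec[1:3, ]), "at least 2")
})
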