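noiseless <- plan_config(perfusion = list(noise_sd_hu = 0))$perfusion

test_that("noiseless deconvolution recovers MBF and Tc within 1%", {
  for (m in c(20, 50, 80, 120)) {
    truth <- list(true_mbf = rep(m, 16), scar_segments = integer(0))
    tac <- generate_tacs(truth, noiseless, seed = 1)
    fit <- fit_compartment_model(tac[, c("time_s", "aif_hu", "seg01_hu")])
    expect_lt(abs(fit$mbf[1] / m - 1), 0.01)
    expect_lt(abs(fit$tc_s[1] / noiseless$tc_s - 1), 0.01)
    expect_equal(fit$pcbv[1], fit$mbf[1] * fit$tc_s[1] / 60, tolerance = 1e-12)
  }
})

test_that("a flat tissue curve gives zero flow and zero enhancement", {
  truth <- list(true_mbf = c(0, rep(80, 15)), scar_segments = integer(0))
  tac <- generate_tacs(truth, noiseless, seed = 2)
  fit <- fit_compartment_model(tac)
  expect_identical(fit$mbf[fit$id == 1], 0)
  expect_equal(fit$avg_enhancement[fit$id == 1], 0, tolerance = 1e-12)
  expect_identical(fit$pcbv[fit$id == 1], 0)
})

test_that("flow linearity: a doubled curve fits a doubled MBF", {
  truth <- list(true_mbf = c(40, 80, rep(60, 14)), scar_segments = integer(0))
  tac <- generate_tacs(truth, noiseless, seed = 3)
  fit <- fit_compartment_model(tac[, c("time_s", "aif_hu", "seg01_hu", "seg02_hu")])
  expect_equal(fit$mbf[fit$id == 2] / fit$mbf[fit$id == 1], 2, tolerance = 1e-3)
})

test_that("MBF is scale-equivariant in the expected way", {
  truth <- list(true_mbf = rep(70, 16), scar_segments = integer(0))
  tac <- generate_tacs(truth, noiseless, seed = 4)
  base <- attr(tac, "baseline_hu")
  sub <- tac[, c("time_s", "aif_hu", "seg01_hu")]
  f0 <- fit_compartment_model(sub, baseline_hu = base)
  # scaling AIF and tissue enhancement together leaves MBF unchanged
  both <- sub
  both$aif_hu <- base + 3 * (sub$aif_hu - base)
  both$seg01_hu <- base + 3 * (sub$seg01_hu - base)
  f1 <- fit_compartment_model(both, baseline_hu = base)
  expect_equal(f1$mbf, f0$mbf, tolerance = 1e-6)
  # scaling tissue only scales MBF by the same factor
  tis <- sub
  tis$seg01_hu <- base + 3 * (sub$seg01_hu - base)
  f2 <- fit_compartment_model(tis, baseline_hu = base)
  expect_equal(f2$mbf, 3 * f0$mbf, tolerance = 1e-6)
})

test_that("median MBF error stays below 10% at 5% peak-enhancement noise", {
  truth <- list(true_mbf = rep(80, 16), scar_segments = integer(0))
  clean <- generate_tacs(truth, noiseless, seed = 5)
  peak <- max(clean$seg01_hu) - noiseless$baseline_hu
  noisy_p <- plan_config(perfusion = list(noise_sd_hu = 0.05 * peak))$perfusion
  errs <- unlist(lapply(1:7, function(s) {
    tac <- generate_tacs(truth, noisy_p, seed = 100 + s)
    fit <- fit_compartment_model(tac)
    abs(fit$mbf / 80 - 1)
  }))
  expect_gte(length(errs), 100)
  expect_lt(median(errs), 0.10)
})

test_that("hypoperfusion classification follows the remote-median rule", {
  res <- tibble::tibble(id = 1:5, mbf = c(80, 80, 80, 80, 30))
  out <- classify_hypoperfusion(res, fraction = 0.6)
  expect_identical(which(out$hypoperfused), 5L)
  uni <- classify_hypoperfusion(tibble::tibble(id = 1:6, mbf = rep(75, 6)))
  expect_false(any(uni$hypoperfused))
  expect_error(classify_hypoperfusion(tibble::tibble(id = 1:4, mbf = rep(2, 4))),
               "no remote reference")
  expect_error(classify_hypoperfusion(tibble::tibble(id = 1:2, mbf = c(80, 80))),
               "at least 3")
})

test_that("generator round-trip: flags reproduce the scar ground truth", {
  hits <- 0
  for (s in c(3, 6, 8, 21)) {
    pat <- generate_lv_geometry(plan_config()$anatomy, seed = s)
    tac <- generate_tacs(pat$truth, plan_config()$perfusion, seed = s)
    fit <- classify_hypoperfusion(fit_compartment_model(tac))
    expect_setequal(fit$id[fit$hypoperfused], pat$truth$scar_segments)
    hits <- hits + length(pat$truth$scar_segments)
  }
  expect_gt(hits, 0) # at least one ischemic patient exercised
})

test_that("late enhancement flags values exceeding the remote median margin", {
  expect_identical(which(detect_late_enhancement(c(30, 30, 30, 60), margin = 0.5)), 4L)
  expect_false(any(detect_late_enhancement(rep(45, 8))))
  # default margin applies when unspecified
  expect_identical(detect_late_enhancement(c(30, 30, 30, 60)),
                   detect_late_enhancement(c(30, 30, 30, 60), margin = 0.5))
})

test_that("degenerate inputs are rejected", {
  truth <- list(true_mbf = rep(80, 16), scar_segments = integer(0))
  tac <- generate_tacs(truth, noiseless, seed = 6)
  expect_error(fit_compartment_model(tac[1:5, ]), "at least 10")
  flataif <- tac
  flataif$aif_hu <- rep(noiseless$baseline_hu, nrow(tac))
  expect_error(fit_compartment_model(flataif, baseline_hu = noiseless$baseline_hu),
               "AIF peak")
})
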