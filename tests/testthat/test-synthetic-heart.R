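cfg0 <- plan_config()

test_that("anatomy generator is byte-identical under a fixed seed", {
  a <- generate_lv_geometry(cfg0$anatomy, seed = 42)
  b <- generate_lv_geometry(cfg0$anatomy, seed = 42)
  expect_identical(a, b)
  c <- generate_lv_geometry(cfg0$anatomy, seed = 43)
  expect_false(identical(a$truth, c$truth))
})

test_that("degenerate thin distribution yields no thin segments", {
  p <- plan_config(anatomy = list(thin_mean = 0, thin_sd = 0))$anatomy
  pat <- generate_lv_geometry(p, seed = 1)
  expect_length(pat$truth$thin_segments, 0)
  expect_true(all(pat$truth$thickness_mm >= 5))
})

test_that("ground truth is internally consistent", {
  for (s in 1:12) {
    tr <- generate_lv_geometry(cfg0$anatomy, seed = s)$truth
    expect_length(intersect(tr$true_target_segments,
                            union(tr$thin_segments, tr$scar_segments)), 0)
    if (length(tr$true_target_segments)) {
      expect_length(tr$true_target_segments, 2)
      expect_true(tr$true_target_segments[2] %in%
                    aha_neighbors(tr$true_target_segments[1]))
    }
    if (length(tr$scar_segments)) {
      expect_true(all(tr$true_mbf[tr$scar_segments] <
                        0.5 * median(tr$true_mbf[-tr$scar_segments])))
      expect_true(all(tr$ahr_class[tr$scar_segments] == "scarred"))
    }
    expect_true(all(sort(unique(tr$ahr_class)) %in%
                      c("nontarget_viable", "scarred", "target")))
  }
})

test_that("motion peaks at the configured time-to-peak and scar is akinetic", {
  pat <- generate_lv_geometry(cfg0$anatomy, seed = 5)
  mot <- generate_motion(pat$geometry, pat$truth, cfg0$mechanics, seed = 5)
  tr <- mot$truth
  # read displacement argmax straight off the generated frames
  prim <- tr$true_target_segments[1]
  faces_in <- pat$geometry$segment_labels == prim
  vids <- unique(as.vector(pat$geometry$endo_faces[faces_in, ]))
  ref <- mot$sequence$positions[[1]][vids, , drop = FALSE]
  disp <- vapply(mot$sequence$positions, function(pos) {
    mean(sqrt(rowSums((pos[vids, , drop = FALSE] - ref)^2)))
  }, numeric(1))
  peak_phase <- mot$sequence$phases[which.max(disp)]
  # frame grid is 0.05 wide; allow one step for boundary-vertex blending
  expect_lt(abs(peak_phase - tr$true_ttp[prim]), 0.05 + 1e-9)
  # scarred segments move less than any viable segment (strain amplitudes)
  if (length(tr$scar_segments)) {
    sc <- compute_strain_curves(mot$sequence, pat$geometry)
    amp <- sc$curves |>
      dplyr::group_by(id) |>
      dplyr::summarise(a = max(area_change) - min(area_change))
    expect_lt(max(amp$a[amp$id %in% tr$scar_segments]),
              min(amp$a[!amp$id %in% tr$scar_segments]))
  }
})

test_that("zero contraction amplitude reproduces the static geometry", {
  p <- plan_config(mechanics = list(amp_viable_min = 0, amp_viable_max = 0,
                                    amp_scar = 0))$mechanics
  pat <- generate_lv_geometry(cfg0$anatomy, seed = 2)
  mot <- generate_motion(pat$geometry, pat$truth, p, seed = 2)
  for (pos in mot$sequence$positions) {
    expect_equal(pos, pat$geometry$endo_vertices, tolerance = 1e-12)
  }
  expect_identical(mot$sequence$positions[[1]], pat$geometry$endo_vertices)
})

test_that("noiseless tissue curves equal the analytic forward model and scale linearly", {
  p <- plan_config(perfusion = list(noise_sd_hu = 0))$perfusion
  truth1 <- list(true_mbf = rep(80, 16), scar_segments = integer(0))
  tac1 <- generate_tacs(truth1, p, seed = 9)
  aif_enh <- tac1$aif_hu - p$baseline_hu
  clean <- tac_forward_model(tac1$time_s, aif_enh, 80, p$tc_s, p$t0_s)
  expect_equal(tac1$seg01_hu - p$baseline_hu, clean, tolerance = 1e-12)
  # doubling flow doubles the enhancement
  truth2 <- list(true_mbf = rep(160, 16), scar_segments = integer(0))
  tac2 <- generate_tacs(truth2, p, seed = 9)
  expect_equal(tac2$seg01_hu - p$baseline_hu,
               2 * (tac1$seg01_hu - p$baseline_hu), tolerance = 1e-10)
  # zero flow: flat at baseline
  truth0 <- list(true_mbf = rep(0, 16), scar_segments = integer(0))
  tac0 <- generate_tacs(truth0, p, seed = 9)
  expect_equal(tac0$seg05_hu, rep(p$baseline_hu, nrow(tac0)), tolerance = 1e-12)
  expect_error(generate_tacs(list(true_mbf = rep(-1, 16),
                                  scar_segments = integer(0)), p, seed = 1),
               "non-negative")
})

test_that("pressure generator realizes the class-conditional response", {
  # degenerate distribution: measured AHR equals the configured mean
  p <- plan_config(hemo = list(ahr_target_sd = 0, ahr_target_mean = 20,
                               beat_noise_frac = 0, ectopy_rate = 0))$hemo
  rec <- generate_pressure_traces("target", p, seed = 3)
  ahr <- compute_ahr(dpdt_max(rec$baseline)$dpdt_mean,
                     dpdt_max(rec$paced)$dpdt_mean)
  expect_equal(ahr, 20, tolerance = 1e-6)
  # Monte-Carlo: empirical class means within 2 SE of the configured means
  p2 <- plan_config()$hemo
  means <- c(target = p2$ahr_target_mean,
             nontarget_viable = p2$ahr_nontarget_viable_mean,
             scarred = p2$ahr_scarred_mean)
  sds <- c(p2$ahr_target_sd, p2$ahr_nontarget_viable_sd, p2$ahr_scarred_sd)
  n <- 120
  for (k in seq_along(means)) {
    cls <- names(means)[k]
    draws <- vapply(seq_len(n), function(i) {
      generate_pressure_traces(cls, p2, seed = 11000 + 13 * i)$true_ahr
    }, numeric(1))
    expect_lt(abs(mean(draws) - means[[k]]), 2 * sds[k] / sqrt(n))
  }
  expect_error(generate_pressure_traces("unknown", p2, seed = 1), "ahr_class")
})

test_that("without ectopy, beat-to-beat dP/dt variation reflects only beat noise", {
  p <- plan_config(hemo = list(ectopy_rate = 0))$hemo
  rec <- generate_pressure_traces("target", p, seed = 8)
  beats <- dpdt_max(rec$baseline)$beats
  # the robust filter may trim a tail beat of ordinary jitter, never more
  expect_gte(mean(beats$retained), 0.9)
  expect_lt(sd(beats$dpdt_max) / mean(beats$dpdt_max), 3 * p$beat_noise_frac)
})

test_that("thorax generator: candidate count, unit axes, cohort distribution", {
  pat <- generate_lv_geometry(fast_cfg()$anatomy, seed = 1)
  th3 <- generate_thorax(pat$geometry, cfg0$thorax, seed = 1, n_candidates = 3)
  expect_identical(nrow(th3), 3L)
  expect_length(unique(th3$ics_id), 3)
  axes <- as.matrix(th3[, c("axis_x", "axis_y", "axis_z")])
  expect_equal(rowSums(axes^2), rep(1, 3), tolerance = 1e-12)
  expect_error(generate_thorax(pat$geometry, cfg0$thorax, seed = 1,
                               n_candidates = 0), "at least one")
  counts <- vapply(1:400, function(i) {
    nrow(generate_thorax(pat$geometry, cfg0$thorax, seed = 500 + i))
  }, numeric(1))
  expect_lt(abs(mean(counts == 1) - 0.36), 3 * sqrt(0.36 * 0.64 / 400))
})

test_that("an aligned beam yields zero angle to the aimed segment", {
  pat <- generate_lv_geometry(fast_cfg()$anatomy, seed = 4)
  cent <- segment_centroid(pat$geometry, 5L)
  entry <- cent + c(60, -40, 10)
  axis <- (cent - entry) / sqrt(sum((cent - entry)^2))
  res <- acoustic_intensity(entry, axis, cent)
  expect_equal(res$angle_deg, 0, tolerance = 1e-9)
})
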