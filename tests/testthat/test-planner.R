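test_that("feature table joins all 16 segments and counts viability", {
  tab <- make_feature_table()
  expect_identical(nrow(tab), 16L)
  expect_identical(sum(tab$viable), 16L)
  tab2 <- make_feature_table(thin = 1L, scar = 7L)
  expect_identical(sum(tab2$viable), 14L)
  # id mismatch across inputs is rejected
  pat <- generate_lv_geometry(fast_cfg()$anatomy, seed = 1)
  th <- suppressWarnings(compute_wall_thickness(pat$geometry))
  expect_error(
    build_feature_table(th[-1, ], th, th, tibble::tibble(id = 1:16, mean_ms = 1, max_ms = 2)),
    "1..16"
  )
})

test_that("a segment latest in both maps is the primary target", {
  ttp <- rep(0.30, 16); ttp[11] <- 0.52
  act <- rep(80, 16); act[11] <- 140
  tab <- make_feature_table(ttp = ttp, act = act)
  tg <- select_target_segments(tab)
  expect_identical(tg[1], 11L)
  expect_true(tg[2] %in% aha_neighbors(11L))
})

test_that("the latest electrical segment is skipped when scarred", {
  ttp <- rep(0.30, 16); ttp[5] <- 0.50; ttp[11] <- 0.48
  act <- rep(80, 16); act[6] <- 150; act[5] <- 140; act[11] <- 135
  tab_ok <- make_feature_table(ttp = ttp, act = act)
  tg_ok <- select_target_segments(tab_ok)
  # make the electrically latest segment scar: it must never be selected
  tab_scar <- make_feature_table(ttp = ttp, act = act, scar = 6L)
  tg <- select_target_segments(tab_scar)
  expect_false(6L %in% tg)
  expect_true(all(tab_scar$viable[match(tg, tab_scar$id)]))
  # exhaustive: scarring any single segment never lets it be selected
  for (s in 1:16) {
    tgs <- tryCatch(select_target_segments(make_feature_table(ttp, act, scar = s)),
                    error = function(e) integer(0))
    expect_false(s %in% tgs)
  }
})

test_that("the worked phenotype selects the basal and mid inferolateral pair", {
  # scar across the anteroseptal / anterior / inferior walls, thin apical
  # anterior and inferior, latest mechanics mid inferior + inferolateral,
  # latest electrics basal-to-mid inferolateral
  ttp <- rep(0.30, 16)
  ttp[10] <- 0.48; ttp[11] <- 0.50; ttp[5] <- 0.44
  act <- rep(70, 16)
  act[5] <- 125; act[11] <- 120; act[16] <- 95
  tab <- make_feature_table(
    ttp = ttp, act = act,
    scar = c(1L, 2L, 4L, 7L, 8L, 10L, 14L, 15L),
    thin = c(13L, 15L)
  )
  expect_setequal(select_target_segments(tab), c(5L, 11L))
})

test_that("fewer than two qualifying segments is an error", {
  tab <- make_feature_table(thin = 1:15)
  expect_error(select_target_segments(tab), "no viable target pair")
  # two viable segments but not adjacent: also no pair
  tab2 <- make_feature_table(thin = setdiff(1:16, c(2L, 5L)))
  expect_error(select_target_segments(tab2), "no viable target pair")
  # all flat mechanics
  tab3 <- make_feature_table(flat = 1:16)
  expect_error(select_target_segments(tab3), "no viable target pair")
})

test_that("fusion switch restricts the lateness score to one map", {
  ttp <- rep(0.30, 16); ttp[5] <- 0.55
  act <- rep(70, 16); act[12] <- 150; act[11] <- 140
  tab <- make_feature_table(ttp = ttp, act = act)
  expect_identical(select_target_segments(tab, fusion = "mechanical")[1], 5L)
  expect_identical(select_target_segments(tab, fusion = "electrical")[1], 12L)
})

test_that("acoustic intensity honours its anchors, cutoffs and monotonicity", {
  entry <- c(0, 0, 0); axis <- c(1, 0, 0)
  # normalization anchor: zero angle, zero depth
  at0 <- acoustic_intensity(entry, axis, c(1e-12, 0, 0))
  expect_identical(at0$intensity, 1)
  expect_true(at0$covered)
  # hard cutoff at 30 degrees
  p30 <- c(cos(30 * pi / 180), sin(30 * pi / 180), 0) * 50
  at30 <- acoustic_intensity(entry, axis, p30)
  expect_equal(at30$angle_deg, 30, tolerance = 1e-9)
  expect_identical(at30$intensity, 0)
  expect_false(at30$covered)
  # hard cutoff at 12 cm depth
  at12 <- acoustic_intensity(entry, axis, c(120, 0, 0))
  expect_identical(at12$intensity, 0)
  expect_false(at12$covered)
  # strictly decreasing in depth on (0, 12) cm at zero angle
  ds <- seq(5, 115, by = 5)
  ints <- vapply(ds, function(d) {
    acoustic_intensity(entry, axis, c(d, 0, 0))$intensity
  }, numeric(1))
  expect_true(all(diff(ints) < 0))
  expect_true(all(ints > 0 & ints <= 1))
  expect_error(acoustic_intensity(entry, c(0, 0, 0), c(50, 0, 0)), "zero length")
})

test_that("transmitter ranking prefers coverage and is order-invariant", {
  pat <- generate_lv_geometry(fast_cfg()$anatomy, seed = 3)
  geom <- pat$geometry
  targets <- c(6L, 12L) # basal + mid anterolateral
  c6 <- segment_centroid(geom, 6L)
  aligned_entry <- c6 + c(70, 20, 5)
  aligned_axis <- (c6 - aligned_entry) / sqrt(sum((c6 - aligned_entry)^2))
  # second candidate points 50 degrees away from the target direction
  ang <- 50 * pi / 180
  off_axis <- c(cos(ang) * aligned_axis[1] - sin(ang) * aligned_axis[2],
                sin(ang) * aligned_axis[1] + cos(ang) * aligned_axis[2],
                aligned_axis[3])
  off_axis <- off_axis / sqrt(sum(off_axis^2))
  thorax <- tibble::tibble(
    ics_id = c(4L, 5L),
    entry_x = aligned_entry[1], entry_y = aligned_entry[2], entry_z = aligned_entry[3],
    axis_x = c(aligned_axis[1], off_axis[1]),
    axis_y = c(aligned_axis[2], off_axis[2]),
    axis_z = c(aligned_axis[3], off_axis[3])
  )
  rk <- rank_transmitter_sites(thorax, targets, geom)
  expect_identical(rk$ranking$ics_id[1], 4L)
  # a candidate with zero intensity at the target is never ranked first
  amap <- rk$acoustic_map
  expect_identical(amap$intensity[amap$ics_id == 5 & amap$id == 6], 0)
  # permuting candidate order leaves the ranking unchanged
  rk2 <- rank_transmitter_sites(thorax[2:1, ], targets, geom)
  expect_identical(rk$ranking, rk2$ranking)
  # full 16-segment map per candidate
  expect_identical(nrow(amap), 32L)
  # single-candidate case still returns a coverage report
  rk1 <- rank_transmitter_sites(thorax[1, ], targets, geom)
  expect_identical(nrow(rk1$ranking), 1L)
  expect_true(rk1$adequate_coverage)
  # no candidate covering either target flags inadequate coverage
  rk0 <- rank_transmitter_sites(thorax[2, ], targets, geom)
  expect_false(rk0$adequate_coverage)
})

test_that("selected targets are always viable and adjacent (randomized tables)", {
  set.seed(202)
  n_checked <- 0
  for (i in 1:1000) {
    thin <- sample(1:16, rbinom(1, 8, 0.3))
    scar <- sample(setdiff(1:16, thin), rbinom(1, 5, 0.3))
    flat <- scar
    tab <- make_feature_table(
      ttp = runif(16, 0.2, 0.55),
      act = runif(16, 40, 160),
      thin = thin, scar = scar, flat = flat
    )
    tg <- tryCatch(select_target_segments(tab), error = function(e) NULL)
    if (is.null(tg)) next
    n_checked <- n_checked + 1
    expect_false(any(tg %in% thin))
    expect_false(any(tg %in% scar))
    expect_true(tg[2] %in% aha_neighbors(tg[1]))
  }
  expect_gt(n_checked, 800)
})
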