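test_that("track generator is seeded and honors degenerate settings", {
  td1 <- generate_tracks(4, 4, track_params(duration_hr = 2), seed = 5)
  td2 <- generate_tracks(4, 4, track_params(duration_hr = 2), seed = 5)
  expect_identical(td1$tracks, td2$tracks)
  expect_identical(td1$divisions, td2$divisions)
  expect_setequal(unique(td1$tracks$class), c("dense", "loose"))
  # zero drift and zero jitter: nobody moves
  still <- generate_tracks(3, 3,
                           track_params(duration_hr = 1, jitter_dense_um = 0,
                                        jitter_loose_um = 0, drift_loose_um = 0),
                           seed = 1)
  expect_true(all(tapply(still$tracks$x_um, still$tracks$cell_id,
                         function(x) diff(range(x))) == 0))
  # infinite concentration: every dense division plane exactly AP (0 deg)
  conc <- generate_tracks(30, 0,
                          track_params(duration_hr = 10, kappa_dense = Inf,
                                       rate_dense = 0.5),
                          seed = 2)
  expect_gt(nrow(conc$divisions), 0)
  expect_true(all(conc$divisions$angle_deg == 0))
  expect_error(generate_tracks(-1, 0), ">= 0")
})

test_that("axial statistics match hand-worked cases", {
  s <- division_angle_stats(c(0, 0, 0))
  expect_equal(s$mean_axis, 0)
  expect_equal(s$resultant_length, 1)
  # perpendicular pair: doubled angles are antipodal and cancel
  s2 <- division_angle_stats(c(0, 90))
  expect_equal(s2$resultant_length, 0, tolerance = 1e-12)
  expect_true(is.na(s2$mean_axis))
  expect_error(division_angle_stats(numeric(0)), "at least one")
  # axial identification: relabelling any angle by 180 changes nothing
  set.seed(3)
  ang <- runif(20, 0, 180)
  flip <- ang + 180 * rbinom(20, 1, 0.5)
  expect_equal(division_angle_stats(ang)$resultant_length,
               division_angle_stats(flip)$resultant_length)
  expect_equal(division_angle_stats(ang)$mean_axis,
               division_angle_stats(flip)$mean_axis)
})

test_that("Rayleigh p-value agrees with a simulated null of the resultant length", {
  set.seed(6)
  ang <- runif(80, 0, 180)
  s <- division_angle_stats(ang)
  # oracle: null distribution of the resultant length by direct simulation
  null_r <- vapply(seq_len(4000), function(i) {
    th <- runif(80, 0, 2 * pi)
    sqrt(sum(cos(th))^2 + sum(sin(th))^2) / 80
  }, numeric(1))
  p_mc <- mean(null_r >= s$resultant_length)
  expect_lt(abs(s$p_uniform - p_mc), 0.03)
})

test_that("Rayleigh test holds its nominal type-I error under the axial null", {
  set.seed(77)
  reject <- vapply(seq_len(2000), function(i) {
    division_angle_stats(runif(100, 0, 180))$p_uniform < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.035)
  expect_lte(mean(reject), 0.065)
})

test_that("dense divisions align with AP while loose divisions stay uniform", {
  td <- generate_tracks(150, 150,
                        track_params(duration_hr = 10, rate_dense = 0.2,
                                     rate_loose = 0.2, kappa_dense = 4),
                        seed = 11)
  dense_ids <- unique(td$tracks$cell_id[td$tracks$class == "dense"])
  dense_ang <- td$divisions$angle_deg[td$divisions$cell_id %in% dense_ids]
  loose_ang <- td$divisions$angle_deg[!td$divisions$cell_id %in% dense_ids]
  sd_ <- division_angle_stats(dense_ang)
  sl <- division_angle_stats(loose_ang)
  expect_lt(sd_$p_uniform, 1e-6)
  expect_true(sd_$mean_axis < 20 || sd_$mean_axis > 160)
  expect_gt(sl$p_uniform, 0.01)
  expect_gt(sd_$resultant_length, sl$resultant_length)
})

test_that("migration bias flags empty reports and recovers drift", {
  still <- generate_tracks(0, 10,
                           track_params(duration_hr = 1, jitter_loose_um = 0,
                                        drift_loose_um = 0),
                           seed = 4)
  rep0 <- migration_bias(still, "loose")
  expect_true(rep0$empty)
  expect_identical(rep0$n_qualifying, 0L)

  # strong ventral drift: CI excludes zero in nearly all seeds
  hits <- vapply(seq_len(25), function(s) {
    td <- generate_tracks(0, 15,
                          track_params(duration_hr = 2, drift_loose_um = -5,
                                       jitter_loose_um = 2),
                          seed = 100 + s)
    r <- migration_bias(td, "loose", min_displacement = 20, n_boot = 400,
                        seed = s)
    r$ci_dv_um[2] < 0 && r$mean_dv_um < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("bootstrap CI covers zero at the nominal rate without drift", {
  covered <- vapply(seq_len(60), function(s) {
    td <- generate_tracks(0, 40,
                          track_params(duration_hr = 2, drift_loose_um = 0,
                                       jitter_loose_um = 6),
                          seed = 500 + s)
    r <- migration_bias(td, "loose", min_displacement = 10, n_boot = 400,
                        seed = s)
    r$ci_dv_um[1] <= 0 && r$ci_dv_um[2] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 1)
})

test_that("translation of coordinates leaves every statistic unchanged", {
  td <- generate_tracks(10, 10, track_params(duration_hr = 2), seed = 9)
  shifted <- td
  shifted$tracks$x_um <- shifted$tracks$x_um + 1234
  shifted$tracks$y_um <- shifted$tracks$y_um - 987
  a <- migration_bias(td, "loose", n_boot = 100, seed = 1)
  b <- migration_bias(shifted, "loose", n_boot = 100, seed = 1)
  expect_equal(a$mean_dv_um, b$mean_dv_um)
  expect_equal(a$n_qualifying, b$n_qualifying)
  expect_equal(proliferation_rates(td)$loose$rate,
               proliferation_rates(shifted)$loose$rate)
})

test_that("proliferation rates: zero-division case and bookkeeping invariance", {
  td <- generate_tracks(5, 0, track_params(duration_hr = 2, rate_dense = 0),
                        seed = 2)
  pr <- proliferation_rates(td)
  expect_equal(pr$dense$divisions, 0)
  expect_equal(pr$dense$rate, 0)
  expect_equal(pr$dense$ci[1], 0)
  expect_gt(pr$dense$ci[2], 0)  # exact Poisson upper bound stays positive

  # splitting one track into two contiguous tracks leaves rates unchanged
  td2 <- generate_tracks(4, 4, track_params(duration_hr = 4, rate_dense = 0.3,
                                            rate_loose = 0.3), seed = 13)
  pr1 <- proliferation_rates(td2)
  tr <- td2$tracks
  id <- tr$cell_id[tr$class == "dense"][1]
  rows <- which(tr$cell_id == id)
  cut <- tr$t_hr[rows] > 2
  tr$cell_id[rows[cut]] <- paste0(id, "_b")
  # keep the halves contiguous: duplicate the boundary frame into the tail
  boundary <- tr[rows[max(which(!cut))], ]
  tail_start <- boundary; tail_start$cell_id <- paste0(id, "_b")
  tr <- rbind(tr, tail_start)
  dv <- td2$divisions
  move <- dv$cell_id == id & dv$t_hr > 2
  dv$cell_id[move] <- paste0(id, "_b")
  split_td <- structure(list(tracks = tr, divisions = dv), class = "track_dataset")
  pr2 <- proliferation_rates(split_td)
  expect_equal(pr2$dense$divisions, pr1$dense$divisions)
  expect_equal(pr2$dense$cell_hours, pr1$dense$cell_hours, tolerance = 1e-9)
  expect_equal(pr2$dense$rate, pr1$dense$rate, tolerance = 1e-9)
})

test_that("rate ratio between classes is recovered", {
  td <- generate_tracks(300, 300,
                        track_params(duration_hr = 10, rate_dense = 0.05,
                                     rate_loose = 0.10),
                        seed = 23)
  pr <- proliferation_rates(td)
  expect_gt(pr$loose$rate, pr$dense$rate)
  expect_true(pr$ratio$ci[1] <= 2.0 && 2.0 <= pr$ratio$ci[2])
})
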