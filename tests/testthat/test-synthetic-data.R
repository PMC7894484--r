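test_that("toy bundle has exact backbone geometry and is reproducible", {
  toy <- gen_toy_structure(251, 7)
  expect_equal(nrow(toy$atoms), 251L)
  expect_equal(toy$atoms$residue_number, 3:253)
  d <- sqrt(rowSums(diff(as.matrix(toy$atoms[, c("x", "y", "z")]))^2))
  expect_true(all(abs(d - 3.8) <= 0.01))

  again <- gen_toy_structure(251, 7)
  expect_identical(toy$atoms, again$atoms)
  expect_error(gen_toy_structure(10, 7), "infeasible")
})

test_that("native-run generator is seeded, centred and recovers its noise scale", {
  toy <- gen_toy_structure(40, 2)
  crystal <- select_calpha(toy)

  silent <- gen_native_runs(toy, sigma = 0, drift = 0, n_runs = 2,
                            window = c(90, 91), interval = 0.5, seed = 3)
  expect_equal(native_state_score(silent, crystal, c(90, 91), 0.5)$mean, 0,
               tolerance = 1e-9)

  r1 <- gen_native_runs(toy, 0.5, n_runs = 2, window = c(90, 92),
                        interval = 0.5, seed = 11)
  r2 <- gen_native_runs(toy, 0.5, n_runs = 2, window = c(90, 92),
                        interval = 0.5, seed = 11)
  expect_equal(native_state_score(r1, crystal, c(90, 92), 0.5)$mean,
               native_state_score(r2, crystal, c(90, 92), 0.5)$mean,
               tolerance = 1e-12)

  # moment contract: fitted displacements are mean-zero with s.d. sigma
  sigma <- 0.6
  runs <- gen_native_runs(toy, sigma, n_runs = 3, window = c(90, 100),
                          interval = 0.2, seed = 5)
  devs <- unlist(lapply(runs, function(run) {
    lapply(run$snapshots, function(m) {
      fit <- kabsch_superpose(select_calpha(m), crystal)
      as.numeric(fit$fitted - crystal$points)
    })
  }))
  n <- length(devs)   # ~18k values
  expect_lt(abs(mean(devs)), 3 * sigma / sqrt(n))
  # the rigid fit absorbs 6 of 3N degrees of freedom per snapshot
  expected_sd <- sigma * sqrt(1 - 6 / (3 * nrow(crystal$points)))
  expect_lt(abs(sd(devs) - expected_sd), 0.02 * sigma)

  # group mean agrees with a direct Monte-Carlo expectation of the same model
  score <- native_state_score(runs, crystal, c(90, 100), 0.2)
  set.seed(99)
  mc <- replicate(2000, {
    noisy <- crystal$points + matrix(rnorm(length(crystal$points), sd = sigma),
                                     ncol = 3)
    bio3d_rmsd(noisy, crystal$points)
  })
  n_frames <- 3 * 51
  expect_lt(abs(score$mean - mean(mc)),
            3 * sd(mc) * sqrt(1 / n_frames + 1 / length(mc)))
})

test_that("coil generator collapses at scale zero and grows with scale", {
  toy <- gen_toy_structure(40, 2)
  frozen <- gen_coil_ensemble(toy, 0, 5, seed = 1)
  expect_equal(superposed_rmsd(select_calpha(frozen[[1]]),
                               select_calpha(frozen[[5]])), 0,
               tolerance = 1e-9)

  means <- vapply(c(0.2, 0.45, 0.8), function(sc) {
    mean(vapply(1:10, function(s) {
      medoid_representative(gen_coil_ensemble(toy, sc, 8, seed = s))$mean_rmsd
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))

  twenty <- gen_coil_ensemble(toy, 0.5, 20, seed = 9)
  expect_length(medoid_representative(twenty)$rmsd_to_others, 19L)
  expect_identical(
    select_calpha(gen_coil_ensemble(toy, 0.5, 3, seed = 2)[[1]])$points,
    select_calpha(gen_coil_ensemble(toy, 0.5, 3, seed = 2)[[1]])$points)
})

test_that("decoloration generator matches its closed form and is seeded", {
  flat <- gen_decoloration(0, 0:10, noise_sd = 0)
  expect_true(all(flat$pigment_pct == 100))
  clean <- gen_decoloration(0.21, 0:10, noise_sd = 0)
  expect_equal(clean$pigment_pct[clean$time_min == 4], 100 * exp(-0.21 * 4),
               tolerance = 1e-9)
  expect_equal(round(clean$pigment_pct[clean$time_min == 4], 1), 43.2)
  a <- gen_decoloration(0.1, 0:10, noise_sd = 2, seed = 8)
  b <- gen_decoloration(0.1, 0:10, noise_sd = 2, seed = 8)
  expect_identical(a$pigment_pct, b$pigment_pct)
  expect_equal(a$pigment_pct[1], 100)   # t = 0 is the normalization point
  expect_error(gen_decoloration(-1, 0:10), "non-negative")
})

test_that("DSC generator inverts through the processing chain at grid precision", {
  g <- gen_dsc(95.93, width = 3, baseline_slope = 0.01, grid = 0.01,
               noise_sd = 0, seed = 1)
  tm <- extract_tm(process_dsc(g$sample, g$buffer, molar_conc = 1.5e-5))
  expect_equal(tm, 95.93, tolerance = 1e-9)
  a <- gen_dsc(95, noise_sd = 0.01, grid = 0.5, seed = 3)
  b <- gen_dsc(95, noise_sd = 0.01, grid = 0.5, seed = 3)
  expect_identical(a$sample$signal, b$sample$signal)
  expect_error(gen_dsc(20), "inside the scan window")
})

test_that("distance-trace generator hits the requested occupancy exactly", {
  expect_equal(ion_pair_occupancy(gen_distance_trace(10, 0))$occupancy_percent, 0)
  expect_equal(ion_pair_occupancy(gen_distance_trace(10, 10))$occupancy_percent, 100)
  d <- gen_distance_trace(501, 460, seed = 6)
  expect_equal(sum(d <= 5), 460L)
  expect_true(all(d >= 2.5 & d <= 12))
  expect_error(gen_distance_trace(10, 11), "n_below")
})

test_that("construct presets carry the printed panel parameters", {
  ps <- construct_presets()
  stab <- tr_stability()
  expect_setequal(names(ps), stab$construct)
  expect_equal(ps$WT$k, 0.21)
  expect_equal(ps$T114D$tm, 95.93)
  expect_equal(ps$T114D$k, 0.069)
  expect_equal(ps$WT$residual_pigment, 44.5)
  # only the one construct with a reported coil difference has a larger scale
  coil_scales <- vapply(ps, `[[`, numeric(1), "coil_scale")
  expect_gt(coil_scales[["S8D"]], coil_scales[["WT"]])
  expect_true(all(coil_scales[setdiff(names(ps), "S8D")] == coil_scales[["WT"]]))
  expect_true(all(vapply(ps, `[[`, numeric(1), "native_sigma") > 0))
})
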