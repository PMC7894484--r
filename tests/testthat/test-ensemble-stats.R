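toy60 <- gen_toy_structure(60, 3)
crystal60 <- select_calpha(toy60)

test_that("frame sampling arithmetic is endpoint-inclusive with tolerance matching", {
  times <- seq(0, 100, by = 0.2)
  expect_length(sample_snapshots(times, c(90, 100), 0.2), 51L)
  expect_length(sample_snapshots(times, c(0, 100), 0.2), 501L)
  expect_length(sample_snapshots(times, c(90, 90), 0.2), 1L)
  # nearest-frame matching within half an interval
  jitter <- times + 0.05
  expect_length(sample_snapshots(jitter, c(90, 100), 0.2), 51L)
  expect_error(sample_snapshots(c(0, 50, 100), c(90, 100), 0.2), "no frame")
  expect_error(sample_snapshots(times, c(90, 100), -1), "positive")
})

test_that("native-state score is zero for crystal-identical runs and matches an independent oracle", {
  frozen <- lapply(1:2, function(r) {
    ensemble(rep(list(toy60), 3), c(90, 95, 100), run_id = r)
  })
  ns0 <- native_state_score(frozen, crystal60, c(90, 100), 5)
  expect_equal(ns0$mean, 0, tolerance = 1e-12)
  expect_equal(ns0$sem, 0, tolerance = 1e-12)

  runs <- gen_native_runs(toy60, sigma = 0.6, n_runs = 3,
                          window = c(90, 100), interval = 0.5, seed = 21)
  ns <- native_state_score(runs, crystal60, c(90, 100), 0.5)
  oracle <- vapply(runs, function(run) {
    idx <- sample_snapshots(run$times, c(90, 100), 0.5)
    mean(vapply(run$snapshots[idx], function(m) {
      bio3d_rmsd(calpha_points(m), crystal60$points)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(ns$per_run_mean_rmsd, oracle, tolerance = 1e-6)
  expect_equal(ns$mean, mean(oracle), tolerance = 1e-6)
  expect_equal(ns$sem, sd(oracle) / sqrt(3), tolerance = 1e-6)
  expect_error(native_state_score(runs[1], crystal60), "at least 2")
})

test_that("native-state score is invariant to rigid-body motion of a snapshot", {
  runs <- gen_native_runs(toy60, sigma = 0.4, n_runs = 2,
                          window = c(90, 100), interval = 1, seed = 9)
  ns1 <- native_state_score(runs, crystal60, c(90, 100), 1)
  R <- thermoshift:::.rot_about(c(1, 2, 3), 1.1)
  m <- runs[[1]]$snapshots[[4]]
  pts <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  pts <- sweep(pts, 2, c(30, -12, 4), `+`)
  m$atoms$x <- pts[, 1]; m$atoms$y <- pts[, 2]; m$atoms$z <- pts[, 3]
  runs[[1]]$snapshots[[4]] <- m
  ns2 <- native_state_score(runs, crystal60, c(90, 100), 1)
  expect_equal(ns1$mean, ns2$mean, tolerance = 1e-9)
})

test_that("medoid selection matches exhaustive enumeration", {
  # identical members: tie broken at the lowest index, all RMSDs zero
  same <- medoid_representative(rep(list(toy60), 4))
  expect_equal(same$representative_index, 1L)
  expect_equal(max(same$rmsd_to_others), 0, tolerance = 1e-9)

  # B is the coordinate midpoint of A and C, so B must be the medoid
  A <- calpha_points(toy60)
  C <- A + matrix(rnorm(length(A), sd = 2), nrow(A), 3)
  B <- (A + C) / 2
  mid <- medoid_representative(lapply(list(A, B, C), function(p) {
    coordinate_set(p, crystal60$labels, crystal60$masses)
  }))
  expect_equal(mid$representative_index, 2L)

  # seeded 20-member coil ensemble against the brute-force oracle
  coil <- gen_coil_ensemble(toy60, 0.5, 20, seed = 31)
  med <- medoid_representative(coil)
  oracle <- enumerate_medoid(lapply(coil, calpha_points))
  expect_equal(med$representative_index, oracle$index)
  expect_equal(med$mean_rmsd, oracle$mean_rmsd, tolerance = 1e-6)
  expect_length(med$rmsd_to_others, 19L)
  expect_equal(med$mean_rmsd, mean(med$rmsd_to_others), tolerance = 1e-12)
})

test_that("coil fluctuation comparison handles self-comparison and missing wild type", {
  coil <- gen_coil_ensemble(toy60, 0.5, 6, seed = 12)
  res <- suppressWarnings(
    coil_fluctuation_compare(list(WT = coil, SAME = coil), "WT"))
  expect_equal(res$comparisons$SAME$p_two_tailed, 1, tolerance = 1e-12)
  expect_error(coil_fluctuation_compare(list(A = coil), "WT"), "not found")
})

test_that("per-residue deviations vanish for crystal-identical runs", {
  frozen <- lapply(1:2, function(r) {
    ensemble(rep(list(toy60), 3), c(90, 95, 100), run_id = r)
  })
  prof <- per_residue_deviation(frozen, crystal60, c(90, 100), 5)
  expect_equal(max(prof$mean_deviation), 0, tolerance = 1e-9)
  cmp <- compare_residue_profiles(prof, prof)
  expect_false(any(cmp$flagged))
})

test_that("null per-residue comparison flags about the nominal share of residues", {
  # same construct, disjoint halves of one long run set: type-I behaviour
  reps <- 8
  flags <- vapply(seq_len(reps), function(r) {
    a <- gen_native_runs(toy60, 0.3, n_runs = 3, window = c(90, 100),
                         interval = 0.5, seed = 400 + 2 * r)
    b <- gen_native_runs(toy60, 0.3, n_runs = 3, window = c(90, 100),
                         interval = 0.5, seed = 401 + 2 * r)
    pa <- per_residue_deviation(a, crystal60, c(90, 100), 0.5)
    pb <- per_residue_deviation(b, crystal60, c(90, 100), 0.5)
    sum(compare_residue_profiles(pa, pb)$flagged)
  }, numeric(1))
  rate <- sum(flags) / (reps * 60)
  # two-sided flag, so the null rate is alpha/2; allow a 3-sigma binomial band
  band <- 3 * sqrt(0.025 * 0.975 / (reps * 60))
  expect_lt(rate, 0.025 + band)
})

test_that("radius of gyration follows the closed forms and scaling law", {
  one <- coordinate_set(matrix(c(1, 2, 3), 1, 3))
  expect_equal(radius_of_gyration(one), 0)
  two <- coordinate_set(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two), 0.1, tolerance = 1e-12)

  pts <- calpha_points(toy60)
  cs <- coordinate_set(pts)
  rg <- radius_of_gyration(cs)
  com <- colMeans(pts)
  scaled <- coordinate_set(sweep(sweep(pts, 2, com) * 2.5, 2, com, `+`))
  expect_equal(radius_of_gyration(scaled), 2.5 * rg, tolerance = 1e-12)
})

test_that("gyration trace recovers a generator expansion curve within its error bars", {
  # runs whose frames are the toy structure inflated about its centre of
  # mass toward 1.5x, plus small random scale noise per run and frame
  times <- seq(0, 1, by = 0.1)
  pts <- calpha_points(toy60)
  com <- colMeans(pts)
  rg0 <- radius_of_gyration(coordinate_set(pts))
  target <- rg0 * (1 + 0.5 * (1 - exp(-times / 0.3)))
  set.seed(77)
  runs <- lapply(1:4, function(r) {
    snaps <- lapply(seq_along(times), function(i) {
      f <- (target[i] / rg0) * (1 + rnorm(1, sd = 0.01))
      m <- toy60
      p <- sweep(sweep(pts, 2, com) * f, 2, com, `+`)
      m$atoms$x <- p[, 1]; m$atoms$y <- p[, 2]; m$atoms$z <- p[, 3]
      m
    })
    ensemble(snaps, times, run_id = r)
  })
  tr <- gyration_trace(runs)
  expect_true(all(abs(tr$rg_mean - target) <= 2 * tr$rg_sem + 1e-9))
  expect_error(gyration_trace(runs[1]), "at least 2")

  frozen <- lapply(1:2, function(r) ensemble(rep(list(toy60), 3),
                                             c(0, 1, 2), run_id = r))
  ft <- gyration_trace(frozen)
  expect_equal(max(ft$rg_sem), 0, tolerance = 1e-12)
  expect_equal(diff(range(ft$rg_mean)), 0, tolerance = 1e-12)
})

test_that("ion-pair occupancy counts boundary-inclusive satisfying frames", {
  expect_equal(ion_pair_occupancy(rep(3, 10))$occupancy_percent, 100)
  expect_equal(ion_pair_occupancy(c(5.0, 7))$n_satisfying, 1L)
  tr <- ion_pair_occupancy(gen_distance_trace(501, 460, seed = 2))
  expect_equal(tr$n_satisfying, 460L)
  expect_equal(round(tr$occupancy_percent, 1), 91.8)
  expect_equal(round(tr$occupancy_percent), 92)
  # exact relation before any rounding
  expect_equal(tr$occupancy_percent * length(tr$distances) / 100,
               tr$n_satisfying, tolerance = 1e-12)

  # ensemble input: distance between two named C-alpha atoms
  frozen <- ensemble(rep(list(toy60), 3), c(0, 1, 2))
  a <- toy60$atoms
  d <- sqrt(sum((a[a$residue_number == 10, c("x", "y", "z")] -
                   a[a$residue_number == 20, c("x", "y", "z")])^2))
  ip <- ion_pair_occupancy(frozen, pair = list(list("A", 10, "CA"),
                                               list("A", 20, "CA")),
                           cutoff = d + 0.1)
  expect_equal(ip$occupancy_percent, 100)
  expect_error(ion_pair_occupancy(frozen, pair = list(list("A", 10, "CB"),
                                                      list("A", 20, "CA"))),
               "not found")
})
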