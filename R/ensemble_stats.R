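# Structural statistics over snapshot ensembles: frame sampling, native-state
# RMSD scoring against a crystal reference, medoid representative selection
# for random-coil ensembles, per-residue deviations, radius of gyration and
# ion-pair distance occupancy.

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Indices of frames sampled at a fixed interval over a time window
#'
#' Requested times are `start, start + interval, ..., end`, both endpoints
#' included; each is matched to the nearest frame within `interval / 2`.
#' Sampling every 0.2 ns over 90-100 ns therefore yields 51 frames, and over
#' 0-100 ns 501 frames.
#'
#' @param times frame time stamps in ns (strictly increasing).
#' @param window numeric pair `c(start, end)` in ns.
#' @param interval sampling interval in ns.
#' @return Integer vector of 1-based frame indices.
#' @export
sample_snapshots <- function(times, window, interval) {
  if (interval <= 0) stop("interval must be positive")
  if (length(window) != 2L || window[2] < window[1]) {
    stop("window must be c(start, end) with end >= start")
  }
  k <- round((window[2] - window[1]) / interval)
  if (abs(window[1] + k * interval - window[2]) > interval / 2) {
    stop("window length is not a multiple of the interval")
  }
  wanted <- window[1] + (0:k) * interval
  idx <- vapply(wanted, function(w) {
    j <- which.min(abs(times - w))
    if (abs(times[j] - w) > interval / 2 + 1e-9) {
      stop(sprintf("no frame within %.4g ns of requested time %.4g ns",
                   interval / 2, w))
    }
    j
  }, integer(1))
  idx
}

.run_calpha <- function(run, residue_range = "all") {
  lapply(run$snapshots, select_calpha, residue_range = residue_range)
}

#' Native-state RMSD score of a construct
#'
#' For each independent run, snapshots sampled over `window` at `interval`
#' are superposed on the crystal reference at corresponding C-alpha atoms
#' and their RMSDs averaged; the per-run averages are then summarised as
#' mean and standard error across runs.  A small per-run mean indicates the
#' native fold is retained.
#'
#' @param runs list of [ensemble] objects (independent runs, >= 2).
#' @param crystal [coordinate_set] of the reference C-alpha atoms.
#' @param window,interval sampling window (ns) and interval (ns).
#' @param residue_range residue range passed to [select_calpha()].
#' @return An object of class `run_group_stats`: `per_run_mean_rmsd`, `mean`,
#'   `sem`, `n_runs` (all RMSDs in Angstrom).
#' @export
native_state_score <- function(runs, crystal, window = c(90, 100),
                               interval = 0.2, residue_range = "all") {
  if (length(runs) < 2L) stop("need at least 2 independent runs")
  per_run <- vapply(runs, function(run) {
    idx <- sample_snapshots(run$times, window, interval)
    sets <- lapply(run$snapshots[idx], select_calpha, residue_range = residue_range)
    mean(vapply(sets, function(s) kabsch_superpose(s, crystal)$rmsd, numeric(1)))
  }, numeric(1))
  structure(list(per_run_mean_rmsd = per_run, mean = mean(per_run),
                 sem = .sem(per_run), n_runs = length(per_run)),
            class = "run_group_stats")
}

#' @export
print.run_group_stats <- function(x, ...) {
  cat(sprintf("run_group_stats: %.3f +/- %.3f A (n = %d runs)\n",
              x$mean, x$sem, x$n_runs))
  invisible(x)
}

#' Medoid representative of a structural ensemble
#'
#' Computes all pairwise superposition RMSDs within the ensemble, selects
#' the member with the smallest mean RMSD to the others (ties broken by the
#' lowest index), and returns that member's RMSDs to the remaining members.
#' For a denatured (random-coil) ensemble this n-1 value group quantifies
#' the intramolecular structural variation, a proxy for denatured-state
#' entropy.
#'
#' @param members list of [structure_model] or [coordinate_set] objects
#'   (n >= 3).
#' @param residue_range residue range for the C-alpha selection.
#' @return An object of class `medoid_result`: `representative_index`,
#'   `rmsd_to_others` (length n-1), `mean_rmsd`, `sem`, and the full
#'   `pairwise` RMSD matrix.
#' @export
medoid_representative <- function(members, residue_range = "all") {
  n <- length(members)
  if (n < 3L) stop("need at least 3 ensemble members")
  sets <- lapply(members, function(m) {
    if (inherits(m, "coordinate_set")) m else select_calpha(m, residue_range)
  })
  npts <- vapply(sets, function(s) nrow(s$points), integer(1))
  if (length(unique(npts)) != 1L) stop("members have mismatched atom selections")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- kabsch_superpose(sets[[i]], sets[[j]])$rmsd
    }
  }
  mean_to_others <- rowSums(D) / (n - 1L)
  rep_idx <- which.min(mean_to_others)   # which.min takes the lowest index on ties
  others <- D[rep_idx, -rep_idx]
  structure(list(representative_index = rep_idx, rmsd_to_others = others,
                 mean_rmsd = mean(others), sem = .sem(others), pairwise = D),
            class = "medoid_result")
}

#' @export
print.medoid_result <- function(x, ...) {
  cat(sprintf(
    "medoid_result: representative %d, rmsd to others %.2f +/- %.2f A (n = %d)\n",
    x$representative_index, x$mean_rmsd, x$sem, length(x$rmsd_to_others)))
  invisible(x)
}

#' Compare random-coil fluctuation statistics across constructs
#'
#' Runs [medoid_representative()] on each construct's coil ensemble and
#' compares every mutant's RMSD group against the wild type with the
#' branching test protocol ([compare_groups()]).  A significantly larger
#' mutant mean suggests higher denatured-state entropy, hence
#' destabilization.
#'
#' @param ensembles named list, one entry per construct, each a list of
#'   [structure_model]s (equal sizes).
#' @param wild_type name of the wild-type entry.
#' @param residue_range residue range for the C-alpha selection.
#' @param alpha significance level for the protocol.
#' @return List with `medoids` (named list of `medoid_result`) and
#'   `comparisons` (named list of `stat_comparison` vs the wild type).
#' @export
coil_fluctuation_compare <- function(ensembles, wild_type = "WT",
                                     residue_range = "all", alpha = 0.05) {
  if (!wild_type %in% names(ensembles)) {
    stop("wild-type entry '", wild_type, "' not found")
  }
  sizes <- vapply(ensembles, length, integer(1))
  if (length(unique(sizes)) != 1L) stop("construct ensembles differ in size")
  medoids <- lapply(ensembles, medoid_representative, residue_range = residue_range)
  wt <- medoids[[wild_type]]$rmsd_to_others
  mutants <- setdiff(names(ensembles), wild_type)
  comparisons <- lapply(medoids[mutants], function(m) {
    compare_groups(m$rmsd_to_others, wt, alpha = alpha)
  })
  list(medoids = medoids, comparisons = comparisons)
}

#' Per-residue C-alpha deviations from a crystal reference
#'
#' After one global C-alpha superposition per sampled snapshot (no
#' per-residue refit), the Euclidean deviation of each residue's C-alpha
#' from the reference is averaged over snapshots within each run.
#'
#' @param runs list of [ensemble] objects (>= 2 runs).
#' @param crystal [coordinate_set] of reference C-alpha atoms.
#' @param window,interval sampling window and interval (ns).
#' @param residue_range residue range for the selection.
#' @return An object of class `residue_deviation_profile`:
#'   `residue_numbers`, `per_run_deviation` (runs x residues, Angstrom),
#'   `mean_deviation`.
#' @export
per_residue_deviation <- function(runs, crystal, window = c(90, 100),
                                  interval = 0.2, residue_range = "all") {
  if (length(runs) < 2L) stop("need at least 2 independent runs")
  resnos <- crystal$labels$residue_number
  per_run <- t(vapply(runs, function(run) {
    idx <- sample_snapshots(run$times, window, interval)
    sets <- lapply(run$snapshots[idx], select_calpha, residue_range = residue_range)
    devs <- vapply(sets, function(s) {
      if (nrow(s$points) != nrow(crystal$points)) {
        stop("residue selection differs from the reference")
      }
      fit <- kabsch_superpose(s, crystal)
      sqrt(rowSums((fit$fitted - crystal$points)^2))
    }, numeric(nrow(crystal$points)))
    rowMeans(devs)
  }, numeric(length(resnos))))
  structure(list(residue_numbers = resnos, per_run_deviation = per_run,
                 mean_deviation = colMeans(per_run)),
            class = "residue_deviation_profile")
}

#' @export
print.residue_deviation_profile <- function(x, ...) {
  cat(sprintf(
    "residue_deviation_profile: %d residues x %d runs, mean deviation %.2f A\n",
    length(x$residue_numbers), nrow(x$per_run_deviation),
    mean(x$mean_deviation)))
  invisible(x)
}

#' Residues with significantly larger deviations in one construct
#'
#' Per-residue two-tailed Student's t-test across runs between two deviation
#' profiles; a residue is flagged when its mean deviation is larger in
#' `profile` than in `reference_profile` and the test is significant.  No
#' multiple-testing correction is applied by default (a Bonferroni option is
#' provided), mirroring raw per-residue reporting.
#'
#' @param profile,reference_profile `residue_deviation_profile` objects over
#'   the same residues.
#' @param alpha significance level.
#' @param bonferroni apply Bonferroni correction across residues.
#' @return Data frame with `residue_number`, means, `p_value`, `flagged`.
#' @export
compare_residue_profiles <- function(profile, reference_profile, alpha = 0.05,
                                     bonferroni = FALSE) {
  if (!identical(profile$residue_numbers, reference_profile$residue_numbers)) {
    stop("profiles cover different residue sets")
  }
  m <- length(profile$residue_numbers)
  thr <- if (bonferroni) alpha / m else alpha
  p <- vapply(seq_len(m), function(i) {
    a <- profile$per_run_deviation[, i]
    b <- reference_profile$per_run_deviation[, i]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }, numeric(1))
  larger <- colMeans(profile$per_run_deviation) >
    colMeans(reference_profile$per_run_deviation)
  data.frame(residue_number = profile$residue_numbers,
             mean_deviation = colMeans(profile$per_run_deviation),
             reference_mean = colMeans(reference_profile$per_run_deviation),
             p_value = p,
             flagged = larger & p < thr)
}

#' Radius of gyration of a selection
#'
#' `Rg = sqrt( sum m_i |r_i - r_com|^2 / sum m_i )` about the centre of mass
#' of the selection.  Mass-weighted by default; with `mass_weighted = FALSE`
#' all points count equally.  Reported in nanometres (coordinates are
#' Angstrom internally).
#'
#' @param model a [structure_model] or [coordinate_set].
#' @param residue_range residue range for the C-alpha selection when a
#'   structure is given; use `atoms = "all"` to include every atom.
#' @param atoms `"calpha"` (default) or `"all"`.
#' @param mass_weighted logical.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(model, residue_range = "all", atoms = "calpha",
                               mass_weighted = TRUE) {
  if (inherits(model, "coordinate_set")) {
    pts <- model$points
    mass <- model$masses
  } else if (identical(atoms, "all")) {
    a <- model$atoms
    if (!identical(residue_range, "all")) {
      a <- a[a$residue_number >= residue_range[1] &
               a$residue_number <= residue_range[2], , drop = FALSE]
    }
    if (!nrow(a)) stop("empty selection")
    pts <- as.matrix(a[, c("x", "y", "z")])
    mass <- a$mass
  } else {
    s <- select_calpha(model, residue_range)
    pts <- s$points
    mass <- s$masses
  }
  w <- if (mass_weighted) mass else rep(1, nrow(pts))
  if (sum(w) <= 0) stop("zero total mass")
  com <- colSums(pts * w) / sum(w)
  rg_A <- sqrt(sum(w * rowSums(sweep(pts, 2, com)^2)) / sum(w))
  rg_A / 10
}

#' Radius-of-gyration time course averaged over runs
#'
#' @param runs list of [ensemble] objects of equal length (>= 2 runs).
#' @param residue_range,atoms,mass_weighted as in [radius_of_gyration()].
#' @return An object of class `gyration_trace`: `times` (ns), `rg_mean`,
#'   `rg_sem` (nm), `n_runs`.
#' @export
gyration_trace <- function(runs, residue_range = "all", atoms = "calpha",
                           mass_weighted = TRUE) {
  if (length(runs) < 2L) stop("need at least 2 runs (s.e.m. undefined otherwise)")
  lens <- vapply(runs, length, integer(1))
  if (length(unique(lens)) != 1L) stop("runs have unequal frame counts")
  if (!all(vapply(runs[-1], function(r) identical(r$times, runs[[1]]$times),
                  logical(1)))) {
    stop("runs have different time stamps")
  }
  rg <- vapply(runs, function(run) {
    vapply(run$snapshots, radius_of_gyration, numeric(1),
           residue_range = residue_range, atoms = atoms,
           mass_weighted = mass_weighted)
  }, numeric(lens[1]))
  structure(list(times = runs[[1]]$times,
                 rg_mean = rowMeans(rg),
                 rg_sem = apply(rg, 1, .sem),
                 n_runs = length(runs)),
            class = "gyration_trace")
}

#' @export
print.gyration_trace <- function(x, ...) {
  cat(sprintf(
    "gyration_trace: %d time points, Rg %.2f -> %.2f nm (n = %d runs)\n",
    length(x$times), x$rg_mean[1], x$rg_mean[length(x$rg_mean)], x$n_runs))
  invisible(x)
}

.atom_xyz <- function(model, chain, resno, atom_name) {
  a <- model$atoms
  hit <- which(a$chain_id == chain & a$residue_number == resno &
                 a$atom_name == atom_name)
  if (!length(hit)) {
    stop("atom ", chain, ":", resno, ":", atom_name, " not found")
  }
  as.numeric(a[hit[1], c("x", "y", "z")])
}

#' Ion-pair distance occupancy
#'
#' Fraction of frames in which a charged-atom pair distance is not greater
#' than a cutoff (boundary inclusive).  Accepts either a numeric vector of
#' per-frame distances or an [ensemble] plus atom specifications.
#'
#' @param x numeric distances (Angstrom) or an [ensemble].
#' @param pair when `x` is an ensemble: list of two atom specs, each
#'   `list(chain, residue_number, atom_name)`, e.g. Glu6 CD and Lys79 NZ.
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return An object of class `ion_pair_trace`: `distances`, `cutoff`,
#'   `n_satisfying`, `occupancy_percent` (unrounded; round only when
#'   reporting).
#' @export
ion_pair_occupancy <- function(x, pair = NULL, cutoff = 5) {
  if (inherits(x, "ensemble")) {
    if (is.null(pair) || length(pair) != 2L) {
      stop("pair must list two atom specifications")
    }
    distances <- vapply(x$snapshots, function(m) {
      p1 <- .atom_xyz(m, pair[[1]][[1]], pair[[1]][[2]], pair[[1]][[3]])
      p2 <- .atom_xyz(m, pair[[2]][[1]], pair[[2]][[2]], pair[[2]][[3]])
      sqrt(sum((p1 - p2)^2))
    }, numeric(1))
  } else {
    distances <- as.numeric(x)
  }
  if (!length(distances)) stop("no distances")
  n_sat <- sum(distances <= cutoff)
  structure(list(distances = distances, cutoff = cutoff, n_satisfying = n_sat,
                 occupancy_percent = 100 * n_sat / length(distances)),
            class = "ion_pair_trace")
}

#' @export
print.ion_pair_trace <- function(x, ...) {
  cat(sprintf("ion_pair_trace: %d of %d frames <= %.1f A (%.0f%%)\n",
              x$n_satisfying, length(x$distances), x$cutoff,
              round(x$occupancy_percent)))
  invisible(x)
}
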