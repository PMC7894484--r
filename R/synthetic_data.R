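# Seeded generators for every input the pipeline consumes: an idealized
# helical-bundle structure, native-state snapshot runs, random-coil
# conformer ensembles, decoloration decays, DSC thermograms and ion-pair
# distance traces.  All generators restore the caller's RNG state and are
# bitwise-reproducible under a fixed seed.

.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# rotation by `angle` about unit `axis` (Rodrigues)
.rot_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# interior points of a circular arc from A to B: m chords of equal length
# `step`, bulging toward unit vector `bulge` (perpendicular component used)
.arc_points <- function(A, B, step, bulge) {
  D <- sqrt(sum((B - A)^2))
  m <- max(2L, ceiling(D / step) + 1L)       # chords; arc longer than chord
  f <- function(theta) D * sin(theta / (2 * m)) - step * sin(theta / 2)
  theta <- stats::uniroot(f, c(1e-8, 2 * pi - 1e-6), tol = 1e-12)$root
  rho <- D / (2 * sin(theta / 2))
  u <- (B - A) / D
  w <- bulge - sum(bulge * u) * u
  w <- w / sqrt(sum(w^2))
  M <- (A + B) / 2
  # signed centre offset: for arcs subtending more than pi the centre lies
  # on the bulge side
  O <- M - w * (rho * cos(theta / 2))
  axis <- .cross(A - O, B - O)
  if (sqrt(sum(axis^2)) < 1e-9 * rho^2) axis <- .cross(u, w)
  axis <- axis / sqrt(sum(axis^2))
  end <- as.numeric(.rot_about(axis, theta) %*% (A - O)) + O
  if (sum((end - B)^2) > 1e-6) axis <- -axis
  pts <- t(vapply(seq_len(m - 1L), function(k) {
    as.numeric(.rot_about(axis, k * theta / m) %*% (A - O)) + O
  }, numeric(3)))
  pts
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate an idealized helical-bundle C-alpha trace
#'
#' Builds a single-chain C-alpha model of `n_res` residues folded into
#' `n_helices` antiparallel ideal helices (rise 1.5 Angstrom per residue,
#' 100 degrees per turn, radius chosen so consecutive C-alpha atoms are
#' exactly 3.8 Angstrom apart) packed on a circle, connected by arc loops
#' that preserve the 3.8 Angstrom spacing.  Residues are numbered from
#' `first_residue` upward (default 3, mimicking crystal numbering 3-253 at
#' the default size).  The construction is deterministic.
#'
#' @param n_res number of residues (>= 4 per helix).
#' @param n_helices number of helices in the bundle.
#' @param seed accepted for interface symmetry with the other generators.
#' @param bundle_radius distance of helix axes from the bundle axis
#'   (Angstrom); the default 10 approximates seven-transmembrane packing.
#' @param helix_length residues per helix; default splits `n_res` evenly
#'   after a 4-residue loop allowance per connection.
#' @param first_residue first residue number.
#' @return A [structure_model] of C-alpha atoms.
#' @export
gen_toy_structure <- function(n_res = 251, n_helices = 7, seed = 1,
                              bundle_radius = 10, helix_length = NULL,
                              first_residue = 3L) {
  if (n_res < 4 * n_helices) {
    stop("infeasible geometry: need at least 4 residues per helix")
  }
  step <- 3.8; rise <- 1.5; turn <- 100 * pi / 180
  r_hel <- sqrt(step^2 - rise^2) / (2 * sin(turn / 2))
  if (is.null(helix_length)) {
    helix_length <- max(4L, floor((n_res - 4L * (n_helices - 1L)) / n_helices))
  }
  pts <- NULL
  h <- 1L
  while (is.null(pts) || nrow(pts) < n_res) {
    phi <- 2 * pi * (h - 1L) / n_helices
    cx <- bundle_radius * cos(phi); cy <- bundle_radius * sin(phi)
    i <- seq_len(helix_length) - 1L
    up <- h %% 2L == 1L
    z <- if (up) rise * i else rise * (helix_length - 1L) - rise * i
    ang <- phi + turn * i * (if (up) 1 else -1)
    helix <- cbind(cx + r_hel * cos(ang), cy + r_hel * sin(ang), z)
    if (is.null(pts)) {
      pts <- helix
    } else {
      A <- pts[nrow(pts), ]
      B <- helix[1L, ]
      out_dir <- (A + B) / 2
      out_dir[3] <- 0
      if (sum(out_dir^2) < 1e-6) out_dir <- c(1, 0, 0)
      loop <- .arc_points(A, B, step, out_dir / sqrt(sum(out_dir^2)))
      pts <- rbind(pts, loop, helix)
    }
    h <- h + 1L
  }
  pts <- pts[seq_len(n_res), , drop = FALSE]
  atoms <- data.frame(
    atom_name = "CA",
    residue_number = first_residue + seq_len(n_res) - 1L,
    residue_type = "ALA", chain_id = "A",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    mass = 12.011, stringsAsFactors = FALSE
  )
  structure_model(atoms, model_id = 1L)
}

.replace_coords <- function(model, pts, model_id = model$model_id) {
  a <- model$atoms
  a$x <- pts[, 1]; a$y <- pts[, 2]; a$z <- pts[, 3]
  structure_model(a, model_id = model_id)
}

#' Generate native-state snapshot runs
#'
#' Emulates independent equilibrium runs around a reference structure: each
#' run applies one rigid-body offset (random rotation and translation,
#' removed again by superposition) and per-frame displacements composed of
#' a slow AR(1) drift of stationary scale `drift` and independent isotropic
#' Gaussian noise of per-coordinate scale `sigma`.  Optionally extra noise
#' is injected at chosen residues, to plant a localized structural change.
#'
#' @param base reference [structure_model] (e.g. [gen_toy_structure()]).
#' @param sigma per-coordinate noise scale in Angstrom.
#' @param drift stationary scale of the AR(1) drift in Angstrom (0 disables).
#' @param n_runs number of independent runs.
#' @param window,interval time window (ns) and frame interval (ns); frames
#'   cover the window inclusive of both endpoints.
#' @param seed RNG seed.
#' @param perturb_residues integer vector of residue numbers receiving
#'   extra noise.
#' @param perturb_sigma extra per-coordinate noise scale (Angstrom) at the
#'   perturbed residues.
#' @param construct_label label stored on each run.
#' @return List of `n_runs` [ensemble] objects.
#' @export
gen_native_runs <- function(base, sigma, drift = 0, n_runs = 3,
                            window = c(90, 100), interval = 0.2, seed = 1,
                            perturb_residues = NULL, perturb_sigma = 0,
                            construct_label = "") {
  if (sigma < 0 || drift < 0 || perturb_sigma < 0) {
    stop("noise scales must be non-negative")
  }
  times <- window[1] + (0:round((window[2] - window[1]) / interval)) * interval
  n_atoms <- nrow(base$atoms)
  base_pts <- as.matrix(base$atoms[, c("x", "y", "z")])
  extra <- rep(0, n_atoms)
  if (length(perturb_residues)) {
    extra[base$atoms$residue_number %in% perturb_residues] <- perturb_sigma
  }
  phi <- 0.95
  .with_seed(seed, {
    lapply(seq_len(n_runs), function(run) {
      R <- .rot_about(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      shift <- stats::runif(3, -20, 20)
      d <- matrix(0, n_atoms, 3)
      snaps <- lapply(seq_along(times), function(fr) {
        if (drift > 0) {
          d <<- phi * d + sqrt(1 - phi^2) *
            matrix(stats::rnorm(n_atoms * 3, sd = drift), n_atoms, 3)
        }
        noise <- matrix(stats::rnorm(n_atoms * 3, sd = 1), n_atoms, 3) *
          (sigma + extra)
        pts <- sweep((base_pts + d + noise) %*% t(R), 2, shift, `+`)
        .replace_coords(base, pts, model_id = fr)
      })
      ensemble(snaps, times, construct_label = construct_label, run_id = run)
    })
  })
}

#' Generate a random-coil conformer ensemble
#'
#' Produces strongly perturbed conformers of a chain by cumulative random
#' angular perturbation: each backbone step direction is rotated by the
#' product of small random rotations accumulated along the chain, so bond
#' lengths are preserved while long-range structure decays.  The expected
#' pairwise RMSD grows monotonically with `coil_scale`; at scale 0 all
#' members equal the base chain.
#'
#' @param base [structure_model] providing the chain (C-alpha atoms used).
#' @param coil_scale fluctuation scale, expressed as the
#'   Angstrom-equivalent displacement per step (per-step rotation angle
#'   s.d. is `coil_scale / 3.8` radians).
#' @param n_members ensemble size (default 20).
#' @param seed RNG seed.
#' @return List of `n_members` [structure_model] objects.
#' @export
gen_coil_ensemble <- function(base, coil_scale, n_members = 20, seed = 1) {
  if (coil_scale < 0) stop("coil_scale must be non-negative")
  ca <- select_calpha(base)
  pts <- ca$points
  steps <- diff(pts)
  step_len <- sqrt(sum(steps[1, ]^2))
  angle_sd <- coil_scale / step_len
  .with_seed(seed, {
    lapply(seq_len(n_members), function(m) {
      R <- diag(3)
      new_steps <- steps
      for (i in seq_len(nrow(steps))) {
        if (angle_sd > 0) {
          R <- R %*% .rot_about(stats::rnorm(3), stats::rnorm(1, sd = angle_sd))
        }
        new_steps[i, ] <- as.numeric(R %*% steps[i, ])
      }
      cs <- apply(new_steps, 2, cumsum)
      new_pts <- rbind(pts[1, ], sweep(cs, 2, pts[1, ], `+`))
      .replace_coords(base, new_pts, model_id = m)
    })
  })
}

#' Generate a decoloration decay series
#'
#' `P(t) = 100 * exp(-k t)` plus Gaussian noise (in percentage points),
#' clipped at 0.  The t = 0 point is the normalization point and is exactly
#' 100.
#'
#' @param k decoloration rate constant in min^-1 (>= 0).
#' @param times sampling times in minutes (default 0 to 10 in 1-minute
#'   steps).
#' @param noise_sd noise standard deviation in percentage points.
#' @param seed RNG seed.
#' @param construct_label label stored on the series.
#' @return A [decoloration_series].
#' @export
gen_decoloration <- function(k, times = 0:10, noise_sd = 0, seed = 1,
                             construct_label = "") {
  if (k < 0) stop("k must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  p <- .with_seed(seed, {
    val <- 100 * exp(-k * times) + stats::rnorm(length(times), sd = noise_sd)
    pmax(val, 0)
  })
  if (times[1] == 0) p[1] <- 100
  decoloration_series(times, p, construct_label = construct_label)
}

#' Generate a sample/buffer DSC thermogram pair
#'
#' The sample scan is the shared buffer profile plus a linear instrumental
#' baseline plus a Gaussian endotherm centred at `tm`; the buffer scan is
#' the profile alone.  Independent Gaussian noise is added to both.
#'
#' @param tm endotherm peak temperature in degrees C (inside the scan
#'   window).
#' @param width Gaussian peak s.d. in degrees C (default 3).
#' @param amplitude peak height in raw signal units (default 1).
#' @param baseline_slope slope of the linear baseline in signal units per
#'   degree C.
#' @param buffer_profile function of temperature giving the buffer signal;
#'   default a gently sloped smooth curve.
#' @param noise_sd Gaussian noise s.d. in raw signal units.
#' @param grid temperature step in degrees C (use <= 0.01 when Tm is needed
#'   to two decimals).
#' @param window scan window in degrees C (default 30 to 130).
#' @param seed RNG seed.
#' @return List with raw [dsc_thermogram] elements `sample` and `buffer`.
#' @export
gen_dsc <- function(tm, width = 3, amplitude = 1, baseline_slope = 0.01,
                    buffer_profile = NULL, noise_sd = 0, grid = 0.01,
                    window = c(30, 130), seed = 1) {
  if (tm <= window[1] || tm >= window[2]) {
    stop("tm must lie inside the scan window")
  }
  if (is.null(buffer_profile)) {
    buffer_profile <- function(T) 2 + 0.004 * T + 0.05 * sin(T / 25)
  }
  temp <- window[1] + (0:round((window[2] - window[1]) / grid)) * grid
  prof <- buffer_profile(temp)
  peak <- amplitude * exp(-((temp - tm)^2) / (2 * width^2))
  base <- baseline_slope * (temp - window[1])
  .with_seed(seed, {
    sample_sig <- prof + base + peak + stats::rnorm(length(temp), sd = noise_sd)
    buffer_sig <- prof + stats::rnorm(length(temp), sd = noise_sd)
    list(sample = dsc_thermogram(temp, sample_sig, "raw"),
         buffer = dsc_thermogram(temp, buffer_sig, "raw"))
  })
}

#' Generate an ion-pair distance trace with fixed occupancy
#'
#' Exactly `n_below` frame distances fall in `[2.5, cutoff]` Angstrom and
#' the remainder in `(cutoff, 12]`, in shuffled order.
#'
#' @param n_frames number of frames.
#' @param n_below number of frames at or below the cutoff.
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @param seed RNG seed.
#' @return Numeric vector of distances in Angstrom.
#' @export
gen_distance_trace <- function(n_frames, n_below, cutoff = 5, seed = 1) {
  if (n_below < 0 || n_below > n_frames) stop("need 0 <= n_below <= n_frames")
  .with_seed(seed, {
    d <- c(stats::runif(n_below, 2.5, cutoff),
           stats::runif(n_frames - n_below, cutoff + 1e-6, 12))
    sample(d)
  })
}
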