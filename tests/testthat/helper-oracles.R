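# Independent oracles and small fixtures shared across tests.

# Brute-force minimum RMSD over a rotation grid (ZYZ Euler angles), refined
# around the coarse optimum down to 0.5 degrees.  Independent of the SVD
# route used by the package.
grid_search_rmsd <- function(X, Y, coarse_deg = 6, fine_deg = 0.5) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  euler_rot <- function(a, b, g) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    matrix(c(ca * cb * cg - sa * sg, sa * cb * cg + ca * sg, -sb * cg,
             -ca * cb * sg - sa * cg, -sa * cb * sg + ca * cg, sb * sg,
             ca * sb, sa * sb, cb), 3, 3)
  }
  scan <- function(as, bs, gs) {
    best <- Inf; arg <- c(0, 0, 0)
    for (a in as) for (b in bs) for (g in gs) {
      r <- sqrt(mean(rowSums((Xc %*% euler_rot(a, b, g) - Yc)^2)))
      if (r < best) { best <- r; arg <- c(a, b, g) }
    }
    list(rmsd = best, angles = arg)
  }
  d2r <- pi / 180
  co <- scan(seq(0, 2 * pi, by = coarse_deg * d2r),
             seq(0, pi, by = coarse_deg * d2r),
             seq(0, 2 * pi, by = coarse_deg * d2r))
  w <- coarse_deg * d2r
  fi <- scan(seq(co$angles[1] - w, co$angles[1] + w, by = fine_deg * d2r),
             seq(co$angles[2] - w, co$angles[2] + w, by = fine_deg * d2r),
             seq(co$angles[3] - w, co$angles[3] + w, by = fine_deg * d2r))
  fi$rmsd
}

# Superposed RMSD through bio3d's fitting (independent of the package's SVD
# code); the RMSD arithmetic on the fitted coordinates is elementary.
bio3d_rmsd <- function(mobile_pts, reference_pts) {
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(reference_pts)),
                   mobile = as.numeric(t(mobile_pts))))
  sqrt(mean((fitted - as.numeric(t(reference_pts)))^2) * 3)
}

# Exhaustive medoid enumeration over a list of coordinate matrices, using
# the bio3d-based RMSD above.
enumerate_medoid <- function(point_list) {
  n <- length(point_list)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- bio3d_rmsd(point_list[[i]], point_list[[j]])
    }
  }
  means <- rowSums(D) / (n - 1)
  list(index = which.min(means), mean_rmsd = min(means))
}

calpha_points <- function(model) select_calpha(model)$points

# Hand-written multi-model PDB fixture: 3 C-alpha atoms, 2 models.
write_tiny_pdb <- function(path, shift = 0) {
  fmt <- function(serial, resno, x, y, z) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, resno, x, y, z)
  }
  lines <- c(
    "MODEL        1",
    fmt(1, 3, 11.104, 6.134, -6.504),
    fmt(2, 4, 12.639, 6.071, -5.147),
    fmt(3, 5, 13.000, 8.000, -4.000),
    "ENDMDL",
    "MODEL        2",
    fmt(1, 3, 11.104 + 1, 6.134, -6.504),
    fmt(2, 4, 12.639 + 1, 6.071, -5.147),
    fmt(3, 5, 13.000 + 1, 8.000, -4.000),
    "ENDMDL",
    "END")
  writeLines(lines, path)
  invisible(path)
}
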