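# Least-squares rigid-body superposition (Kabsch algorithm) and RMSD.

.points_of <- function(x) {
  if (inherits(x, "coordinate_set")) x$points
  else if (inherits(x, "structure_model")) select_calpha(x)$points
  else as.matrix(x)
}

#' Optimal rigid-body superposition of two point sets
#'
#' Finds the proper rotation and translation minimising the RMSD between a
#' mobile point set and a reference (Kabsch algorithm via SVD of the
#' cross-covariance, with determinant correction so reflections are never
#' returned).  Points are matched by position in the set; when both inputs
#' carry labels they must agree.
#'
#' @param mobile,reference [coordinate_set] objects (or bare N x 3 matrices)
#'   with equal point counts N >= 3.
#' @return An object of class `superposition` with elements `rotation`
#'   (3 x 3, det +1), `translation` (length-3, Angstrom), `rmsd` (Angstrom),
#'   `degenerate` (TRUE when the points are collinear so the rotation is not
#'   unique; the RMSD is still valid), and `fitted` (the transformed mobile
#'   points).  The transform maps mobile points x to
#'   `rotation %*% (x - centroid_mobile) + centroid_reference + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  if (inherits(mobile, "coordinate_set") && inherits(reference, "coordinate_set")) {
    if (!identical(unname(as.matrix(mobile$labels)),
                   unname(as.matrix(reference$labels)))) {
      stop("mobile and reference labels do not match")
    }
  }
  X <- .points_of(mobile)
  Y <- .points_of(reference)
  if (nrow(X) != nrow(Y)) stop("point counts differ: ", nrow(X), " vs ", nrow(Y))
  n <- nrow(X)
  if (n < 3L) stop("superposition needs at least 3 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)            # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)       # maps centred mobile onto centred reference
  # collinear (or coincident) point sets leave the rotation underdetermined
  degenerate <- sv$d[2] <= max(sv$d[1], 1) * 1e-10
  fitted <- sweep(Xc %*% t(R), 2, cy, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  if (rmsd < 1e-9) rmsd <- max(rmsd, 0)
  structure(list(rotation = R, translation = cy - as.numeric(R %*% cx),
                 rmsd = rmsd, degenerate = degenerate, fitted = fitted),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A%s\n", x$rmsd,
              if (x$degenerate) " (degenerate geometry)" else ""))
  invisible(x)
}

#' RMSD after optimal superposition
#'
#' Convenience wrapper around [kabsch_superpose()] returning only the RMSD.
#'
#' @param mobile,reference as in [kabsch_superpose()].
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(mobile, reference) {
  kabsch_superpose(mobile, reference)$rmsd
}
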