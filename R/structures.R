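# Containers for single structures, snapshot ensembles and coordinate
# selections.  Coordinates are stored in Angstrom throughout; the only
# nanometre quantity in the package is the reported radius of gyration.

# Atomic masses (amu) by element symbol; covers everything that occurs in
# protein ATOM records plus retinal.  Unknown elements fall back to carbon.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971
)

.mass_from_element <- function(element, atom_name) {
  el <- toupper(trimws(element))
  bad <- is.na(el) | el == "" | !(el %in% names(.element_masses))
  if (any(bad)) {
    # fall back to the first alphabetic character of the atom name
    guess <- toupper(substr(gsub("[^A-Za-z].*$", "", trimws(atom_name[bad])), 1, 1))
    guess[!(guess %in% names(.element_masses))] <- "C"
    el[bad] <- guess
  }
  unname(.element_masses[el])
}

#' Construct a structure model
#'
#' A `structure_model` holds the atoms of one conformer: names, residue
#' numbering (taken verbatim from the source, e.g. crystal numbering 3-253),
#' residue types, chain identifiers, coordinates in Angstrom and masses in
#' amu.
#'
#' @param atoms data frame with columns `atom_name`, `residue_number`,
#'   `residue_type`, `chain_id`, `x`, `y`, `z` and optionally `mass` and
#'   `element`.  Missing masses are filled from the element.
#' @param model_id integer identifier of the conformer (1-based).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  required <- c("atom_name", "residue_number", "residue_type", "chain_id",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!nrow(atoms)) stop("structure_model needs at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atomic coordinates")
  if (is.null(atoms$mass)) {
    el <- if (is.null(atoms$element)) NA_character_ else atoms$element
    atoms$mass <- .mass_from_element(el, atoms$atom_name)
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("atomic masses must be positive and finite")
  }
  # residue numbers must not revisit earlier residues within a chain
  for (ch in unique(atoms$chain_id)) {
    rn <- atoms$residue_number[atoms$chain_id == ch]
    blocks <- rle(rn)$values
    if (any(diff(blocks) <= 0)) {
      stop("residue numbers not strictly increasing within chain ", ch)
    }
  }
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$residue_number)), " residues, chain(s) ",
      paste(unique(x$atoms$chain_id), collapse = ","),
      ", model ", x$model_id, "\n", sep = "")
  invisible(x)
}

#' Construct a snapshot ensemble
#'
#' An ordered series of conformers with time stamps, e.g. snapshots written
#' out along a molecular-dynamics run.
#'
#' @param snapshots list of [structure_model] objects with identical atom
#'   ordering for the shared C-alpha selection.
#' @param times numeric vector of non-negative, strictly increasing time
#'   stamps in nanoseconds, one per snapshot.
#' @param construct_label character label (e.g. `"WT"`, `"T114D"`).
#' @param run_id integer identifier of the independent run.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(snapshots, times, construct_label = "", run_id = 1L) {
  if (length(snapshots) != length(times)) {
    stop("length(snapshots) must equal length(times)")
  }
  if (!length(snapshots)) stop("empty ensemble")
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("times must be non-negative and strictly increasing")
  }
  key <- function(m) {
    ca <- m$atoms[m$atoms$atom_name == "CA", , drop = FALSE]
    paste(ca$chain_id, ca$residue_number, sep = ":")
  }
  k1 <- key(snapshots[[1]])
  for (i in seq_along(snapshots)[-1]) {
    if (!identical(key(snapshots[[i]]), k1)) {
      stop("snapshot ", i, " has a different C-alpha selection than snapshot 1")
    }
  }
  structure(list(snapshots = snapshots, times = as.numeric(times),
                 construct_label = construct_label, run_id = as.integer(run_id)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble: ", length(x$snapshots), " snapshots, ",
      sprintf("%.3f-%.3f ns", min(x$times), max(x$times)),
      if (nzchar(x$construct_label)) paste0(", construct ", x$construct_label),
      ", run ", x$run_id, "\n", sep = "")
  invisible(x)
}

#' @export
length.ensemble <- function(x) length(x$snapshots)

#' Extract the C-alpha coordinate set of a model
#'
#' Selects C-alpha atoms of a residue range and returns them as a labelled
#' point set, ordered by residue number, with carbon masses.
#'
#' @param model a [structure_model].
#' @param residue_range inclusive integer pair `c(first, last)`, or `"all"`.
#' @return An object of class `coordinate_set`: a list with `points` (N x 3
#'   matrix, Angstrom), `labels` (data frame `chain_id`, `residue_number`)
#'   and `masses` (amu).
#' @export
select_calpha <- function(model, residue_range = "all") {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms[model$atoms$atom_name == "CA", , drop = FALSE]
  if (!identical(residue_range, "all")) {
    if (length(residue_range) != 2L || residue_range[1] > residue_range[2]) {
      stop("residue_range must be c(first, last) with first <= last, or \"all\"")
    }
    a <- a[a$residue_number >= residue_range[1] &
             a$residue_number <= residue_range[2], , drop = FALSE]
  }
  if (!nrow(a)) stop("empty C-alpha selection for the requested residue range")
  a <- a[order(a$chain_id, a$residue_number), , drop = FALSE]
  coordinate_set(points = as.matrix(a[, c("x", "y", "z")]),
                 labels = data.frame(chain_id = a$chain_id,
                                     residue_number = a$residue_number,
                                     stringsAsFactors = FALSE),
                 masses = rep(.element_masses[["C"]], nrow(a)))
}

#' Construct a labelled coordinate set
#'
#' @param points N x 3 numeric matrix (Angstrom).
#' @param labels data frame with columns `chain_id` and `residue_number`,
#'   one row per point.
#' @param masses numeric vector of masses in amu (default all 1).
#' @return An object of class `coordinate_set`.
#' @export
coordinate_set <- function(points, labels = NULL, masses = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L) stop("points must be N x 3, N >= 1")
  if (!all(is.finite(points))) stop("non-finite coordinates")
  n <- nrow(points)
  if (is.null(labels)) {
    labels <- data.frame(chain_id = rep("A", n), residue_number = seq_len(n),
                         stringsAsFactors = FALSE)
  }
  if (nrow(labels) != n) stop("labels must have one row per point")
  if (is.null(masses)) masses <- rep(1, n)
  if (length(masses) != n || any(masses <= 0)) {
    stop("masses must be positive, one per point")
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, labels = labels, masses = as.numeric(masses)),
            class = "coordinate_set")
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat("coordinate_set: ", nrow(x$points), " points\n", sep = "")
  invisible(x)
}
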