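# File readers and writers.  PDB handling is delegated to bio3d; CSV tables
# go through a thin schema-checked layer over read.csv/write.csv.

#' Read one model from a PDB file
#'
#' Reads ATOM records of one chain from a PDB file (single- or multi-MODEL).
#' HETATM records are ignored unless `het` names residue types to keep (e.g.
#' `"RET"` for retinal).  Alternate locations: altloc `"A"` or blank are
#' kept, all others dropped, so a file with altlocs yields one deterministic
#' conformer.
#'
#' @param path path to a PDB-format text file.
#' @param chain chain identifier (default `"A"`).
#' @param model_index 1-based index of the MODEL block to read.
#' @param het character vector of HETATM residue types to retain (default
#'   none).
#' @return A [structure_model].
#' @export
read_structure <- function(path, chain = "A", model_index = 1L, het = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > nmod) {
    stop("model_index ", model_index, " out of range; file has ", nmod, " model(s)")
  }
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  keep <- at$chain == chain &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    (at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% het))
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("chain '", chain, "' not found (or empty) in ", path)
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  atoms <- data.frame(
    atom_name = trimws(at$elety),
    residue_number = at$resno,
    residue_type = trimws(at$resid),
    chain_id = at$chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = trimws(at$elesy),
    stringsAsFactors = FALSE
  )
  structure_model(atoms, model_id = model_index)
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$residue_number, resid = a$residue_type,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain_id)
  invisible(path)
}

#' Write an ensemble to a multi-model PDB file
#'
#' @param ens an [ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  a <- ens$snapshots[[1]]$atoms
  xyz <- t(vapply(ens$snapshots, function(m) {
    as.numeric(t(as.matrix(m$atoms[, c("x", "y", "z")])))
  }, numeric(3L * nrow(a))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$residue_number, resid = a$residue_type,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain_id)
  invisible(path)
}

#' Read a snapshot ensemble
#'
#' Accepts either one multi-MODEL PDB file or a vector of single-model
#' files, paired with time stamps.
#'
#' @param paths one or more PDB file paths.
#' @param times numeric vector of time stamps in nanoseconds, one per model.
#' @param chain chain identifier.
#' @param construct_label,run_id passed to [ensemble()].
#' @return An [ensemble].
#' @export
read_ensemble <- function(paths, times, chain = "A", construct_label = "",
                          run_id = 1L) {
  if (length(paths) == 1L) {
    pdb <- bio3d::read.pdb(paths, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    nmod <- nrow(pdb$xyz)
    snaps <- lapply(seq_len(nmod), function(i) read_structure(paths, chain, i))
  } else {
    snaps <- lapply(paths, read_structure, chain = chain, model_index = 1L)
  }
  if (length(snaps) != length(times)) {
    stop("read ", length(snaps), " model(s) but ", length(times), " time stamp(s)")
  }
  n_atoms <- vapply(snaps, function(m) nrow(m$atoms), integer(1))
  if (length(unique(n_atoms)) != 1L) {
    stop("atom-count mismatch across models: ",
         paste(unique(n_atoms), collapse = ", "))
  }
  ensemble(snaps, times, construct_label = construct_label, run_id = run_id)
}

#' Read a schema-checked CSV table
#'
#' @param path CSV file with a header row.
#' @param schema named character vector mapping column name to type, one of
#'   `"integer"`, `"numeric"`, `"character"`, `"logical"`.  Extra columns in
#'   the file are kept as-is.
#' @return A data frame with the schema columns coerced to their types.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in names(schema)) {
    raw <- df[[col]]
    val <- switch(schema[[col]],
      integer = suppressWarnings(as.integer(raw)),
      numeric = suppressWarnings(as.numeric(raw)),
      character = as.character(raw),
      logical = as.logical(raw),
      stop("unknown schema type: ", schema[[col]])
    )
    bad <- is.na(val) & !is.na(raw) & !(is.character(raw) & raw == "NA")
    if (schema[[col]] %in% c("integer", "numeric", "logical") && any(bad)) {
      stop("column '", col, "' has non-", schema[[col]], " value(s), e.g. '",
           raw[which(bad)[1]], "'")
    }
    df[[col]] <- val
  }
  df
}

#' Write a table to CSV
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
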