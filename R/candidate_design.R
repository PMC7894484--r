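# Candidate-selection rules for thermo-stabilizing extramembrane mutations:
# filter solvent-exposed sites by exclusion rules, rank single mutations by
# predicted folding free-energy change, and apply final-selection
# constraints.

.acidic <- c("ASP", "GLU")
.basic <- c("ARG", "LYS", "HIS")

#' Select exposed extramembrane residues eligible for mutation
#'
#' Keeps residues that are extramembrane and solvent-exposed (relative
#' exposure at or above the threshold) and drops any residue matching an
#' exclusion rule: (i) its main-chain dihedral position is allowed only for
#' limited residue types (supplied as the `dihedral_restricted` flag);
#' (ii) it is a proline or an acidic residue capping the N-terminus of a
#' helix; (iii) it is a basic residue at the C-terminus of a helix; (iv) it
#' forms an ion pair; (v) a native-state simulation predicts its burial.
#'
#' @param annotations data frame with columns `residue_number`,
#'   `residue_type` (3-letter), `side` (`"N"`/`"C"`), `region`
#'   (`"extramembrane"`/`"intramembrane"`), `relative_exposure` (0-1),
#'   `ss_position` (one of `helix_N_cap`, `helix_C_cap`, `helix_body`,
#'   `strand`, `turn`, `coil`), `in_ion_pair`, `dihedral_restricted`,
#'   `predicted_buried_in_md` (logicals).
#' @param exposure_threshold minimum relative solvent exposure (default
#'   0.3).
#' @return Sorted integer vector of eligible residue numbers.
#' @export
select_exposed_sites <- function(annotations, exposure_threshold = 0.3) {
  req <- c("residue_number", "residue_type", "region", "relative_exposure",
           "ss_position", "in_ion_pair", "dihedral_restricted",
           "predicted_buried_in_md")
  missing_cols <- setdiff(req, names(annotations))
  if (length(missing_cols)) {
    stop("annotations lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(annotations)) stop("empty annotation table")
  if (any(annotations$relative_exposure < 0 | annotations$relative_exposure > 1)) {
    stop("relative_exposure must lie in [0, 1]")
  }
  a <- annotations
  rt <- toupper(a$residue_type)
  keep <- a$region == "extramembrane" &
    a$relative_exposure >= exposure_threshold &
    !a$dihedral_restricted &
    !(a$ss_position == "helix_N_cap" & (rt == "PRO" | rt %in% .acidic)) &
    !(a$ss_position == "helix_C_cap" & rt %in% .basic) &
    !a$in_ion_pair &
    !a$predicted_buried_in_md
  sort(a$residue_number[keep])
}

#' Rank candidate mutations by position-scan free-energy change
#'
#' Sorts candidates ascending by their predicted folding free-energy change
#' (most negative, i.e. most stabilizing, first) and truncates to the top
#' `top_n`.  Ties are broken by site number then substitution.
#'
#' @param candidates data frame with columns `site`, `wild_type`,
#'   `substitution`, `ddg_position_scan` (kcal/mol; finite).
#' @param top_n number of candidates to keep.
#' @return The `top_n` best rows, reordered.
#' @export
rank_position_scan <- function(candidates, top_n = nrow(candidates)) {
  req <- c("site", "substitution", "ddg_position_scan")
  missing_cols <- setdiff(req, names(candidates))
  if (length(missing_cols)) {
    stop("candidates lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (top_n <= 0) stop("top_n must be positive")
  if (top_n > nrow(candidates)) stop("top_n exceeds the number of candidates")
  if (any(!is.finite(candidates$ddg_position_scan))) {
    stop("non-finite ddg_position_scan value(s)")
  }
  ord <- order(candidates$ddg_position_scan, candidates$site,
               candidates$substitution)
  out <- candidates[ord, , drop = FALSE][seq_len(top_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Final selection of mutation candidates
#'
#' Greedy selection of `n_final` candidates by the refined (build-model)
#' free-energy change, subject to: at most one substitution per site;
#' exclusion of candidates flagged as causing a substantial structural
#' change; an optional bound on the imbalance between candidates on the N-
#' and C-terminal sides of the protein.  On free-energy ties, candidates
#' whose putative effect is not yet represented in the selection are
#' preferred (then site, then substitution).
#'
#' @param ranked data frame with columns `site`, `substitution`,
#'   `ddg_build_model` (kcal/mol) and optionally `structural_change`
#'   (logical, default `FALSE`), `side` (`"N"`/`"C"`), `effect_tag`.
#' @param n_final number of candidates to select.
#' @param max_side_imbalance optional bound on `abs(count(N) - count(C))`;
#'   `Inf` (default) disables the constraint (requires a `side` column when
#'   finite).
#' @return Data frame of the selected candidates in selection order.
#' @export
finalize_candidates <- function(ranked, n_final, max_side_imbalance = Inf) {
  req <- c("site", "substitution", "ddg_build_model")
  missing_cols <- setdiff(req, names(ranked))
  if (length(missing_cols)) {
    stop("ranked lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(ranked$ddg_build_model))) {
    stop("every candidate needs a finite ddg_build_model")
  }
  if (is.finite(max_side_imbalance) && is.null(ranked$side)) {
    stop("side-balance constraint requires a side column")
  }
  if (is.null(ranked$structural_change)) ranked$structural_change <- FALSE
  pool <- ranked[!ranked$structural_change, , drop = FALSE]
  sel <- integer(0)
  n_side <- c(N = 0, C = 0)
  tags <- character(0)
  while (length(sel) < n_final) {
    cand <- setdiff(seq_len(nrow(pool)), sel)
    cand <- cand[!(pool$site[cand] %in% pool$site[sel])]
    if (is.finite(max_side_imbalance)) {
      # the bound constrains the final selection; a transient imbalance is
      # fine while enough picks remain to repair it
      remaining_after <- n_final - length(sel) - 1L
      ok <- vapply(cand, function(i) {
        ns <- n_side
        ns[pool$side[i]] <- ns[pool$side[i]] + 1
        abs(ns["N"] - ns["C"]) <= max_side_imbalance + remaining_after
      }, logical(1))
      cand <- cand[ok]
    }
    if (!length(cand)) {
      stop("only ", length(sel), " feasible candidate(s) for n_final = ", n_final)
    }
    ddg <- pool$ddg_build_model[cand]
    best <- cand[ddg == min(ddg)]
    if (length(best) > 1L && !is.null(pool$effect_tag)) {
      fresh <- !(pool$effect_tag[best] %in% tags)
      if (any(fresh)) best <- best[fresh]
    }
    if (length(best) > 1L) {
      best <- best[order(pool$site[best], pool$substitution[best])]
    }
    pick <- best[1]
    sel <- c(sel, pick)
    if (!is.null(pool$side)) {
      n_side[pool$side[pick]] <- n_side[pool$side[pick]] + 1
    }
    if (!is.null(pool$effect_tag)) tags <- c(tags, pool$effect_tag[pick])
  }
  out <- pool[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
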