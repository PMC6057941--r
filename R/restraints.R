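# Contact selection and all energy terms: the switchable restraint potential,
# its lambda-gradient, the soft-core clash term, and the violation energy used
# for evaluation.

#' Select the input contacts for a filtering run
#'
#' Walks a ranked contact list from the top, skipping pairs whose two residues
#' lie inside one and the same predicted secondary-structure segment (i.e.
#' keeping only long-range pairs), until `floor(factor * n_aa)` contacts are
#' collected or the list is exhausted (with a warning). Restraint weights are
#' initialized to 1 (all contacts on).
#'
#' @param ranked data.frame with columns `i`, `j`, `score`, sorted by
#'   descending score (as returned by [read_contacts()]).
#' @param segments segment table from [segments_from_ss()].
#' @param n_aa protein length (residues).
#' @param factor selection quota multiplier (default 1.2).
#' @param d0 violation onset distance in Angstrom (default 7).
#' @return object of class `restraint_set`: list with `contacts` (data.frame
#'   `i`, `j`, `score`, `lambda`, `on`), `d0`, `D`.
#' @export
select_input_contacts <- function(ranked, segments, n_aa, factor = 1.2, d0 = 7) {
  if (!is.numeric(n_aa) || n_aa <= 0) stop("n_aa must be positive")
  quota <- floor(factor * n_aa)
  if (nrow(ranked) > 0 && any(ranked$j > n_aa)) {
    stop("contact index exceeds sequence length ", n_aa)
  }
  eligible <- !same_segment(ranked$i, ranked$j, segments)
  sel <- which(eligible)
  if (length(sel) < quota) {
    warning("ranked list exhausted: ", length(sel), " eligible contacts < quota ",
            quota)
  } else {
    sel <- sel[seq_len(quota)]
  }
  contacts <- ranked[sel, c("i", "j", "score"), drop = FALSE]
  rownames(contacts) <- NULL
  contacts$lambda <- rep(1, nrow(contacts))
  contacts$on <- rep(TRUE, nrow(contacts))
  structure(list(contacts = contacts, d0 = d0, D = NA_real_),
            class = "restraint_set")
}

# TRUE where both residues of a pair fall inside a single segment
same_segment <- function(i, j, segments) {
  out <- rep(FALSE, length(i))
  if (is.null(segments) || nrow(segments) == 0L) return(out)
  for (k in seq_len(nrow(segments))) {
    out <- out | (i >= segments$start[k] & i <= segments$end[k] &
                  j >= segments$start[k] & j <= segments$end[k])
  }
  out
}

#' Switchable distance-restraint energy
#'
#' For a contact at proxy distance `d` with weight `lambda`, the energy is
#' `lambda * (d - d0)^2 + D^2 * (1 - lambda^2)` when `d > d0` and 0 otherwise.
#' `D^2` is the cost of switching the restraint off entirely (`lambda = 0`);
#' switching off is favorable precisely when `(d - d0)^2 > D^2`.
#'
#' @param d distance (Angstrom); vectorized.
#' @param lam restraint weight in \[0, 1\].
#' @param D switching-cost scale (Angstrom).
#' @param d0 violation onset distance (Angstrom, default 7).
#' @return energy (same length as `d`).
#' @export
restraint_term <- function(d, lam, D, d0 = 7) {
  if (any(lam < 0 | lam > 1)) stop("lambda outside [0, 1]")
  ifelse(d > d0, lam * (d - d0)^2 + D^2 * (1 - lam^2), 0)
}

#' Gradient of the restraint energy with respect to lambda
#'
#' `(d - d0)^2 - 2 D^2 lambda` for `d > d0`, 0 otherwise. The stationary
#' weight is `lambda* = (d - d0)^2 / (2 D^2)` (when below 1).
#'
#' @inheritParams restraint_term
#' @return dE/dlambda (same length as `d`).
#' @export
lambda_gradient <- function(d, lam, D, d0 = 7) {
  ifelse(d > d0, (d - d0)^2 - 2 * D^2 * lam, 0)
}

#' Total restraint energy of a set over chain coordinates
#'
#' @param rset a `restraint_set` (its `D` field must be set, or pass `D`).
#' @param coords a `chain_coordinates`.
#' @param D switching-cost scale; defaults to `rset$D`.
#' @return non-negative total energy (sum over contacts).
#' @export
total_restraint_energy <- function(rset, coords, D = rset$D) {
  ct <- rset$contacts
  if (nrow(ct) == 0L) return(0)
  d <- contact_distances(coords, ct$i, ct$j)
  sum(restraint_term(d, ct$lambda, D, rset$d0))
}

#' Soft-core clash energy
#'
#' Purely repulsive harmonic term `k (r_min - r)^2` for every N/CA/C/CB atom
#' pair closer than `r_min`, excluding pairs within the same or adjacent
#' residues (which are constrained by the ideal covalent geometry already).
#'
#' @param coords a `chain_coordinates`.
#' @param r_min repulsion onset (Angstrom, default 3).
#' @param k force constant (default 1).
#' @return non-negative energy.
#' @export
clash_energy <- function(coords, r_min = 3.0, k = 1.0) {
  cb <- cb_proxy(coords)  # engine expects CA in Gly CB slots
  cf_clash_energy(coords$N, coords$CA, coords$C, cb, coords$is_gly, r_min, k)
}

#' Restraint violation energy of a contact set
#'
#' Mean squared violation beyond the contact cutoff: `mean((d - cutoff)^2)`
#' over contacts with `d > cutoff`, others contributing 0. Used to quantify
#' how severely a contact list violates a reference structure.
#'
#' @param distances vector of observed proxy distances (Angstrom); `NA`
#'   entries (unverifiable contacts) are dropped.
#' @param cutoff violation onset (Angstrom, default 9, the contact definition).
#' @return mean violation energy (Angstrom^2).
#' @export
violation_energy <- function(distances, cutoff = 9) {
  distances <- distances[!is.na(distances)]
  if (length(distances) == 0L) stop("no distances to evaluate")
  mean(ifelse(distances > cutoff, (distances - cutoff)^2, 0))
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("restraint_set:", nrow(x$contacts), "contacts, d0 =", x$d0, "A\n")
  invisible(x)
}
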