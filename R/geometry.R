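# Torsion-space polypeptide model: canonical secondary-structure dihedrals,
# sequential internal-to-Cartesian construction, and pairwise side-chain-proxy
# distances.

# canonical dihedral angles (degrees) for idealized secondary structure
PHI_HELIX <- -60
PSI_HELIX <- -45
PHI_STRAND <- -135
PSI_STRAND <- 135

#' Secondary-structure segments from a per-residue label string
#'
#' Collapses maximal runs of helix (`H`) and strand (`E`) labels into segment
#' records. Coil (`C`) runs produce no segments. DSSP-style extra codes are
#' accepted and mapped onto the three-state alphabet (`G`/`I` to `H`, `B` to
#' `E`, turn/bend/loop codes to `C`).
#'
#' @param ss_labels character string (or character vector of single letters),
#'   one label per residue.
#' @return data.frame with columns `start`, `end` (1-based, inclusive) and
#'   `kind` (`"helix"` or `"strand"`), sorted by `start`.
#' @export
segments_from_ss <- function(ss_labels) {
  labs <- normalize_ss_labels(ss_labels)
  n <- length(labs)
  r <- rle(labs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("H", "E")
  data.frame(
    start = starts[keep],
    end = ends[keep],
    kind = ifelse(r$values[keep] == "H", "helix", "strand"),
    stringsAsFactors = FALSE
  )
}

#' @rdname segments_from_ss
#' @export
normalize_ss_labels <- function(ss_labels) {
  if (length(ss_labels) == 1L) ss_labels <- strsplit(ss_labels, "")[[1]]
  labs <- toupper(as.character(ss_labels))
  if (length(labs) == 0L) stop("empty secondary structure")
  labs[labs %in% c("G", "I")] <- "H"
  labs[labs == "B"] <- "E"
  labs[labs %in% c("T", "S", "L", "-", ".", " ")] <- "C"
  bad <- which(!labs %in% c("H", "E", "C"))
  if (length(bad) > 0L) {
    stop("invalid secondary-structure label '", labs[bad[1]],
         "' at position ", bad[1])
  }
  labs
}

#' Build a torsion chain with fixed canonical secondary structure
#'
#' Residues inside helix segments are fixed at (phi, psi) = (-60, -45),
#' residues inside strand segments at (-135, 135). All remaining residues are
#' free and initialized extended at (-135, 135). Omega is 180 degrees
#' throughout (all-trans backbone).
#'
#' @param sequence one-letter amino-acid string.
#' @param segments data.frame as returned by [segments_from_ss()]; may have
#'   zero rows for a fully free chain.
#' @return object of class `torsion_chain`: list with `sequence`, `aa`
#'   (per-residue letters), `phi`, `psi`, `omega` (degrees), `fixed` (logical).
#' @export
build_torsion_chain <- function(sequence, segments = NULL) {
  aa <- toupper(strsplit(sequence, "")[[1]])
  n <- length(aa)
  if (n == 0L) stop("empty sequence")
  phi <- rep(PHI_STRAND, n)
  psi <- rep(PSI_STRAND, n)
  fixed <- rep(FALSE, n)
  if (!is.null(segments) && nrow(segments) > 0L) {
    if (any(segments$start < 1L) || any(segments$end > n) ||
        any(segments$start > segments$end)) {
      stop("segment out of range for sequence of length ", n)
    }
    for (k in seq_len(nrow(segments))) {
      idx <- segments$start[k]:segments$end[k]
      if (segments$kind[k] == "helix") {
        phi[idx] <- PHI_HELIX
        psi[idx] <- PSI_HELIX
      } else {
        phi[idx] <- PHI_STRAND
        psi[idx] <- PSI_STRAND
      }
      fixed[idx] <- TRUE
    }
  }
  structure(
    list(sequence = paste(aa, collapse = ""), aa = aa,
         phi = phi, psi = psi, omega = rep(180, n), fixed = fixed),
    class = "torsion_chain"
  )
}

#' Cartesian coordinates of a torsion chain
#'
#' Deterministic sequential construction with ideal bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; N-CA-C 111.2, CA-C-N 116.2,
#' C-N-CA 121.7 degrees). The first residue is placed in a canonical frame.
#' The side-chain proxy CB is placed by ideal tetrahedral geometry; Gly has no
#' CB (its row is `NA` in the `CB` matrix and CA substitutes in distances).
#'
#' @param chain a `torsion_chain`.
#' @return object of class `chain_coordinates`: list of n x 3 matrices `N`,
#'   `CA`, `C`, `CB` (Angstrom) plus `is_gly` and `aa`.
#' @export
to_coordinates <- function(chain) {
  stopifnot(inherits(chain, "torsion_chain"))
  is_gly <- chain$aa == "G"
  xyz <- cf_build_coords(chain$phi, chain$psi, chain$omega, is_gly)
  cb <- xyz$CB
  cb[is_gly, ] <- NA_real_
  structure(
    list(N = xyz$N, CA = xyz$CA, C = xyz$C, CB = cb,
         is_gly = is_gly, aa = chain$aa),
    class = "chain_coordinates"
  )
}

# CB coordinates with CA substituted for Gly: the distance proxy used by
# every restraint and every contact classification.
cb_proxy <- function(coords) {
  cb <- coords$CB
  if (any(coords$is_gly)) cb[coords$is_gly, ] <- coords$CA[coords$is_gly, ]
  cb
}

#' Side-chain proxy distance between two residues
#'
#' Euclidean CB-CB distance (CA for Gly) between residues `i` and `j`.
#'
#' @param coords a `chain_coordinates`.
#' @param i,j 1-based residue indices.
#' @return distance in Angstrom.
#' @export
pair_distance <- function(coords, i, j) {
  n <- nrow(coords$CA)
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) {
    stop("residue index out of range [1, ", n, "]")
  }
  cb <- cb_proxy(coords)
  sqrt(sum((cb[i, ] - cb[j, ])^2))
}

# all pairwise proxy distances for a set of contacts (vectorized)
contact_distances <- function(coords, i, j) {
  cb <- cb_proxy(coords)
  sqrt(rowSums((cb[i, , drop = FALSE] - cb[j, , drop = FALSE])^2))
}

#' @export
print.torsion_chain <- function(x, ...) {
  cat("torsion_chain:", length(x$aa), "residues,",
      sum(x$fixed), "fixed,", sum(!x$fixed), "free\n")
  invisible(x)
}

#' @export
print.chain_coordinates <- function(x, ...) {
  cat("chain_coordinates:", nrow(x$CA), "residues (N, CA, C, CB)\n")
  invisible(x)
}
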