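# Evaluation against reference structures: contact classification, precision
# and recall, Kabsch superposition, GDT scores, and effective-sequence
# counting for alignments.

#' Classify contacts against a reference structure
#'
#' A contact is a true positive iff the reference CB-CB distance (CA for Gly)
#' is at or below `cutoff` (9 Angstrom), a false positive if above, and
#' unverifiable if either residue is unresolved in the reference.
#'
#' @param contacts data.frame with columns `i`, `j`.
#' @param reference a `reference_structure` (or a ToyFold's `reference`).
#' @param cutoff contact definition cutoff (Angstrom, default 9).
#' @return character vector, one of `"TP"`, `"FP"`, `"unverifiable"` per
#'   contact; reference distances attached as attribute `"distance"`.
#' @export
classify_contacts <- function(contacts, reference, cutoff = 9) {
  stopifnot(inherits(reference, "reference_structure"))
  n <- length(reference$aa)
  if (any(contacts$j > n)) stop("contact index beyond reference length")
  ok <- reference$resolved[contacts$i] & reference$resolved[contacts$j]
  d <- rep(NA_real_, nrow(contacts))
  d[ok] <- sqrt(rowSums(
    (reference$cb[contacts$i[ok], , drop = FALSE] -
       reference$cb[contacts$j[ok], , drop = FALSE])^2
  ))
  cls <- rep("unverifiable", nrow(contacts))
  cls[ok & d <= cutoff] <- "TP"
  cls[ok & d > cutoff] <- "FP"
  attr(cls, "distance") <- d
  cls
}

#' Precision and recall of a filtered contact set
#'
#' Precision is `TP / (TP + FP)` over the kept contacts; recall is the
#' fraction of input true positives that are kept. Unverifiable contacts are
#' excluded from both denominators.
#'
#' @param classification output of [classify_contacts()] on the full input
#'   set.
#' @param kept logical vector: which input contacts were kept.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn` (counts over the
#'   kept set; `fn` = input TPs not kept). Zero denominators give `NA` with a
#'   warning.
#' @export
precision_recall <- function(classification, kept) {
  stopifnot(length(classification) == length(kept))
  tp_kept <- sum(classification == "TP" & kept)
  fp_kept <- sum(classification == "FP" & kept)
  tp_input <- sum(classification == "TP")
  precision <- if (tp_kept + fp_kept > 0) tp_kept / (tp_kept + fp_kept) else {
    warning("no verifiable kept contacts: precision undefined")
    NA_real_
  }
  recall <- if (tp_input > 0) tp_kept / tp_input else {
    warning("no verifiable input TPs: recall undefined")
    NA_real_
  }
  list(precision = precision, recall = recall,
       tp = tp_kept, fp = fp_kept, fn = tp_input - tp_kept)
}

#' Kabsch superposition
#'
#' Least-squares superposition of paired CA coordinate sets: proper rotation
#' (determinant +1) and translation minimizing the RMSD, via singular value
#' decomposition of the covariance matrix.
#'
#' @param model_ca,ref_ca n x 3 matrices of paired coordinates, n >= 3.
#' @return list with `rotation` (3 x 3, applied on the right of the centered
#'   model), `translation`, `rmsd`, and `aligned` (the transformed model).
#' @export
kabsch_superpose <- function(model_ca, ref_ca) {
  model_ca <- as.matrix(model_ca); ref_ca <- as.matrix(ref_ca)
  stopifnot(ncol(model_ca) == 3, ncol(ref_ca) == 3,
            nrow(model_ca) == nrow(ref_ca))
  if (nrow(model_ca) < 3) stop("need at least 3 paired atoms")
  mc <- colMeans(model_ca); rc <- colMeans(ref_ca)
  A <- sweep(model_ca, 2, mc); B <- sweep(ref_ca, 2, rc)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- A %*% R
  rmsd <- sqrt(mean(rowSums((aligned - B)^2)))
  aligned <- sweep(aligned, 2, rc, `+`)
  list(rotation = R, translation = rc - mc %*% R, rmsd = rmsd,
       aligned = aligned)
}

#' Global distance test
#'
#' For each cutoff, the largest fraction of paired CA atoms within the cutoff
#' of the reference over a superposition search. The search is an iterative
#' trimmed Kabsch from multiple seeds: the global superposition plus every
#' sliding fragment of 5 consecutive residues; from each seed, pairs beyond
#' the cutoff are dropped and the remainder re-superposed (at most 10
#' iterations), and the best fraction over all seeds is kept. This is a
#' deterministic approximation to the exhaustive fragment search of full GDT
#' implementations.
#'
#' @param model_ca,ref_ca paired CA coordinates (rows with `NA` are dropped).
#' @param cutoffs distance cutoffs in Angstrom (default `c(1, 2, 4, 8)`, the
#'   GDT-TS set).
#' @return named numeric vector of fractions, one per cutoff.
#' @export
gdt <- function(model_ca, ref_ca, cutoffs = c(1, 2, 4, 8)) {
  keep <- stats::complete.cases(model_ca) & stats::complete.cases(ref_ca)
  model_ca <- as.matrix(model_ca)[keep, , drop = FALSE]
  ref_ca <- as.matrix(ref_ca)[keep, , drop = FALSE]
  n <- nrow(model_ca)
  if (n < 3) stop("fewer than 3 paired atoms")
  starts <- if (n > 5) seq(1L, n - 4L, by = 2L) else 1L
  seeds <- c(list(seq_len(n)),
             lapply(starts, function(s) s:min(n, s + 4L)))
  out <- numeric(length(cutoffs))
  for (ci in seq_along(cutoffs)) {
    cutoff <- cutoffs[ci]
    best <- 0
    for (seed in seeds) {
      subset <- seed
      for (iter in 1:10) {
        fit <- kabsch_superpose(model_ca[subset, , drop = FALSE],
                                ref_ca[subset, , drop = FALSE])
        moved <- sweep(model_ca, 2,
                       colMeans(model_ca[subset, , drop = FALSE])) %*%
          fit$rotation
        moved <- sweep(moved, 2, colMeans(ref_ca[subset, , drop = FALSE]), `+`)
        dev <- sqrt(rowSums((moved - ref_ca)^2))
        best <- max(best, mean(dev <= cutoff))
        new_subset <- which(dev <= cutoff)
        if (length(new_subset) < 3 || identical(new_subset, subset)) break
        subset <- new_subset
      }
    }
    out[ci] <- best
  }
  names(out) <- paste0("gdt", cutoffs)
  out
}

#' @rdname gdt
#' @export
gdt5 <- function(model_ca, ref_ca) unname(gdt(model_ca, ref_ca, cutoffs = 5))

#' @rdname gdt
#' @export
gdt_ts <- function(model_ca, ref_ca) {
  mean(gdt(model_ca, ref_ca, cutoffs = c(1, 2, 4, 8)))
}

#' Effective number of sequences in an alignment
#'
#' Each sequence is weighted by `1 / n`, where `n` counts the sequences
#' (including itself) with pairwise identity above `identity_threshold`;
#' the effective count is the sum of weights. Pairwise identity is the
#' fraction of matching columns among columns where both sequences are
#' non-gap.
#'
#' @param msa an `msa` object (or list with `seqs`).
#' @param identity_threshold clustering threshold (default 0.8).
#' @return effective sequence count in `[1, m]`.
#' @export
n_effective <- function(msa, identity_threshold = 0.8) {
  seqs <- msa$seqs
  m <- length(seqs)
  if (m == 0L) stop("empty MSA")
  mat <- do.call(rbind, strsplit(seqs, ""))
  nongap <- mat != "-"
  neigh <- integer(m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (b == a) { neigh[a] <- neigh[a] + 1L; next }
      both <- nongap[a, ] & nongap[b, ]
      nb <- sum(both)
      if (nb == 0L) next
      ident <- sum(mat[a, both] == mat[b, both]) / nb
      if (ident > identity_threshold) neigh[a] <- neigh[a] + 1L
    }
  }
  sum(1 / neigh)
}

#' Benchmark-mode chain with experimental dihedrals fixed
#'
#' Builds a torsion chain whose structured residues (helix or strand in the
#' supplied assignment) are fixed at the experimental phi/psi extracted from
#' the reference; all other residues are free. Structured residues with an
#' undefined dihedral (chain termini, gaps) fall back to the canonical angle
#' for their assigned kind, with a warning.
#'
#' @param reference a `reference_structure`.
#' @param ss_assignment per-residue H/E/C string (structured vs loop).
#' @return a `torsion_chain`.
#' @export
reference_dihedral_chain <- function(reference, ss_assignment) {
  labs <- normalize_ss_labels(ss_assignment)
  n <- length(reference$aa)
  if (length(labs) != n) {
    stop("assignment length ", length(labs), " does not match reference ", n)
  }
  chain <- build_torsion_chain(reference$sequence, segments_from_ss(labs))
  structured <- labs %in% c("H", "E")
  fallback <- FALSE
  for (r in which(structured)) {
    if (!is.na(reference$phi[r])) chain$phi[r] <- reference$phi[r]
    else fallback <- TRUE
    if (!is.na(reference$psi[r])) chain$psi[r] <- reference$psi[r]
    else fallback <- TRUE
  }
  if (fallback) {
    warning("some structured residues lack experimental dihedrals; ",
            "canonical values used")
  }
  chain
}

#' Evaluation report for a filtering run
#'
#' Summarizes a `filter_result` against a reference structure: contact counts,
#' precision and recall, violation energies of the input and kept sets, and
#' (when a model is available) GDT scores of the consensus model.
#'
#' @param result a `filter_result`.
#' @param reference a `reference_structure`.
#' @param msa optional `msa` for the effective-sequence count.
#' @return object of class `evaluation_report` (named list).
#' @export
evaluate_filtering <- function(result, reference, msa = NULL) {
  ct <- result$contacts
  cls <- classify_contacts(ct, reference, cutoff = result$config$tp_cutoff)
  d <- attr(cls, "distance")
  pr <- precision_recall(cls, ct$kept)
  input_cls_ok <- cls != "unverifiable"
  input_precision <- if (any(input_cls_ok)) {
    mean(cls[input_cls_ok] == "TP")
  } else NA_real_
  rep <- list(
    n_input = nrow(ct), n_kept = sum(ct$kept),
    tp = pr$tp, fp = pr$fp, fn = pr$fn,
    precision = pr$precision, recall = pr$recall,
    input_precision = input_precision,
    violation_energy_input = violation_energy(d, result$config$tp_cutoff),
    violation_energy_kept = if (any(ct$kept & !is.na(d))) {
      violation_energy(d[ct$kept], result$config$tp_cutoff)
    } else NA_real_,
    gdt5 = NA_real_, gdt_ts = NA_real_,
    n_eff = if (!is.null(msa)) n_effective(msa) else NA_real_
  )
  if (!is.null(result$model)) {
    ok <- reference$resolved
    if (sum(ok) >= 3) {
      rep$gdt5 <- gdt5(result$model$CA[ok, , drop = FALSE],
                       reference$ca[ok, , drop = FALSE])
      rep$gdt_ts <- gdt_ts(result$model$CA[ok, , drop = FALSE],
                           reference$ca[ok, , drop = FALSE])
    }
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "n/a" else sprintf("%.0f%%", 100 * v)
  cat("evaluation_report\n")
  cat("  contacts: ", x$n_input, " input, ", x$n_kept, " kept\n", sep = "")
  cat("  precision:", pct(x$precision), "(input", paste0(pct(x$input_precision), ")"),
      "| recall:", pct(x$recall), "\n")
  cat("  violation energy:", format(x$violation_energy_input, digits = 3),
      "->", format(x$violation_energy_kept, digits = 3), "A^2\n")
  if (!is.na(x$gdt5)) {
    cat("  GDT(5):", format(x$gdt5, digits = 3),
        "GDT-TS:", format(x$gdt_ts, digits = 3), "\n")
  }
  if (!is.na(x$n_eff)) cat("  N_eff:", format(x$n_eff, digits = 4), "\n")
  invisible(x)
}

#' Write an evaluation report as a flat key-value file
#'
#' @param path output path.
#' @param report an `evaluation_report`.
#' @export
write_report <- function(path, report) {
  keys <- names(report)
  vals <- vapply(report, function(v) {
    if (is.na(v)) "n/a" else format(v, digits = 10)
  }, character(1))
  writeLines(paste0(keys, "\t", vals), path)
  invisible(path)
}
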