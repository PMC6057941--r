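# Deterministic synthetic fixtures: an idealized antiparallel beta-sheet toy
# fold, true-contact extraction, controlled false-positive injection, the
# five-contact three-strand scenario with one erroneous inter-strand contact,
# and toy alignments with a known effective-sequence count.

#' Idealized antiparallel beta-sheet toy fold
#'
#' Builds a deterministic flat antiparallel sheet: `n_strands` strands of
#' `strand_len` residues at 4.8 Angstrom inter-strand spacing and 3.5 Angstrom
#' spacing along each strand, joined by `loop_len`-residue turns, with the CB
#' proxy alternating above and below the sheet plane. The sequence alternates
#' Gly/Ser (`tail_len` coil residues may pad each terminus); strand residues
#' are labelled `E`, the rest `C`. True contacts are all long-range pairs
#' (pairs not inside one strand segment) with proxy distance at or below
#' 9 Angstrom in the constructed geometry.
#'
#' @param n_strands number of strands (>= 2).
#' @param strand_len residues per strand.
#' @param loop_len residues per connecting turn.
#' @param tail_len coil residues appended at each terminus (default 0).
#' @return object of class `toy_fold`: list with `sequence`, `ss_labels`,
#'   `reference` (a `reference_structure`), `true_contacts` (data.frame
#'   `i`, `j`), `strands` (segment table).
#' @export
make_toy_sheet <- function(n_strands = 3, strand_len = 5, loop_len = 2,
                           tail_len = 0) {
  if (n_strands < 2) stop("need at least 2 strands")
  n <- tail_len + n_strands * strand_len + (n_strands - 1) * loop_len + tail_len
  ca <- matrix(NA_real_, n, 3)
  labs <- rep("C", n)
  spacing_x <- 4.8; spacing_y <- 3.5
  strands <- data.frame(start = integer(0), end = integer(0),
                        kind = character(0), stringsAsFactors = FALSE)
  pos <- tail_len
  ymax <- (strand_len - 1) * spacing_y
  for (s in seq_len(n_strands)) {
    x <- (s - 1) * spacing_x
    for (t in seq_len(strand_len)) {
      r <- pos + t
      y <- if (s %% 2 == 1) (t - 1) * spacing_y else ymax - (t - 1) * spacing_y
      ca[r, ] <- c(x, y, 0.3 * ((r %% 2) * 2 - 1))
      labs[r] <- "E"
    }
    strands <- rbind(strands, data.frame(start = pos + 1L,
                                         end = pos + strand_len,
                                         kind = "strand"))
    pos <- pos + strand_len
    if (s < n_strands) {
      # turn residues bulge beyond the strand ends
      y_end <- if (s %% 2 == 1) ymax else 0
      y_out <- y_end + (if (s %% 2 == 1) 1 else -1) * 2.2
      for (t in seq_len(loop_len)) {
        r <- pos + t
        frac <- t / (loop_len + 1)
        ca[r, ] <- c(x + frac * spacing_x, y_out, 0)
      }
      pos <- pos + loop_len
    }
  }
  # terminal coil tails extend away from the sheet
  if (tail_len > 0) {
    for (t in seq_len(tail_len)) {
      ca[tail_len + 1 - t, ] <- ca[tail_len + 1, ] + c(0, -3.5 * t, 0)
      ca[pos + t, ] <- ca[pos, ] + c(0, 3.5 * t * ifelse(n_strands %% 2 == 1, 1, -1), 0)
    }
  }
  aa <- rep(c("G", "S"), length.out = n)
  # CB proxy: CA shifted off the sheet plane, alternating sides; Gly uses CA
  cb <- ca
  shift <- 1.5 * ((seq_len(n) %% 2) * 2 - 1)
  cb[, 3] <- cb[, 3] + ifelse(aa == "G", 0, shift)
  cb[aa == "G", ] <- ca[aa == "G", ]
  reference <- structure(
    list(sequence = paste(aa, collapse = ""), aa = aa, ca = ca, cb = cb,
         resolved = rep(TRUE, n), phi = rep(NA_real_, n),
         psi = rep(NA_real_, n)),
    class = "reference_structure"
  )
  # true contacts: all long-range pairs within the 9 A proxy cutoff
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pij <- data.frame(i = pairs[, 1], j = pairs[, 2])
  keep <- !same_segment(pij$i, pij$j, strands)
  d <- sqrt(rowSums((cb[pij$i, ] - cb[pij$j, ])^2))
  true_contacts <- pij[keep & d <= 9, , drop = FALSE]
  rownames(true_contacts) <- NULL
  structure(
    list(sequence = paste(aa, collapse = ""),
         ss_labels = paste(labs, collapse = ""),
         reference = reference, true_contacts = true_contacts,
         strands = strands),
    class = "toy_fold"
  )
}

#' The three-strand five-contact fixture
#'
#' A three-stranded antiparallel sheet with five designed contacts: two
#' between strands 1-2, two between strands 2-3, and a fifth, erroneous
#' contact between the far corners of strands 1 and 3, whose distance in the
#' native geometry is far above the 9 Angstrom contact cutoff. Mirrors the
#' classic equilibrium experiment in which the weight of the geometrically
#' inconsistent restraint collapses to zero.
#'
#' The strands are 8 residues long (28 residues in total). This is chosen so
#' that the erroneous corner contact is genuinely inconsistent with the
#' restrained native ensemble under the energy model: each true restraint
#' tolerates about `sqrt(d0^2 - t^2)` of free inter-strand sliding (t being
#' the transverse strand spacing), about 12.6 Angstrom in total for two strand
#' pairs, so the corner separation (24.5 Angstrom here) must exceed that slack
#' budget plus the switch-off range for the erroneous restraint to remain
#' violated in every conformation that satisfies the true ones. With shorter
#' strands the erroneous contact degenerates into a borderline error that the
#' consensus filter, by design, does not remove.
#'
#' @return list with `fold` (a `toy_fold`) and `contacts` (data.frame `i`,
#'   `j`, `score`, with `truth` flags).
#' @export
gsgs_fixture <- function() {
  fold <- make_toy_sheet(n_strands = 3, strand_len = 8, loop_len = 2)
  # strands: 1-8, 11-18, 21-28; strand 2 runs antiparallel
  contacts <- data.frame(
    i = c(3L, 6L, 13L, 16L, 1L),
    j = c(16L, 13L, 26L, 23L, 28L),
    score = c(1.0, 0.9, 0.8, 0.7, 0.6),
    truth = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  cls <- classify_contacts(contacts, fold$reference)
  stopifnot(identical(cls[1:4], rep("TP", 4)), cls[5] == "FP")
  list(fold = fold, contacts = contacts)
}

#' Synthetic ranked contact prediction with controlled precision
#'
#' Emulates a noisy contact predictor on a toy fold: `round(n * p)` true
#' contacts drawn from the fold's true-contact list plus decoys drawn from
#' long-range pairs whose native distance exceeds `decoy_min` Angstrom, with
#' descending scores assigned to a random interleaving. Deterministic per
#' seed.
#'
#' @param fold a `toy_fold`.
#' @param n_contacts list length.
#' @param target_precision fraction of true contacts in (0, 1].
#' @param seed integer seed.
#' @param decoy_min minimal native distance of decoys (default 12 Angstrom,
#'   avoiding borderline errors just outside the contact cutoff).
#' @return data.frame `i`, `j`, `score` sorted by descending score, with a
#'   logical `truth` column.
#' @export
make_prediction <- function(fold, n_contacts, target_precision, seed,
                            decoy_min = 12) {
  if (target_precision <= 0 || target_precision > 1) {
    stop("target_precision must lie in (0, 1]")
  }
  set.seed(seed)
  n_true <- round(n_contacts * target_precision)
  n_decoy <- n_contacts - n_true
  truth <- fold$true_contacts
  if (nrow(truth) < n_true) stop("insufficient true-contact pool")
  ref <- fold$reference
  nres <- length(ref$aa)
  pairs <- which(upper.tri(matrix(0, nres, nres)), arr.ind = TRUE)
  pij <- data.frame(i = pairs[, 1], j = pairs[, 2])
  keep <- !same_segment(pij$i, pij$j, fold$strands)
  d <- sqrt(rowSums((ref$cb[pij$i, ] - ref$cb[pij$j, ])^2))
  decoys <- pij[keep & d > decoy_min, , drop = FALSE]
  if (nrow(decoys) < n_decoy) stop("insufficient decoy pool")
  sel_t <- truth[sample.int(nrow(truth), n_true), c("i", "j")]
  sel_d <- decoys[sample.int(nrow(decoys), n_decoy), c("i", "j")]
  sel_t$truth <- rep(TRUE, nrow(sel_t))
  sel_d$truth <- rep(FALSE, nrow(sel_d))
  out <- rbind(sel_t, sel_d)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out$score <- seq(2, 1, length.out = nrow(out))
  rownames(out) <- NULL
  out[, c("i", "j", "score", "truth")]
}

#' Toy alignment with a known effective-sequence count
#'
#' Builds clusters of sequences that share mutations at a fixed position set,
#' so that within-cluster pairwise identity stays at or above
#' `within_identity` (> 0.8) while between-cluster identity stays far below
#' 0.8. By construction the effective-sequence count equals `n_clusters`.
#'
#' @param n_clusters number of clusters.
#' @param cluster_sizes integer vector (recycled to `n_clusters`).
#' @param within_identity within-cluster identity floor (> 0.8).
#' @param between_identity nominal between-cluster identity (< 0.8); the
#'   construction uses independent random centers, which land far below it.
#' @param length_ alignment width.
#' @param seed integer seed.
#' @return an `msa` object.
#' @export
make_toy_msa <- function(n_clusters, cluster_sizes = 3,
                         within_identity = 0.92, between_identity = 0.2,
                         length_ = 50, seed = 1) {
  if (!(within_identity > 0.8 && between_identity < 0.8)) {
    stop("need within_identity > 0.8 > between_identity")
  }
  set.seed(seed)
  sizes <- rep_len(cluster_sizes, n_clusters)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_mut <- floor((1 - within_identity) * length_)
  seqs <- character(0); ids <- character(0)
  centers <- matrix("", n_clusters, length_)
  for (c1 in seq_len(n_clusters)) {
    centers[c1, ] <- sample(alphabet, length_, replace = TRUE)
    mut_pos <- if (n_mut > 0) sample.int(length_, n_mut) else integer(0)
    for (m in seq_len(sizes[c1])) {
      s <- centers[c1, ]
      if (n_mut > 0) s[mut_pos] <- sample(alphabet, n_mut, replace = TRUE)
      seqs <- c(seqs, paste(s, collapse = ""))
      ids <- c(ids, sprintf("cluster%d_seq%d", c1, m))
    }
  }
  msa <- structure(list(ids = ids, seqs = seqs, width = length_),
                   class = "msa")
  # guard: random centers must not collide across clusters
  if (n_clusters > 1) {
    for (a in seq_len(n_clusters - 1)) {
      for (b in (a + 1):n_clusters) {
        ident <- mean(centers[a, ] == centers[b, ])
        stopifnot(ident < 0.8)
      }
    }
  }
  msa
}

#' Write an MSA in aligned FASTA format
#'
#' @param path output path.
#' @param msa an `msa`.
#' @export
write_msa <- function(path, msa) {
  writeLines(paste0(">", msa$ids, "\n", msa$seqs), path)
  invisible(path)
}

#' Write the four standard-format files of a toy fold
#'
#' FASTA sequence, secondary-structure string, a contact table from
#' [make_prediction()], and a synthetic reference PDB (backbone approximated
#' around the ground-truth CA trace).
#'
#' @param fold a `toy_fold`.
#' @param dir output directory (created if needed).
#' @param n_contacts,target_precision,seed prediction parameters.
#' @param prefix file name prefix (default `"toy"`).
#' @return named character vector of the written paths.
#' @export
write_toy_fixture <- function(fold, dir, n_contacts = 20,
                              target_precision = 0.8, seed = 1,
                              prefix = "toy") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  writeLines(c(">toy synthetic sheet", fold$sequence), p(".fasta"))
  writeLines(fold$ss_labels, p(".ss"))
  pred <- make_prediction(fold, n_contacts, target_precision, seed)
  utils::write.table(pred[, c("i", "j", "score")], p(".contacts"),
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  # synthetic backbone around the CA trace for the reference PDB
  ref <- fold$reference
  n <- length(ref$aa)
  cb <- ref$cb
  cb[ref$aa == "G", ] <- NA_real_
  coords <- structure(
    list(
      N = ref$ca + matrix(rep(c(-0.8, -0.8, 0), each = n), n),
      CA = ref$ca,
      C = ref$ca + matrix(rep(c(0.8, 0.8, 0), each = n), n),
      CB = cb,
      is_gly = ref$aa == "G", aa = ref$aa
    ),
    class = "chain_coordinates"
  )
  write_model_pdb(p(".pdb"), coords)
  c(fasta = p(".fasta"), ss = p(".ss"), contacts = p(".contacts"),
    pdb = p(".pdb"))
}
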