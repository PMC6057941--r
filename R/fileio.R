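# Readers and writers for the standard formats the tool touches: FASTA and
# alignments, PSIPRED secondary-structure output, contact lists (plain table
# and CASP-RR), and PDB reference/model structures.

#' Read the query sequence from a FASTA file
#'
#' The first record is used as the query; letters are uppercased and `*` and
#' gap characters are stripped.
#'
#' @param path FASTA file.
#' @return character scalar (the sequence).
#' @export
read_fasta <- function(path) {
  aln <- bio3d::read.fasta(path, rm.dup = FALSE)
  if (is.null(aln$ali) || nrow(aln$ali) == 0L) stop("empty FASTA file: ", path)
  s <- toupper(paste(aln$ali[1, ], collapse = ""))
  gsub("[-*.]", "", s)
}

#' Read a multiple sequence alignment (FASTA or A3M)
#'
#' A3M-style lowercase insertion states are removed before width checking, so
#' both aligned FASTA and A3M inputs yield an equal-width alignment.
#'
#' @param path alignment file.
#' @return object of class `msa`: list with `ids`, `seqs` (uppercase, aligned,
#'   `-` gaps) and `width`.
#' @export
read_msa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA/A3M alignment: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  # drop A3M insertion states (lowercase and '.'), normalize gaps
  seqs <- vapply(seqs, function(s) {
    s <- gsub("[a-z.]", "", s)
    gsub("[*]", "", toupper(s))
  }, character(1), USE.NAMES = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("aligned sequences have unequal lengths: ", path)
  structure(list(ids = ids, seqs = unname(seqs), width = w), class = "msa")
}

#' Read a PSIPRED secondary-structure prediction
#'
#' Accepts the vertical `.ss2` format (per-line: index, residue, label, three
#' class scores, `#` header) and the horizontal format (`Pred:` lines).
#'
#' @param path PSIPRED output file.
#' @return per-residue H/E/C string.
#' @export
read_psipred <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pred <- grep("^\\s*Pred:", lines, value = TRUE)
  if (length(pred) > 0L) {
    labs <- paste(gsub("^\\s*Pred:\\s*", "", pred), collapse = "")
    labs <- gsub("\\s", "", labs)
    return(paste(normalize_ss_labels(labs), collapse = ""))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  labs <- character(0)
  for (ln in which(keep)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 3L) {
      stop("malformed .ss2 line ", ln, ": '", lines[ln], "'")
    }
    lab <- tryCatch(normalize_ss_labels(tok[3]), error = function(e) {
      stop("invalid secondary-structure label '", tok[3], "' on line ", ln)
    })
    labs <- c(labs, lab)
  }
  if (length(labs) == 0L) stop("no secondary-structure records in ", path)
  paste(labs, collapse = "")
}

#' Read a ranked contact list
#'
#' Accepts a whitespace table `i j score` (extra columns ignored) or the
#' CASP-RR dialect (header lines `PFRMAT`/`TARGET`/`AUTHOR`/`METHOD`/`MODEL`/
#' `REMARK`/`END` and sequence lines skipped; data rows `i j d1 d2 score` use
#' column 5 as the score). Pairs are normalized to `i < j`; duplicates are
#' collapsed keeping the maximum score; the output is sorted by descending
#' score with ties broken by ascending `(i, j)`.
#'
#' @param path contact file.
#' @return data.frame with columns `i`, `j`, `score`.
#' @export
read_contacts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rr <- any(grepl("^PFRMAT\\b", lines))
  skip <- grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END)\\b", lines) |
    grepl("^[A-Za-z*-]+$", lines)  # RR sequence lines
  lines <- lines[!skip]
  if (length(lines) == 0L) stop("no contact records in ", path)
  recs <- lapply(seq_along(lines), function(k) {
    tok <- strsplit(lines[k], "\\s+")[[1]]
    if (length(tok) < 3L) stop("malformed contact line: '", lines[k], "'")
    ij <- suppressWarnings(as.numeric(tok[1:2]))
    if (any(is.na(ij)) || any(ij != floor(ij))) {
      stop("non-integer residue indices in line: '", lines[k], "'")
    }
    score_col <- if (rr && length(tok) >= 5L) 5L else 3L
    score <- suppressWarnings(as.numeric(tok[score_col]))
    if (is.na(score)) stop("no numeric score in line: '", lines[k], "'")
    c(ij[1], ij[2], score)
  })
  m <- do.call(rbind, recs)
  if (any(m[, 1] == m[, 2])) stop("self-contact (i == j) in ", path)
  i <- pmin(m[, 1], m[, 2])
  j <- pmax(m[, 1], m[, 2])
  df <- data.frame(i = as.integer(i), j = as.integer(j), score = m[, 3])
  # collapse duplicates, keep maximum score
  key <- paste(df$i, df$j)
  df <- do.call(rbind, lapply(split(df, key), function(g) {
    g[which.max(g$score), , drop = FALSE]
  }))
  df <- df[order(-df$score, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a contact table with consensus annotations
#'
#' Tab-separated columns `i`, `j`, `score`, `on_fraction`, `kept` (encoded
#' `1`/`0`).
#'
#' @param path output path.
#' @param contacts data.frame with those columns (as in
#'   `filter_result$contacts`).
#' @export
write_contacts <- function(path, contacts) {
  out <- data.frame(
    i = contacts$i, j = contacts$j, score = contacts$score,
    on_fraction = contacts$on_fraction,
    kept = as.integer(contacts$kept)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# three-letter residue names for PDB output
aa_three <- function(aa) {
  out <- bio3d::aa123(aa)
  out[is.na(out) | out == "---"] <- "UNK"
  out
}

#' Write chain coordinates as a PDB model
#'
#' Backbone N/CA/C plus the CB proxy (absent for Gly), single chain A.
#'
#' @param path output path.
#' @param coords a `chain_coordinates`.
#' @export
write_model_pdb <- function(path, coords) {
  n <- nrow(coords$CA)
  xyz <- c(); resno <- c(); elety <- c(); resid <- c()
  three <- aa_three(coords$aa)
  for (r in seq_len(n)) {
    atoms <- c("N", "CA", "C")
    if (!coords$is_gly[r]) atoms <- c(atoms, "CB")
    for (a in atoms) {
      xyz <- c(xyz, coords[[a]][r, ])
      resno <- c(resno, r)
      elety <- c(elety, a)
      resid <- c(resid, three[r])
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep("A", length(resno)))
  invisible(path)
}

#' Read a model PDB written by [write_model_pdb()]
#'
#' @param path PDB file.
#' @return a `chain_coordinates`.
#' @export
read_model_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  resnos <- sort(unique(at$resno))
  n <- length(resnos)
  take <- function(elety) {
    m <- matrix(NA_real_, n, 3)
    sel <- at[at$elety == elety, ]
    idx <- match(sel$resno, resnos)
    m[idx, ] <- as.matrix(sel[, c("x", "y", "z")])
    m
  }
  Nm <- take("N"); CAm <- take("CA"); Cm <- take("C"); CBm <- take("CB")
  aa <- bio3d::aa321(at$resid[match(resnos, at$resno)])
  structure(
    list(N = Nm, CA = CAm, C = Cm, CB = CBm, is_gly = aa == "G", aa = aa),
    class = "chain_coordinates"
  )
}

#' Read a reference structure and map it onto the query sequence
#'
#' Reads a single-chain PDB (or the selected chain), maps its residues to the
#' query by aligning the one-letter sequences, and extracts per-residue CA and
#' CB (CA for Gly or when CB is missing) coordinates plus backbone dihedrals
#' where computable. Query positions without a resolved residue are flagged
#' unresolved.
#'
#' @param path PDB file.
#' @param query_sequence the query one-letter sequence.
#' @param chain chain identifier; default: the first chain in the file.
#' @param min_identity minimal sequence identity of the mapping (default 0.9).
#' @return object of class `reference_structure`: list with `sequence`, `aa`,
#'   `ca`, `cb` (n x 3, `NA` where unresolved), `resolved`, `phi`, `psi`.
#' @export
read_reference_structure <- function(path, query_sequence, chain = NULL,
                                     min_identity = 0.9) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, ]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain, " in ", path)
  # one residue per (resno, insert) in order of appearance
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  ukey <- unique(key)
  ref_aa <- bio3d::aa321(at$resid[match(ukey, key)])
  ref_seq <- paste(ref_aa, collapse = "")
  q_aa <- toupper(strsplit(query_sequence, "")[[1]])
  map <- map_by_alignment(paste(q_aa, collapse = ""), ref_seq, min_identity)

  nq <- length(q_aa)
  ca <- matrix(NA_real_, nq, 3)
  cb <- matrix(NA_real_, nq, 3)
  phi <- rep(NA_real_, nq)
  psi <- rep(NA_real_, nq)
  resolved <- rep(FALSE, nq)
  # backbone coordinates per reference residue (for dihedrals)
  get_atom <- function(k, elety) {
    rows <- which(key == ukey[k] & at$elety == elety)
    if (length(rows) == 0L) return(NULL)
    as.numeric(at[rows[1], c("x", "y", "z")])
  }
  nref <- length(ukey)
  Nv <- lapply(seq_len(nref), get_atom, elety = "N")
  CAv <- lapply(seq_len(nref), get_atom, elety = "CA")
  Cv <- lapply(seq_len(nref), get_atom, elety = "C")
  CBv <- lapply(seq_len(nref), get_atom, elety = "CB")
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
    m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
    -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  uresno <- at$resno[match(ukey, key)]
  for (q in seq_len(nq)) {
    k <- map[q]
    if (is.na(k)) next
    cav <- CAv[[k]]
    if (is.null(cav)) next
    resolved[q] <- TRUE
    ca[q, ] <- cav
    cbq <- CBv[[k]]
    cb[q, ] <- if (q_aa[q] != "G" && !is.null(cbq)) cbq else cav
    # phi needs C(k-1), N, CA, C; psi needs N, CA, C, N(k+1); both only
    # within a contiguous stretch of residue numbers
    if (k > 1 && uresno[k - 1] == uresno[k] - 1 && !is.null(Cv[[k - 1]]) &&
        !is.null(Nv[[k]]) && !is.null(Cv[[k]])) {
      phi[q] <- dihedral(Cv[[k - 1]], Nv[[k]], cav, Cv[[k]])
    }
    if (k < nref && uresno[k + 1] == uresno[k] + 1 && !is.null(Nv[[k]]) &&
        !is.null(Cv[[k]]) && !is.null(Nv[[k + 1]])) {
      psi[q] <- dihedral(Nv[[k]], cav, Cv[[k]], Nv[[k + 1]])
    }
  }
  structure(
    list(sequence = paste(q_aa, collapse = ""), aa = q_aa, ca = ca, cb = cb,
         resolved = resolved, phi = phi, psi = psi),
    class = "reference_structure"
  )
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# map query positions to reference residue ranks; identity check over the
# aligned region
map_by_alignment <- function(query, ref, min_identity) {
  if (identical(query, ref)) return(seq_len(nchar(query)))
  al <- Biostrings::pairwiseAlignment(query, ref, type = "global",
                                      gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  qi <- Biostrings::start(Biostrings::pattern(al)) - 1L
  ri <- Biostrings::start(Biostrings::subject(al)) - 1L
  map <- rep(NA_integer_, nchar(query))
  matches <- 0L; aligned <- 0L
  for (t in seq_along(qa)) {
    qgap <- qa[t] == "-"; rgap <- ra[t] == "-"
    if (!qgap) qi <- qi + 1L
    if (!rgap) ri <- ri + 1L
    if (!qgap && !rgap) {
      map[qi] <- ri
      aligned <- aligned + 1L
      if (qa[t] == ra[t]) matches <- matches + 1L
    }
  }
  if (aligned == 0L || matches / aligned < min_identity) {
    stop("reference chain does not match query sequence (identity ",
         if (aligned > 0) round(matches / aligned, 2) else 0,
         " < ", min_identity, ")")
  }
  map
}

#' @export
print.reference_structure <- function(x, ...) {
  cat("reference_structure:", length(x$aa), "residues,",
      sum(x$resolved), "resolved\n")
  invisible(x)
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$seqs), "sequences, width", x$width, "\n")
  invisible(x)
}
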