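test_that("contacts classify against the reference at the 9 A boundary", {
  n <- 4
  ca <- matrix(0, n, 3); ca[, 1] <- c(0, 9.0, 18.05, 100)
  ref <- structure(
    list(sequence = "AAAA", aa = rep("A", n), ca = ca, cb = ca,
         resolved = c(TRUE, TRUE, TRUE, FALSE),
         phi = rep(NA_real_, n), psi = rep(NA_real_, n)),
    class = "reference_structure"
  )
  ct <- data.frame(i = c(1L, 2L, 1L), j = c(2L, 3L, 4L))
  cls <- classify_contacts(ct, ref)
  expect_equal(as.character(cls), c("TP", "FP", "unverifiable"))
  expect_equal(attr(cls, "distance")[1:2], c(9.0, 9.05))
})

test_that("precision and recall follow the worked arithmetic", {
  # 82 true positives among 114 input contacts, all kept
  cls <- c(rep("TP", 82), rep("FP", 32))
  pr <- precision_recall(cls, rep(TRUE, 114))
  expect_equal(pr$precision, 82 / 114)
  expect_equal(sprintf("%.0f%%", 100 * pr$precision), "72%")
  expect_equal(pr$recall, 1.0)
  # keeping 102 of them with 21 false positives: one true positive lost
  kept <- c(rep(TRUE, 81), FALSE, rep(TRUE, 21), rep(FALSE, 11))
  pr2 <- precision_recall(cls, kept)
  expect_equal(pr2$precision, 81 / 102)
  expect_equal(pr2$recall, 81 / 82)
  # order invariance
  perm <- sample(114)
  pr3 <- precision_recall(cls[perm], kept[perm])
  expect_equal(pr3$precision, pr2$precision)
  expect_warning(pr4 <- precision_recall(cls, rep(FALSE, 114)), "undefined")
  expect_true(is.na(pr4$precision))
})

test_that("Kabsch superposition recovers rigid transforms", {
  set.seed(8)
  x <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(x, x)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  fit1 <- kabsch_superpose(x, sweep(x, 2, c(5, -2, 11), `+`))
  expect_equal(fit1$rmsd, 0, tolerance = 1e-12)
  # random proper rotation, recovered to high precision
  th <- 0.7; ph <- 1.3
  R1 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  Rk <- R1 %*% R2
  y <- x %*% Rk + matrix(rep(c(1, 2, 3), each = 10), 10)
  fit <- kabsch_superpose(x, y)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(fit$rotation - Rk)), 1e-6)
  expect_lt(fit$rmsd, 1e-9)
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("Kabsch agrees with the bio3d least-squares fit", {
  set.seed(21)
  a <- matrix(rnorm(36), 12, 3)
  b <- a %*% diag(3) + matrix(rnorm(36, sd = 0.3), 12, 3)
  ours <- kabsch_superpose(a, b)$rmsd
  rot <- bio3d::rot.lsq(xx = as.vector(t(a)), yy = as.vector(t(b)))
  moved <- matrix(rot, ncol = 3, byrow = TRUE)
  theirs <- sqrt(mean(rowSums((moved - b)^2)))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("GDT is superposition-invariant and finds intact cores", {
  set.seed(12)
  ref <- matrix(rnorm(60, sd = 8), 20, 3)
  expect_equal(gdt5(ref, ref), 1.0)
  th <- 0.5
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ref %*% Rz + matrix(rep(c(10, -4, 2), each = 20), 20)
  expect_equal(gdt5(moved, ref), 1.0)
  expect_equal(gdt_ts(moved, ref), 1.0)
  # half the atoms displaced far away: at least the exact half is found
  broken <- ref
  broken[1:10, ] <- broken[1:10, ] + 20
  expect_gte(gdt5(broken, ref), 0.5)
  expect_error(gdt(ref[1:2, ], ref[1:2, ]), "fewer than 3")
})

test_that("effective sequence counts match constructed alignments", {
  msa_k <- list(seqs = rep(strrep("ACDEFGHIKL", 3), 5))
  expect_equal(n_effective(msa_k), 1.0)
  # all pairwise identities far below the threshold
  msa_m <- list(seqs = c(strrep("A", 20), strrep("C", 20), strrep("D", 20)))
  expect_equal(n_effective(msa_m), 3)
  # one pair at 90% identity among four sequences: weights 1/2,1/2,1,1
  s1 <- strrep("A", 20)
  s2 <- paste0(strrep("A", 18), "CC")
  msa4 <- list(seqs = c(s1, s2, strrep("D", 20), strrep("E", 20)))
  expect_equal(n_effective(msa4), 3.0)
  # identity ignores columns where either sequence is gapped
  gap <- list(seqs = c("AAAA----", "AAAACCCC"))
  expect_equal(n_effective(gap), 1.0)   # 4/4 identity over shared columns
  expect_error(n_effective(list(seqs = character(0))), "empty")
  # bounds on arbitrary alignments
  m <- make_toy_msa(2, c(2, 3), seed = 4)
  val <- n_effective(m)
  expect_gte(val, 1)
  expect_lte(val, 5)
})

test_that("benchmark-mode chains fix experimental dihedrals", {
  ch <- build_torsion_chain("GASDFKL", data.frame(start = 2L, end = 6L,
                                                  kind = "helix"))
  xy <- to_coordinates(ch)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(f, xy)
  ref <- read_reference_structure(f, "GASDFKL")
  bench <- reference_dihedral_chain(ref, "CHHHHHC")
  expect_true(all(bench$fixed[2:6]))
  expect_equal(bench$phi[3:6], rep(-60, 4), tolerance = 0.2)
  expect_equal(bench$psi[2:5], rep(-45, 4), tolerance = 0.2)
  # all-loop assignment leaves everything free
  free <- reference_dihedral_chain(ref, "CCCCCCC")
  expect_false(any(free$fixed))
  # a structured terminus lacks phi: canonical fallback with a warning
  expect_warning(rb <- reference_dihedral_chain(ref, "HHHHHHC"), "canonical")
  expect_equal(rb$phi[1], -60)
  expect_error(reference_dihedral_chain(ref, "CC"), "length")
})
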