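test_that("contact selection applies the quota and long-range rule", {
  set.seed(1)
  n_aa <- 95
  # abundant ranked list of eligible long-range pairs
  pairs <- expand.grid(i = 1:n_aa, j = 1:n_aa)
  pairs <- pairs[pairs$j > pairs$i + 10, ]
  pairs <- pairs[sample.int(nrow(pairs), 400), ]
  ranked <- data.frame(i = pairs$i, j = pairs$j,
                       score = sort(runif(400), decreasing = TRUE))
  segs <- data.frame(start = c(10L, 40L), end = c(20L, 50L),
                     kind = c("helix", "strand"))
  rset <- select_input_contacts(ranked, segs, n_aa)
  expect_s3_class(rset, "restraint_set")
  expect_equal(nrow(rset$contacts), 114L)   # floor(1.2 * 95)
  expect_true(all(rset$contacts$lambda == 1))
  expect_true(all(rset$contacts$on))
  # pairs inside one segment are skipped
  ranked2 <- data.frame(i = c(3L, 2L), j = c(5L, 30L), score = c(2, 1))
  seg_h <- data.frame(start = 3L, end = 7L, kind = "helix")
  r2 <- suppressWarnings(select_input_contacts(ranked2, seg_h, 30))
  expect_equal(nrow(r2$contacts), 1L)
  expect_equal(r2$contacts$i, 2L)
  # exhaustion keeps what exists and warns
  expect_warning(r3 <- select_input_contacts(ranked[1:50, ], segs, n_aa),
                 "exhausted")
  expect_lte(nrow(r3$contacts), 50L)
  expect_error(select_input_contacts(ranked, segs, 0), "positive")
})

test_that("restraint energy follows the switchable-weight form", {
  expect_equal(restraint_term(6, 0.5, 10, 7), 0)
  expect_equal(restraint_term(10, 1, 10, 7), 9)
  expect_equal(restraint_term(10, 0, 5, 7), 25)
  expect_error(restraint_term(10, 1.5, 10, 7), "lambda")
  # non-negative over the whole weight range
  lam <- seq(0, 1, by = 0.05)
  expect_true(all(restraint_term(11, lam, 3, 7) >= 0))
  # switching off is favorable exactly when (d - d0)^2 > D^2
  D <- 4
  expect_lt(restraint_term(7 + D + 0.5, 0, D), restraint_term(7 + D + 0.5, 1, D))
  expect_gt(restraint_term(7 + D - 0.5, 0, D), restraint_term(7 + D - 0.5, 1, D))
})

test_that("lambda gradient is analytic and matches finite differences", {
  expect_equal(lambda_gradient(6.9, 0.3, 10, 7), 0)
  expect_equal(lambda_gradient(10, 1, 3, 7), 9 - 18)
  # stationary weight has zero gradient
  d <- 9; D <- 5
  lam_star <- (d - 7)^2 / (2 * D^2)
  expect_equal(lambda_gradient(d, lam_star, D, 7), 0)
  # centered finite-difference oracle
  h <- 1e-6
  for (d in c(7.5, 9, 12, 20)) {
    for (lam in c(0.2, 0.5, 0.9)) {
      num <- (restraint_term(d, lam + h, 4, 7) -
                restraint_term(d, lam - h, 4, 7)) / (2 * h)
      expect_equal(lambda_gradient(d, lam, 4, 7), num, tolerance = 1e-6)
    }
  }
})

test_that("total restraint energy is additive over contacts", {
  ch <- build_torsion_chain(strrep("A", 20), NULL)
  xy <- to_coordinates(ch)
  ct <- data.frame(i = c(1L, 2L), j = c(15L, 20L), score = 1,
                   lambda = c(0.8, 0.3), on = TRUE)
  rset <- structure(list(contacts = ct, d0 = 7, D = 5),
                    class = "restraint_set")
  d1 <- pair_distance(xy, 1, 15)
  d2 <- pair_distance(xy, 2, 20)
  expect_equal(total_restraint_energy(rset, xy),
               restraint_term(d1, 0.8, 5) + restraint_term(d2, 0.3, 5))
  empty <- structure(list(contacts = ct[0, ], d0 = 7, D = 5),
                     class = "restraint_set")
  expect_equal(total_restraint_energy(empty, xy), 0)
})

test_that("clash energy penalizes only close non-bonded pairs", {
  far <- matrix(c(0, 0, 0, 500, 0, 0, 1000, 0, 0), 3, 3, byrow = TRUE)
  coords_far <- make_coords(far, far + 1, far + 2, far + 3,
                            c("A", "A", "A"))
  expect_equal(clash_energy(coords_far), 0)
  # a single atom pair at r_min - 1 contributes exactly k
  N <- matrix(c(0, 0, 1.5, 500, 500, 500, 3.5, 0, 0), 3, 3, byrow = TRUE)
  CA <- matrix(c(0, 0, 0, 500, 500, 501, 4.9, 0, 0), 3, 3, byrow = TRUE)
  C <- matrix(c(0, 0, -1.5, 500, 500, 502, 6.3, 0, 0), 3, 3, byrow = TRUE)
  CB <- matrix(c(1.5, 0, 0, 500, 501, 500, 4.9, 1.4, 0), 3, 3, byrow = TRUE)
  coords <- make_coords(N, CA, C, CB, c("A", "A", "A"))
  # CB of residue 1 and N of residue 3 sit 2 A apart; all else >= 3 A
  expect_equal(clash_energy(coords, r_min = 3, k = 1), 1)
  expect_equal(clash_energy(coords, r_min = 3, k = 2.5), 2.5)
  # energy vanishes continuously at the onset
  Nc <- N; Nc[3, 1] <- 1.5 + 2.999999   # pair distance -> r_min
  coords2 <- make_coords(Nc, CA, C, CB, c("A", "A", "A"))
  expect_lt(clash_energy(coords2), 1e-10)
})

test_that("clash energy matches a brute-force oracle on collapsed chains", {
  oracle_clash <- function(xy, r_min = 3, k = 1) {
    cb <- xy$CB
    if (any(xy$is_gly)) cb[xy$is_gly, ] <- xy$CA[xy$is_gly, ]
    n <- nrow(xy$CA)
    e <- 0
    for (i in seq_len(n - 2)) {
      for (j in (i + 2):n) {
        ai <- rbind(xy$N[i, ], xy$CA[i, ], xy$C[i, ],
                    if (!xy$is_gly[i]) cb[i, ])
        aj <- rbind(xy$N[j, ], xy$CA[j, ], xy$C[j, ],
                    if (!xy$is_gly[j]) cb[j, ])
        for (a in seq_len(nrow(ai))) {
          d <- sqrt(colSums((t(aj) - ai[a, ])^2))
          e <- e + sum(k * (r_min - d[d < r_min])^2)
        }
      }
    }
    e
  }
  set.seed(42)
  for (rep in 1:3) {
    ch <- build_torsion_chain(strrep("AGS", 5), NULL)
    ch$phi <- runif(15, -180, 180)
    ch$psi <- runif(15, -180, 180)
    xy <- to_coordinates(ch)
    expect_equal(clash_energy(xy), oracle_clash(xy), tolerance = 1e-12)
  }
})

test_that("violation energy averages squared excess over the cutoff", {
  expect_equal(violation_energy(c(3, 8, 9)), 0)
  expect_equal(violation_energy(10), 1)
  expect_equal(violation_energy(c(9, 11)), 2)
  expect_error(violation_energy(numeric(0)), "no distances")
  expect_error(violation_energy(c(NA_real_, NA_real_)), "no distances")
})
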