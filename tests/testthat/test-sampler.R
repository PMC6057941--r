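test_that("annealing schedules interpolate geometrically with exact endpoints", {
  s <- make_schedule(100)
  expect_equal(s$D_values[1], 150)
  expect_equal(s$D_values[100], 3)
  expect_true(all(diff(s$D_values) < 0))
  ratios <- s$D_values[-1] / s$D_values[-100]
  expect_lt(diff(range(ratios)), 1e-12)
  s2 <- make_schedule(2, T_start = 5, T_end = 0.5)
  expect_equal(s2$D_values, c(150, 3))
  expect_equal(s2$T_values, c(5, 0.5))
  expect_error(make_schedule(1), "at least 2")
  expect_error(make_schedule(10, D_start = 3, D_end = 150), "D_start")
})

test_that("lambda updates drift by the switching gradient and clamp", {
  # zero gradient and zero noise: unchanged
  lam <- c(0.2, 0.7)
  set.seed(1)
  expect_equal(update_lambdas(lam, c(5, 6.5), D = 3, T_ = 0), lam)
  # satisfied contact at T = 0 never moves regardless of D
  set.seed(1)
  expect_equal(update_lambdas(0.4, 3, D = 150, T_ = 0), 0.4)
  # violated contact with weight below the basin boundary drifts down
  set.seed(1)
  l1 <- update_lambdas(0.1, 17, D = 3, T_ = 0)
  expect_lt(l1, 0.1)
  # clamping: weight 1 with positive noise draw stays 1
  set.seed(7)
  z <- rnorm(1)   # peek the draw this seed produces
  stopifnot(z > 0)
  set.seed(7)
  expect_equal(update_lambdas(1, 3, D = 3, T_ = 4), 1)
  # always within [0, 1]
  set.seed(2)
  for (k in 1:50) {
    out <- update_lambdas(runif(5), runif(5, 3, 20), D = 3, T_ = 5)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("the noiseless lambda map is bistable about the stationary weight", {
  # lambda* = (d - d0)^2 / (2 D^2) separates the basins of 0 and 1
  d <- 10; D <- 5
  lam_star <- (d - 7)^2 / (2 * D^2)   # 0.18
  iterate <- function(lam0, d_ = d, D_ = D) {
    lam <- lam0
    for (k in 1:2000) lam <- update_lambdas(lam, d_, D = D_, T_ = 0)
    lam
  }
  expect_equal(iterate(lam_star), lam_star)       # stationary point
  expect_equal(iterate(lam_star - 0.01), 0)       # below: switched off
  expect_equal(iterate(lam_star + 0.01), 1)       # above: fully on
  # badly violated restraint (boundary above 1): switch-off from any weight
  expect_equal(iterate(0.99, d_ = 17, D_ = 3), 0)
})

test_that("violated-contact weight mass shifts to zero as D anneals down", {
  # fixed structure, fixed T: estimate the lambda marginal over many updates
  mean_lambda <- function(D) {
    set.seed(99)
    lam <- 0.5
    acc <- numeric(2000)
    for (k in 1:2000) {
      lam <- update_lambdas(lam, 13, D = D, T_ = 0.002)
      acc[k] <- lam
    }
    mean(acc[-(1:500)])
  }
  m <- vapply(c(150, 30, 3), mean_lambda, numeric(1))
  expect_true(m[1] >= m[2] && m[2] >= m[3])
  expect_gt(m[1], 0.9)   # switching off unaffordable at D = 150
  expect_lt(m[3], 0.1)   # cheap at D = 3
  expect_gt(m[1] - m[3], 0.8)
})

test_that("torsion moves respect fixed dihedrals and Metropolis", {
  segs <- data.frame(start = 1L, end = 6L, kind = "strand")
  ch_fixed <- build_torsion_chain("ASDFGH", segs)
  xy <- to_coordinates(ch_fixed)
  rset <- structure(list(contacts = data.frame(i = integer(0), j = integer(0),
                                               score = numeric(0),
                                               lambda = numeric(0),
                                               on = logical(0)),
                         d0 = 7, D = 3),
                    class = "restraint_set")
  # all dihedrals fixed: no-op
  mv <- torsion_move(ch_fixed, rset, xy, T_ = 1)
  expect_identical(mv$chain$phi, ch_fixed$phi)
  expect_false(mv$accepted)
  # free chain: fixed residues untouched over many moves, angles stay wrapped
  segs2 <- data.frame(start = 3L, end = 4L, kind = "helix")
  ch <- build_torsion_chain("ASDFGH", segs2)
  cur <- list(chain = ch, coords = to_coordinates(ch))
  set.seed(3)
  for (k in 1:40) {
    cur <- torsion_move(cur$chain, rset, cur$coords, T_ = 2)
  }
  expect_equal(cur$chain$phi[3:4], c(-60, -60))
  expect_equal(cur$chain$psi[3:4], c(-45, -45))
  expect_true(all(cur$chain$phi > -180 & cur$chain$phi <= 180))
  # with T = 0 accepted moves never increase the energy
  e <- function(st) clash_energy(st$coords) +
    total_restraint_energy(rset, st$coords)
  cur <- list(chain = ch, coords = to_coordinates(ch))
  set.seed(4)
  for (k in 1:20) {
    nxt <- torsion_move(cur$chain, rset, cur$coords, T_ = 0)
    if (nxt$accepted) expect_lte(e(nxt), e(cur) + 1e-9)
    cur <- nxt
  }
})

test_that("annealing runs are reproducible and conserve constraints", {
  g <- gsgs_fixture()
  segs <- segments_from_ss(g$fold$ss_labels)
  chain <- build_torsion_chain(g$fold$sequence, segs)
  rset <- suppressWarnings(
    select_input_contacts(g$contacts, segs, nchar(g$fold$sequence)))
  sched <- make_schedule(60)
  a <- run_annealing(chain, rset, sched, moves_per_step = 40, seed = 123)
  b <- run_annealing(chain, rset, sched, moves_per_step = 40, seed = 123)
  expect_identical(a$chain$phi, b$chain$phi)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$coords$CA, b$coords$CA)
  expect_true(all(a$lambda >= 0 & a$lambda <= 1))
  # fixed dihedrals never altered by a protocol run
  expect_identical(a$chain$phi[chain$fixed], chain$phi[chain$fixed])
  expect_identical(a$chain$psi[chain$fixed], chain$psi[chain$fixed])
  # zero contacts: pure clash annealing with an empty weight vector
  rset0 <- rset
  rset0$contacts <- rset$contacts[0, ]
  z <- run_annealing(chain, rset0, sched, moves_per_step = 20, seed = 5)
  expect_length(z$lambda, 0)
  expect_true(is.finite(z$energy))
})

test_that("an enormous switching cost pins violated restraint weights at one", {
  # rigid extended chain (all dihedrals fixed): the contacts stay violated,
  # yet switching off is never favorable when D is huge, so weights drift to
  # one and stay there
  chain <- build_torsion_chain(strrep("AS", 15),
                               data.frame(start = 1L, end = 30L,
                                          kind = "strand"))
  ct <- data.frame(i = c(1L, 3L), j = c(20L, 28L), score = 1,
                   lambda = c(0.6, 0.6), on = TRUE)
  rset <- structure(list(contacts = ct, d0 = 7, D = 1e6),
                    class = "restraint_set")
  sched <- make_schedule(80, D_start = 1e6, D_end = 1e5, T_start = 1,
                         T_end = 1e-3)
  for (s in 1:5) {
    r <- run_annealing(chain, rset, sched, moves_per_step = 10, seed = s)
    expect_true(all(r$lambda > 0.5))
  }
})
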