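# Simulated-annealing engine: coupled D and T schedules, the stochastic
# lambda update, single Monte Carlo torsion moves, and the full annealing run
# (compiled inner loop).

#' Geometric annealing schedule for D and T
#'
#' The switching-cost scale `D` is annealed from `D_start` (150 Angstrom by
#' default, making it prohibitively expensive to switch any restraint off)
#' down to `D_end` (3 Angstrom), while the Metropolis temperature `T` cools
#' geometrically alongside it. Endpoints are exact.
#'
#' @param n_steps number of schedule steps (>= 2).
#' @param D_start,D_end switching-cost scale endpoints (Angstrom).
#' @param T_start,T_end temperature endpoints (energy units).
#' @return object of class `anneal_schedule`: list with `n_steps`, `D_values`,
#'   `T_values`.
#' @export
make_schedule <- function(n_steps, D_start = 150, D_end = 3,
                          T_start = 10, T_end = 1e-3) {
  if (n_steps < 2) stop("n_steps must be at least 2")
  if (!(D_start > D_end && D_end > 0)) stop("need D_start > D_end > 0")
  if (!(T_start >= T_end && T_end >= 0)) stop("need T_start >= T_end >= 0")
  geo <- function(a, b, n) exp(seq(log(a), log(b), length.out = n))
  structure(
    list(n_steps = as.integer(n_steps),
         D_values = geo(D_start, D_end, n_steps),
         T_values = geo(T_start, T_end, n_steps)),
    class = "anneal_schedule"
  )
}

#' One stochastic update of the restraint weights
#'
#' Brownian-motion-like step on each weight:
#' `lambda' = clamp( lambda - gamma * dE/dlambda * dt + delta * sqrt(T dt) * z )`
#' with `z` standard normal, clamped to \[0, 1\]. The drift is gradient descent
#' on the switching energy, so weights of systematically violated restraints
#' drift towards 0 once switching off becomes favorable.
#'
#' @param lambdas current weights in \[0, 1\].
#' @param distances current proxy distances of the contacts (Angstrom).
#' @param D switching-cost scale (Angstrom).
#' @param T_ temperature.
#' @param dt time step (default 1).
#' @param gamma drift coefficient (default 0.00025).
#' @param delta noise coefficient (default 0.6666).
#' @param d0 violation onset (Angstrom, default 7).
#' @return updated weight vector.
#' @export
update_lambdas <- function(lambdas, distances, D, T_, dt = 1,
                           gamma = 0.00025, delta = 0.6666, d0 = 7) {
  stopifnot(length(lambdas) == length(distances))
  if (any(lambdas < 0 | lambdas > 1)) stop("lambda outside [0, 1]")
  grad <- lambda_gradient(distances, lambdas, D, d0)
  z <- stats::rnorm(length(lambdas))
  pmin(1, pmax(0, lambdas - gamma * grad * dt + delta * sqrt(T_ * dt) * z))
}

#' One Metropolis torsion move
#'
#' Perturbs a uniformly chosen free phi or psi dihedral by a uniform step in
#' `[-max_step_deg, max_step_deg]` and accepts with Metropolis probability
#' `min(1, exp(-dE / T))` under `E = clash + restraint` energy. Fixed
#' dihedrals are never touched. With no free dihedral the move is a no-op.
#'
#' @param chain a `torsion_chain`.
#' @param rset a `restraint_set` (with `D` set or passed via `D`).
#' @param coords current `chain_coordinates` of `chain`.
#' @param T_ temperature.
#' @param max_step_deg maximal perturbation (degrees).
#' @param D switching-cost scale.
#' @return list with `chain`, `coords`, `accepted`.
#' @export
torsion_move <- function(chain, rset, coords, T_, max_step_deg = 30,
                         D = rset$D) {
  n <- length(chain$aa)
  free <- which(!chain$fixed)
  phi_res <- free[free > 1L]
  psi_res <- free[free < n]
  res <- c(phi_res, psi_res)
  kind <- c(rep(0L, length(phi_res)), rep(1L, length(psi_res)))
  if (length(res) == 0L) {
    return(list(chain = chain, coords = coords, accepted = FALSE))
  }
  pick <- sample.int(length(res), 1L)
  cand <- chain
  step <- stats::runif(1, -max_step_deg, max_step_deg)
  wrap <- function(x) {
    x <- (x + 180) %% 360
    ifelse(x <= 0, x + 360, x) - 180
  }
  if (kind[pick] == 0L) {
    cand$phi[res[pick]] <- wrap(cand$phi[res[pick]] + step)
  } else {
    cand$psi[res[pick]] <- wrap(cand$psi[res[pick]] + step)
  }
  cand_coords <- to_coordinates(cand)
  e_old <- clash_energy(coords) + total_restraint_energy(rset, coords, D = D)
  e_new <- clash_energy(cand_coords) +
    total_restraint_energy(rset, cand_coords, D = D)
  dE <- e_new - e_old
  acc <- dE <= 0 || (T_ > 0 && stats::runif(1) < exp(-dE / T_))
  if (acc) list(chain = cand, coords = cand_coords, accepted = TRUE)
  else list(chain = chain, coords = coords, accepted = FALSE)
}

#' Run one simulated-annealing structure calculation
#'
#' Iterates the schedule; at each step performs `moves_per_step` Metropolis
#' torsion moves at that step's temperature, then (when `sample_lambda`) one
#' stochastic lambda update with that step's `D` and `T`. The whole loop runs
#' in compiled code on R's RNG stream, so results are reproducible under
#' `set.seed()` / the `seed` argument.
#'
#' @param chain starting `torsion_chain` (fixed dihedrals are never altered).
#' @param rset `restraint_set`; its `lambda` column is the starting weights.
#' @param schedule an `anneal_schedule`.
#' @param moves_per_step Monte Carlo moves per schedule step; `NULL` means
#'   `moves_factor` times the number of free dihedrals.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param sample_lambda sample restraint weights (TRUE) or keep them fixed.
#' @param moves_factor multiplier used when `moves_per_step` is `NULL`
#'   (default 20).
#' @param max_step_deg maximal torsion perturbation (degrees, default 30).
#' @param gamma,delta,dt lambda-update parameters.
#' @param r_min,k_clash clash-term parameters.
#' @param trace record the energy after every schedule step.
#' @return object of class `anneal_result`: list with final `chain`, `coords`,
#'   `lambda`, `energy`, acceptance counts, `seed` and optional `trace`.
#' @export
run_annealing <- function(chain, rset, schedule, moves_per_step = NULL,
                          seed = NULL, sample_lambda = TRUE,
                          moves_factor = 20, max_step_deg = 30,
                          gamma = 0.00025, delta = 0.6666, dt = 1,
                          r_min = 3.0, k_clash = 1.0, trace = FALSE) {
  stopifnot(inherits(chain, "torsion_chain"), inherits(rset, "restraint_set"),
            inherits(schedule, "anneal_schedule"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(chain$aa)
  n_free_dihedrals <- sum(!chain$fixed & seq_len(n) > 1L) +
    sum(!chain$fixed & seq_len(n) < n)
  if (is.null(moves_per_step)) {
    moves_per_step <- moves_factor * max(1L, n_free_dihedrals)
  }
  ct <- rset$contacts
  res <- cf_anneal(
    chain$phi, chain$psi, chain$omega, chain$fixed, chain$aa == "G",
    as.integer(ct$i) - 1L, as.integer(ct$j) - 1L, as.numeric(ct$lambda),
    rset$d0, schedule$D_values, schedule$T_values,
    as.integer(moves_per_step), max_step_deg,
    gamma, delta, dt, sample_lambda, r_min, k_clash, trace
  )
  out_chain <- chain
  out_chain$phi <- res$phi
  out_chain$psi <- res$psi
  cb <- res$CB
  cb[chain$aa == "G", ] <- NA_real_
  coords <- structure(
    list(N = res$N, CA = res$CA, C = res$C, CB = cb,
         is_gly = chain$aa == "G", aa = chain$aa),
    class = "chain_coordinates"
  )
  structure(
    list(chain = out_chain, coords = coords, lambda = res$lambda,
         energy = res$energy, accepted = res$accepted,
         attempted = res$attempted, seed = seed,
         trace = if (trace) res$trace else NULL),
    class = "anneal_result"
  )
}

#' @export
print.anneal_result <- function(x, ...) {
  cat("anneal_result: final energy", format(x$energy, digits = 4),
      "| acceptance", format(x$accepted / max(1, x$attempted), digits = 3), "\n")
  invisible(x)
}
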