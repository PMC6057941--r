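# The full filtering pipeline: repeated annealing runs with sampled restraint
# weights, per-run refinement with fixed weights, per-run on/off decisions and
# the consensus filter over independent repeats.

#' Protocol configuration
#'
#' All protocol constants in one place, with the published defaults where the
#' method states them: selection quota factor 1.2, violation onset d0 = 7
#' Angstrom, switching-cost scale annealed 150 -> 3 Angstrom, lambda-update
#' coefficients gamma = 0.00025 and delta = 0.6666, 64 independent repeats,
#' consensus threshold "on in more than 30% of runs", contact cutoff 9
#' Angstrom. Sampler settings (schedule length, moves per step, temperature
#' endpoints, maximal torsion step) are this implementation's own calibration
#' and are exposed here.
#'
#' @param factor contact-selection quota multiplier.
#' @param d0 violation onset distance (Angstrom).
#' @param D_start,D_end switching-cost annealing endpoints (Angstrom).
#' @param gamma,delta,dt lambda-update parameters.
#' @param n_repeats number of independent protocol runs.
#' @param consensus_on_fraction strict consensus threshold on the on-fraction.
#' @param lambda_on_threshold weight above which an annealed restraint enters
#'   the refined list.
#' @param tp_cutoff contact definition cutoff (Angstrom) for evaluation.
#' @param n_steps annealing schedule steps.
#' @param moves_per_step Monte Carlo moves per step (`NULL`: `moves_factor`
#'   times the number of free dihedrals).
#' @param moves_factor multiplier for the default `moves_per_step`.
#' @param T_start,T_end temperature schedule endpoints.
#' @param max_step_deg maximal torsion perturbation (degrees).
#' @param r_min,k_clash soft-core clash parameters.
#' @param base_seed base RNG seed; run k uses `base_seed + k - 1`.
#' @return object of class `protocol_config` (a named list).
#' @export
protocol_config <- function(factor = 1.2, d0 = 7, D_start = 150, D_end = 3,
                            gamma = 0.00025, delta = 0.6666, dt = 1,
                            n_repeats = 64, consensus_on_fraction = 0.30,
                            lambda_on_threshold = 0.5, tp_cutoff = 9,
                            n_steps = 300, moves_per_step = NULL,
                            moves_factor = 20, T_start = 10, T_end = 1e-3,
                            max_step_deg = 30, r_min = 3.0, k_clash = 1.0,
                            base_seed = 1) {
  cfg <- list(factor = factor, d0 = d0, D_start = D_start, D_end = D_end,
              gamma = gamma, delta = delta, dt = dt, n_repeats = n_repeats,
              consensus_on_fraction = consensus_on_fraction,
              lambda_on_threshold = lambda_on_threshold,
              tp_cutoff = tp_cutoff, n_steps = n_steps,
              moves_per_step = moves_per_step, moves_factor = moves_factor,
              T_start = T_start, T_end = T_end, max_step_deg = max_step_deg,
              r_min = r_min, k_clash = k_clash, base_seed = base_seed)
  pos <- c("factor", "d0", "D_start", "D_end", "gamma", "delta", "dt",
           "n_repeats", "lambda_on_threshold", "tp_cutoff", "n_steps",
           "moves_factor", "T_start", "max_step_deg", "r_min", "k_clash")
  if (any(unlist(cfg[pos]) <= 0) || T_end < 0) {
    stop("all protocol constants must be positive")
  }
  if (consensus_on_fraction <= 0 || consensus_on_fraction >= 1) {
    stop("consensus_on_fraction must lie in (0, 1)")
  }
  structure(cfg, class = "protocol_config")
}

#' One protocol run: anneal, refine, re-anneal, decide on/off
#'
#' Stage 1 anneals the chain with restraint-weight sampling (weights start at
#' 1, the switching cost D annealed from `D_start` to `D_end`). Stage 2 takes
#' the refined list (final weight >= `lambda_on_threshold`) and performs a
#' final structure calculation with only those restraints, all weights fixed
#' at 1. A contact is marked on iff it is in the refined list and its distance
#' in the final structure does not violate the upper limit `d0` by more than
#' `D_end` (i.e. distance <= d0 + D_end, 10 Angstrom with defaults).
#'
#' @param chain_template starting `torsion_chain` (not modified).
#' @param rset selected `restraint_set`.
#' @param config a `protocol_config`.
#' @param seed integer seed for this run.
#' @return object of class `run_outcome`: list with per-contact `on`, final
#'   `lambda` (stage 1), refined-list flags, final `coords`, `seed`.
#' @export
single_protocol_run <- function(chain_template, rset, config, seed) {
  sched <- make_schedule(config$n_steps, config$D_start, config$D_end,
                         config$T_start, config$T_end)
  res1 <- run_annealing(
    chain_template, rset, sched, moves_per_step = config$moves_per_step,
    seed = seed, sample_lambda = TRUE, moves_factor = config$moves_factor,
    max_step_deg = config$max_step_deg, gamma = config$gamma,
    delta = config$delta, dt = config$dt, r_min = config$r_min,
    k_clash = config$k_clash
  )
  refined <- res1$lambda >= config$lambda_on_threshold
  rset2 <- rset
  rset2$contacts <- rset$contacts[refined, , drop = FALSE]
  rset2$contacts$lambda <- rep(1, nrow(rset2$contacts))
  res2 <- run_annealing(
    chain_template, rset2, sched, moves_per_step = config$moves_per_step,
    seed = NULL, sample_lambda = FALSE, moves_factor = config$moves_factor,
    max_step_deg = config$max_step_deg, gamma = config$gamma,
    delta = config$delta, dt = config$dt, r_min = config$r_min,
    k_clash = config$k_clash
  )
  on <- rep(FALSE, nrow(rset$contacts))
  if (any(refined)) {
    d_final <- contact_distances(res2$coords, rset2$contacts$i, rset2$contacts$j)
    on[refined] <- d_final <= config$d0 + config$D_end
  }
  structure(
    list(on = on, lambda = res1$lambda, refined = refined,
         coords = res2$coords, energy = res2$energy, seed = seed),
    class = "run_outcome"
  )
}

#' Consensus filter over independent protocol runs
#'
#' A contact is kept iff it is on in strictly more than `threshold` of the
#' runs ("on in more than 30% of the 64 refined contact lists").
#'
#' @param outcomes list of `run_outcome` objects over the same contact list.
#' @param threshold consensus on-fraction threshold (default 0.30, strict).
#' @return data.frame with `on_fraction` and logical `kept`, one row per
#'   contact.
#' @export
consensus_filter <- function(outcomes, threshold = 0.30) {
  if (length(outcomes) < 1L) stop("need at least one run outcome")
  lens <- vapply(outcomes, function(o) length(o$on), integer(1))
  if (length(unique(lens)) != 1L) stop("mismatched contact lists across runs")
  on_mat <- vapply(outcomes, function(o) o$on, logical(lens[1]))
  on_mat <- matrix(on_mat, nrow = lens[1])
  on_fraction <- rowMeans(on_mat)
  data.frame(on_fraction = on_fraction, kept = on_fraction > threshold)
}

#' Filter a ranked contact list by structural self-consistency
#'
#' The full pipeline: builds secondary-structure segments and a torsion chain
#' with canonical fixed dihedrals, selects `floor(factor * n_aa)` long-range
#' contacts from the ranked list, executes `n_repeats` independent protocol
#' runs (seeds `base_seed + 0 ... n_repeats - 1`), applies the consensus
#' filter, and computes a final consensus model with the kept contacts as
#' fixed restraints.
#'
#' @param sequence one-letter amino-acid string.
#' @param ss_labels per-residue H/E/C string (same length as `sequence`).
#' @param ranked_contacts data.frame `i`, `j`, `score` sorted by descending
#'   score.
#' @param config a `protocol_config`.
#' @return object of class `filter_result`: list with `contacts` (data.frame
#'   `i`, `j`, `score`, `on_fraction`, `kept`), `segments`, `chain`, `model`
#'   (consensus-model `chain_coordinates`), `seeds`, `config`.
#' @export
filter_contacts <- function(sequence, ss_labels, ranked_contacts,
                            config = protocol_config()) {
  n_aa <- nchar(sequence)
  labs <- normalize_ss_labels(ss_labels)
  if (length(labs) != n_aa) {
    stop("secondary-structure length ", length(labs),
         " does not match sequence length ", n_aa)
  }
  segments <- segments_from_ss(labs)
  rset <- select_input_contacts(ranked_contacts, segments, n_aa,
                                factor = config$factor, d0 = config$d0)
  if (nrow(rset$contacts) == 0L) stop("no eligible contacts")
  chain <- build_torsion_chain(sequence, segments)
  seeds <- config$base_seed + seq_len(config$n_repeats) - 1L
  outcomes <- lapply(seeds, function(s) {
    single_protocol_run(chain, rset, config, seed = s)
  })
  cons <- consensus_filter(outcomes, threshold = config$consensus_on_fraction)
  contacts <- cbind(rset$contacts[, c("i", "j", "score")], cons)
  # consensus model: one final fixed-weight calculation with the kept set
  model <- NULL
  if (any(cons$kept)) {
    rset_kept <- rset
    rset_kept$contacts <- rset$contacts[cons$kept, , drop = FALSE]
    rset_kept$contacts$lambda <- rep(1, nrow(rset_kept$contacts))
    sched <- make_schedule(config$n_steps, config$D_start, config$D_end,
                           config$T_start, config$T_end)
    model <- run_annealing(
      chain, rset_kept, sched, moves_per_step = config$moves_per_step,
      seed = config$base_seed + config$n_repeats, sample_lambda = FALSE,
      moves_factor = config$moves_factor, max_step_deg = config$max_step_deg,
      gamma = config$gamma, delta = config$delta, dt = config$dt,
      r_min = config$r_min, k_clash = config$k_clash
    )$coords
  }
  structure(
    list(contacts = contacts, segments = segments, chain = chain,
         model = model, seeds = seeds, config = config),
    class = "filter_result"
  )
}

#' @export
print.filter_result <- function(x, ...) {
  cat("filter_result:", nrow(x$contacts), "input contacts,",
      sum(x$contacts$kept), "kept (consensus >",
      x$config$consensus_on_fraction, "over", x$config$n_repeats, "runs)\n")
  invisible(x)
}
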