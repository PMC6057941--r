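# Shared fixtures and independent oracles used across the suite.

# Independent pure-R internal-to-Cartesian oracle: direct trigonometric
# construction with the same ideal geometry constants, written against the
# textbook reference-frame formula rather than the compiled engine.
oracle_nerf <- function(A, B, C, r, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  bc <- (C - B) / sqrt(sum((C - B)^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + (-r * cos(th)) * bc + (r * sin(th) * cos(ph)) * m +
    (r * sin(th) * sin(ph)) * n
}

oracle_build_ca <- function(phi, psi, omega) {
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7
  n <- length(phi)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_n_ca, 0, 0)
  a <- a_n_ca_c * pi / 180
  C[1, ] <- c(CA[1, 1] - b_ca_c * cos(a), b_ca_c * sin(a), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- oracle_nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          b_c_n, a_ca_c_n, psi[i - 1])
    CA[i, ] <- oracle_nerf(CA[i - 1, ], C[i - 1, ], N[i, ],
                           b_n_ca, a_c_n_ca, omega[i - 1])
    C[i, ] <- oracle_nerf(C[i - 1, ], N[i, ], CA[i, ],
                          b_ca_c, a_n_ca_c, phi[i])
  }
  list(N = N, CA = CA, C = C)
}

# hand-made chain_coordinates object for direct energy tests
make_coords <- function(N, CA, C, CB, aa) {
  structure(
    list(N = N, CA = CA, C = C, CB = CB, is_gly = aa == "G", aa = aa),
    class = "chain_coordinates"
  )
}

pairwise_ref_distance <- function(fold, i, j) {
  sqrt(sum((fold$reference$cb[i, ] - fold$reference$cb[j, ])^2))
}

# a small fast protocol configuration for end-to-end tests
fast_config <- function(...) {
  args <- utils::modifyList(list(n_steps = 120, moves_factor = 8,
                                 n_repeats = 8), list(...))
  do.call(protocol_config, args)
}
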