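# Shared helpers: small random fixtures built in code.

# neutral random charge set on random coordinates (Angstrom)
random_charge_set <- function(n = 8, seed = 1, spread = 2,
                              id = "random") {
  set.seed(seed)
  q <- stats::rnorm(n, sd = 0.1)
  q <- q - mean(q)                      # exactly neutral
  coords <- matrix(stats::rnorm(3 * n, sd = spread), n, 3)
  transition_charge_set(id, "S1", rep("C", n), coords, q)
}

random_positioned <- function(n = 8, seed = 1, shift = c(0, 0, 0),
                              spread = 2) {
  cs <- random_charge_set(n, seed, spread)
  position_charges(cs, sweep(cs$coords, 2, shift, "+"))
}

# random proper rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_out)
  Q %*% diag(c(1, 1, det(Q)))
}

# photophysics used across tests: tau_D 5 ns, R0 25 A, n^2 = 2
test_photophysics <- function() {
  photophysics(tau_d_ns = 5, r0_ang = 25, n_refr = sqrt(2),
               mu_d_mag = 1.2, mu_a_mag = 0.8)
}

# coupling magnitude giving k * tau_D = 1 under test_photophysics()
coupling_for_unit_ktau <- function(p = test_photophysics()) {
  sqrt(1 / trespfret:::rate_prefactor(p))
}
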