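# Polarizable environment: selection, fields, induced dipoles, screening.

test_that("environment selection honors the cutoff boundary and exclusions", {
  # donor atom at origin, acceptor at (0,0,20); candidates along +x
  coords <- rbind(c(0, 0, 0), c(0, 0, 20),
                  c(14.9, 0, 0), c(15.1, 0, 0), c(15, 0, 0))
  fr <- geometry_frame(c("C", "C", "O", "O", "O"), coords)
  sites <- select_environment(fr, 1, 2, cutoff = 15)
  expect_equal(sites$source_atom_id, c("3", "5"))  # closed interval at 15
  # empty candidate set
  fr2 <- geometry_frame(c("C", "C"), coords[1:2, ])
  expect_equal(nrow(select_environment(fr2, 1, 2)$coords), 0L)
  # unknown atom type is an error naming the type
  fr3 <- geometry_frame(c("C", "C", "Xx"), coords[1:3, ])
  expect_error(select_environment(fr3, 1, 2), "Xx")
})

test_that("selection equals a brute-force distance filter on a random shell", {
  set.seed(31)
  n <- 100
  env <- matrix(stats::rnorm(3 * n, sd = 12), n, 3)
  chrom <- rbind(c(0, 0, 0), c(0, 0, 8))
  fr <- geometry_frame(rep("O", n + 2), rbind(chrom, env))
  sel <- select_environment(fr, 1, 2, cutoff = 10)
  # oracle: all-pairs distances, any-atom criterion
  keep <- which(apply(env, 1, function(r) {
    min(sqrt(sum((r - chrom[1, ])^2)), sqrt(sum((r - chrom[2, ])^2))) <= 10
  }))
  expect_equal(as.integer(sel$source_atom_id), keep + 2L)
})

test_that("fields match the unit Coulomb case and a direct summation", {
  b2a <- 1 / 1.889726124626
  src <- positioned_charges(matrix(0, 1, 3), 1)
  E <- field_at_sites(src, matrix(c(b2a, 0, 0), 1, 3))
  expect_equal(as.numeric(E), c(1, 0, 0), tolerance = 1e-12)

  expect_equal(field_at_sites(positioned_charges(matrix(0, 1, 3), 0),
                              matrix(c(5, 0, 0), 1, 3)),
               matrix(0, 1, 3), tolerance = 1e-15)

  # 4 charges, 3 sites: independent direct sum
  pc <- random_positioned(4, seed = 9)
  sites <- matrix(c(6, 0, 0, 0, 7, 0, 0, 0, 8), 3, 3, byrow = TRUE)
  E2 <- field_at_sites(pc, sites)
  for (l in 1:3) {
    acc <- c(0, 0, 0)
    for (j in 1:4) {
      rv <- (sites[l, ] - pc$coords[j, ]) * 1.889726124626
      acc <- acc + pc$charges[j] * rv / sum(rv^2)^1.5
    }
    expect_equal(E2[l, ], unname(acc), tolerance = 1e-13)
  }
  expect_error(field_at_sites(pc, pc$coords[1, , drop = FALSE]), "clash")
})

test_that("induced-dipole solver: closed forms, zero alpha, direct/iterative", {
  # single site, alpha = 2, field along z: mu = alpha E, no mutual term
  s1 <- polarizable_sites(matrix(0, 1, 3), 2)
  sol <- solve_induced_dipoles(s1, matrix(c(0, 0, 1), 1, 3))
  expect_equal(as.numeric(sol$dipoles), c(0, 0, 2), tolerance = 1e-14)

  # all alpha = 0 -> zero dipoles, no system solved
  s0 <- polarizable_sites(matrix(stats::rnorm(9), 3, 3), 0)
  sol0 <- solve_induced_dipoles(s0, matrix(1, 3, 3))
  expect_equal(sol0$dipoles, matrix(0, 3, 3))

  # direct vs iterative on random fixtures
  for (seed in 1:3) {
    set.seed(seed)
    n <- 50
    coords <- matrix(stats::rnorm(3 * n, sd = 10), n, 3)
    # enforce pair separation so the fixed point is well-conditioned
    d <- as.matrix(stats::dist(coords)); diag(d) <- Inf
    coords <- coords[apply(d, 1, min) > 1.5, , drop = FALSE]
    n <- nrow(coords)
    sites <- polarizable_sites(coords, stats::runif(n, 1, 3))
    E <- matrix(stats::rnorm(3 * n), n, 3)
    dir <- solve_induced_dipoles(sites, E, method = "direct")
    it <- solve_induced_dipoles(sites, E, method = "iterative", tol = 1e-14,
                                max_iter = 2000)
    scale <- max(abs(dir$dipoles))
    expect_lt(max(abs(it$dipoles - dir$dipoles)) / scale, 1e-10)
    expect_lte(it$residual_norm, 1e-12)
  }
  # non-convergence is reported, not silently returned (two coupled sites
  # cannot reach an impossible tolerance in two sweeps)
  pair <- polarizable_sites(rbind(c(0, 0, 0), c(0, 0, 2)), 2)
  expect_error(
    solve_induced_dipoles(pair, matrix(1, 2, 3), method = "iterative",
                          tol = 1e-30, max_iter = 2),
    "did not converge")
})

test_that("environment term matches the single-site closed form exactly", {
  fx <- make_dipole_pair(1, 1, 30, "collinear")
  site <- polarizable_sites(matrix(c(5, 0, 15), 1, 3), 4)
  Ea <- field_at_sites(fx$acceptor, site$coords)
  Ed <- field_at_sites(fx$donor, site$coords)
  sol <- solve_induced_dipoles(site, Ea)
  v_env <- env_coupling(fx$donor, site, sol)
  expect_equal(v_env, -4 * sum(Ed * Ea), tolerance = 1e-10)
  # no sites: V_env = 0, V_total = V_coul, s = 1
  empty <- polarizable_sites(numeric(0), numeric(0))
  expect_equal(env_coupling(fx$donor, empty, matrix(numeric(0), 0, 3)), 0)
  v_c <- coulomb_coupling(fx$donor, fx$acceptor)
  expect_equal(screening_factor(v_c, 0), 1)
})

test_that("V_env is reciprocal under donor/acceptor exchange", {
  for (seed in 1:10) {
    set.seed(seed)
    d <- random_positioned(5, seed = seed)
    a <- random_positioned(6, seed = seed + 50, shift = c(0, 0, 18))
    sites <- make_polarizable_shell(20, 12, alpha = 2, center = c(0, 0, 9),
                                    seed = seed + 200)
    Ea <- field_at_sites(a, sites$coords)
    Ed <- field_at_sites(d, sites$coords)
    v1 <- env_coupling(d, sites, solve_induced_dipoles(sites, Ea))
    v2 <- env_coupling(a, sites, solve_induced_dipoles(sites, Ed))
    expect_equal(v2, v1, tolerance = 1e-8)
  }
})

test_that("V_env vanishes with alpha and is invariant under global rigid motion", {
  fx <- make_dipole_pair(1, 1, 25, "collinear")
  sites <- make_polarizable_shell(30, 10, alpha = 0, center = c(0, 0, 12.5),
                                  seed = 5)
  Ea <- field_at_sites(fx$acceptor, sites$coords)
  v0 <- env_coupling(fx$donor, sites, solve_induced_dipoles(sites, Ea))
  expect_equal(v0, 0)

  sites$alpha[] <- 2
  v1 <- env_coupling(fx$donor, sites, solve_induced_dipoles(
    sites, field_at_sites(fx$acceptor, sites$coords)))
  R <- random_rotation(17); shift <- c(4, -2, 9)
  move <- function(m) sweep(m %*% t(R), 2, shift, "+")
  d2 <- positioned_charges(move(fx$donor$coords), fx$donor$charges)
  a2 <- positioned_charges(move(fx$acceptor$coords), fx$acceptor$charges)
  s2 <- polarizable_sites(move(sites$coords), sites$alpha)
  v2 <- env_coupling(d2, s2, solve_induced_dipoles(
    s2, field_at_sites(a2, s2$coords)))
  expect_equal(v2, v1, tolerance = 1e-10)
})

test_that("screening factor: identity, Forster value, and near-zero flagging", {
  expect_equal(screening_factor(1e-5, 0), 1)
  expect_equal(screening_factor(1e-5, -0.5e-5), 0.5)  # 1/n^2 at n^2 = 2
  expect_true(is.na(screening_factor(1e-10, 1e-6)))
})

test_that("screening profile brackets an attenuating fixture", {
  # sites near the inter-chromophore axis attenuate the coupling of two
  # parallel transition dipoles: s below 1 but above the Forster 1/n^2
  p_records <- do.call(rbind, lapply(seq(20, 40, by = 5), function(r) {
    fx <- make_dipole_pair(1, 1, r, "parallel")
    sites <- polarizable_sites(rbind(c(0.5, 0, r / 2),
                                     c(-0.5, 0.3, r / 2 + 1),
                                     c(0, -0.4, r / 2 - 1)), alpha = 6)
    coupling_record(fx$donor, fx$acceptor, sites = sites, frame_time = r)
  }))
  prof <- screening_profile(p_records, bin_width = 5)
  expect_equal(attr(prof, "forster_s"), 0.5)
  # attenuating environment: s below 1 but above the Forster limit here
  expect_true(all(prof$mean < 1))
  expect_true(all(prof$mean > 0.5))
  # all-empty environment puts every bin mean at exactly 1
  e_records <- do.call(rbind, lapply(c(20, 30), function(r) {
    fx <- make_dipole_pair(1, 1, r, "collinear")
    coupling_record(fx$donor, fx$acceptor, frame_time = r)
  }))
  expect_equal(screening_profile(e_records)$mean, c(1, 1))
})
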