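test_that("shell_config partitions the orbital space and counts electrons", {
  cfg <- shell_config("++-", n_closed = 2, n_basis = 8, n_electrons = 7)
  expect_identical(cfg$spaces$closed, 1:2)
  expect_identical(cfg$spaces$shell1, 3:4)
  expect_identical(cfg$spaces$shell2, 5L)
  expect_identical(cfg$spaces$virtual, 6:8)
  expect_error(shell_config("++-", 2, 8, 9), "electron-count mismatch")
  expect_error(shell_config("++-", 3, 4), "basis")
})

test_that("hand-computable two-electron CSF energies come out exactly", {
  h <- matrix(c(-1.0, 0.2, 0.2, -0.6), 2)
  g <- array(0, c(2, 2, 2, 2))
  g[1, 1, 1, 1] <- 0.7; g[2, 2, 2, 2] <- 0.6
  g[1, 1, 2, 2] <- g[2, 2, 1, 1] <- 0.3                     # J12
  g[1, 2, 1, 2] <- g[2, 1, 2, 1] <- g[1, 2, 2, 1] <- g[2, 1, 1, 2] <- 0.1  # K12
  ints <- model_hamiltonian(h = h, eri = g, n_electrons = 2)
  Cid <- diag(2)
  # triplet "++": E = h11 + h22 + J12 - K12
  et <- total_energy(ints, Cid, shell_config("++", 0, 2, 2),
                     vector_coupling_coefficients("++"))
  expect_equal(et, h[1, 1] + h[2, 2] + 0.3 - 0.1, tolerance = 1e-13)
  # open-shell singlet "+-": E = h11 + h22 + J12 + K12
  es <- total_energy(ints, Cid, shell_config("+-", 0, 2, 2),
                     vector_coupling_coefficients("+-"))
  expect_equal(es, h[1, 1] + h[2, 2] + 0.3 + 0.1, tolerance = 1e-13)
  # closed shell in orbital 1: E = 2 h11 + J11
  ec <- total_energy(ints, Cid, shell_config(NULL, 1, 2, 2))
  expect_equal(ec, 2 * h[1, 1] + 0.7, tolerance = 1e-13)
})

test_that("the energy functional equals the determinant-expansion oracle", {
  set.seed(21)
  for (pat in c("+-", "++-", "+-+", "++--", "+-+-")) {
    pp <- parse_pattern(pat)
    n <- pp$n + 2L
    ints <- random_integral_set(n, seed = 100 + pp$n, scale_eri = 0.5)
    ints$n_electrons <- pp$n
    cfg <- shell_config(pp, 0, n, pp$n)
    C <- random_orthogonal(n)
    e1 <- total_energy(ints, C, cfg, vector_coupling_coefficients(pp))
    e2 <- csf_energy_oracle(ints, C, cfg)
    expect_equal(e1, e2, tolerance = 1e-12, label = sprintf("energy(%s)", pat))
  }
  # and with a closed shell underneath
  ints <- random_integral_set(5, seed = 77, scale_eri = 0.5)
  ints$n_electrons <- 5L
  cfg <- shell_config("++-", 1, 5, 5)
  C <- random_orthogonal(5)
  expect_equal(total_energy(ints, C, cfg, vector_coupling_coefficients("++-")),
               csf_energy_oracle(ints, C, cfg), tolerance = 1e-12)
})

test_that("closed-shell SCF reproduces an independent RHF oracle", {
  h2 <- fixture_system("h2")
  st <- scf_solve(h2, n_closed = 1)
  expect_true(st$converged)
  ref <- rhf_oracle(h2, 1)
  expect_equal(st$energy, ref$energy, tolerance = 1e-9)
  # and the known minimal-basis value for this bond length
  expect_equal(st$energy, -1.116714325063, tolerance = 1e-6)
  hub <- model_hamiltonian(4, t = 1, U = 2)
  st2 <- scf_solve(hub, n_closed = 2)
  expect_true(st2$converged)
  expect_equal(st2$energy, rhf_oracle(hub, 2)$energy, tolerance = 1e-9)
})

test_that("a one-electron system relaxes to the lowest generalized eigenvalue", {
  g <- geometry("H", matrix(0, 1, 3))
  ints <- sgto_integrals(g)
  st <- scf_solve(ints, "+")
  ev <- eigen(solve(ints$overlap, ints$h_core), only.values = TRUE)$values
  expect_equal(st$energy, min(Re(ev)), tolerance = 1e-10)
})

test_that("analytic and numerical rotation gradients agree off-stationarity", {
  ints <- random_integral_set(4, seed = 31, scale_eri = 0.4)
  ints$n_electrons <- 3L
  cfg <- shell_config("++-", 0, 4, 3)
  vct <- vector_coupling_coefficients("++-")
  set.seed(8)
  C <- random_orthogonal(4)
  dens <- build_densities(C, cfg, vct)
  focks <- build_shell_fock(ints, dens)
  occw <- dens$ext$occupations
  # analytic gradient dE/dtheta_pq = 2 (F~P - F~Q)_pq in the MO basis
  Fsc <- lapply(seq_along(focks), function(I)
    occw[I] * (t(C) %*% focks[[I]] %*% C))
  sid <- c(1L, 1L, 2L, 3L)  # shell1, shell1, shell2, virtual
  for (pq in list(c(1, 3), c(2, 3), c(1, 4), c(3, 4))) {
    p <- pq[1]; q <- pq[2]
    fp <- if (sid[p] == 3L) 0 else Fsc[[sid[p]]][p, q]
    fq <- if (sid[q] == 3L) 0 else Fsc[[sid[q]]][p, q]
    expect_equal(2 * (fp - fq),
                 numerical_rotation_gradient(ints, C, cfg, p, q, vct),
                 tolerance = 1e-6)
  }
})

test_that("open-shell chain states converge to stationary points", {
  h3 <- fixture_system("h3")
  st3 <- scf_solve(h3, "+++", options = list(g_tol = 1e-8))
  expect_true(st3$converged)
  expect_lt(max_numerical_gradient(st3, h3), 1e-6)
  h6 <- fixture_system("h6")
  st6 <- scf_solve(h6, "++", n_closed = 2, options = list(g_tol = 1e-8))
  expect_true(st6$converged)
  expect_lt(max_numerical_gradient(st6, h6), 1e-6)
  # SCF energy is variational against its own functional under a random kick
  set.seed(4)
  Ck <- st3$C %*% random_orthogonal(3)
  expect_gte(total_energy(h3, Ck, st3$config, st3$vct), st3$energy - 1e-12)
})

test_that("the Newton fallback converges where the fixed point cycles", {
  h4 <- fixture_system("h4")
  X <- lowdin_orbitals(h4)
  fixed <- scf_solve(h4, "++--", C0 = X, somo_orbitals = c(1, 3, 2, 4),
                     options = list(optimizer = "fock"))
  expect_false(fixed$converged)
  st <- scf_solve(h4, "++--", C0 = X, somo_orbitals = c(1, 3, 2, 4),
                  options = list(g_tol = 1e-7))
  expect_true(st$converged)
  expect_lt(st$gradient_norm, 1e-7)
  direct <- scf_solve(h4, "++--", C0 = st$C,
                      options = list(optimizer = "direct", g_tol = 1e-7))
  expect_true(direct$converged)
  expect_equal(direct$energy, st$energy, tolerance = 1e-9)
})

test_that("the energy is invariant under within-shell rotations", {
  h4 <- fixture_system("h4")
  X <- lowdin_orbitals(h4)
  st <- scf_solve(h4, "++--", C0 = X, somo_orbitals = c(1, 3, 2, 4),
                  options = list(g_tol = 1e-7))
  e0 <- total_energy(h4, st$C, st$config, st$vct)
  for (theta in c(0.17, 0.5, 1.1)) {
    expect_lt(abs(rotate_pair_energy(h4, st, 1, 2, theta) - e0), 1e-12)
    expect_lt(abs(rotate_pair_energy(h4, st, 3, 4, theta) - e0), 1e-12)
  }
})

test_that("block recanonicalization preserves the energy and block spans", {
  h6 <- fixture_system("h6")
  st <- scf_solve(h6, "++", n_closed = 2, options = list(g_tol = 1e-8))
  blocks <- list(1:2, 3:4, 5:6)
  C2 <- block_recanonicalize(st$C, st$shell_fock[[1]], blocks)
  expect_equal(total_energy(h6, C2, st$config, st$vct), st$energy,
               tolerance = 1e-10)
  F_mo <- t(C2) %*% st$shell_fock[[1]] %*% C2
  for (b in blocks) {
    sub <- F_mo[b, b]
    expect_lt(max(abs(sub - diag(diag(sub)))), 1e-9)
  }
})

test_that("solver input validation catches bad starting points", {
  h2 <- fixture_system("h2")
  expect_error(scf_solve(h2, "+-", C0 = 2 * diag(2)), "not orthonormal")
  expect_error(scf_solve(h2, "+-", somo_orbitals = 1L),
               "one orbital per SOMO slot")
  expect_error(scf_solve(h2, "+", n_closed = 1), "electron-count mismatch")
})
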