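test_that("two-site Hubbard CI reproduces the closed-form spectrum", {
  t <- 1; U <- 4
  hub <- model_hamiltonian(2, t = t, U = U)
  ci <- ci_solve(hub, 2, 1:2, M = 0)
  # singlet ground state of the 2-site Hubbard dimer
  expect_equal(ci$eigenvalues[1], U / 2 - sqrt((U / 2)^2 + 4 * t^2),
               tolerance = 1e-12)
  expect_equal(sort(ci$eigenvalues),
               sort(c(U / 2 - sqrt((U / 2)^2 + 4 * t^2), 0, U,
                      U / 2 + sqrt((U / 2)^2 + 4 * t^2))),
               tolerance = 1e-12)
  expect_equal(ci$spin_squared[1], 0, tolerance = 1e-10)
  # triplet sector
  ci_t <- ci_solve(hub, 2, 1:2, M = 1)
  expect_equal(ci_t$eigenvalues[1], 0, tolerance = 1e-12)
  expect_equal(ci_t$spin_squared[1], 2, tolerance = 1e-10)
})

test_that("a one-electron CI returns the one-electron spectrum", {
  ri <- random_integral_set(4, seed = 13)
  ci <- ci_solve(ri, 1, 1:4, M = 0.5)
  expect_equal(ci$eigenvalues, sort(eigen(ri$h_core)$values),
               tolerance = 1e-12)
})

test_that("full CI energies are invariant under orbital rotations", {
  ri <- random_integral_set(4, seed = 2, scale_eri = 0.3)
  set.seed(19)
  mo <- ao_to_mo(ri, random_orthogonal(4))
  for (spec in list(c(2, 0), c(2, 2), c(3, 1), c(4, 0), c(5, 1), c(6, 0))) {
    a <- ci_solve(ri, spec[1], 1:4, M = spec[2] / 2)$eigenvalues
    b <- ci_solve(mo, spec[1], 1:4, M = spec[2] / 2)$eigenvalues
    expect_equal(a, b, tolerance = 1e-10,
                 label = sprintf("spectrum(nel=%d, M=%g)", spec[1], spec[2] / 2))
  }
})

test_that("the CI Hamiltonian matches an operator-algebra construction", {
  # independent check of the Slater-Condon rules: apply
  # H = sum h_pq E_pq + 1/2 sum (pq|rs) (E_pq E_rs - delta_qr E_ps)
  # through the substitution operators and compare matrix elements
  ri <- random_integral_set(3, seed = 23, scale_eri = 0.5)
  h <- ri$h_core; eri <- ri$eri
  dets <- list()
  astr <- combn(3, 2)
  for (i in 1:ncol(astr)) for (b in 1:3)
    dets[[length(dets) + 1L]] <- list(alpha = astr[, i], beta = b)
  keys <- vapply(dets, csfrohf:::det_key, character(1))
  H_op <- matrix(0, length(dets), length(dets))
  for (j in seq_along(dets)) {
    col <- setNames(numeric(length(keys)), keys)
    add <- function(dl, cf, w) {
      for (i in seq_along(dl)) {
        m <- match(csfrohf:::det_key(dl[[i]]), keys)
        if (!is.na(m)) col[m] <<- col[m] + w * cf[i]
      }
    }
    for (p in 1:3) for (q in 1:3) {
      r1 <- csfrohf:::apply_E(list(dets[[j]]), 1, p, q)
      if (length(r1$dets) == 0) next
      add(r1$dets, r1$coef, h[p, q])
      for (r in 1:3) for (s in 1:3) {
        r2 <- csfrohf:::apply_E(r1$dets, r1$coef, r, s)
        add(r2$dets, r2$coef, 0.5 * eri[p, q, r, s])
      }
    }
    for (p in 1:3) for (q in 1:3) for (s in 1:3) {
      r1 <- csfrohf:::apply_E(list(dets[[j]]), 1, p, s)
      add(r1$dets, r1$coef, -0.5 * eri[p, q, q, s])
    }
    H_op[, j] <- col
  }
  H_sc <- matrix(0, length(dets), length(dets))
  for (i in seq_along(dets)) for (j in seq_along(dets))
    H_sc[i, j] <- slater_condon(dets[[i]], dets[[j]], h, eri)
  expect_equal(H_sc, H_op, tolerance = 1e-11)
  expect_equal(H_sc, t(H_sc), tolerance = 1e-12)
})

test_that("frozen-core folding equals an explicit fold of the integrals", {
  h4 <- fixture_system("h4")
  X <- lowdin_orbitals(h4)
  mo <- ao_to_mo(h4, X)
  ci_frozen <- ci_solve(mo, 2, 2:4, M = 0, frozen_orbitals = 1L)
  # fold orbital 1 by hand: h_eff = h + 2 J_c - K_c over a unit density
  Dc <- matrix(0, 4, 4); Dc[1, 1] <- 1
  Jc <- csfrohf:::coulomb_matrix(mo$eri, Dc)
  Kc <- csfrohf:::exchange_matrix(mo$eri, Dc)
  folded <- integral_set(mo$h_core + 2 * Jc - Kc, mo$eri,
                         e_nuclear = mo$e_nuclear + 2 * mo$h_core[1, 1] +
                           sum((2 * Jc - Kc) * Dc))
  ci_manual <- ci_solve(folded, 2, 2:4, M = 0)
  expect_equal(ci_frozen$eigenvalues, ci_manual$eigenvalues, tolerance = 1e-11)
})

test_that("CI roots are spin eigenstates", {
  h3 <- fixture_system("h3")
  ci <- ci_solve(ao_to_mo(h3, lowdin_orbitals(h3)), 3, 1:3, M = 0.5)
  allowed <- c(0.5 * 1.5, 1.5 * 2.5)  # doublet, quartet
  for (s2 in ci$spin_squared)
    expect_lt(min(abs(s2 - allowed)), 1e-8)
})

test_that("CSF weights decompose CI roots completely", {
  h2 <- fixture_system("h2_stretched")
  ci <- ci_solve(ao_to_mo(h2, lowdin_orbitals(h2)), 2, 1:2, M = 0)
  wt <- csf_weight_table(ci, 1)
  expect_equal(sum(wt$weight), 1, tolerance = 1e-10)
  expect_true(all(diff(wt$weight) <= 1e-14))
  # at 6 bohr the ground state is dominated by the open-shell singlet of
  # the two (localized-equivalent) site orbitals
  top <- wt[1, ]
  expect_identical(top$occupation, "11")
  expect_identical(top$pattern, "+-")
  expect_gt(top$weight, 0.5)
  # weights are squared projections onto normalized CSFs
  expect_true(all(wt$weight >= -1e-14 & wt$weight <= 1 + 1e-14))
})

test_that("CI input validation rejects inconsistent requests", {
  ri <- random_integral_set(3, seed = 1)
  expect_error(ci_solve(ri, 2, 1:3, M = 0.5), "incompatible")
  expect_error(ci_solve(ri, 2, 1:2, frozen_orbitals = 2L), "disjoint")
  expect_error(ci_solve(ri, 5, 1:2, M = 0.5), "one spin channel")
  expect_error(ci_solve(random_integral_set(2), 14, 1:13), "limit 12")
})
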