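test_that("determinant expansions reproduce hand-derived CG coefficients", {
  # singlet pair: (ab - ba)/sqrt(2)
  e <- determinant_expansion("+-", M = 0)
  e <- e[order(e$string), ]
  expect_identical(e$string, c("ab", "ba"))
  expect_equal(e$coeff, c(1, -1) / sqrt(2))

  # doublet from a triplet parent: sqrt(2/3)|aab> - sqrt(1/6)(|aba> + |baa>)
  e2 <- determinant_expansion("++-")
  e2 <- e2[order(e2$string), ]
  expect_identical(e2$string, c("aab", "aba", "baa"))
  expect_equal(e2$coeff, c(sqrt(2 / 3), -sqrt(1 / 6), -sqrt(1 / 6)))

  # doublet from a singlet parent: (|aba> - |baa>)/sqrt(2)
  e3 <- determinant_expansion("+-+")
  e3 <- e3[order(e3$string), ]
  expect_identical(e3$string, c("aba", "baa"))
  expect_equal(e3$coeff, c(1, -1) / sqrt(2))

  # high-spin stretched state is a single determinant
  e4 <- determinant_expansion("+++")
  expect_identical(e4$string, "aaa")
  expect_equal(e4$coeff, 1)
})

test_that("expansions are normalized and orthonormal within an M sector", {
  for (n in 2:5) {
    pats <- all_patterns(n)
    for (m2 in seq(n %% 2, n, by = 2)) {
      vecs <- list()
      for (p in pats) {
        pp <- parse_pattern(p)
        if (pp$s2[n] < m2) next
        e <- determinant_expansion(pp, M = m2 / 2)
        v <- setNames(e$coeff, e$string)
        vecs[[p]] <- v
      }
      strs <- unique(unlist(lapply(vecs, names)))
      mat <- sapply(vecs, function(v) { w <- setNames(numeric(length(strs)), strs); w[names(v)] <- v; w })
      mat <- matrix(mat, nrow = length(strs))
      G <- t(mat) %*% mat
      expect_equal(G, diag(ncol(mat)), tolerance = 1e-12)
    }
  }
})

test_that("coupling matrix elements take the derived closed-form values", {
  expect_equal(coupling_matrix_element("+-", 1, 2), 2, tolerance = 1e-12)
  expect_equal(coupling_matrix_element("++", 1, 2), 0, tolerance = 1e-12)
  expect_equal(coupling_matrix_element("++-", 1, 3), 1.5, tolerance = 1e-12)
  expect_equal(coupling_matrix_element("++-", 2, 3), 1.5, tolerance = 1e-12)
  expect_equal(coupling_matrix_element("++-", 1, 2), 0, tolerance = 1e-12)
  expect_equal(coupling_matrix_element("+-+", 1, 2), 2, tolerance = 1e-12)
  expect_equal(coupling_matrix_element("+-+", 1, 3), 0.5, tolerance = 1e-12)
  expect_equal(coupling_matrix_element("+-+", 2, 3), 0.5, tolerance = 1e-12)
  # symmetry in the slot pair and slot validation
  expect_equal(coupling_matrix_element("++-", 3, 1),
               coupling_matrix_element("++-", 1, 3), tolerance = 1e-14)
  expect_error(coupling_matrix_element("++-", 2, 2), "distinct")
  expect_error(coupling_matrix_element("++-", 1, 4), "slot")
})

test_that("elements are constant over slot pairs within a shell pair", {
  for (pat in c("++-", "+++--", "++--+", "+-+++")) {
    part <- shell_partition(pat)
    for (I in seq_len(part$n_shells - 1)) for (J in (I + 1):part$n_shells) {
      vals <- c()
      for (t in part$slots[[I]]) for (u in part$slots[[J]])
        vals <- c(vals, coupling_matrix_element(pat, t, u))
      expect_lt(max(vals) - min(vals), 1e-12)
    }
    # within-shell pairs couple at high spin: element 0
    for (I in seq_len(part$n_shells)) {
      sl <- part$slots[[I]]
      if (length(sl) > 1)
        expect_equal(coupling_matrix_element(pat, sl[1], sl[2]), 0,
                     tolerance = 1e-12)
    }
  }
})

test_that("elements are independent of the spin projection M", {
  for (pat in c("++-", "++--", "+-+-+")) {
    pp <- parse_pattern(pat)
    ref <- csfrohf:::coupling_element_bruteforce(pp, 1, pp$n, M = pp$total_spin)
    for (m2 in seq(-pp$s2[pp$n], pp$s2[pp$n], by = 2))
      expect_equal(csfrohf:::coupling_element_bruteforce(pp, 1, pp$n, M = m2 / 2),
                   ref, tolerance = 1e-12)
  }
})

test_that("coupled-basis evaluation matches the determinant oracle (N <= 5)", {
  for (n in 2:5) for (pat in all_patterns(n)) {
    for (t in seq_len(n - 1)) for (u in (t + 1):n) {
      expect_equal(coupling_matrix_element(pat, t, u),
                   csfrohf:::coupling_element_bruteforce(pat, t, u),
                   tolerance = 1e-12,
                   label = sprintf("element(%s; %d,%d)", pat, t, u))
    }
  }
})

test_that("spin correlation and the b coefficient obey their exact relations", {
  for (pat in c("+-", "++-", "++--", "+-+-+")) {
    pp <- parse_pattern(pat)
    part <- shell_partition(pp)
    v <- vector_coupling_coefficients(pp)
    for (I in seq_len(part$n_shells - 1)) for (J in (I + 1):part$n_shells) {
      t <- part$slots[[I]][1]; u <- part$slots[[J]][1]
      elem <- coupling_matrix_element(pp, t, u)
      # b^IJ = 2 - 2 <E E> and b^IJ = 1 + 4 <S_t . S_u>
      expect_equal(v$b[I, J], 2 - 2 * elem, tolerance = 1e-13)
      expect_equal(v$b[I, J], 1 + 4 * spin_correlation(pp, t, u),
                   tolerance = 1e-12)
    }
    expect_true(all(diag(v$b) == 2))
    expect_true(all(v$a == 1))
  }
})

test_that("high-spin patterns give Roothaan coefficients", {
  v <- vector_coupling_coefficients("+++++")
  expect_identical(v$n_shells, 1L)
  expect_equal(as.vector(v$b), 2)
  expect_equal(as.vector(v$a), 1)
  # a stretched pair in any high-spin pattern couples with b = 2 - 0 = 2
  expect_equal(2 - 2 * coupling_matrix_element("++++", 1, 4), 2,
               tolerance = 1e-12)
})

test_that("the singlet-pair coupling table carries the textbook entries", {
  v <- vector_coupling_coefficients("+-")
  expect_equal(v$b, matrix(c(2, -2, -2, 2), 2), tolerance = 1e-13)
  tab <- coupling_table("+-")
  expect_identical(nrow(tab), 3L)
  off <- tab[tab$shell_I == 1 & tab$shell_J == 2, ]
  expect_equal(off$element, 2, tolerance = 1e-13)
  expect_equal(off$b, -2, tolerance = 1e-13)
  expect_equal(off$alpha, 1)
  expect_equal(off$beta, -1, tolerance = 1e-13)
})

test_that("csf construction validates its occupation", {
  x <- csf("++-", n_closed = 2)
  expect_identical(x$somo_orbitals, 3:5)
  expect_error(csf("++-", somo_orbitals = c(1, 2)), "one orbital per")
  expect_error(csf("++-", somo_orbitals = c(3, 3, 4)), "distinct")
  expect_error(csf("++-", somo_orbitals = c(1, 3, 4), n_closed = 2), "disjoint")
  expect_error(csf("++-", M = 1), "integer")
  expect_error(csf("++-", M = 1.5), "exceeds")
  expect_error(determinant_expansion("++", M = 2), "exceeds")
})
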