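# Mapping a CSF onto concrete Slater determinants over orbital indices:
# used by the energy oracle, the brute-force coupling-element oracle, and
# CSF-weight analysis of CI vectors.

# Determinant-space vector of a CSF: list(dets, coef). Spin strings of the
# genealogical expansion are attached to `somo_orbitals`; `closed_orbitals`
# are doubly occupied. Phase convention: creation in ascending orbital order,
# alpha before beta within an orbital (then re-phased to canonical order).
csf_det_vector <- function(pattern, somo_orbitals, closed_orbitals = integer(0),
                           M = NULL) {
  pattern <- as_spin_pattern(pattern)
  exp <- determinant_expansion(pattern, M = M)
  dets <- vector("list", nrow(exp))
  coef <- numeric(nrow(exp))
  for (i in seq_len(nrow(exp))) {
    sig <- strsplit(exp$string[i], "")[[1]]
    somo_spin <- ifelse(sig == "a", 1L, -1L)
    orbs <- c(rep(closed_orbitals, each = 2L), somo_orbitals)
    spins <- c(rep(c(1L, -1L), length(closed_orbitals)), somo_spin)
    ord <- order(orbs, -spins)  # ascending orbital, alpha before beta
    cd <- canonical_det(orbs[ord], spins[ord])
    dets[[i]] <- list(alpha = cd$alpha, beta = cd$beta)
    coef[i] <- cd$phase * exp$coeff[i]
  }
  list(dets = dets, coef = coef)
}

# Brute-force <Phi| E^t_u E^u_t |Phi> from the determinant expansion
# (independent oracle for coupling_matrix_element). Slots t, u are attached
# to distinct orbital indices 1..N.
coupling_element_bruteforce <- function(pattern, t, u, M = NULL) {
  pattern <- as_spin_pattern(pattern)
  v <- csf_det_vector(pattern, seq_len(pattern$n), M = M)
  w <- apply_E(v$dets, v$coef, u, t)            # E^u_t
  w <- apply_E(w$dets, w$coef, t, u)            # E^t_u
  dot_detvec(v$dets, v$coef, w$dets, w$coef)
}

# One- and two-particle reduced density matrices of a CSF over its N SOMO
# orbitals (no closed shell), from the determinant expansion:
#   gamma[p,q]      = <E^p_q>
#   Gamma[p,q,r,s]  = <E^p_q E^r_s> - delta_qr <E^p_s>
# so that E2 = (1/2) sum (pq|rs) Gamma[p,q,r,s] in chemists' notation.
csf_rdms <- function(pattern, M = NULL) {
  pattern <- as_spin_pattern(pattern)
  n <- pattern$n
  v <- csf_det_vector(pattern, seq_len(n), M = M)
  gam <- matrix(0, n, n)
  Gam <- array(0, c(n, n, n, n))
  Ev <- vector("list", n * n)  # E^r_s |Phi>
  idx <- function(r, s) (r - 1L) * n + s
  for (r in seq_len(n)) for (s in seq_len(n)) {
    Ev[[idx(r, s)]] <- apply_E(v$dets, v$coef, r, s)
    gam[r, s] <- dot_detvec(v$dets, v$coef, Ev[[idx(r, s)]]$dets,
                            Ev[[idx(r, s)]]$coef)
  }
  for (p in seq_len(n)) for (q in seq_len(n)) for (r in seq_len(n))
    for (s in seq_len(n)) {
      w <- Ev[[idx(r, s)]]
      pq_w <- apply_E(w$dets, w$coef, p, q)
      val <- dot_detvec(v$dets, v$coef, pq_w$dets, pq_w$coef)
      Gam[p, q, r, s] <- val - (if (q == r) gam[p, s] else 0)
    }
  list(gamma = gam, Gamma = Gam)
}
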