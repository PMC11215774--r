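# Slater-determinant algebra: canonical-ordering phases, Slater-Condon
# Hamiltonian elements, substitution-operator application, spin-squared.
# Determinants are lists with sorted integer vectors `alpha` and `beta` of
# occupied spatial orbitals; the canonical operator order is all alpha
# creators (ascending) followed by all beta creators (ascending).
#
# Cross-block signs: a beta-channel annihilator passes all alpha creators and
# a beta-channel creator does so too, so for number-conserving substitutions
# within one spin channel (and for the alpha<->beta moves of S-S+, which pick
# up the factor twice) the (-1)^{n_alpha} factors cancel; only within-block
# position phases remain.

det_key <- function(det) paste(paste(det$alpha, collapse = ","),
                               paste(det$beta, collapse = ","), sep = ";")

# Build a canonical determinant from a creation sequence given as parallel
# vectors of orbitals and spins (+1 alpha / -1 beta), applied left to right.
# Returns list(alpha, beta, phase) with the sign relating the sequence order
# to the canonical order, or NULL if an orbital-spin is repeated.
canonical_det <- function(orbs, spins) {
  keyrank <- ifelse(spins > 0, 0, 1) * 1e6 + orbs  # alphas first, then orbital
  if (anyDuplicated(keyrank)) return(NULL)
  perm <- order(keyrank)
  list(alpha = sort(orbs[spins > 0]), beta = sort(orbs[spins < 0]),
       phase = perm_parity(perm))
}

perm_parity <- function(perm) {
  n <- length(perm)
  visited <- logical(n); sgn <- 1L
  for (i in seq_len(n)) {
    if (visited[i]) next
    j <- i; len <- 0L
    while (!visited[j]) { visited[j] <- TRUE; j <- perm[j]; len <- len + 1L }
    if (len %% 2L == 0L) sgn <- -sgn
  }
  sgn
}

# annihilate / create orbital p in a sorted occupation vector (within-block
# phase only, see header note)
ann_orb <- function(occ, p) {
  i <- match(p, occ)
  if (is.na(i)) return(NULL)
  list(occ = occ[-i], phase = if ((i - 1L) %% 2L == 0L) 1L else -1L)
}

cre_orb <- function(occ, p) {
  if (p %in% occ) return(NULL)
  i <- sum(occ < p)
  list(occ = sort(c(occ, p)), phase = if (i %% 2L == 0L) 1L else -1L)
}

# Apply a+_{p sigma} a_{q sigma} to det; returns list(det, phase) or NULL.
apply_sub <- function(det, p, q, sigma) {
  if (sigma > 0) {
    a <- ann_orb(det$alpha, q); if (is.null(a)) return(NULL)
    cr <- cre_orb(a$occ, p);    if (is.null(cr)) return(NULL)
    list(det = list(alpha = cr$occ, beta = det$beta), phase = a$phase * cr$phase)
  } else {
    a <- ann_orb(det$beta, q); if (is.null(a)) return(NULL)
    cr <- cre_orb(a$occ, p);   if (is.null(cr)) return(NULL)
    list(det = list(alpha = det$alpha, beta = cr$occ), phase = a$phase * cr$phase)
  }
}

# Apply the spin-summed substitution E^p_q = sum_sigma a+_{p sigma} a_{q sigma}
# to a determinant vector (list of dets + coefficient vector).
apply_E <- function(dets, coef, p, q) {
  acc <- new.env(parent = emptyenv())
  res_dets <- list()
  for (i in seq_along(dets)) {
    for (sigma in c(1L, -1L)) {
      r <- apply_sub(dets[[i]], p, q, sigma)
      if (is.null(r)) next
      k <- det_key(r$det)
      if (is.null(acc[[k]])) { acc[[k]] <- 0; res_dets[[k]] <- r$det }
      acc[[k]] <- acc[[k]] + r$phase * coef[i]
    }
  }
  keys <- ls(acc)
  list(dets = unname(res_dets[keys]),
       coef = vapply(keys, function(k) acc[[k]], numeric(1), USE.NAMES = FALSE))
}

dot_detvec <- function(dets1, coef1, dets2, coef2) {
  k1 <- vapply(dets1, det_key, character(1))
  k2 <- vapply(dets2, det_key, character(1))
  m <- match(k1, k2)
  ok <- !is.na(m)
  sum(coef1[ok] * coef2[m[ok]])
}

# --- excitation analysis -----------------------------------------------------

single_phase <- function(occ1, occ2) {
  p <- setdiff(occ1, occ2)  # annihilated
  q <- setdiff(occ2, occ1)  # created
  a <- ann_orb(occ1, p)
  cr <- cre_orb(a$occ, q)
  list(p = p, q = q, phase = a$phase * cr$phase)
}

double_phase_same_spin <- function(occ1, occ2) {
  ps <- setdiff(occ1, occ2)
  qs <- setdiff(occ2, occ1)
  # annihilate p1 then p2 (so |D1> = a1 a2 p1+ p2+ |core>) and create q2
  # then q1 (so |D2> = c1 c2 q1+ q2+ |core>): both phases are then relative
  # to the same p_i <-> q_i pairing order
  a1 <- ann_orb(occ1, ps[1]); a2 <- ann_orb(a1$occ, ps[2])
  c1 <- cre_orb(a2$occ, qs[2]); c2 <- cre_orb(c1$occ, qs[1])
  list(p = ps, q = qs, phase = a1$phase * a2$phase * c1$phase * c2$phase)
}

#' Hamiltonian matrix element between two Slater determinants
#'
#' Slater-Condon rules in a spatial-orbital basis with chemists'-notation
#' two-electron integrals `(pq|rs)`.
#'
#' @param det1,det2 Determinants: lists with sorted integer vectors `alpha`
#'   and `beta` of occupied spatial orbitals.
#' @param h One-electron integral matrix.
#' @param eri Two-electron integral array, `eri[p,q,r,s] = (pq|rs)`.
#' @return The matrix element (no nuclear term).
#' @export
slater_condon <- function(det1, det2, h, eri) {
  if (length(det1$alpha) != length(det2$alpha) ||
      length(det1$beta) != length(det2$beta)) return(0)
  da <- length(setdiff(det1$alpha, det2$alpha))
  db <- length(setdiff(det1$beta, det2$beta))
  nex <- da + db
  if (nex > 2L) return(0)
  if (nex == 0L) {
    occ <- c(det1$alpha, det1$beta)
    spin <- c(rep(1L, length(det1$alpha)), rep(-1L, length(det1$beta)))
    e <- sum(diag(h)[occ])
    no <- length(occ)
    if (no > 1L) for (i in 1:(no - 1L)) for (j in (i + 1L):no) {
      p <- occ[i]; q <- occ[j]
      e <- e + eri[p, p, q, q]
      if (spin[i] == spin[j]) e <- e - eri[p, q, q, p]
    }
    return(e)
  }
  if (nex == 1L) {
    if (da == 1L) {
      s <- single_phase(det1$alpha, det2$alpha)
      same <- setdiff(det1$alpha, s$p); other <- det1$beta
    } else {
      s <- single_phase(det1$beta, det2$beta)
      same <- setdiff(det1$beta, s$p); other <- det1$alpha
    }
    p <- s$p; q <- s$q
    e <- h[p, q]
    for (r in c(same, other)) e <- e + eri[p, q, r, r]
    for (r in same) e <- e - eri[p, r, r, q]
    return(s$phase * e)
  }
  if (da == 2L) {
    d <- double_phase_same_spin(det1$alpha, det2$alpha)
    p <- d$p; q <- d$q
    return(d$phase * (eri[p[1], q[1], p[2], q[2]] - eri[p[1], q[2], p[2], q[1]]))
  }
  if (db == 2L) {
    d <- double_phase_same_spin(det1$beta, det2$beta)
    p <- d$p; q <- d$q
    return(d$phase * (eri[p[1], q[1], p[2], q[2]] - eri[p[1], q[2], p[2], q[1]]))
  }
  sa <- single_phase(det1$alpha, det2$alpha)
  sb <- single_phase(det1$beta, det2$beta)
  sa$phase * sb$phase * eri[sa$p, sa$q, sb$p, sb$q]
}

# S^2 in a determinant basis via S^2 = S_z(S_z + 1) + S_- S_+ ; for a full
# M sector the listed determinants are closed under S^2.
spin_squared_matrix <- function(dets) {
  nd <- length(dets)
  keys <- vapply(dets, det_key, character(1))
  S2 <- matrix(0, nd, nd)
  for (j in seq_len(nd)) {
    d <- dets[[j]]
    mz <- (length(d$alpha) - length(d$beta)) / 2
    S2[j, j] <- S2[j, j] + mz * (mz + 1)
    for (q in d$beta) {
      ab <- ann_orb(d$beta, q)
      ca <- cre_orb(d$alpha, q)
      if (is.null(ca)) next
      mid <- list(alpha = ca$occ, beta = ab$occ)
      ph1 <- ab$phase * ca$phase
      for (p in mid$alpha) {
        aa <- ann_orb(mid$alpha, p)
        cb <- cre_orb(mid$beta, p)
        if (is.null(cb)) next
        fin_key <- det_key(list(alpha = aa$occ, beta = cb$occ))
        i <- match(fin_key, keys)
        if (!is.na(i)) S2[i, j] <- S2[i, j] + ph1 * aa$phase * cb$phase
      }
    }
  }
  S2
}
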