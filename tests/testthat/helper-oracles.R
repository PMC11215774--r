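# Shared helpers: independent oracles and small utilities used across the
# test files. Nothing here calls into the code paths it is used to check.

lowdin_orbitals <- function(ints) {
  es <- eigen(ints$overlap, symmetric = TRUE)
  es$vectors %*% diag(1 / sqrt(es$values), length(es$values)) %*% t(es$vectors)
}

random_orthogonal <- function(n) qr.Q(qr(matrix(stats::rnorm(n * n), n)))

# Independent closed-shell RHF oracle: damped Roothaan fixed-point iteration
# with an explicit-loop Fock build; shares no code with the package SCF.
# Density damping avoids the charge-density-wave two-cycles the bare
# iteration falls into for lattice models; convergence is judged on the
# density, not just the energy.
rhf_oracle <- function(ints, n_occ, max_iter = 1000, tol = 1e-11,
                       damp = 0.5) {
  n <- ints$n_basis
  X <- lowdin_orbitals(ints)
  C <- X
  D <- NULL
  e <- Inf
  for (it in seq_len(max_iter)) {
    Cocc <- C[, seq_len(n_occ), drop = FALSE]
    D_new <- Cocc %*% t(Cocc)
    D <- if (is.null(D)) D_new else damp * D_new + (1 - damp) * D
    Fm <- ints$h_core
    for (p in 1:n) for (q in 1:n) {
      v <- 0
      for (r in 1:n) for (s in 1:n)
        v <- v + D[r, s] * (2 * ints$eri[p, q, r, s] - ints$eri[p, s, r, q])
      Fm[p, q] <- Fm[p, q] + v
    }
    e_new <- sum(D * (ints$h_core + Fm)) + ints$e_nuclear
    Fo <- t(X) %*% Fm %*% X
    ev <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    C <- X %*% ev$vectors[, order(ev$values), drop = FALSE]
    dd <- max(abs(D_new - D))
    if (abs(e_new - e) < tol && dd < 1e-8)
      return(list(energy = e_new, C = C, iterations = it))
    e <- e_new
  }
  list(energy = e, C = C, iterations = max_iter)
}

# Maximum numerical inter-space rotation gradient of a converged SCF state.
max_numerical_gradient <- function(st, ints) {
  nb <- ints$n_basis
  sid <- integer(nb)
  K <- length(st$config$shell_sizes)
  for (i in st$config$spaces$closed) sid[i] <- 0L
  for (k in seq_len(K))
    for (i in st$config$spaces[[paste0("shell", k)]]) sid[i] <- k
  for (i in st$config$spaces$virtual) sid[i] <- K + 1L
  mx <- 0
  for (p in seq_len(nb - 1L)) for (q in (p + 1L):nb) if (sid[p] != sid[q])
    mx <- max(mx, abs(numerical_rotation_gradient(ints, st$C, st$config,
                                                  p, q, st$vct)))
  mx
}

# Energy of a within-shell-rotated state, for invariance checks.
rotate_pair_energy <- function(ints, st, p, q, theta) {
  nb <- ints$n_basis
  R <- diag(nb)
  R[c(p, q), c(p, q)] <- matrix(c(cos(theta), sin(theta),
                                  -sin(theta), cos(theta)), 2)
  total_energy(ints, st$C %*% R, st$config, st$vct)
}
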