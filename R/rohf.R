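# Multi-shell restricted open-shell Hartree-Fock driven by the
# vector-coupling coefficients of a genealogically coupled CSF.
#
# Energy functional over per-shell densities D^I (closed shell n^C = 2,
# open shells n^I = 1, virtual absent):
#   E = sum_I n^I tr(h D^I)
#     + 1/2 sum_IJ n^I n^J [ a^IJ tr(J(D^J) D^I) - b^IJ/2 tr(K(D^J) D^I) ]
# with a = 1 everywhere, b^CC = b^CI = 1, open-open b from the coupling
# table. The per-shell Fock matrices are the exact derivatives
#   F^I = h + J(A^I) - K(B^I),  A^I = sum_J alpha^IJ D^J,
#                               B^I = sum_J beta^IJ D^J,
# with alpha^IJ = n^J a^IJ and beta^IJ = n^J b^IJ / 2.

#' Shell configuration of an SCF problem
#'
#' @param pattern Coupling pattern (`spin_pattern`, string, or `NULL` for a
#'   closed-shell problem).
#' @param n_closed Number of doubly occupied orbitals.
#' @param n_basis Basis size (to derive the virtual count).
#' @param n_electrons Expected electron count; validated when given.
#' @return An object of class `shell_config`: `n_closed`, `pattern`,
#'   `partition`, `shell_sizes`, `n_somo`, `n_virtual`, and the orbital
#'   column ranges of each space under the canonical ordering
#'   (closed, shells in pattern order, virtual).
#' @export
shell_config <- function(pattern = NULL, n_closed = 0L, n_basis,
                         n_electrons = NULL) {
  n_closed <- as.integer(n_closed)
  if (is.null(pattern)) {
    part <- NULL; sizes <- integer(0); n_somo <- 0L; pattern_obj <- NULL
  } else {
    pattern_obj <- as_spin_pattern(pattern)
    part <- shell_partition(pattern_obj)
    sizes <- part$sizes
    n_somo <- pattern_obj$n
  }
  if (n_closed + n_somo > n_basis)
    stop("more occupied orbitals than basis functions")
  nel <- 2L * n_closed + n_somo
  if (!is.null(n_electrons) && !is.na(n_electrons) && n_electrons != nel)
    stop(sprintf("electron-count mismatch: configuration holds %d electrons, integrals declare %d",
                 nel, n_electrons))
  spaces <- list(closed = seq_len(n_closed))
  ofs <- n_closed
  for (k in seq_along(sizes)) {
    spaces[[paste0("shell", k)]] <- ofs + seq_len(sizes[k])
    ofs <- ofs + sizes[k]
  }
  spaces$virtual <- if (ofs < n_basis) (ofs + 1L):n_basis else integer(0)
  structure(list(n_closed = n_closed, pattern = pattern_obj, partition = part,
                 shell_sizes = sizes, n_somo = n_somo,
                 n_basis = as.integer(n_basis),
                 n_virtual = n_basis - ofs, n_electrons = nel,
                 spaces = spaces),
            class = "shell_config")
}

# extended coefficient matrices over (closed, open shells): occupations,
# a, b, alpha, beta, with the closed shell first (index 1) when present.
extended_coefficients <- function(config, vct) {
  K <- length(config$shell_sizes)
  has_closed <- config$n_closed > 0L
  m <- K + has_closed
  occ <- c(if (has_closed) 2, rep(1, K))
  a <- matrix(1, m, m)
  b <- matrix(1, m, m)
  if (K > 0) {
    op <- (m - K + 1):m
    b[op, op] <- vct$b
  }
  list(occupations = occ, a = a, b = b,
       alpha = sweep(a, 2L, occ, `*`),
       beta = sweep(b, 2L, occ, `*`) / 2,
       has_closed = has_closed, n_groups = m)
}

#' Per-shell and special densities from orbital coefficients
#'
#' Shell densities `D^J = C_J C_J^T` (AO basis, columns in canonical space
#' order) and the special densities `A^I`, `B^I` as coupling-weighted sums
#' over shells, closed shell included.
#'
#' @param C Orbital coefficient matrix, orthonormal under the overlap.
#' @param config A `shell_config`.
#' @param vct A `vct` for the configuration's pattern (`NULL` when there are
#'   no open shells).
#' @return A list with `D` (per group: closed first if present, then open
#'   shells), `A`, `B`, and the extended coefficient matrices.
#' @export
build_densities <- function(C, config, vct = NULL) {
  if (is.null(vct) && config$n_somo > 0L)
    vct <- vector_coupling_coefficients(config$pattern)
  if (!is.null(vct) && vct$n_shells != length(config$shell_sizes))
    stop("vector-coupling table does not match the shell configuration")
  ext <- extended_coefficients(config, vct)
  groups <- if (ext$has_closed) c(list(config$spaces$closed),
                                  config$spaces[grep("^shell", names(config$spaces))])
            else config$spaces[grep("^shell", names(config$spaces))]
  D <- lapply(groups, function(cols) {
    Ci <- C[, cols, drop = FALSE]
    Ci %*% t(Ci)
  })
  m <- ext$n_groups
  A <- vector("list", m); B <- vector("list", m)
  for (I in seq_len(m)) {
    Ai <- 0; Bi <- 0
    for (J in seq_len(m)) {
      Ai <- Ai + ext$alpha[I, J] * D[[J]]
      Bi <- Bi + ext$beta[I, J] * D[[J]]
    }
    A[[I]] <- Ai; B[[I]] <- Bi
  }
  list(D = D, A = A, B = B, ext = ext, groups = groups)
}

#' Per-shell Fock matrices
#'
#' One Fock matrix per shell (closed shell included):
#' `F^I = h + J(A^I) - K(B^I)` with the special densities of
#' [build_densities()].
#'
#' @param ints An `integral_set`.
#' @param dens Output of [build_densities()].
#' @return List of AO-basis Fock matrices, in group order (closed first when
#'   present).
#' @export
build_shell_fock <- function(ints, dens) {
  lapply(seq_along(dens$A), function(I) {
    F <- ints$h_core + coulomb_matrix(ints$eri, dens$A[[I]]) -
      exchange_matrix(ints$eri, dens$B[[I]])
    (F + t(F)) / 2
  })
}

#' Total CSF-ROHF energy
#'
#' The Edwards-Zerner energy evaluated with the pattern's vector-coupling
#' table and unit SOMO occupations; includes the nuclear repulsion.
#'
#' @param ints An `integral_set`.
#' @param C Orbital coefficients (columns in canonical space order).
#' @param config A `shell_config`.
#' @param vct Optional precomputed `vct`.
#' @return Energy in hartree.
#' @export
total_energy <- function(ints, C, config, vct = NULL) {
  if (!is.na(ints$n_electrons) && ints$n_electrons != config$n_electrons)
    stop(sprintf("electron-count mismatch: configuration holds %d electrons, integrals declare %d",
                 config$n_electrons, ints$n_electrons))
  dens <- build_densities(C, config, vct)
  focks <- build_shell_fock(ints, dens)
  e <- ints$e_nuclear
  occ <- dens$ext$occupations
  for (I in seq_along(focks))
    e <- e + 0.5 * occ[I] * sum((ints$h_core + focks[[I]]) * dens$D[[I]])
  e
}

#' CSF energy by determinant contraction (validation oracle)
#'
#' Expands the CSF into Slater determinants, transforms the integrals to the
#' occupied MO basis, and contracts with Slater-Condon rules. Exists solely
#' to validate [total_energy()]; the two agree to machine precision for any
#' orbitals and any pattern.
#'
#' @param ints An `integral_set` (AO basis).
#' @param C Orbital coefficients (canonical space order).
#' @param config A `shell_config`.
#' @param M Spin projection (default `S`).
#' @return Energy in hartree.
#' @export
csf_energy_oracle <- function(ints, C, config, M = NULL) {
  if (!is.na(ints$n_electrons) && ints$n_electrons != config$n_electrons)
    stop("electron-count mismatch between integrals and configuration")
  nocc <- config$n_closed + config$n_somo
  Co <- C[, seq_len(nocc), drop = FALSE]
  mo <- ao_to_mo(ints, Co)
  closed <- seq_len(config$n_closed)
  if (config$n_somo == 0L) {
    det0 <- list(alpha = closed, beta = closed)
    return(slater_condon(det0, det0, mo$h_core, mo$eri) + mo$e_nuclear)
  }
  somos <- config$n_closed + seq_len(config$n_somo)
  v <- csf_det_vector(config$pattern, somos, closed_orbitals = closed, M = M)
  e <- 0
  for (i in seq_along(v$dets)) for (j in seq_along(v$dets))
    e <- e + v$coef[i] * v$coef[j] *
      slater_condon(v$dets[[i]], v$dets[[j]], mo$h_core, mo$eri)
  e + mo$e_nuclear
}

# ---------------------------------------------------------------------------
# SCF driver
# ---------------------------------------------------------------------------

#' Solve the CSF-ROHF SCF problem
#'
#' Iterates densities -> per-shell Fock matrices -> unified effective Fock ->
#' new orbitals until the largest inter-space rotation gradient and the
#' energy change fall below tolerance. Convergence is accelerated by DIIS on
#' the unified matrix in the orthogonalized AO basis; non-Aufbau coupling
#' patterns are held by maximum-overlap (MOM) space tracking, on by default
#' for any pattern containing `-`.
#'
#' The unified matrix takes, between two different spaces, the scaled Fock
#' difference (the orbital-rotation gradient direction; the virtual space
#' carries a zero scaled Fock), and within each space the shell's own Fock
#' (the virtual block sees the test-charge Fock
#' `h + sum_J n^J (J(D^J) - K(D^J)/2)`).
#'
#' @param ints An `integral_set`.
#' @param pattern Coupling pattern (or `NULL` for closed-shell).
#' @param n_closed Doubly occupied orbital count.
#' @param C0 Starting orbitals (AO coefficients); default: core-Hamiltonian
#'   guess. Columns are taken in canonical space order.
#' @param somo_orbitals Optional indices (into the guess orbital ordering)
#'   assigned to the SOMO slots, overriding the default
#'   `n_closed + 1, ..., n_closed + N`; used to steer non-Aufbau solutions.
#' @param options List of solver options; see Details.
#' @details Options (defaults): `e_tol` (1e-8 hartree), `g_tol` (1e-5),
#'   `max_iter` (200), `diis` (TRUE), `diis_dim` (8), `diis_start` (3),
#'   `mom` (TRUE when the pattern contains `-`), `level_shift` (0, hartree,
#'   applied to the virtual diagonal block), `optimizer` (`"auto"`:
#'   fixed-point iteration with a Newton polish on failure; `"fock"`:
#'   fixed-point only; `"direct"`: Newton only), `newton_max` (60).
#' @return An object of class `scf_state`: `C`, `energy`, `shell_fock`,
#'   `gradient_norm`, `iterations`, `converged`, `history`, `config`, `vct`.
#' @export
scf_solve <- function(ints, pattern = NULL, n_closed = 0L, C0 = NULL,
                      somo_orbitals = NULL, options = list()) {
  opt <- modifyList(list(e_tol = 1e-8, g_tol = 1e-5, max_iter = 200L,
                         diis = TRUE, diis_dim = 8L, diis_start = 3L,
                         mom = NULL, level_shift = 0,
                         optimizer = "auto", newton_max = 60L), options)
  config <- shell_config(pattern, n_closed, ints$n_basis, ints$n_electrons)
  vct <- if (config$n_somo > 0L) vector_coupling_coefficients(config$pattern) else NULL
  if (is.null(opt$mom))
    opt$mom <- config$n_somo > 0L && any(config$pattern$signs < 0)

  S <- ints$overlap
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-10) stop("singular overlap matrix")
  X <- es$vectors %*% diag(1 / sqrt(es$values), length(es$values)) %*% t(es$vectors)
  Xinv <- es$vectors %*% diag(sqrt(es$values), length(es$values)) %*% t(es$vectors)

  if (is.null(C0)) {
    ho <- X %*% ints$h_core %*% X
    eh <- eigen((ho + t(ho)) / 2, symmetric = TRUE)
    C <- X %*% eh$vectors[, order(eh$values), drop = FALSE]
  } else {
    C <- as.matrix(C0)
    ortho <- t(C) %*% S %*% C
    if (max(abs(ortho - diag(ncol(C)))) > 1e-6)
      stop("starting orbitals are not orthonormal under the overlap metric")
  }
  if (!is.null(somo_orbitals)) {
    if (length(somo_orbitals) != config$n_somo)
      stop("somo_orbitals must assign one orbital per SOMO slot")
    occ_cols <- c(seq_len(n_closed), as.integer(somo_orbitals))
    if (anyDuplicated(occ_cols))
      stop("somo_orbitals overlap the closed orbitals")
    C <- C[, c(occ_cols, setdiff(seq_len(ncol(C)), occ_cols)), drop = FALSE]
  }

  nb <- ints$n_basis
  space_id <- integer(nb)  # group id per column: 0 closed, 1..K shells, K+1 virtual
  K <- length(config$shell_sizes)
  for (i in config$spaces$closed) space_id[i] <- 0L
  for (k in seq_len(K)) for (i in config$spaces[[paste0("shell", k)]]) space_id[i] <- k
  for (i in config$spaces$virtual) space_id[i] <- K + 1L

  diis_F <- list(); diis_E <- list()
  history <- data.frame(iteration = integer(0), energy = numeric(0),
                        gradient_norm = numeric(0))
  energy <- NA_real_; gnorm <- NA_real_; converged <- FALSE
  focks <- NULL
  it <- 0L

  fock_iters <- if (opt$optimizer == "direct") 0L else opt$max_iter
  for (it in seq_len(fock_iters)) {
    dens <- build_densities(C, config, vct)
    focks <- build_shell_fock(ints, dens)
    e_new <- ints$e_nuclear
    occw <- dens$ext$occupations
    for (I in seq_along(focks))
      e_new <- e_new + 0.5 * occw[I] * sum((ints$h_core + focks[[I]]) * dens$D[[I]])

    # scaled (n-weighted) Fock per group, plus zero for virtual
    Fsc <- lapply(seq_along(focks), function(I) occw[I] * focks[[I]])
    # group index per column mapped to Fock list position
    gidx <- function(sid) {
      if (sid == 0L) 1L
      else if (sid <= K) sid + (config$n_closed > 0L)
      else NA_integer_  # virtual
    }
    # test-charge Fock for the virtual diagonal block
    Dtot <- 0
    for (I in seq_along(dens$D)) Dtot <- Dtot + occw[I] * dens$D[[I]]
    Fvirt <- ints$h_core + coulomb_matrix(ints$eri, Dtot) -
      0.5 * exchange_matrix(ints$eri, Dtot)

    Fsc_mo <- lapply(Fsc, function(F) t(C) %*% F %*% C)
    Fun_mo <- lapply(focks, function(F) t(C) %*% F %*% C)
    Fvirt_mo <- t(C) %*% Fvirt %*% C

    R <- matrix(0, nb, nb)
    G <- matrix(0, nb, nb)  # gradient (inter-space blocks only)
    for (p in seq_len(nb)) for (q in seq_len(nb)) {
      sp <- space_id[p]; sq <- space_id[q]
      if (sp == sq) {
        R[p, q] <- if (sp == K + 1L) Fvirt_mo[p, q]
                   else Fun_mo[[gidx(sp)]][p, q]
      } else {
        fp <- if (sp == K + 1L) 0 else Fsc_mo[[gidx(sp)]][p, q]
        fq <- if (sq == K + 1L) 0 else Fsc_mo[[gidx(sq)]][p, q]
        R[p, q] <- fp - fq
        G[p, q] <- fp - fq
      }
    }
    R <- (R + t(R)) / 2
    gnorm <- if (all(G == 0)) 0 else max(abs(G))

    de <- if (is.na(energy)) Inf else abs(e_new - energy)
    energy <- e_new
    history <- rbind(history, data.frame(iteration = it, energy = energy,
                                         gradient_norm = gnorm))
    if (gnorm < opt$g_tol && de < opt$e_tol) { converged <- TRUE; break }

    if (opt$level_shift != 0) {
      vir <- which(space_id == K + 1L)
      R[cbind(vir, vir)] <- R[cbind(vir, vir)] + opt$level_shift
    }

    # orthogonalized-AO representation for DIIS
    Ct <- Xinv %*% C                 # orthonormal columns
    R_oao <- Ct %*% R %*% t(Ct)
    E_oao <- Ct %*% G %*% t(Ct)
    if (opt$diis) {
      diis_F[[length(diis_F) + 1L]] <- R_oao
      diis_E[[length(diis_E) + 1L]] <- E_oao
      if (length(diis_F) > opt$diis_dim) {
        diis_F <- diis_F[-1]; diis_E <- diis_E[-1]
      }
      if (it >= opt$diis_start && length(diis_F) >= 2L) {
        m <- length(diis_E)
        Bm <- matrix(0, m + 1, m + 1)
        for (i in 1:m) for (j in 1:m)
          Bm[i, j] <- sum(diis_E[[i]] * diis_E[[j]])
        Bm[m + 1, 1:m] <- -1; Bm[1:m, m + 1] <- -1
        rhs <- c(rep(0, m), -1)
        wts <- tryCatch(solve(Bm, rhs)[1:m], error = function(e) NULL)
        if (!is.null(wts) && all(is.finite(wts))) {
          R_oao <- Reduce(`+`, Map(`*`, diis_F, wts))
          R_oao <- (R_oao + t(R_oao)) / 2
        }
      }
    }

    ed <- eigen(R_oao, symmetric = TRUE)
    asc <- order(ed$values)
    evals <- ed$values[asc]
    U <- ed$vectors[, asc, drop = FALSE]  # ascending eigenvalue order
    if (opt$mom) {
      Ov <- t(Ct) %*% U   # overlap of new orbitals with previous ones
      assign_cols <- integer(nb)
      taken <- logical(nb)
      order_groups <- c(if (config$n_closed > 0L) 0L, seq_len(K))
      pos <- 1L
      for (g in order_groups) {
        cols_g <- which(space_id == g)
        proj <- colSums(Ov[cols_g, , drop = FALSE]^2)
        proj[taken] <- -Inf
        sel <- order(-proj, seq_len(nb))[seq_along(cols_g)]
        sel <- sel[order(evals[sel])]
        assign_cols[pos:(pos + length(sel) - 1L)] <- sel
        taken[sel] <- TRUE
        pos <- pos + length(sel)
      }
      rest <- which(!taken)
      rest <- rest[order(evals[rest])]
      if (pos <= nb) assign_cols[pos:nb] <- rest
      U <- U[, assign_cols, drop = FALSE]
    }
    C <- X %*% U
  }
  it <- nrow(history)  # a for over an empty sequence leaves `it` NULL

  # Second-order polish over the inter-space rotation parameters. The
  # fixed-point iteration above can cycle for strongly coupled open-shell
  # configurations (equal shell occupations make the unified matrix a poor
  # contraction); a regularized Newton step on the exact rotation gradient
  # converges to the nearest stationary point instead, which keeps the
  # solver in the basin selected by the starting orbitals.
  if (!converged && opt$optimizer != "fock") {
    prs <- list()
    for (p in seq_len(nb - 1L)) for (q in (p + 1L):nb)
      if (space_id[p] != space_id[q]) prs[[length(prs) + 1L]] <- c(p, q)
    npar <- length(prs)
    gidx <- function(sid) {
      if (sid == 0L) 1L else if (sid <= K) sid + (config$n_closed > 0L)
      else NA_integer_
    }
    eval_state <- function(Cm) {
      dens <- build_densities(Cm, config, vct)
      fks <- build_shell_fock(ints, dens)
      occw <- dens$ext$occupations
      e <- ints$e_nuclear
      for (I in seq_along(fks))
        e <- e + 0.5 * occw[I] * sum((ints$h_core + fks[[I]]) * dens$D[[I]])
      Fsc_mo <- lapply(seq_along(fks),
                       function(I) occw[I] * (t(Cm) %*% fks[[I]] %*% Cm))
      g <- vapply(prs, function(pq) {
        sp <- space_id[pq[1]]; sq <- space_id[pq[2]]
        fp <- if (sp == K + 1L) 0 else Fsc_mo[[gidx(sp)]][pq[1], pq[2]]
        fq <- if (sq == K + 1L) 0 else Fsc_mo[[gidx(sq)]][pq[1], pq[2]]
        2 * (fp - fq)
      }, numeric(1))
      list(energy = e, g = g,
           gnorm = if (npar == 0L) 0 else max(abs(g)), focks = fks)
    }
    rotate <- function(Cm, theta) {
      A <- matrix(0, nb, nb)
      for (i in seq_len(npar)) A[prs[[i]][1], prs[[i]][2]] <- theta[i]
      Cm %*% expm_antisym(A - t(A))
    }
    h_fd <- 1e-4
    if (npar > 0L) for (nit in seq_len(opt$newton_max)) {
      st0 <- eval_state(C)
      it <- it + 1L
      de <- if (is.na(energy)) Inf else abs(st0$energy - energy)
      energy <- st0$energy; gnorm <- st0$gnorm; focks <- st0$focks
      history <- rbind(history, data.frame(iteration = it, energy = energy,
                                           gradient_norm = gnorm))
      if (gnorm < opt$g_tol && de < opt$e_tol) { converged <- TRUE; break }
      # rotation Hessian by central differences of the exact gradient
      H <- matrix(0, npar, npar)
      for (j in seq_len(npar)) {
        ej <- numeric(npar); ej[j] <- h_fd
        H[, j] <- (eval_state(rotate(C, ej))$g -
                   eval_state(rotate(C, -ej))$g) / (2 * h_fd)
      }
      H <- (H + t(H)) / 2
      eh <- eigen(H, symmetric = TRUE)
      lam <- eh$values
      # floor eigenvalue magnitudes, keeping their sign, so the step
      # targets the stationary point of the local quadratic model
      lam <- ifelse(abs(lam) < 1e-8,
                    ifelse(lam < 0, -1e-8, 1e-8), lam)
      delta <- -as.vector(eh$vectors %*% ((t(eh$vectors) %*% st0$g) / lam))
      mx <- max(abs(delta))
      if (mx > 0.2) delta <- delta * (0.2 / mx)
      C <- rotate(C, delta)
    }
  }

  structure(list(C = C, energy = energy, shell_fock = focks,
                 gradient_norm = gnorm, iterations = it,
                 converged = converged, history = history,
                 config = config, vct = vct, overlap = S),
            class = "scf_state")
}

# Exponential of a real antisymmetric matrix via the Hermitian
# eigendecomposition of i*A (eigenvalues purely real, result orthogonal).
expm_antisym <- function(A) {
  eh <- eigen(1i * A, symmetric = TRUE)
  Re(eh$vectors %*% (exp(-1i * eh$values) * Conj(t(eh$vectors))))
}

#' @export
print.scf_state <- function(x, ...) {
  cat(sprintf("<scf_state> E = %.10f hartree, %s after %d iteration(s), max|g| = %.2e\n",
              x$energy,
              if (x$converged) "converged" else "NOT CONVERGED",
              x$iterations, x$gradient_norm))
  invisible(x)
}

#' Recanonicalize orbitals within blocks
#'
#' Rotates the orbitals of each (disjoint) block to diagonalize the given
#' Fock matrix within that block. Each block's span — and therefore the total
#' energy — is unchanged.
#'
#' @param C Orbital coefficients.
#' @param fock AO-basis Fock matrix to diagonalize.
#' @param blocks List of disjoint column-index vectors.
#' @return The rotated coefficient matrix.
#' @export
block_recanonicalize <- function(C, fock, blocks) {
  all_idx <- unlist(blocks)
  if (anyDuplicated(all_idx)) stop("blocks must be disjoint")
  C <- as.matrix(C)
  for (b in blocks) {
    if (length(b) < 2L) next
    Cb <- C[, b, drop = FALSE]
    Fb <- t(Cb) %*% fock %*% Cb
    ed <- eigen((Fb + t(Fb)) / 2, symmetric = TRUE)
    C[, b] <- Cb %*% ed$vectors[, order(ed$values), drop = FALSE]
  }
  C
}

#' Numerical orbital-rotation gradient of the CSF-ROHF energy
#'
#' Central finite differences of [total_energy()] along the rotation mixing
#' a pair of orbital columns; used in tests and convergence diagnostics.
#'
#' @param ints,config,vct As in [total_energy()].
#' @param C Orbital coefficients.
#' @param p,q Column indices to rotate.
#' @param h Step size (radians).
#' @return dE/d(theta) at theta = 0.
#' @export
numerical_rotation_gradient <- function(ints, C, config, p, q, vct = NULL,
                                        h = 1e-5) {
  rot <- function(theta) {
    Cr <- C
    Cr[, p] <- cos(theta) * C[, p] + sin(theta) * C[, q]
    Cr[, q] <- -sin(theta) * C[, p] + cos(theta) * C[, q]
    Cr
  }
  (total_energy(ints, rot(h), config, vct) -
     total_energy(ints, rot(-h), config, vct)) / (2 * h)
}
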