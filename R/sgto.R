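# s-type Gaussian integral backend: closed-form overlap, kinetic,
# nuclear-attraction (Boys F0) and (ss|ss) repulsion integrals over
# contracted s functions. Internal units: bohr and hartree.

#' @rdname units
#' @export
BOHR_PER_ANGSTROM <- 1 / 0.52917721092

#' Unit conversion constants
#'
#' `BOHR_PER_ANGSTROM` converts angstrom to bohr; `CM1_PER_HARTREE` converts
#' hartree to wavenumbers.
#' @name units
#' @export
CM1_PER_HARTREE <- 219474.6313632

element_z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10)

#' Construct a molecular geometry
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix (n x 3) of positions.
#' @param unit `"bohr"` (default) or `"angstrom"`.
#' @param charge Total molecular charge.
#' @return An object of class `geometry`: data frame of atoms (positions in
#'   bohr) plus `total_charge` and `n_electrons` attributes.
#' @export
geometry <- function(elements, coords, unit = c("bohr", "angstrom"),
                     charge = 0L) {
  unit <- match.arg(unit)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) != nrow(coords))
    stop("one coordinate row per element is required")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (unit == "angstrom") coords <- coords * BOHR_PER_ANGSTROM
  z <- element_z[elements]
  if (any(is.na(z)))
    stop(sprintf("unknown element symbol: %s",
                 paste(elements[is.na(z)], collapse = ", ")))
  atoms <- data.frame(element = elements, Z = as.integer(z),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, total_charge = as.integer(charge),
                 n_electrons = sum(z) - as.integer(charge)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d atom(s), charge %+d, %d electron(s)\n",
              nrow(x$atoms), x$total_charge, x$n_electrons))
  print(x$atoms)
  invisible(x)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` records in
#' angstrom (converted to bohr internally).
#'
#' @param path Path to the file.
#' @param charge Total charge.
#' @return A `geometry`.
#' @export
read_xyz <- function(path, charge = 0L) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n)) stop("XYZ file must start with the atom count")
  rec <- lines[3:(2 + n)]
  tok <- strsplit(trimws(rec), "\\s+")
  elements <- vapply(tok, `[[`, character(1), 1)
  coords <- t(vapply(tok, function(x) as.numeric(x[2:4]), numeric(3)))
  geometry(elements, coords, unit = "angstrom", charge = charge)
}

#' Built-in minimal hydrogen s basis (STO-3G)
#'
#' Three-primitive contraction for the hydrogen 1s function.
#' @return A basis specification: per-element list of contractions, each with
#'   `exponents` and `coefficients`.
#' @export
hydrogen_sto3g <- function() {
  list(H = list(list(exponents = c(3.42525091, 0.62391373, 0.16885540),
                     coefficients = c(0.15432897, 0.53532814, 0.44463454))))
}

# Boys function F0(x) = (1/2) sqrt(pi/x) erf(sqrt(x)); short series near 0.
boys_f0 <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-12
  out[small] <- 1 - x[small] / 3
  xs <- x[!small]
  out[!small] <- 0.5 * sqrt(pi / xs) * pracma_erf(sqrt(xs))
  out
}

pracma_erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' s-type Gaussian integrals over a geometry
#'
#' Evaluates overlap, kinetic, nuclear-attraction and two-electron repulsion
#' integrals for contracted s-type Gaussians from their closed forms, plus
#' the nuclear repulsion energy. Contractions are normalized to unity.
#'
#' @param geom A `geometry`.
#' @param basis Per-element list of contractions (see [hydrogen_sto3g()]).
#' @return An `integral_set` (non-identity overlap).
#' @export
sgto_integrals <- function(geom, basis = hydrogen_sto3g()) {
  shells <- list()
  for (ia in seq_len(nrow(geom$atoms))) {
    el <- geom$atoms$element[ia]
    if (is.null(basis[[el]]))
      stop(sprintf("no s-basis provided for element %s", el))
    for (ctr in basis[[el]]) {
      if (!is.null(ctr$l) && ctr$l != 0)
        stop("only s-type Gaussian functions are supported")
      a <- ctr$exponents
      # primitive normalization
      c0 <- ctr$coefficients * (2 * a / pi)^0.75
      shells[[length(shells) + 1L]] <-
        list(center = as.numeric(geom$atoms[ia, c("x", "y", "z")]),
             exp = a, coef = c0)
    }
  }
  nb <- length(shells)

  prim_pairs <- function(s1, s2) {
    # all primitive pair data between two contracted functions
    g <- expand.grid(i = seq_along(s1$exp), j = seq_along(s2$exp))
    a <- s1$exp[g$i]; b <- s2$exp[g$j]
    cc <- s1$coef[g$i] * s2$coef[g$j]
    p <- a + b
    AB2 <- sum((s1$center - s2$center)^2)
    Ex <- exp(-a * b / p * AB2)
    P <- (outer(a, s1$center) + outer(b, s2$center)) / p
    list(a = a, b = b, cc = cc, p = p, AB2 = AB2, Ex = Ex, P = P)
  }

  S <- matrix(0, nb, nb); T <- matrix(0, nb, nb); V <- matrix(0, nb, nb)
  pair_cache <- vector("list", nb * nb)
  for (i in 1:nb) for (j in 1:i) {
    pp <- prim_pairs(shells[[i]], shells[[j]])
    pair_cache[[(i - 1) * nb + j]] <- pp
    s_prim <- (pi / pp$p)^1.5 * pp$Ex
    S[i, j] <- S[j, i] <- sum(pp$cc * s_prim)
    mu <- pp$a * pp$b / pp$p
    T[i, j] <- T[j, i] <- sum(pp$cc * mu * (3 - 2 * mu * pp$AB2) * s_prim)
    v <- 0
    for (ia in seq_len(nrow(geom$atoms))) {
      Cc <- as.numeric(geom$atoms[ia, c("x", "y", "z")])
      PC2 <- rowSums(sweep(pp$P, 2, Cc)^2)
      v <- v - geom$atoms$Z[ia] *
        sum(pp$cc * 2 * pi / pp$p * pp$Ex * boys_f0(pp$p * PC2))
    }
    V[i, j] <- V[j, i] <- v
  }

  # normalize contracted functions
  nrm <- 1 / sqrt(diag(S))
  S <- S * outer(nrm, nrm); T <- T * outer(nrm, nrm); V <- V * outer(nrm, nrm)

  eri <- array(0, c(nb, nb, nb, nb))
  get_pair <- function(i, j) pair_cache[[(max(i, j) - 1) * nb + min(i, j)]]
  for (i in 1:nb) for (j in 1:i) for (k in 1:i) {
    lmax <- if (k == i) j else k
    for (l in 1:lmax) {
      p1 <- get_pair(i, j); p2 <- get_pair(k, l)
      val <- 0
      for (u in seq_along(p1$a)) {
        pq <- p1$p[u] + p2$p
        PQ2 <- rowSums(sweep(p2$P, 2, p1$P[u, ])^2)
        val <- val + sum(p1$cc[u] * p2$cc *
          2 * pi^2.5 / (p1$p[u] * p2$p * sqrt(pq)) *
          p1$Ex[u] * p2$Ex * boys_f0(p1$p[u] * p2$p / pq * PQ2))
      }
      val <- val * nrm[i] * nrm[j] * nrm[k] * nrm[l]
      for (perm in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                        c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                        c(k, l, j, i), c(l, k, j, i)))
        eri[perm[1], perm[2], perm[3], perm[4]] <- val
    }
  }

  e_nuc <- 0
  na <- nrow(geom$atoms)
  if (na > 1) for (i in 1:(na - 1)) for (j in (i + 1):na) {
    rij <- sqrt(sum((as.numeric(geom$atoms[i, c("x", "y", "z")]) -
                     as.numeric(geom$atoms[j, c("x", "y", "z")]))^2))
    e_nuc <- e_nuc + geom$atoms$Z[i] * geom$atoms$Z[j] / rij
  }

  integral_set(T + V, eri, overlap = S, e_nuclear = e_nuc,
               n_electrons = geom$n_electrons)
}

#' Equally spaced hydrogen chain
#'
#' The desk-scale stand-in for extended antiferromagnetic chains: `n`
#' hydrogen atoms on a line at fixed spacing.
#'
#' @param n Number of atoms.
#' @param spacing Interatomic distance in bohr (default 2.0).
#' @return A `geometry`.
#' @export
h_chain <- function(n, spacing = 2.0) {
  geometry(rep("H", n), cbind(0, 0, spacing * (seq_len(n) - 1)), unit = "bohr")
}

#' Random orthonormal-basis integral set
#'
#' Symmetric one-electron matrix and 8-fold symmetric two-electron tensor
#' with standard-normal entries (symmetrized); identity overlap. Used for
#' property tests of the energy expressions.
#'
#' @param n_basis Basis size.
#' @param seed RNG seed (applied via a local RNG state when not `NULL`).
#' @param scale_eri Scale factor for the two-electron part.
#' @return An `integral_set` (electron count unset).
#' @export
random_integral_set <- function(n_basis, seed = NULL, scale_eri = 1) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  h <- matrix(stats::rnorm(n_basis^2), n_basis)
  h <- (h + t(h)) / 2
  g <- array(stats::rnorm(n_basis^4), rep(n_basis, 4))
  integral_set(h, symmetrize_eri(g) * scale_eri)
}
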