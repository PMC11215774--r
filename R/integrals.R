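# One- and two-electron integral container and backends: FCIDUMP files,
# model Hamiltonians, AO->MO transformation. All quantities in hartree;
# two-electron integrals in chemists' notation (pq|rs) with 8-fold symmetry.

#' Construct an integral set
#'
#' The common contract shared by all integral backends: overlap, core
#' Hamiltonian, two-electron tensor, nuclear repulsion and electron count.
#'
#' @param h_core Symmetric one-electron matrix (hartree).
#' @param eri Two-electron tensor `(pq|rs)`, chemists' notation, 8-fold
#'   permutational symmetry (hartree).
#' @param overlap Overlap matrix; identity for orthonormal bases (default).
#' @param e_nuclear Nuclear repulsion / frozen scalar (hartree).
#' @param n_electrons Electron count.
#' @return An object of class `integral_set`.
#' @export
integral_set <- function(h_core, eri, overlap = NULL, e_nuclear = 0,
                         n_electrons = NULL) {
  h_core <- as.matrix(h_core)
  n <- nrow(h_core)
  if (ncol(h_core) != n) stop("h_core must be square")
  if (max(abs(h_core - t(h_core))) > 1e-10)
    stop("h_core must be symmetric")
  if (is.null(overlap)) overlap <- diag(n)
  overlap <- as.matrix(overlap)
  if (!all(dim(overlap) == c(n, n))) stop("overlap dimension mismatch")
  ev <- eigen(overlap, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("overlap matrix must be positive definite")
  if (!is.array(eri) || length(dim(eri)) != 4L || !all(dim(eri) == n))
    stop("eri must be an n x n x n x n array matching h_core")
  chk <- max(abs(eri - aperm(eri, c(2, 1, 3, 4))),
             abs(eri - aperm(eri, c(3, 4, 1, 2))),
             abs(eri - aperm(eri, c(1, 2, 4, 3))))
  if (chk > 1e-10) stop("eri must have 8-fold permutational symmetry")
  structure(list(n_basis = n, overlap = overlap, h_core = h_core, eri = eri,
                 e_nuclear = e_nuclear,
                 n_electrons = if (is.null(n_electrons)) NA_integer_
                               else as.integer(n_electrons)),
            class = "integral_set")
}

#' @export
print.integral_set <- function(x, ...) {
  cat(sprintf("<integral_set> %d basis function(s), %s electron(s), E_nuc = %.10f\n",
              x$n_basis,
              if (is.na(x$n_electrons)) "?" else x$n_electrons, x$e_nuclear))
  invisible(x)
}

# Coulomb and exchange contractions of a density matrix:
#   J(D)_pq = sum_rs (pq|rs) D_rs ,  K(D)_pq = sum_rs (pr|qs) D_rs
coulomb_matrix <- function(eri, D) {
  n <- nrow(D)
  matrix(matrix(eri, n * n) %*% as.vector(D), n, n)
}

exchange_matrix <- function(eri, D) {
  n <- nrow(D)
  matrix(matrix(aperm(eri, c(1, 3, 2, 4)), n * n) %*% as.vector(D), n, n)
}

# Symmetrize a raw tensor over the 8 chemists'-notation permutations.
symmetrize_eri <- function(t4) {
  (t4 + aperm(t4, c(2, 1, 3, 4)) + aperm(t4, c(1, 2, 4, 3)) +
     aperm(t4, c(2, 1, 4, 3)) + aperm(t4, c(3, 4, 1, 2)) +
     aperm(t4, c(4, 3, 1, 2)) + aperm(t4, c(3, 4, 2, 1)) +
     aperm(t4, c(4, 3, 2, 1))) / 8
}

#' Read an FCIDUMP integral file
#'
#' Molpro-style dialect: free-format `&FCI NORB=...,NELEC=...,MS2=...`
#' namelist header (orbital symmetry labels are read and ignored), then
#' `value i j k l` records with 1-based indices in chemists' notation;
#' `i=j=k=l=0` carries the core/nuclear scalar, `k=l=0` a one-electron
#' element. Integrals are expanded to full 8-fold symmetric storage.
#'
#' @param path Path to the file.
#' @return An `integral_set` (orthonormal overlap assumed).
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop(sprintf("FCIDUMP file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  end <- grep("(&END|/)\\s*$", toupper(lines))[1]
  if (is.na(end)) stop("FCIDUMP header not terminated by &END or /")
  header <- paste(lines[1:end], collapse = " ")
  get_field <- function(name) {
    m <- regmatches(header,
                    regexpr(paste0(name, "\\s*=\\s*-?[0-9]+"), header,
                            ignore.case = TRUE))
    if (length(m) == 0) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- get_field("NORB")
  nelec <- get_field("NELEC")
  ms2 <- get_field("MS2")
  if (is.na(norb)) stop("FCIDUMP header missing NORB")
  if (is.na(nelec)) stop("FCIDUMP header missing NELEC")
  if (is.na(ms2)) stop("FCIDUMP header missing MS2")
  h <- matrix(0, norb, norb)
  eri <- array(0, c(norb, norb, norb, norb))
  e_nuc <- 0
  body <- lines[-(1:end)]
  for (ln in body) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "") next
    if (length(tok) != 5)
      stop(sprintf("malformed FCIDUMP record: '%s'", ln))
    val <- as.numeric(tok[1])
    ijkl <- as.integer(tok[2:5])
    if (any(ijkl < 0) || any(ijkl > norb))
      stop(sprintf("FCIDUMP index out of range in record: '%s'", ln))
    i <- ijkl[1]; j <- ijkl[2]; k <- ijkl[3]; l <- ijkl[4]
    if (i == 0 && j == 0 && k == 0 && l == 0) {
      e_nuc <- val
    } else if (k == 0 && l == 0) {
      if (i == 0 || j == 0) stop("malformed one-electron FCIDUMP record")
      if (h[i, j] != 0 && abs(h[i, j] - val) > 1e-10)
        stop(sprintf("inconsistent duplicate one-electron entry (%d,%d)", i, j))
      h[i, j] <- val; h[j, i] <- val
    } else {
      if (i == 0 || j == 0 || k == 0 || l == 0)
        stop("malformed two-electron FCIDUMP record")
      prev <- eri[i, j, k, l]
      if (prev != 0 && abs(prev - val) > 1e-10)
        stop(sprintf("inconsistent duplicate two-electron entry (%d %d|%d %d)",
                     i, j, k, l))
      for (p in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k),
                     c(j, i, l, k), c(k, l, i, j), c(l, k, i, j),
                     c(k, l, j, i), c(l, k, j, i)))
        eri[p[1], p[2], p[3], p[4]] <- val
    }
  }
  integral_set(h, eri, e_nuclear = e_nuc, n_electrons = nelec)
}

#' Write an FCIDUMP integral file
#'
#' Inverse of [read_fcidump()]: unique permutationally distinct two-electron
#' elements, one-electron elements, then the scalar on the index-0 record.
#'
#' @param ints An `integral_set` (orthonormal basis assumed).
#' @param path Output path.
#' @param ms2 Doubled spin projection for the header (default 0).
#' @param threshold Entries with absolute value at or below this are omitted
#'   (exact zeros are always omitted; default 0).
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(ints, path, ms2 = 0L, threshold = 0) {
  n <- ints$n_basis
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n,
                       ints$n_electrons, as.integer(ms2)),
               sprintf(" ORBSYM=%s", paste(rep("1,", n), collapse = "")),
               " ISYM=1,", "&END"), con)
  fmt <- function(val, i, j, k, l) sprintf("%23.16E %3d %3d %3d %3d",
                                           val, i, j, k, l)
  out <- character(0)
  for (i in 1:n) for (j in 1:i) for (k in 1:i) {
    lmax <- if (k == i) j else k
    for (l in 1:lmax) {
      v <- ints$eri[i, j, k, l]
      if (abs(v) > threshold) out <- c(out, fmt(v, i, j, k, l))
    }
  }
  for (i in 1:n) for (j in 1:i) {
    v <- ints$h_core[i, j]
    if (abs(v) > threshold) out <- c(out, fmt(v, i, j, 0L, 0L))
  }
  out <- c(out, fmt(ints$e_nuclear, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

#' Model Hamiltonians in an orthonormal basis
#'
#' Either a Hubbard chain (`n_sites`, hopping `t`, on-site repulsion `U`) or
#' explicit arrays passed through unchanged. Hopping maps to the one-electron
#' matrix, `U` to the on-site elements `(pp|pp)`.
#'
#' @param n_sites Chain length (ignored when `h` is supplied).
#' @param t Hopping amplitude (positive convention: `h[i,i+1] = -t`).
#' @param U On-site repulsion.
#' @param periodic Wrap the chain into a ring.
#' @param n_electrons Electron count (default: half filling, one per site).
#' @param h,eri Explicit arrays (both must be given together).
#' @param e_nuclear Scalar offset for the explicit form.
#' @return An `integral_set`.
#' @examples
#' model_hamiltonian(2, t = 1, U = 4)
#' @export
model_hamiltonian <- function(n_sites = NULL, t = 1, U = 0, periodic = FALSE,
                              n_electrons = NULL, h = NULL, eri = NULL,
                              e_nuclear = 0) {
  if (!is.null(h) || !is.null(eri)) {
    if (is.null(h) || is.null(eri))
      stop("explicit model Hamiltonians need both h and eri")
    return(integral_set(h, eri, e_nuclear = e_nuclear,
                        n_electrons = n_electrons))
  }
  if (is.null(n_sites) || n_sites < 1) stop("n_sites must be a positive integer")
  n <- as.integer(n_sites)
  hmat <- matrix(0, n, n)
  if (n > 1) for (i in 1:(n - 1)) { hmat[i, i + 1] <- -t; hmat[i + 1, i] <- -t }
  if (periodic && n > 2) { hmat[1, n] <- hmat[1, n] - t; hmat[n, 1] <- hmat[n, 1] - t }
  eri4 <- array(0, c(n, n, n, n))
  for (i in 1:n) eri4[i, i, i, i] <- U
  if (is.null(n_electrons)) n_electrons <- n
  integral_set(hmat, eri4, n_electrons = n_electrons)
}

#' Transform integrals to a molecular-orbital basis
#'
#' @param ints An `integral_set`.
#' @param C Orbital coefficient matrix, orthonormal under the overlap metric
#'   (`t(C) %*% S %*% C = I`); may have fewer columns than basis functions.
#' @param tol Orthonormality tolerance.
#' @return An `integral_set` in the MO basis (identity overlap).
#' @export
ao_to_mo <- function(ints, C, tol = 1e-8) {
  C <- as.matrix(C)
  m <- ncol(C)
  ortho <- t(C) %*% ints$overlap %*% C
  if (max(abs(ortho - diag(m))) > tol)
    stop("orbital coefficients are not orthonormal under the overlap metric")
  h_mo <- t(C) %*% ints$h_core %*% C
  h_mo <- (h_mo + t(h_mo)) / 2
  eri_mo <- eri_transform(ints$eri, C)
  integral_set(h_mo, eri_mo, e_nuclear = ints$e_nuclear,
               n_electrons = ints$n_electrons)
}

# four quarter-transformations via reshaping
eri_transform <- function(eri, C) {
  n <- dim(eri)[1]; m <- ncol(C)
  g <- eri
  for (leg in 1:4) {
    d <- dim(g)
    g <- aperm(g, c(2, 3, 4, 1))              # rotate target leg to the end
    dim(g) <- c(d[2] * d[3] * d[4], d[1])
    g <- g %*% C
    dim(g) <- c(d[2], d[3], d[4], m)
  }
  g
}
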