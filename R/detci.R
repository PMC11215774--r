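# Dense determinant-basis CI in small active spaces: validation oracle,
# post-SCF step on CSF-ROHF orbitals, and CSF-weight analysis.

enumerate_occupations <- function(n_orb, n_el) {
  if (n_el == 0L) return(list(integer(0)))
  if (n_el > n_orb) stop("more electrons than orbitals in one spin channel")
  cmb <- utils::combn(n_orb, n_el)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

#' Dense CI in a small active orbital space
#'
#' Enumerates all (alpha-string, beta-string) determinant pairs of the active
#' space at fixed spin projection, folds any frozen doubly occupied orbitals
#' into an effective one-electron operator plus scalar, builds the dense
#' Hamiltonian with Slater-Condon rules and diagonalizes it.
#'
#' @param ints An `integral_set` in the MO basis of interest (identity
#'   overlap).
#' @param n_active_el Number of active electrons.
#' @param active_orbitals Orbital indices of the active space (at most 12).
#' @param M Spin projection of the determinant sector.
#' @param frozen_orbitals Doubly occupied orbitals folded into the core.
#' @return An object of class `ci_result`: ascending `eigenvalues` (hartree,
#'   nuclear and core energy included), `eigenvectors` (columns, determinant
#'   basis), `dets`, `active_orbitals`, `M`, `e_core`, `spin_squared`
#'   (per-root `<S^2>`).
#' @examples
#' hub <- model_hamiltonian(2, t = 1, U = 4)
#' ci_solve(hub, 2, 1:2, M = 0)$eigenvalues[1]  # U/2 - sqrt((U/2)^2 + 4 t^2)
#' @export
ci_solve <- function(ints, n_active_el, active_orbitals, M = 0,
                     frozen_orbitals = integer(0)) {
  active_orbitals <- as.integer(active_orbitals)
  n_act <- length(active_orbitals)
  if (n_act > 12L) stop("active space too large for a dense CI (limit 12 orbitals)")
  if (length(intersect(active_orbitals, frozen_orbitals)) > 0)
    stop("active and frozen orbitals must be disjoint")
  m2 <- as.integer(round(2 * M))
  if ((n_active_el - m2) %% 2L != 0L || abs(m2) > n_active_el)
    stop(sprintf("electron count %d and projection M = %s are incompatible",
                 n_active_el, format(M)))
  n_alpha <- (n_active_el + m2) %/% 2L
  n_beta <- n_active_el - n_alpha
  if (n_alpha > n_act || n_beta > n_act)
    stop("more electrons than active orbitals can hold in one spin channel")

  # frozen-core folding
  h <- ints$h_core; eri <- ints$eri
  e_core <- ints$e_nuclear
  if (length(frozen_orbitals) > 0) {
    fo <- as.integer(frozen_orbitals)
    Dc <- matrix(0, ints$n_basis, ints$n_basis)
    diag(Dc)[fo] <- 1
    Jc <- coulomb_matrix(eri, Dc); Kc <- exchange_matrix(eri, Dc)
    e_core <- e_core + 2 * sum(diag(h)[fo]) + sum((2 * Jc - Kc) * Dc)
    h <- h + 2 * Jc - Kc
  }
  h_act <- h[active_orbitals, active_orbitals, drop = FALSE]
  eri_act <- eri[active_orbitals, active_orbitals, active_orbitals,
                 active_orbitals, drop = FALSE]

  astr <- enumerate_occupations(n_act, n_alpha)
  bstr <- enumerate_occupations(n_act, n_beta)
  dets <- list()
  for (a in astr) for (b in bstr)
    dets[[length(dets) + 1L]] <- list(alpha = a, beta = b)
  nd <- length(dets)
  H <- matrix(0, nd, nd)
  for (i in seq_len(nd)) for (j in i:nd) {
    v <- slater_condon(dets[[i]], dets[[j]], h_act, eri_act)
    H[i, j] <- v; H[j, i] <- v
  }
  ed <- eigen(H, symmetric = TRUE)
  ord <- order(ed$values)
  vals <- ed$values[ord] + e_core
  vecs <- ed$vectors[, ord, drop = FALSE]
  S2 <- spin_squared_matrix(dets)
  s2exp <- vapply(seq_len(nd), function(r) sum(vecs[, r] * (S2 %*% vecs[, r])),
                  numeric(1))
  structure(list(eigenvalues = vals, eigenvectors = vecs, dets = dets,
                 active_orbitals = active_orbitals, M = m2 / 2,
                 n_active_el = n_active_el, e_core = e_core,
                 spin_squared = s2exp),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("<ci_result> %d determinant(s), M = %s\n", length(x$dets),
              format(x$M)))
  cat("lowest eigenvalues (hartree):",
      paste(sprintf("%.8f", x$eigenvalues[1:k]), collapse = ", "), "\n")
  invisible(x)
}

#' Weight of one genealogical CSF in a CI root
#'
#' Squared overlap of the selected root with the CSF built from `pattern` on
#' `somo_orbitals` (active-space indexing, 1-based positions within
#' `active_orbitals`), with `closed_orbitals` doubly occupied.
#'
#' @param result A `ci_result`.
#' @param root Root index (1 = ground state).
#' @param pattern Coupling pattern.
#' @param somo_orbitals Positions of the SOMOs within the active space;
#'   default: all active orbitals in order (neutral CSF).
#' @param closed_orbitals Doubly occupied active positions (for ionic
#'   configurations).
#' @return The squared projection.
#' @export
csf_weight <- function(result, root, pattern, somo_orbitals = NULL,
                       closed_orbitals = integer(0)) {
  pattern <- as_spin_pattern(pattern)
  if (is.null(somo_orbitals))
    somo_orbitals <- seq_along(result$active_orbitals)
  if (length(somo_orbitals) != pattern$n)
    stop(sprintf("pattern length %d incompatible with %d SOMO positions",
                 pattern$n, length(somo_orbitals)))
  if (2 * length(closed_orbitals) + pattern$n != result$n_active_el)
    stop("occupation does not hold the active electron count")
  if (abs(result$M) > pattern$total_spin + 1e-12) return(0)
  v <- csf_det_vector(pattern, somo_orbitals,
                      closed_orbitals = closed_orbitals, M = result$M)
  keys <- vapply(result$dets, det_key, character(1))
  proj <- 0
  for (i in seq_along(v$dets)) {
    k <- match(det_key(v$dets[[i]]), keys)
    if (!is.na(k)) proj <- proj + v$coef[i] * result$eigenvectors[k, root]
  }
  proj^2
}

#' Full spin-adapted decomposition of a CI root
#'
#' Projects a root onto the complete genealogical CSF basis of its M sector:
#' every occupation pattern (doubly occupied + singly occupied orbitals)
#' combined with every branching-diagram coupling of its SOMOs, over all
#' total spins `S >= |M|`. Weights sum to 1 over the complete basis.
#'
#' @param result A `ci_result`.
#' @param root Root index.
#' @return A data frame with columns `occupation` (e.g. `"2ab0"` style
#'   string: per active orbital `2`, `1`, or `0`), `pattern`, `S`, `weight`,
#'   sorted by decreasing weight.
#' @export
csf_weight_table <- function(result, root = 1L) {
  n_act <- length(result$active_orbitals)
  n_el <- result$n_active_el
  rows <- list()
  # enumerate occupations: n_d doubly occupied, n_s singly occupied
  for (n_d in 0:(n_el %/% 2L)) {
    n_s <- n_el - 2L * n_d
    if (n_d + n_s > n_act) next
    if (n_s < abs(2 * result$M)) next
    dsets <- enumerate_occupations(n_act, n_d)
    for (dset in dsets) {
      rest <- setdiff(seq_len(n_act), dset)
      ssets <- if (n_s == 0L) list(integer(0))
               else enumerate_occupations(length(rest), n_s)
      for (sidx in ssets) {
        sset <- rest[sidx]
        occ_str <- paste(ifelse(seq_len(n_act) %in% dset, "2",
                         ifelse(seq_len(n_act) %in% sset, "1", "0")),
                         collapse = "")
        pats <- if (n_s == 0L) "" else
          unlist(lapply(seq(abs(2 * result$M), n_s, by = 2) / 2,
                        function(S) all_patterns(n_s, total_spin = S)))
        for (p in pats) {
          w <- if (n_s == 0L) {
            det0 <- list(alpha = sort(dset), beta = sort(dset))
            keys <- vapply(result$dets, det_key, character(1))
            k <- match(det_key(det0), keys)
            if (is.na(k)) 0 else result$eigenvectors[k, root]^2
          } else {
            csf_weight(result, root, p, somo_orbitals = sset,
                       closed_orbitals = dset)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            occupation = occ_str, pattern = p,
            S = if (n_s == 0L) 0 else parse_pattern(p)$total_spin,
            weight = w, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(-out$weight), , drop = FALSE]
}
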