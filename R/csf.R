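# Genealogical CSF construction: Clebsch-Gordan expansion into Slater
# determinants (the validation oracle) and the direct coupled-basis
# evaluation of two-body substitution-operator matrix elements.

#' Construct a configuration state function (CSF)
#'
#' A CSF is a genealogical coupling pattern attached to a concrete orbital
#' occupation: `n_closed` doubly occupied orbitals plus one singly occupied
#' orbital (SOMO) per coupling symbol.
#'
#' @param pattern A `spin_pattern` or pattern string.
#' @param somo_orbitals Orbital indices of the SOMOs, in genealogical order.
#'   Default `n_closed + 1, ..., n_closed + N`.
#' @param n_closed Number of doubly occupied orbitals (default 0).
#' @param M Spin projection (default: the total spin `S`).
#' @return An object of class `csf`.
#' @export
csf <- function(pattern, somo_orbitals = NULL, n_closed = 0L, M = NULL) {
  pattern <- as_spin_pattern(pattern)
  if (is.null(somo_orbitals)) somo_orbitals <- n_closed + seq_len(pattern$n)
  somo_orbitals <- as.integer(somo_orbitals)
  if (length(somo_orbitals) != pattern$n)
    stop("somo_orbitals must supply exactly one orbital per coupling symbol")
  if (anyDuplicated(somo_orbitals))
    stop("somo_orbitals must be distinct")
  if (n_closed > 0 && any(somo_orbitals <= 0))
    stop("orbital indices must be positive")
  if (any(somo_orbitals %in% seq_len(n_closed)))
    stop("somo_orbitals must be disjoint from the closed (doubly occupied) orbitals")
  S <- pattern$total_spin
  if (is.null(M)) M <- S
  if (abs(round(2 * M) - 2 * M) > 1e-12 || (round(2 * M) - pattern$s2[pattern$n]) %% 2 != 0)
    stop("spin projection M must differ from S by an integer")
  if (abs(M) > S + 1e-12)
    stop(sprintf("|M| = %s exceeds the total spin S = %s", format(M), format(S)))
  structure(list(pattern = pattern, somo_orbitals = somo_orbitals,
                 n_closed = as.integer(n_closed), M = M),
            class = "csf")
}

#' @export
print.csf <- function(x, ...) {
  cat(sprintf("<csf> [%s]  SOMOs (%s), %d closed, S = %s, M = %s\n",
              pattern_string(x$pattern),
              paste(x$somo_orbitals, collapse = ", "),
              x$n_closed, format(x$pattern$total_spin), format(x$M)))
  invisible(x)
}

# Clebsch-Gordan factor for coupling one spin-1/2 (sigma = +1 alpha / -1 beta)
# to a parent of doubled spin a2 and doubled projection m2 (projection BEFORE
# the new spin), forming doubled spin b2 = a2 +/- 1. Condon-Shortley phases.
# Returned exactly: list(sign, num, den) with coefficient = sign*sqrt(num/den).
cg_step <- function(a2, m2, sigma, b2) {
  den <- 2L * (a2 + 1L)
  if (b2 == a2 + 1L) {
    num <- if (sigma > 0) a2 + m2 + 2L else a2 - m2 + 2L
    sgn <- 1L
  } else if (b2 == a2 - 1L) {
    if (sigma > 0) { num <- a2 - m2; sgn <- -1L }
    else           { num <- a2 + m2; sgn <- 1L }
  } else stop("cg_step: b2 must be a2 +/- 1")
  if (num < 0L || num > den) stop("cg_step: projection out of range")
  list(sign = sgn, num = num, den = den)
}

#' Expand a CSF into Slater determinants
#'
#' Builds the spin-adapted expansion by sequential Clebsch-Gordan coupling
#' along the genealogical path. Coefficients are accumulated in exact rational
#' arithmetic (sign and squared magnitude) and converted to floating point at
#' the interface. The determinant phase convention is: creation operators
#' applied in genealogical (slot) order, alpha before beta within an orbital.
#'
#' @param x A `csf`, `spin_pattern`, or pattern string.
#' @param M Spin projection; defaults to the CSF's `M` (or `S` for a bare
#'   pattern).
#' @return An object of class `determinant_expansion`: a data frame with
#'   columns `string` (e.g. `"aab"`, one letter per SOMO slot) and `coeff`,
#'   plus attributes `M` and `pattern`.
#' @examples
#' determinant_expansion("+-", M = 0)  # (ab - ba)/sqrt(2)
#' @export
determinant_expansion <- function(x, M = NULL) {
  if (inherits(x, "csf")) {
    pattern <- x$pattern
    if (is.null(M)) M <- x$M
  } else {
    pattern <- as_spin_pattern(x)
    if (is.null(M)) M <- pattern$total_spin
  }
  n <- pattern$n
  m2_target <- as.integer(round(2 * M))
  if ((m2_target - pattern$s2[n]) %% 2 != 0)
    stop("spin projection M must differ from S by an integer")
  if (abs(m2_target) > pattern$s2[n])
    stop(sprintf("|M| = %s exceeds the total spin S = %s",
                 format_half(abs(m2_target)), format_half(pattern$s2[n])))

  # depth-first accumulation of exact CG products over alpha/beta strings
  strings <- character(0); coeffs <- numeric(0)
  recurse <- function(k, m2, sgn, num, den, str) {
    if (k > n) {
      if (m2 == m2_target && num != 0) {
        strings[[length(strings) + 1L]] <<- str
        coeffs[[length(coeffs) + 1L]] <<- sgn * sqrt(num / den)
      }
      return(invisible(NULL))
    }
    a2 <- if (k == 1L) 0L else pattern$s2[k - 1L]
    b2 <- pattern$s2[k]
    rest_down <- sum(pattern$signs[seq_len(n) > k] < 0)  # max m2 still removable
    for (sigma in c(1L, -1L)) {
      m2_new <- m2 + sigma
      # prune: remaining slots can change m2 by at most n-k in either direction
      if (abs(m2_target - m2_new) > n - k) next
      f <- cg_step(a2, m2, sigma, b2)
      if (f$num == 0L) next
      recurse(k + 1L, m2_new, sgn * f$sign, num * f$num, den * f$den,
              paste0(str, if (sigma > 0) "a" else "b"))
    }
  }
  recurse(1L, 0L, 1L, 1, 1, "")
  out <- data.frame(string = strings, coeff = coeffs, stringsAsFactors = FALSE)
  attr(out, "M") <- m2_target / 2
  attr(out, "pattern") <- pattern
  class(out) <- c("determinant_expansion", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Direct evaluation of <Phi| E_u^t E_t^u |Phi> in the genealogical path basis.
#
# The genealogical CSFs of fixed (N, S) carry the Yamanouchi-Kotani
# (Young orthogonal) representation of the symmetric group acting on the
# electron spins. For singly occupied t and u,
#     <E_u^t E_t^u> = 1 - <P_tu>,
# where P_tu is the spin transposition; P_tu is assembled from adjacent
# transpositions whose blocks follow from two-spin recoupling. No determinant
# expansion is involved, so the expansion above remains an independent oracle.
# ---------------------------------------------------------------------------

# numeric CG value for cg_step
cg_step_num <- function(a2, m2, sigma, b2) {
  f <- cg_step(a2, m2, sigma, b2)
  f$sign * sqrt(f$num / f$den)
}

# All genealogical paths of length n ending at doubled spin s2_final,
# as a matrix of doubled intermediate spins (rows = paths).
path_basis <- function(n, s2_final) {
  pats <- all_patterns(n, total_spin = s2_final / 2)
  t(vapply(pats, function(p) cumsum(parse_pattern(p)$signs), integer(n)))
}

# Matrix of the adjacent spin transposition (k, k+1) on the path basis.
# Paths couple (a2 = S_{k-1}) x 1/2 -> b2 = S_k, then x 1/2 -> c2 = S_{k+1};
# the transposition swaps the two spin-1/2's. Its block over the compatible
# b2 values is computed by explicit coupling in the |m_a, s1, s2> carrier.
adjacent_transposition <- function(paths, k) {
  npaths <- nrow(paths); n <- ncol(paths)
  Tk <- matrix(0, npaths, npaths)
  a_of <- function(i) if (k == 1L) 0L else paths[i, k - 1L]
  # group paths by everything except S_k
  key <- apply(paths[, -k, drop = FALSE], 1L, paste, collapse = ",")
  for (grp in split(seq_len(npaths), key)) {
    a2 <- a_of(grp[1]); c2 <- paths[grp[1], k + 1L]
    b2s <- paths[grp, k]
    blk <- transposition_block(a2, c2, b2s)
    Tk[grp, grp] <- blk
  }
  Tk
}

# <(a,1/2)b',1/2;c | P_swap | (a,1/2)b,1/2;c> over the listed b2 values.
transposition_block <- function(a2, c2, b2s) {
  m_target <- c2  # evaluate at highest projection; result is M-independent
  ma_vals <- seq.int(-a2, a2, by = 2L)
  basis_keys <- character(0)
  vecs <- matrix(0, nrow = 0, ncol = length(b2s))
  amp <- function(b2) {
    # named amplitude vector over |m_a, s1, s2>
    out <- new.env(parent = emptyenv())
    for (ma in ma_vals) for (s1 in c(1L, -1L)) for (s2 in c(1L, -1L)) {
      if (ma + s1 + s2 != m_target) next
      c1 <- cg_step_num(a2, ma, s1, b2)
      if (c1 == 0) next
      c2v <- cg_step_num(b2, ma + s1, s2, c2)
      if (c2v == 0) next
      keyv <- paste(ma, s1, s2)
      out[[keyv]] <- (if (is.null(out[[keyv]])) 0 else out[[keyv]]) + c1 * c2v
    }
    out
  }
  amps <- lapply(b2s, amp)
  blk <- matrix(0, length(b2s), length(b2s))
  for (i in seq_along(b2s)) for (j in seq_along(b2s)) {
    # <v_i | P | v_j>: P swaps s1 and s2
    vj <- amps[[j]]; vi <- amps[[i]]
    s <- 0
    for (keyv in ls(vj)) {
      parts <- as.integer(strsplit(keyv, " ")[[1]])
      swapped <- paste(parts[1], parts[3], parts[2])
      if (!is.null(vi[[swapped]])) s <- s + vi[[swapped]] * vj[[keyv]]
    }
    blk[i, j] <- s
  }
  blk
}

# <Phi| P_tu |Phi> for the path `s2` (doubled intermediate spins) among its
# basis; t < u SOMO slot indices.
transposition_expectation <- function(pattern, t, u) {
  n <- pattern$n
  s2f <- pattern$s2[n]
  paths <- path_basis(n, s2f)
  me <- which(apply(paths, 1L, function(r) all(r == pattern$s2)))
  if (t > u) { tmp <- t; t <- u; u <- tmp }
  # P_(t,u) = T_t T_{t+1} ... T_{u-2} T_{u-1} T_{u-2} ... T_t
  P <- adjacent_transposition(paths, u - 1L)
  if (u - 1L > t) {
    for (k in seq.int(u - 2L, t)) {
      Tk <- adjacent_transposition(paths, k)
      P <- Tk %*% P %*% Tk
    }
  }
  P[me, me]
}

#' Two-body coupling matrix element between two SOMOs of a CSF
#'
#' Evaluates `<Phi| E_u^t E_t^u |Phi>` directly in the genealogically coupled
#' basis (no determinant expansion), where `E_u^t = sum_sigma
#' a+(t,sigma) a(u,sigma)` is the spin-summed one-particle substitution
#' operator. The value depends only on the coupling pattern and the shells
#' containing the two slots, never on the spin projection.
#'
#' @param x A `csf`, `spin_pattern`, or pattern string.
#' @param t,u Distinct SOMO slot indices (1-based, genealogical order).
#' @return The matrix element (e.g. 2 for the two slots of `"+-"`).
#' @examples
#' coupling_matrix_element("+-", 1, 2)   # 2
#' coupling_matrix_element("++-", 1, 3)  # 1.5
#' @export
coupling_matrix_element <- function(x, t, u) {
  pattern <- if (inherits(x, "csf")) x$pattern else as_spin_pattern(x)
  n <- pattern$n
  t <- as.integer(t); u <- as.integer(u)
  if (t < 1L || t > n || u < 1L || u > n)
    stop(sprintf("SOMO slot out of range: pattern has %d slots", n))
  if (t == u)
    stop("SOMO slots t and u must be distinct")
  1 - transposition_expectation(pattern, t, u)
}

#' Spin-spin correlation between two SOMOs of a CSF
#'
#' `<S_t . S_u>` from the same coupled-basis route as
#' [coupling_matrix_element()]; the two are related by
#' `<E_u^t E_t^u> = 1/2 - 2 <S_t . S_u>`.
#'
#' @inheritParams coupling_matrix_element
#' @return The correlation (e.g. -3/4 for the open singlet `"+-"`).
#' @export
spin_correlation <- function(x, t, u) {
  pattern <- if (inherits(x, "csf")) x$pattern else as_spin_pattern(x)
  p <- transposition_expectation(pattern, t, u)
  (2 * p - 1) / 4
}
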