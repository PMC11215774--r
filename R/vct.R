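# Vector-coupling coefficient tables for the Edwards-Zerner open-shell energy.
#
# With unit SOMO occupations the CSF expectation value contributes, per SOMO
# pair t in shell I, u in shell J,
#     J_tu + (<E_u^t E_t^u> - 1) K_tu,
# while the ROHF energy expression carries n^I n^J (a^IJ J_tu - b^IJ/2 K_tu).
# Matching terms gives a^IJ = 1 and b^IJ = 2 - 2 <E_u^t E_t^u>. Within a shell
# the pair is parallel-coupled, <E E> = 0, so the diagonal convention
# a^II = 1, b^II = 2 both satisfies the diagonal constraint and reduces to
# Roothaan's high-spin ROHF for a single shell. The matrix element is constant
# over slot pairs drawn from one shell pair, which makes the representative
# pair immaterial (asserted in the test suite, not assumed).

#' Vector-coupling coefficients for a coupling pattern
#'
#' Derives the full `a`/`b` (and `alpha`/`beta`) coefficient matrices over the
#' open shells of a pattern from genealogical coupling matrix elements:
#' `a^IJ = 1`, `b^IJ = 2 - 2 <Phi|E_u^t E_t^u|Phi>` for representative SOMOs
#' `t` in shell I, `u` in shell J; diagonal `a^II = 1`, `b^II = 2`. The
#' `alpha`/`beta` matrices entering the special densities of the Fock build
#' are `alpha^IJ = n^J a^IJ` and `beta^IJ = n^J b^IJ / 2` with all open-shell
#' occupations `n^J = 1`.
#'
#' @param pattern A `spin_pattern` or pattern string.
#' @return An object of class `vct`: `n_shells`, `partition`, `occupations`,
#'   and matrices `a`, `b`, `alpha`, `beta` (open shells only; the closed
#'   shell couples with `a = 1`, `b = 1` and `n = 2`, handled by the SCF
#'   builders).
#' @examples
#' vector_coupling_coefficients("+-")$b  # off-diagonal -2
#' @export
vector_coupling_coefficients <- function(pattern) {
  pattern <- as_spin_pattern(pattern)
  part <- shell_partition(pattern)
  K <- part$n_shells
  a <- matrix(1, K, K)
  b <- matrix(2, K, K)
  if (K > 1) {
    for (I in 1:(K - 1)) for (J in (I + 1):K) {
      t <- part$slots[[I]][1]
      u <- part$slots[[J]][1]
      bIJ <- 2 - 2 * coupling_matrix_element(pattern, t, u)
      b[I, J] <- bIJ
      b[J, I] <- bIJ
    }
  }
  occ <- rep(1, K)
  structure(
    list(n_shells = K, partition = part, occupations = occ,
         a = a, b = b,
         alpha = sweep(a, 2L, occ, `*`),
         beta = sweep(b, 2L, occ, `*`) / 2),
    class = "vct"
  )
}

#' @export
print.vct <- function(x, ...) {
  cat(sprintf("<vct> [%s]: %d open shell(s)\n",
              pattern_string(x$partition$pattern), x$n_shells))
  cat("b^IJ:\n"); print(x$b)
  invisible(x)
}

#' Coupling-coefficient table as a data frame
#'
#' One row per shell pair (I <= J) with the coupling matrix element and the
#' derived `a`, `b`, `alpha`, `beta` entries; convenient for TSV export.
#'
#' @param pattern A `spin_pattern` or pattern string.
#' @return A data frame.
#' @export
coupling_table <- function(pattern) {
  v <- vector_coupling_coefficients(pattern)
  part <- v$partition
  rows <- list()
  for (I in seq_len(v$n_shells)) for (J in I:v$n_shells) {
    elem <- if (I == J) 0 else
      coupling_matrix_element(part$pattern, part$slots[[I]][1], part$slots[[J]][1])
    rows[[length(rows) + 1L]] <- data.frame(
      shell_I = I, shell_J = J, element = elem,
      a = v$a[I, J], b = v$b[I, J],
      alpha = v$alpha[I, J], beta = v$beta[I, J])
  }
  do.call(rbind, rows)
}
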