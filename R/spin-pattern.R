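#' Parse a genealogical spin-coupling pattern
#'
#' A configuration state function (CSF) with N unpaired electrons is specified
#' by a genealogical coupling path: a string of `+`/`-` symbols, one per singly
#' occupied orbital (SOMO), recording whether each successive spin-1/2 raises
#' or lowers the intermediate total spin. The path must stay on the branching
#' diagram: every intermediate spin `S_k` is non-negative, so the first symbol
#' is necessarily `+`.
#'
#' @param text A string over `+` and `-` (whitespace, commas and brackets are
#'   tolerated and stripped), e.g. `"++-"`. Alternatively a numeric vector of
#'   `+1`/`-1` signs.
#' @return An object of class `spin_pattern` with fields
#'   `signs` (integer vector of +1/-1), `s2` (the doubled intermediate spins
#'   `2*S_k`), `total_spin` (the final `S`), and `n` (number of SOMOs).
#' @examples
#' p <- parse_pattern("++-")
#' p$total_spin   # 0.5
#' @export
parse_pattern <- function(text) {
  if (is.numeric(text)) {
    signs <- as.integer(text)
    if (length(signs) == 0L)
      stop("empty spin-coupling pattern: at least one coupling symbol is required")
    if (!all(signs %in% c(-1L, 1L)))
      stop("illegal sign in spin-coupling pattern: only +1 and -1 are allowed")
  } else {
    if (!is.character(text) || length(text) != 1L || is.na(text))
      stop("spin-coupling pattern must be a single character string")
    cleaned <- gsub("[][(){} \t,;]", "", text)
    if (nchar(cleaned) == 0L)
      stop("empty spin-coupling pattern: at least one coupling symbol is required")
    chars <- strsplit(cleaned, "")[[1]]
    bad <- setdiff(unique(chars), c("+", "-"))
    if (length(bad) > 0L)
      stop(sprintf("illegal character '%s' in spin-coupling pattern: only '+' and '-' are allowed",
                   bad[[1]]))
    signs <- ifelse(chars == "+", 1L, -1L)
  }
  if (signs[1] == -1L)
    stop("invalid spin-coupling pattern: the first spin must couple '+' (the branching diagram starts at S = 0)")
  s2 <- cumsum(signs)
  if (any(s2 < 0L)) {
    k <- which(s2 < 0L)[1]
    stop(sprintf("invalid spin-coupling pattern: intermediate spin below zero at position %d", k))
  }
  structure(
    list(signs = signs, s2 = s2, total_spin = s2[length(s2)] / 2,
         n = length(signs)),
    class = "spin_pattern"
  )
}

#' @export
print.spin_pattern <- function(x, ...) {
  cat(sprintf("<spin_pattern> [%s]  N = %d, S = %s\n",
              pattern_string(x), x$n, format_half(x$s2[x$n])))
  invisible(x)
}

#' @export
format.spin_pattern <- function(x, ...) pattern_string(x)

#' Render a spin pattern back to its `+`/`-` string
#' @param pattern A `spin_pattern` (or a string, returned cleaned).
#' @return A character scalar such as `"++-"`.
#' @export
pattern_string <- function(pattern) {
  pattern <- as_spin_pattern(pattern)
  paste(ifelse(pattern$signs > 0, "+", "-"), collapse = "")
}

as_spin_pattern <- function(x) {
  if (inherits(x, "spin_pattern")) x else parse_pattern(x)
}

format_half <- function(s2) {
  if (s2 %% 2 == 0) as.character(s2 %/% 2) else sprintf("%d/2", s2)
}

#' Partition a coupling pattern into open shells
#'
#' An open shell is a maximal run of consecutive parallel-coupled spins: all
#' SOMOs within such a run share one set of Fock-operator coupling
#' coefficients. The partition of the pattern into runs therefore fixes the
#' number of Fock matrices of the open-shell SCF problem.
#'
#' @param pattern A `spin_pattern` or pattern string.
#' @return An object of class `shell_partition`: `n_shells`, `sizes`,
#'   `signs` (one per shell), and `slots` (list of SOMO slot indices covered
#'   by each shell).
#' @examples
#' shell_partition("+-+-+")$n_shells  # 5
#' @export
shell_partition <- function(pattern) {
  pattern <- as_spin_pattern(pattern)
  r <- rle(pattern$signs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  slots <- mapply(function(a, b) seq.int(a, b), starts, ends, SIMPLIFY = FALSE)
  structure(
    list(n_shells = length(r$lengths), sizes = r$lengths,
         signs = r$values, slots = slots, pattern = pattern),
    class = "shell_partition"
  )
}

#' @export
print.shell_partition <- function(x, ...) {
  cat(sprintf("<shell_partition> [%s]: %d open shell(s), sizes %s\n",
              pattern_string(x$pattern), x$n_shells,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Index of the shell containing a given SOMO slot
#' @param partition A `shell_partition`.
#' @param slot SOMO slot index (1-based).
#' @return The shell index.
#' @export
shell_of_slot <- function(partition, slot) {
  for (i in seq_len(partition$n_shells))
    if (slot %in% partition$slots[[i]]) return(i)
  stop(sprintf("SOMO slot %d out of range", slot))
}

#' Enumerate all valid genealogical coupling patterns
#'
#' Walks the branching diagram: every path of N `+`/`-` steps starting at
#' S = 0 that never dips below zero. Optionally restricted to a final total
#' spin.
#'
#' @param n Number of SOMOs.
#' @param total_spin Optional final total spin `S` to filter on.
#' @return A character vector of pattern strings.
#' @examples
#' length(all_patterns(5, total_spin = 1/2))  # 5 doublet CSFs
#' @export
all_patterns <- function(n, total_spin = NULL) {
  stopifnot(n >= 1)
  paths <- list(list(signs = 1L, s2 = 1L))
  if (n > 1) {
    for (k in 2:n) {
      nxt <- list()
      for (p in paths) {
        nxt[[length(nxt) + 1L]] <- list(signs = c(p$signs, 1L), s2 = p$s2 + 1L)
        if (p$s2 >= 1L)
          nxt[[length(nxt) + 1L]] <- list(signs = c(p$signs, -1L), s2 = p$s2 - 1L)
      }
      paths <- nxt
    }
  }
  if (!is.null(total_spin)) {
    s2_target <- as.integer(round(2 * total_spin))
    paths <- Filter(function(p) p$s2 == s2_target, paths)
  }
  vapply(paths, function(p) paste(ifelse(p$signs > 0, "+", "-"), collapse = ""),
         character(1))
}
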