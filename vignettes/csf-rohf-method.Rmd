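---
title: "CSF-ROHF: self-consistent fields for arbitrary genealogical spin couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSF-ROHF: self-consistent fields for arbitrary genealogical spin couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfrohf)
```

## The model

A configuration state function (CSF) with `N` singly occupied orbitals
(SOMOs) and total spin `S` is specified genealogically: starting from `S = 0`,
each unpaired electron couples its spin either *up* (`+`, raising the
intermediate spin by 1/2) or *down* (`-`, lowering it). A pattern such as
`"++--"` is therefore a path on the spin branching diagram; validity requires
every intermediate spin to stay non-negative, which forces the first symbol
to be `+`.

```{r}
parse_pattern("++--")
all_patterns(4, total_spin = 0)
```

The number of paths ending at spin `S` equals the dimension of the
corresponding irreducible representation, `(2S+1)/(N/2+S+1) * choose(N, N/2-S)`
— the paths form a complete spin-adapted basis for the `N`-SOMO space.

### Determinant expansion

Walking the path and attaching one spin-1/2 Clebsch–Gordan factor per step
expands the CSF into Slater determinants. Only four closed-form factors are
needed (coupling a spin-1/2 up or down to a parent of doubled spin `a2` and
doubled projection `m2`), and each is a signed square root of a rational
number, so the package accumulates the products exactly and converts to
floating point only at the interface:

```{r}
determinant_expansion("++-")
```

This expansion is deliberately kept *separate* from the production evaluation
of matrix elements below; it serves as an independent oracle in the test
suite.

### Coupling matrix elements without determinants

The central quantity of the energy expression is the two-body substitution
expectation `<Phi| E_u^t E_t^u |Phi>` for SOMOs `t < u`, with
`E_u^t = sum_sigma a+(t,sigma) a(u,sigma)`. For singly occupied orbitals it
reduces to spin algebra:

`<E_u^t E_t^u> = 1 - <P_tu>`,

where `P_tu` transposes the spins of electrons `t` and `u`. The genealogical
path basis of fixed `(N, S)` carries the Young orthogonal (symmetric-group)
representation of these transpositions: an adjacent transposition `T_k` only
mixes paths that differ in the single intermediate spin `S_k`, and its 2x2
blocks follow from re-coupling two adjacent spin-1/2s — again requiring only
the four exact Clebsch–Gordan factors. A general `P_tu` is the conjugated
product `T_t ... T_{u-2} T_{u-1} T_{u-2} ... T_t`. This route never touches a
determinant, depends only on the pattern (not the spin projection `M`), and
is exact up to floating-point rounding:

```{r}
coupling_matrix_element("+-", 1, 2)
coupling_matrix_element("++-", 1, 3)
coupling_matrix_element("+-+", 2, 3)
```

### From matrix elements to shell-coupling coefficients

A maximal run of equal symbols is an open *shell*: the matrix element is
constant for any slot pair drawn from a fixed pair of shells (a property the
test suite asserts rather than assumes), so one Fock operator per shell
suffices. Writing the CSF energy with unit SOMO occupations, a pair `t` in
shell `I`, `u` in shell `J` contributes `J_tu + (<E_u^t E_t^u> - 1) K_tu`,
while the shell-pair energy ansatz carries
`n^I n^J (a^IJ J_tu - (b^IJ/2) K_tu)`. Term matching gives

* `a^IJ = 1` for all shell pairs,
* `b^IJ = 2 - 2 <E_u^t E_t^u>` across shells,
* `a^II = 1`, `b^II = 2` within a shell (parallel coupling, element 0 —
  the familiar high-spin values),
* closed shells couple with `a = 1`, `b = 1` at occupation `n = 2`, which
  reduces the expression to restricted Hartree–Fock when no SOMOs remain.

Equivalently `b^IJ = 1 + 4 <S_t . S_u>`: `b = 2` for triplet-coupled pairs,
`b = -2` for an open-shell singlet.

```{r}
vector_coupling_coefficients("++--")$b
coupling_table("+-+")
```

## The self-consistent field

The total energy is

`E = sum_I n^I tr(h D^I) + 1/2 sum_IJ n^I n^J [ a^IJ tr(J(D^J) D^I) - (b^IJ/2) tr(K(D^J) D^I) ]`

over closed (`n = 2`) and open (`n = 1`) shells, with `J`/`K` the Coulomb and
exchange contractions. Each shell has the Fock operator
`F^I = h + J(A^I) - K(B^I)` built from the coupling-weighted densities
`A^I = sum_J alpha^IJ D^J`, `B^I = sum_J beta^IJ D^J`; this `F^I` is the
exact derivative of the energy with respect to that shell's density, so the
inter-space orbital-rotation gradient is `2 (n^I F^I - n^J F^J)_pq` (the
virtual space carries a zero scaled Fock).

### Unified iteration

One effective matrix drives the iteration: between two different spaces it
takes the scaled Fock difference (the gradient direction), within each space
the shell's own Fock (the virtual diagonal block sees the test-charge
operator `h + sum_J n^J (J(D^J) - K(D^J)/2)`). Diagonalizing it
simultaneously canonicalizes every space and rotates the gradient toward
zero. Convergence is accelerated by DIIS on this matrix in the
orthogonalized-AO basis; for patterns containing `-`, the target CSF is
generally not the Aufbau occupation of the effective matrix, so
maximum-overlap (MOM) tracking reassigns each space to the new orbitals with
the largest projection onto the previous ones.

### Newton polish

For strongly coupled cases with equal shell occupations (for example
`"++--"` on a stretched chain) the fixed-point iteration can cycle without
converging. `scf_solve` then switches to a direct second-order step over all
inter-space rotation angles: the exact analytic gradient above, a Hessian
obtained by central finite differences *of that gradient* (cost: two Fock
builds per parameter and iteration, trivial at the problem sizes the package
targets), eigenvalue magnitudes floored at 1e-8 with their sign kept — so
the step targets the *nearest stationary point*, consistent with the
non-Aufbau philosophy of MOM — and a 0.2 rad cap on the step, applied
through the exponential of the antisymmetric generator. Options:
`optimizer = "auto"` (default; polish only on fixed-point failure),
`"fock"`, `"direct"`.

```{r}
h4 <- sgto_integrals(h_chain(4, 2.0))
es <- eigen(h4$overlap, symmetric = TRUE)
X  <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
st <- scf_solve(h4, "++--", C0 = X, somo_orbitals = c(1, 3, 2, 4))
st
```

The energy is invariant under rotations *within* a shell (and within the
closed or virtual space); converged states are validated in the test suite
against numerical gradients over all inter-space pairs.

## Validation layers

Three independent routes to the same quantities are implemented and pitted
against each other in the tests:

1. coupled-basis matrix elements (production) vs. brute-force operator
   algebra on the determinant expansion (oracle), for every pattern with up
   to 8 SOMOs;
2. the shell-pair energy functional vs. the determinant contraction
   `sum h gamma + 1/2 sum (pq|rs) Gamma` with RDMs built from the expansion,
   on hundreds of random symmetric integral sets;
3. the SCF vs. dense determinant CI: a converged high-spin state must equal
   the single-determinant CI energy in its own orbitals, and any CSF energy
   must lie above the CI ground state of the same sector.

The determinant CI itself is checked for invariance of full-CI spectra under
orbital rotations — a test sharp enough that it caught a sign error in the
same-spin double-substitution phase during development.

## Toy systems and parameter choices

The built-in fixtures are hydrogen chains in a minimal s-Gaussian basis
(closed-form integrals; 2.0 bohr spacing — stretched enough for strong
static correlation, short enough to remain single-reference per site) and
Hubbard models for basis-free checks against closed-form spectra. These sizes
keep every reference quantity computable by brute force in seconds, which is
what makes the oracle-first validation scheme feasible; nothing in the
implementation limits it to these sizes except the dense CI (capped at 12
active orbitals) and the O(n^4) integral storage.

For the antiferromagnetic `"++--"` worked example the SOMOs are steered onto
*alternating* Löwdin-orthogonalized sites (`somo_orbitals = c(1, 3, 2, 4)`),
the four-site Néel arrangement. With the default adjacent assignment the
solver converges to a lower-lying but qualitatively different solution whose
correlated ground state is dominated by closed-shell configurations; the
alternating assignment yields the state whose CI decomposition is led by the
neutral `"++--"` CSF itself — the physics the pattern is meant to capture.

```{r}
ci <- ci_solve(ao_to_mo(h4, st$C), 4, 1:4, M = 0)
head(csf_weight_table(ci, 1), 3)
```

## Numerical choices

* Exact rational accumulation of Clebsch–Gordan products; floating point
  only at interfaces.
* Default tolerances: `e_tol = 1e-8` hartree, `g_tol = 1e-5` on the maximum
  inter-space gradient element (tightened in the validation suite).
* DIIS depth 8, started at iteration 3, extrapolating the unified matrix in
  the Löwdin-orthogonalized AO basis.
* Boys function `F0` via `erf` with a series switch below `1e-12`.
* FCIDUMP I/O uses the Molpro-style free-format dialect with chemists'
  notation and 8-fold permutational expansion.

## Limitations

* One genealogical CSF per SCF; no state averaging and no direct open-shell
  response properties.
* s-type Gaussians only in the built-in integral backend; use FCIDUMP input
  for general basis sets produced elsewhere.
* Dense CI scales factorially and is capped at 12 active orbitals.
* The Newton polish converges to the nearest stationary point; as with all
  non-Aufbau SCF methods, the physical character of a solution should be
  checked (e.g. with `csf_weight_table`) rather than assumed.
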