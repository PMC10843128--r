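---
title: "Decomposing information gain over the redundancy lattice: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing information gain over the redundancy lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infodecomp)
```

## The problem and the model

Classical information theory treats a multivariate system **X** = (X₁,…,X_N)
as a lump: the entropy H(**X**) or a divergence D(P‖Q) says how much
uncertainty or information there is, but not *where* it lives. This package
decomposes such quantities over the **redundancy lattice**: the set of
antichains of variable subsets ("sources"), ordered by

α ⪯ β  ⇔  every source of β contains some source of α.

An antichain like {X₁}{X₂} names information available from X₁ alone *or*
X₂ alone (redundancy); {X₁,X₂} names information available only from the
pair jointly (synergy). For N = 1..4 the lattice has 1, 4, 18, 166 atoms;
the package refuses N ≥ 5, where the antichain count (a Dedekind-type
sequence) explodes and the decomposition stops being practical.

Three layers are built on this scaffold:

1. **Partial entropy decomposition (PED).** For one realization x, a
   redundancy function h_∩ assigns each atom the surprisal shared by all of
   its sources; Möbius inversion (recursive subtraction down the lattice)
   converts these cumulative values into partial atoms that sum exactly to
   the local surprisal h(x) = −log₂P(x). Expected atoms are the P-weighted
   average of the local tables — decompose locally first, then average,
   which is what makes the next layer possible.

2. **Generalized information decomposition (GID).** Since
   D(P‖Q) = E_P[h_Q(x) − h_P(x)], and both local entropies decompose, the
   divergence decomposes atomwise:
   D_∂(α) = E_P[h_∂^Q(α) − h_∂^P(α)]. Atoms always sum to D(P‖Q) ≥ 0, but
   individual atoms may be negative: the observer is *more* surprised by
   that configuration under the posterior than under the prior — that
   information was lost in the update. This interpretation is only coherent
   because the shipped redundancy function yields non-negative local
   entropy atoms.

3. **Derived measures.** Fixing the prior recovers standard measures: the
   product of marginals gives the total correlation, the uniform
   distribution the negentropy, P(inputs)×P(T) or the per-target-value
   conditional construction the mutual information. O-information and TSE
   complexity are linear combinations of subset total correlations and
   therefore expand into linear combinations of partial-TC atoms.

## The redundancy function

The shipped h_min assigns an antichain the *minimum* local surprisal over
its sources — the most conservative reading of "resolvable by observing any
single source". It is localizable (defined per realization, which the GID
requires), permutation-symmetric, and induces non-negative local partial
atoms. The contract is pluggable: any `rf(P, x, alpha)` returning bits can
be passed to the decomposition functions. The co-information-based
redundancy is deliberately not shipped — it can produce negative local
entropy atoms, which destroys the surprisal-comparison reading of the GID —
and no alternative formula is bundled, since none is needed by the shipped
measures.

A consequence worth knowing: with h_min, the single-target PID
(`pid_single_target()`) is the pointwise informative/misinformative
decomposition. For the COPY gate (T = X₁, X₂ irrelevant) it reports one bit
of *pointwise* redundancy and −1 bit unique to X₂ — not the zero-redundancy
answer older expectation-based redundancy measures give. This is the
documented behaviour of the pointwise family, not a defect; the consistency
equations (atoms summing to I, redundancy + unique_i = I(X_i;T)) hold
exactly.

## Numerical conventions

* **Bits everywhere.** All logarithms are base 2.
* **Floating-point probabilities.** Values below 1e-15 are treated as zero
  and removed from support at construction; pmf sums are enforced to 1
  within 1e-12 (file ingest is laxer: deviations up to 1e-6 are
  renormalized with a warning, larger ones rejected).
* **Decomposition identities** (reconstruction, conservation, marginal
  constraints) are asserted in the test suite at 1e-9; the O-information
  and TSE atom-expansion identities at 1e-8.
* **Atom labels** are canonical: sources sorted by (cardinality, index
  order), each rendered `{X1}{X2,X3}` with the distribution's variable
  names. Tables are emitted in a fixed topological order — ascending
  strict-down-set size, ties broken by the index-based label — so equal
  inputs give byte-identical outputs. This order is a linear extension of
  the lattice order, which is the only property Möbius inversion needs.
* **Möbius inversion** is computed by recursive subtraction in that
  topological order rather than via precomputed Möbius coefficients:
  identical results, and each atom's value is auditable as
  cumulative − sum(partials below).
* **Degenerate inputs.** A single-state distribution has zero surprisal
  everywhere and decomposes to an all-zero table; conditioning on a
  zero-probability value, evaluating surprisal outside the support, and
  posterior states missing from a strict prior all raise classed support
  errors rather than returning infinities.

## Support policies

D(P‖Q) diverges if P has support where Q has none. The default policy is
`strict`: such a pair is an error, on the view that the prior-posterior
relationship is then genuinely undefined. Two explicit opt-ins exist:

* `pseudocount` adds ε to *every* state of Q's declared alphabet product and
  renormalizes Q. Default ε = 1e-6, added before renormalization. This is
  documented as biased: h_Q of a pseudocount state is enormous, and those
  differences dominate the expectation.
* `restrict` drops the offending states from P and renormalizes, losing
  whatever information they carried.

Neither ε nor the renormalization order is canonical; both are conventions
of this package, chosen once (ε small enough not to disturb well-supported
states at the 1e-6 ingest tolerance, addition before renormalization so the
result is a proper distribution).

## Open choices made here

* **TC of a single variable is 0.** The TSE sum averages subset total
  correlations over every size, including size 1, where "deviation from
  independence" is vacuous; the size-1 average is therefore fixed at zero.
  With that convention the direct TSE definition and the 18-atom expansion
  agree to machine precision.
* **Atom-expansion coefficients are stored for N = 3 only**, keyed by the
  structural class of each atom (the multiset of its source sizes, which is
  unambiguous at N = 3). The bivariate-source atoms {X_i,X_j} carry
  coefficient 0 in the O-information expansion — it is blind to pairwise
  structure — and the singleton atoms carry 0 in the TSE expansion. No
  general-N expansion is attempted.
* **Prior/posterior alphabets must match.** The divergence between
  distributions over different alphabets is not defined here; a mismatch is
  a validation error, not a policy case.
* **Expectation weights in the GID come only from P** over its support;
  prior-only states contribute nothing. The cross-entropy decomposition
  reuses the same machinery with the prior-side tables alone, so
  cross-entropy − PED(P) = GID holds atomwise by construction (and is
  tested).

## The fixtures: what they do and do not establish

The built-in generators state the worlds the tests live in: the XOR / AND /
OR / COPY gates (two equiprobable independent inputs, deterministic
target), the uniform (maximum-entropy) distribution, the giant bit (all
variables copy one fair coin — the redundancy extreme), and seeded
symmetric-Dirichlet random distributions (default concentration 1, i.e.
flat on the simplex; seeds are mandatory arguments and the global RNG
stream is left untouched). The random panels exercise the algebraic
invariants — conservation, reconstruction, marginal constraints,
non-negativity, the atom-expansion identities — across the interior of the
probability simplex.

What a green suite does *not* establish: anything about estimation. These
are exact decompositions of known pmfs; finite-sample bias, plug-in
estimation from counts, and continuous variables are out of scope. The
fixtures are also all exchangeable or near-symmetric at small N; the
decompositions are well defined for arbitrary discrete pmfs, but intuition
built on the fixtures' symmetry should not be over-extrapolated.

## Known limitations

* N ≤ 4, by design; the lattice itself is the bottleneck.
* One redundancy function is shipped. Alternatives (e.g. differentiable
  shared-exclusion variants) can be plugged in through the `rf` argument
  but are not provided or validated here.
* The two mutual-information decompositions (4-atom single-target and
  18-atom joint) are both exact but not interconvertible; no linear bridge
  between them is implemented because none is known.
* Temporal/dynamical decompositions (multi-target lattices, entropy
  production) are out of scope.
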