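---
title: "Deciding path connectivity of multistationarity regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding path connectivity of multistationarity regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnconnect)
```

## The question

A mass-action reaction network with species concentrations $x \in
\mathbb{R}^n_{\ge 0}$, rate constants $\kappa \in \mathbb{R}^r_{>0}$ and
stoichiometric matrix $N$ evolves as $\dot x = N v_\kappa(x)$, where
$v_{\kappa,j}(x) = \kappa_j x^{A_j}$ and $A$ collects the reactant
coefficients. Trajectories are confined to stoichiometric compatibility
classes $\{x \ge 0 : Wx = c\}$, with $W$ a row-reduced basis of the left
kernel of $N$. A parameter pair $(\kappa, c)$ *enables multistationarity*
when its class carries at least two positive steady states; the set of such
pairs is the multistationarity region.

`crnconnect` certifies that this region is **path connected** — the property
separating ordinary hysteresis switches from composite switches whose
bistable regimes are mechanistically distinct. The certificate is symbolic:
no numerical continuation or sampling is involved, and no sign decision is
ever made in floating point.

## The procedure

1. **Structural preconditions.** The network must be conservative (a strictly
   positive $w$ with $wN = 0$, certified by exact rational feasibility), and
   relevant boundary steady states must be excluded: for every minimal siphon
   $Z$ there must be a nonnegative conservation vector whose support is
   exactly $Z$. Siphons use the gross-production convention (a reaction
   produces a species whenever its product coefficient is positive, even for
   catalysts). A failed precondition yields an *inconclusive* verdict, never
   a claim about the region.

2. **Convex parametrization and the critical polynomial.** The flux cone
   $\ker N \cap \mathbb{R}^r_{\ge 0}$ is generated by extreme rays, collected
   as columns of $E$; the network is consistent when $E$ has no zero row.
   Writing the positive steady states as $x = 1/h$, $v_\kappa(x) = E\lambda$,
   the Jacobian of the vector field becomes $N\,\mathrm{diag}(E\lambda)\,
   A^{\mathsf T}\mathrm{diag}(h)$. Replacing the pivot rows by the rows of $W$
   gives $\tilde M(h, \lambda)$, and the **critical polynomial**
   $(-1)^s \det \tilde M$ (with $s = \operatorname{rank} N$) has, at every
   positive steady state, the sign that the determinant criterion for
   multistationarity tests: somewhere negative means some parameter pair
   enables multistationarity.

3. **Separating hyperplane.** Split the exponent vectors of the critical
   polynomial by coefficient sign into $\sigma_+$ and $\sigma_-$. If some
   hyperplane $v \cdot \mu = a$ has all of $\sigma_+$ on one closed side, all
   of $\sigma_-$ on the other, and not all of $\sigma_-$ on the hyperplane
   itself, then the negativity region of the polynomial on the positive
   orthant is path connected and its closure is the nonpositivity region —
   and consequently the multistationarity region is path connected.

4. **Reduction.** When the intermediate of a reversible binding step occurs
   in exactly three reactions (formed reversibly, consumed irreversibly),
   deleting the unbinding reaction preserves the connectivity conclusion.
   Each deleted reaction removes one extreme ray, often shrinking the
   polynomial dramatically (for the shared-kinase cascade: 5312 to 204
   monomials). The pipeline analyses the original network first and falls
   back to the reduced one; a failure on the reduced network never overrides
   the original analysis, because hyperplane existence for the two is
   independent.

```{r example}
report <- check_connectivity(example_network("running_example"))
report
```

## Exactness and the hyperplane decision

Every decision is made in exact rational arithmetic:

* Ranks, reduced row-echelon forms and kernels use rational elimination on
  numerator/denominator pairs held in doubles, with every intermediate
  checked against $2^{53}$; an overflow aborts rather than rounds.
* Extreme rays come from exact double description over the orthant with
  minimal-support pruning (for flux cones, extreme = minimal support), with
  primitive-integer normalization and lexicographic sorting so outputs are
  reproducible. The $\lambda$ variable order is therefore canonical; printed
  polynomials from other sources may differ by a permutation of $\lambda$.
* The symbolic determinant is expanded in C++ by a generalized Laplace
  expansion along the block of $W$ rows: for each admissible column subset,
  an integer $W$-minor multiplies a $\lambda$-determinant that is computed by
  row expansion memoized on the column bitmask and shared across subsets.
  Coefficients are 64-bit integers with 128-bit overflow guards. A
  configurable term budget (default $10^6$ stored monomials) converts
  combinatorial blow-up into a clean error that suggests reducing the
  network first. In practice the expansion is efficient enough to compute
  even the full 4-site phosphorylation cycle polynomials (33k–45k monomials)
  in about two seconds on one CPU.
* The hyperplane decision is a single exact feasibility problem: the side
  conditions together with the normalized slack condition
  $\sum_{\beta \in \sigma_-}(v\cdot\beta - a) \ge 1$ (equivalent to $> 0$ by
  scale invariance of the cone cut out by the side conditions). A phase-1
  simplex on the Farkas dual — whose basis has only $k+2$ rows however many
  exponents there are — either proves infeasibility (then every weakly
  separating hyperplane contains all of $\sigma_-$, so no strict separator
  exists) or yields an exact certificate $(v, a)$, which is re-verified
  against the definition before being returned. This is equivalent to, and
  replaces, enumerating the cone of weak separators and testing a relative
  interior point: the slack sum is linear on that cone, so it is positive
  somewhere iff it is positive at a relative interior point.
  `relative_interior_point()` (generator sum via double description) is
  nevertheless provided, and the two routes are cross-checked in the tests.

Certificates are not unique; the solver's canonical certificate will
generally differ from a hand-chosen one, so external certificates should be
checked with `verify_hyperplane()` rather than compared for equality.

## Verdicts and degenerate inputs

* `PATH_CONNECTED` — a strict separating hyperplane exists for the original
  network or for a valid reduction.
* `EMPTY_REGION` — the critical polynomial has no negative coefficients (no
  parameter pair enables multistationarity, so the region is empty and
  trivially path connected). The same verdict is used for inconsistent
  networks, which have no positive steady states at all; this extends the
  empty-support case to the situation where the parametrization itself is
  empty.
* `PRECONDITION_FAILED` — conservativity or the siphon criterion could not
  be established; reported as inconclusive-with-reason.
* `INCONCLUSIVE` — no strict separating hyperplane (for the original and,
  under the automatic fallback, the reduced network). The region may still
  be path connected; the criterion is sufficient, not necessary.

Networks where reactant and product coincide are rejected at construction;
empty complexes (`0`) are allowed; a trivial left kernel simply yields a $W$
with zero rows.

## The corpus and what passing it shows

`example_network()` builds the cell-signaling corpus: the running example,
the cell-cycle module and hybrid histidine kinase (pinned to their published
species orders and matrices), $m$-site sequential distributive
phosphorylation cycles with one or with per-site phosphatases, weakly and
fully weakly irreversible 2-site cycles, the ERK dual-site network, the
shared-kinase and MAPK two-layer cascades, and the allosteric and covalent
reciprocal-regulation motifs. Where a source prints matrices, the builders
reproduce them entry for entry; the remaining mechanisms are reconstructed
from the cited literature and validated against the published species,
reaction, extreme-ray and signed-support counts. For the covalent
reciprocal-regulation motif no reaction list is published; the builder uses
a mechanism selected by an automated search to match every published count
for that network simultaneously, and its docstring marks the mechanism as a
reconstruction.

Two findings from this corpus are worth knowing:

* For the cell-cycle module, the siphon $\{C, M\}$ (a consequence of the
  catalytic reactions) admits no supported conservation vector, and the
  network genuinely has a relevant boundary steady state
  $(0, c_1, 0, c_2, c_3, 0)$. The sufficient criterion therefore honestly
  reports `FALSE` for this fixture, and the pipeline verdict is
  inconclusive even though the polynomial-level computations (the six-term
  critical polynomial and its certificate) are reproduced exactly.
* For the running example at $\kappa = (18, 1, 10)$, the class $Wx = 3$
  carries three steady states; the sign function is negative at the middle
  one, $x \approx (0.558, 2.442)$.

These are exact symbolic computations on fixed networks, so passing tests
carry no sampling caveat; what they do *not* show is anything about networks
outside the mass-action/conservative setting, about kinetics with
non-integer exponents, or about the region's shape beyond connectivity.

## Problem sizes and budgets

The test suite and the reproduction script run everything at the published
sizes: the largest routine computations are the ERK network (18,472
monomials in 21 variables, about 20 s including its hyperplane certificate)
and the fully weakly irreversible cycle (19,968 monomials, decided NO). The
default term budget of $10^6$ accommodates all of these; tests exercise the
budget error path with a deliberately undersized budget. The exact simplex
handles the 20k-constraint hyperplane problems in seconds because its basis
size is bounded by the support dimension plus two, independent of the number
of exponents.

## Known limitations

* The hyperplane criterion is sufficient only; `INCONCLUSIVE` is common for
  networks whose negativity region is connected but not hyperplane-certified
  (the fully weakly irreversible cycle is the canonical example).
* Only the reverse-unbinding reduction pattern is implemented; general
  intermediate elimination or quasi-steady-state reductions are out of
  scope, as are disconnectedness certificates and component counts.
* Exponent packing in the determinant expansion supports up to 12 extreme
  rays and 31 species; beyond that the expansion refuses and suggests
  reduction (the 5-site full cycle, with 15 rays, requires reducing first).
* SBML import is not provided; the plain-text reaction format and the
  programmatic constructor are the interfaces.
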