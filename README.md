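# crnconnect

Symbolic certification that the **multistationarity region** of a mass-action
reaction network is **path connected**.

For a network with stoichiometric matrix `N` (rank `s`), reactant matrix `A`
and conservation matrix `W`, a pair (rate constants κ, total concentrations
c) *enables multistationarity* when the compatibility class `{x ≥ 0 : Wx = c}`
carries two or more positive steady states. Whether the set of such pairs is
connected decides which kinds of bistable switches the network can implement:
a connected region gives ordinary hysteresis, a disconnected one allows
switching regimes with distinct mechanistic origins.

`crnconnect` decides connectivity without computing the region:

1. **Preconditions** — conservativity (`w > 0`, `wN = 0`) and exclusion of
   relevant boundary steady states via minimal siphons, both by exact
   rational feasibility.
2. **Critical polynomial** — with extreme rays `E` of the flux cone
   `ker N ∩ R^r_{≥0}`, expand `(−1)^s det M̃(h, λ)` exactly, where `M̃` is
   `N diag(Eλ) Aᵀ diag(h)` with the pivot rows replaced by the rows of `W`.
   Its negative values on the positive orthant mark multistationarity.
3. **Strict separating hyperplane** — if a hyperplane `v·μ = a` puts the
   positive-coefficient exponents on one closed side, the negative ones on
   the other, and not all negative exponents on the hyperplane, the region
   is path connected. The decision is one exact rational linear program.
4. **Reduction** — removing the reverse reaction of a reversible binding
   step whose intermediate occurs in exactly three reactions preserves the
   conclusion and can shrink the polynomial by orders of magnitude.

All arithmetic is exact (rationals over guarded 64/128-bit integers); no
sign is ever decided in floating point.

## Worked example

The three-reaction network `X1 → X2, X2 → X1, 2X1 + X2 → 3X1`:

```r
library(crnconnect)
net <- parse_network("X1 -> X2
                      X2 -> X1
                      2 X1 + X2 -> 3 X1")
check_connectivity(net)
#> n = 2
#> r = 3
#> The reaction network is conservative.
#> There are no relevant boundary steady states.
#> l = 2
#> Number of positive coefficients: 3
#> Number of negative coefficients: 1
#> The support set has a strict separating hyperplane.
#> All the conditions are satisfied.
#> We conclude that the parameter region of multistationarity
#> is path connected.
```

`n`, `r`, `l` are the numbers of species, reactions and extreme rays of the
flux cone. The critical polynomial here is `−h1λ1 + h1λ2 + h2λ1 + h2λ2`
(three positive coefficients, one negative), its signed support admits a
strict separating hyperplane, and the multistationarity region — the cusp
region visible in `(κ, c)` space for this classic example — is path
connected. Intermediate objects are available individually:

```r
sd <- stoichiometry(net)
fc <- extreme_rays(sd$N)       # rays (1,0,1) and (1,1,0)
cp <- critical_polynomial(sd, fc)
glance(cp)                     # terms, sign counts
find_strict_separating_hyperplane(signed_support(cp))
```

A corpus of published cell-signaling motifs is built in via
`example_network()` — phosphorylation cycles (`phospho_cycle(m)`),
cascades (`shared_kinase`, `mapk_two_layer`), the ERK network, and the
reciprocal enzyme-regulation motifs — each validated against its published
species/reaction/ray counts and signed-support sizes.

A command-line front end is installed with the package:

```sh
crnconnect check network.txt --report json
```

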