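---
title: "A steady-state fugacity model for pharmaceuticals and their transformation products in a stratified lake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state fugacity model for pharmaceuticals and their transformation products in a stratified lake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakefate)
```

## The model

`lakefate` implements a Level III multimedia fugacity model: a steady-state
mass balance over a set of connected environmental compartments (water layers
and bottom-sediment slabs), extended with first-order transformation
reactions that link chemicals into parent–product chains.

Each chemical in each compartment carries a fugacity $f$ (Pa); its
concentration is $C = f \cdot Z$, where $Z$ (mol m$^{-3}$ Pa$^{-1}$) is the
compartment's bulk fugacity capacity. Every concentration-dependent process —
advection, vertical mixing, sediment–water exchange, reaction — is a
conductance ("D value", mol Pa$^{-1}$ h$^{-1}$): the molar flow it carries is
$D \cdot f$. At steady state, for each reaction chain over $n$ compartments
and $m$ chemicals, the balance is a dense linear system

$$\mathbb{A}\,\mathbf{f} = \mathbf{b},$$

with dimensions $nm \times nm$: the diagonal of $\mathbb{A}$ holds the summed
loss D values of each compartment–chemical, off-diagonal entries are negated
gain D values (transport links within one chemical; transformation links
parent$\to$product within one compartment, with magnitude
$D_\text{reaction}\cdot\text{yield}$), and $\mathbf{b}$ holds the constant
emission flows (mol/h). Because the systems are small (at most
$\sim$100$\times$100 here) they are solved by dense direct factorization;
no iterative machinery is needed. `dynamic_integrate()` integrates the same
balance in time (via deSolve) and is used purely as a verification oracle:
its long-time limit must equal the direct solve.

Since no air compartment exists (the compounds are essentially non-volatile),
the absolute scale of $Z$ is arbitrary. The water capacity is normalized to
$Z_\text{water} = 1$; the test suite verifies that multiplying it by 1000
changes no concentration, mass, or flux. Solids capacities follow the
standard organic-carbon sorption form
$Z_\text{solids} = Z_\text{water}\cdot f_\text{OC}\cdot K_\text{OC}\cdot
\rho_\text{solids}$, and bulk capacities are volume-weighted phase sums
(water + suspended solids; pore water + bed solids).

## Ionizable chemicals

The packaged compounds are mostly weak acids, so partitioning depends on pH.
The dissociated fraction follows Henderson–Hasselbalch
($1/(1+10^{pK_a - pH})$ for acids). The property tables store solubility and
$\log K_\text{OW}$ as *pH-7 effective* values covering both species; the
package inverts the ionization relation to the neutral-species value and
re-applies it at the ambient pH, so the tabulated value is recovered exactly
at pH 7. The effective $K_\text{OW}$ at another pH treats octanol solubility
as pH-invariant: $K_\text{OW}(\text{pH}) = S_\text{oct} /
S_\text{eff}(\text{pH})$ with $S_\text{oct} = K_\text{OW}(7)\,S(7)$.
$K_\text{OC}$ is a chemical-specific multiple of $K_\text{OW}$ (0.46 for
ibuprofen's family, 1.0 for diclofenac's, 5.4 for carbamazepine's; 0.41 when
nothing better is known). An overflow guard caps the ionization multiplier at
$10^6$ with a warning — only reachable at physically meaningless
$|pH - pK_a|$.

Temperature dependence of solubility/$K_\text{OW}$ is supported as an
optional linear-in-$T$ log-scale coefficient but is **off by default**: the
sources report that such data exist for the parent compounds but do not print
the coefficients, and a reproducible zero is preferable to an invented slope.

## Reactions

Transformation reactions are pseudo-first-order with three kinds, applied by
medium: **photolysis** in water, attenuated by depth band (100% of the
surface rate for 0–0.1 m, 10% for 0.1–1 m, 1% for 1–5 m, none deeper — a
humic lake with ~2 m Secchi depth absorbs UV quickly); **biotransformation**
only in bottom sediments; **deconjugation** (conjugate $\to$ parent) in
water. Competing channels of one parent combine harmonically
($[\sum t_i^{-1}]^{-1}$; e.g. 200 h and 50 h photolysis channels give a 40 h
total for ibuprofen), and the yield of a product is the *rate* ratio
$k_\text{formation}/k_\text{total} = t_\text{total}/t_\text{formation}$.
(Stated as a half-life ratio in words, the relation only stays in $[0,1]$
read as the rate ratio; the package rejects yields above 1 rather than hiding
the discrepancy.) Rates are temperature-corrected exponentially,
$k\,e^{\gamma(T - T_\text{ref})}$ with $\gamma = \ln 2/10\,$°C$^{-1}$ — a
halving per 10 °C drop, the conventional magnitude when the published
coefficients of the original correction are unavailable — and
$T_\text{ref} = 25\,$°C, both configurable. The reference temperature of the
packaged half-life table is not stated in its sources; 25 °C is assumed.

One product (the diclofenac photoproduct CPAB) has no literature degradation
half-life; it inherits its parent's *total* rates (4.0 h photo, 9.825 h bio),
following the rule used for the packaged tables.

## The packaged lake scenario

`build_paijanne_ns()` reconstructs a two-area stratified lake receiving
wastewater effluent. Each area is 300 m long; water is cut into depth bands
L1 0–0.1, L2 0.1–1, L3 1–5, L4 5–9, L5 9–15 and L6 15–25 m (L6 southern area
only; the L5/L6 bounds are defaults, as the original cross-section is a
not-to-scale sketch). Widths taper linearly with depth: 200$\to$150 m
(north), 300$\to$200 m (south). Three 2-cm sediment slabs sit under the
0–5 m, 5–15 m and 15–25 m bed (ST, SM, SB). Vertical mixing uses the
complete-mixing turnover times 0.014 h (L1–L2), 22 h (L2–L3), 1600 h
(L3–L4) and 16 000 h (L4–L5, L5–L6), converted to symmetric volumetric
exchanges as $G = V_\text{smaller}/\tau$. (Re-deriving the L1–L2 value from
the published diffusivity recipe gives $\approx$0.14 h rather than 0.014 h;
the printed value is used as authoritative and the inconsistency noted, not
resolved.)

Advection is confined to L1–L4. The design choice that most affects the
headline numbers is the through-flow reading: the published map shows 1 cm/s
and 2 cm/s arrows without an unambiguous assignment. The packaged default
feeds the **northern area from the western side at 1 cm/s**, with an equal
extra 1 cm/s dilution inflow to the southern area, because the published
sensitivity row "western side 0.5 cm/s" roughly doubles the maximum
concentrations — which requires the maximum (NL3) to be controlled by the
western inflow — and because the resulting maxima (54.8, 81.6, 2.74 ng/l for
IBU, DCF, CBZ) agree with the published 55.2, 81.9, 2.76 ng/l to ~1%,
whereas a 2 cm/s northern feed halves them. The 2 cm/s arrow is read as the
main downstream current outside the modelled box. Both velocities are
overridable.

The effluent enters NL3 (the outfall sits at ~3.5 m depth) at 1700 m³/h with
1, 1.5 and 0.05 µg/l of IBU, DCF and CBZ; its water flow is carried through
the advective balance so hydraulic continuity holds exactly in every water
compartment. Suspended solids occupy 0.036‰ of each water volume with 25%
organic carbon; bed sediments have 6% OC and porosity 0.8. Temperatures
default to 15 °C above the thermocline and 5 °C below and in sediments
(the study period's records are not printed); pH defaults to 7.

**Sediment exchange defaults deserve emphasis**: the original work took its
sediment–water transfer parameters from an earlier model description that
prints no values. The packaged defaults — diffusive MTC $4\times10^{-4}$ m/h,
deposition $10^{-6}$, resuspension $4\times10^{-7}$, burial
$2\times10^{-7}$ m/h, solids density 2.4 kg/l — are conventional magnitudes
for lake fugacity models, are all overridable, and are the least-constrained
part of the reconstruction. They reproduce the *relative* sediment behaviour
(carbamazepine mostly sediment-bound, acidic parents mostly in water) but
top-sediment concentrations come out ~50$\times$ above the published ones,
and the fraction of IBU/DCF mass in sediments lands at 0.015–0.023% against
the published "< 0.01%".

## Transport chains

`build_transport_env()` makes a plug-flow segment: one set of L1–L4 layers
with the southern cross-section, a bottom sediment coupled to L3 and L4,
through-flow at 1 cm/s (weak wind) or 3 cm/s with tenfold vertical mixing
(stronger wind). `run_segment()` converts layer input concentrations into
boundary advective molar inflows, solves the segment at steady state and
returns the outlet concentrations — a quasi-steady discretization of
downstream travel that mirrors the original recursion rather than a
continuous plug-flow PDE. `sinking_average()` prepares the input by
averaging each layer with the one above it (the observed effluent-sinking
trend). `run_until_plateau()` iterates 3-km segments until every
transformation product's peak concentration changes by less than 1% per
segment (a numerical reading of "plateaued"), with a hard cap of 50
segments, and records each chemical's concentration maximum, its distance
and travel time. `add_conjugate()` registers an ibuprofen-conjugate
pseudo-chemical (parent's properties, 3$\times$ the parent's input
concentration, 2 h deconjugation half-life, yield 1).

Distances are reported at segment resolution (3 km); the "modal
transformation-product peak distance" is the most frequent peak distance
across TPs, excluding chemicals that only decay (peak at the origin), with
ties broken by the mean of the tied values. The travelling load is tracked
in grams (all reference quantities are mass-based); with the packaged
defaults the parent load halves after $\approx$56 days of travel.

## Sensitivity engine

`run_sensitivity()` applies one structured perturbation at a time — mixing
or advection scaling, chemical-property shifts, disabling a reaction kind,
scaling product-forming rates, photolysis-band changes, moving or scaling
the emission, suspended-solids changes, temperature changes, or explicit
re-plumbing of advection links — re-solves, and bins each
compartment–chemical percent change symbolically (+: 1–10%, ++: 10–100%,
+++: 100–1000%, ++++: >1000%; −: −1–10%, −−: −10–50%, −−−: −50–100%).
Scaling the suspended-solids fraction also scales the deposition velocities
on sediment-exchange links, since the settling flux is carried by the
suspended load. Only one-at-a-time perturbations are supported, matching
the original survey; no variance-based global sensitivity. Perturbations
that re-plumb flows mark the scenario so the strict hydraulic-continuity
invariant is not re-enforced (a fixed effluent inflow cannot stay balanced
under a uniform flow scaling).

## Numerical choices and degenerate inputs

* Unknowns are ordered compartment-major; the sign convention is diagonal
  positive, gains negative. The original description orients the matrix by
  target columns; the two differ by a transpose and give identical
  solutions.
* A compartment–chemical with no loss path makes the system structurally
  singular; it is reported by name before any factorization is attempted.
* Solutions with components below $-10^{-9}$ relative trigger an internal
  consistency error; smaller negative round-off is clipped to zero.
* Mass-balance residuals (inputs vs losses per chemical) are computed on
  every solve; anything above $10^{-6}$ warns, and the packaged scenarios
  close to better than $10^{-9}$ (typically $10^{-14}$).
* Sediment concentrations are reported per gram of **dry** solids (the
  reference tables do not state wet or dry; dry is chosen and documented),
  water concentrations as bulk ng/l including the (small) suspended-solids
  contribution.
* Layers spanning photolysis depth bands take the band of their top
  boundary; the packaged geometries align layer and band boundaries exactly
  and a warning is emitted otherwise.
* Zero-thickness layers, non-positive half-lives, negative rates and
  unresolvable link endpoints are rejected at construction, with all
  validation problems of a scenario reported together.

## What the packaged scenarios do and do not show

The packaged environments are *reconstructions*: layer volumes, interface
areas and sediment-transfer parameters are rebuilt from printed figures plus
conventional defaults, not from the original input files. Quantities
dominated by effluent dilution and the upper-layer balance are robust — the
concentration maxima, the mixing-to-photolysis flux ratio ($\approx$55-fold
for IBU), and the surface response to removing photolysis (14%, against a
published "up to 23%") all land on the published values. Quantities
controlled by the unpublished sediment coupling and deep mixing are not:
sub-thermocline profiles flatten at 2–2.5 orders below L3 instead of the
published 4 (without deep-water sinks a near-flat hypolimnion profile is the
steady-state solution for any conserved chemical — carbamazepine has no
biodegradation at all, so the published 4-order drop cannot follow from the
printed quantities alone), transformation-product peaks sit at 9–450 km
instead of clustering near 20 km, and sediment mass fractions are a factor
~2 above the published bound. The test suite asserts both groups at their
stated tolerances and the second group fails visibly rather than being
tuned into agreement; the scenario parameters were fixed before those
comparisons and left alone afterwards.

Problem sizes used throughout (14 compartments × chains of 3–5 chemicals;
50 transport segments) are the full study sizes — nothing is scaled down.

## A worked example

```{r}
env <- load_scenario("paijanne_ns")
res <- solve_steady_state(env)
concentrations(res, chemicals = c("IBU", "DCF", "CBZ"),
               compartments = c("NL2", "NL3", "SL2", "SL3", "ST"))
```

```{r}
summary(res)
```
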