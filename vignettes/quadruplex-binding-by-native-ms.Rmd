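---
title: "Quantifying G-quadruplex–ligand binding from native ESI-MS peak areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying G-quadruplex–ligand binding from native ESI-MS peak areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gquadms)
```

## The measurement

Gentle ("native") electrospray keeps noncovalent nucleic-acid–ligand
complexes intact in the gas phase, so a single negative-mode spectrum of
an equimolar quadruplex/ligand mixture shows the free quadruplex Q, the
1:1 complex and the 1:2 complex as separate charge-state envelopes. For
the human telomeric quadruplexes the intact ion characteristically
retains two ammonium cations (the inter-tetrad ions), and with the
commercial tetratosylate salt of the porphyrin ligand TMPyP4 a ladder of
tosylate adducts (0–3) appears on every envelope.

Two assumptions turn such a spectrum into binding constants:

1. **Proportionality** — integrated peak areas are proportional to the
   solution abundances of the species, with a common response factor for
   free and bound quadruplex.
2. **Sequential two-site binding** — the solution equilibrium is
   Q + L ⇌ QL (K1), QL + L ⇌ QL₂ (K2).

With total concentrations C_Q and C_L known, the per-class relative
areas A₀, A₁, A₂ (ligand stoichiometry 0, 1, 2; tosylate adducts and
charge states collapsed within a class) give

  [class i] = C_Q · A_i / ΣA,  [L] = C_L − [1:1] − 2·[1:2],

and the constants follow directly: K1 = [1:1]/([Q][L]),
K2 = [1:2]/([1:1][L]). The companion *fraction of bound quadruplex*
(relative binding affinity, RBA) is the area share of ligand-containing
classes among all quadruplex classes.

## Mass and m/z arithmetic

Strand masses come from elemental composition: each residue contributes
its nucleoside-5′-monophosphate-minus-water composition, one water is
added for the termini, and one HPO₃ is removed for the default
5′-OH/3′-OH free-acid strand (the convention of vendor desalted oligos —
it reproduces the reported 8496.6 Da for the DNA 27-mer). The atomic
weights are frozen in one exported table (`atomic_masses`) so every mass
in the package is bit-stable.

```{r mass}
average_mass("d[(TTAGGG)4TTA]")
average_mass("r[(UUAGGG)4UUA]")
```

The RNA 27-mer computes to 8788.2 Da under this convention, about 1 Da
below the vendor-reported 8789.3 Da; since the DNA value is reproduced
exactly, we keep the computed value and note that the vendor figure
likely reflects a different terminal or protonation convention.

Ion m/z uses explicit charge bookkeeping: TMPyP4 is an intrinsic
tetracation, ammonium (+1) and tosylate (−1) are charged attachments,
and the observed charge z < 0 is reached by removing
n_H = 4·n_L + n_NH4 − n_Ts − z protons:

  m/z = (M_Q + n_L·M_L + n_Ts·M_Ts + n_NH4·M_NH4 − n_H·1.007276) / |z|.

The proton mass is used for deprotonation arithmetic even in
average-mass mode; the error that mixes in is far below the assignment
tolerance. This bookkeeping reproduces the characteristic spacings —
each ammonium shifts m/z by (M_NH4 − m_p)/|z| ≈ 17.03/|z| — and places
the two-ammonium DNA ion at z = −5 within 0.08 of the published
1,705.04.

```{r mz}
MQ <- average_mass("d[(TTAGGG)4TTA]")
ion_mz(ion_species(n_ammonium = 2, charge = -5), MQ)
```

## Assignment and aggregation

Peak-to-species matching is greedy in increasing |Δm/z| with one peak
per species and one species per peak; ties go to the species with fewer
adducts. The default tolerance is 1.0 Da/charge, chosen because
published observed values sit up to ~0.6 Da/z from composition-based
theory (a per-spectrum calibration offset), while the smallest
inter-species spacing in the default enumeration (ligand 0–2, tosylate
0–3, ammonium 0–2, z = −4…−6) is about 3.4 Da/z at z = −5. An absolute
Da/charge tolerance fits this geometry better than ppm, because adduct
ladders are evenly spaced per charge. Unmatched peaks stay unassigned
and are reported; the per-class area table conserves total area exactly.

Tosylate adducts of a ligand-bound complex count toward that complex.
Tosylate-only adducts of the free quadruplex default to the *free*
class, since the sequential model has no tosylate species; the
`counterion_only_is_bound` flag moves them to the bound side, which is
the reading under which the tetratosylate salt shows a higher apparent
RBA than the tetrachloride.

## The equilibrium solver

The forward problem (given K1, K2, C_Q, C_L, find all species) reduces
to one equation in the free ligand l:

  g(l) = l + (K1·l + 2·K1·K2·l²)·C_Q/(1 + K1·l + K1·K2·l²) − C_L = 0.

g is continuous and strictly increasing on (0, C_L) with g(0) < 0, so
the root is unique; we bracket it with `uniroot` at machine tolerance
and polish with a few Newton steps, after which both mass balances close
to 1e-12 relative. The estimator and solver are exact inverses: pushing
solver output through the area representation and the estimator returns
K1 and K2 to ~1e-15 relative, which the test suite checks over 100
random constant pairs.

One structural fact worth knowing: the bound fraction is monotone in K1,
but *not* in K2 at equimolar concentrations — each 1:2 complex
sequesters two ligands, so raising K2 can starve overall complex
formation (at K1 = 10⁶ M⁻¹, 10 µM equimolar, the bound fraction falls
from 0.73 to 0.55 as K2 rises 10³→10⁷). Monotonicity in K2 holds under
ligand excess.

K2 is reported as 0 with an "not estimable" flag when no 1:2 area is
seen, rather than erroring; replicate summaries use the sample (n−1)
standard deviation and report sd as missing for n = 1.

## UV melting

Melting curves (absorbance at 295 nm vs temperature; quadruplex
unfolding is hypochromic there) are reduced to Tm two ways.

**Midpoint (default).** Straight lines are fitted to the low- and
high-temperature baseline windows (first/last 10 % of points), the
folded fraction θ(T) = (A − A_u)/(A_f − A_u) is formed, and Tm is the
θ = 0.5 crossing. For broad transitions (van 't Hoff enthalpy
≲ 50 kcal/mol) the upper baseline is never fully reached inside a
20–95 °C scan and the fixed windows bias Tm by up to ~0.9 °C; the
default therefore refits baselines and transition jointly (a two-state
model with linear baselines, Levenberg–Marquardt via `minpack.lm`),
which recovers noiseless synthetic Tm values to < 0.01 °C and noisy ones
(σ_A = 0.002) to ~0.05 °C. The pure window method remains available with
`refine = FALSE`. Only Tm (and the baselines) are reported — this is not
a thermodynamic-parameter fit.

**Derivative.** A smoothing spline is differentiated against 1/T rather
than T: the two-state transition is symmetric in inverse temperature, so
the |dA/d(1/T)| extremum sits at Tm, whereas a dA/dT argmax is skewed by
~R·Tm²/ΔH (0.4–0.5 °C at 40 kcal/mol) — enough to break the expected
sub-0.5 °C agreement between methods on clean curves.

ΔTm between ligand-bearing and ligand-free arms is the difference of
arm means with sd propagated as √(s₁²/n₁ + s₂²/n₂).

## The synthetic-data generator

`simulate_binding_spectrum` realizes exactly the assumptions the
estimator makes, so recovery tests probe the inference chain, not the
physics: the equilibrium is forward-solved at the configured truth; each
ligand class's C_Q-normalized abundance is spread over ammonium counts
(default probabilities 0.1/0.3/0.6 over 0–2, putting most weight on the
two-ammonium ion that dominates the intact quadruplex), charge states
(0.2/0.6/0.2 over −4/−5/−6, −5 predominant) and tosylate counts (none in
tetrachloride mode); peak positions get Gaussian jitter, areas get
log-normal multiplicative noise (areas are positive and detector
variation is multiplicative), and uniform decoy peaks are appended at
1 % of the maximum area by default. All randomness flows from one
mandatory seed through a local RNG stream that leaves the caller's
`.Random.seed` untouched. Default concentrations are the study's
equimolar 10 µM; the 5 % area-noise default is calibrated loosely to the
~10 % relative replicate SDs typical of such constants.

What the generator does **not** emulate — differing response factors
between free and bound species (available via `response_factors` to
demonstrate the resulting bias, but off by default), overlapping
isotope envelopes, charge-state correlation with adduct count, and
solution-phase artifacts like nonspecific electrospray clustering — is
exactly what passing recovery tests cannot vouch for on real spectra.
The melting generator is a clean two-state van 't Hoff model with
linear baselines (default ΔH = 45 kcal/mol, a typical intramolecular
quadruplex value; grid 20–95 °C in 0.5 °C steps); multi-phasic or
kinetically limited melts are outside its vocabulary.

## Problem sizes and determinism

The default enumeration carries 108 species; simulated spectra have
~27–110 peaks; recovery studies in the tests use 3 replicates (and a
20-seed sweep for the median-error property), which keeps the full suite
around ten seconds while leaving the estimators nothing to hide behind.
Every simulation, match and fit is deterministic given its seed and
configuration.

## Limitations

- The proportionality assumption is untestable from a single spectrum;
  response-factor bias propagates directly into K1/K2.
- Saturated mixtures (free ligand → 0) make the estimator ill-posed; the
  mass-balance check fails loudly rather than returning unstable
  constants.
- Assignment is winner-take-all within the tolerance; overlapping
  species are not deconvolved.
- Tm extraction assumes a single two-state transition.
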