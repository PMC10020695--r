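---
title: "Beta-turn geometry and autoproteolysis kinetics with lexturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-turn geometry and autoproteolysis kinetics with lexturn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexturn)
```

## Background

LexA is the transcriptional repressor of the bacterial SOS regulon. Upon
DNA damage, activated RecA filaments stimulate LexA self-cleavage at the
Ala-84/Gly-85 scissile bond inside a flexible loop, the cleavage site
region (CSR, residues ~79-95), releasing repression of the SOS genes.
Small molecules that block this autoproteolysis are candidate
anti-evolution adjuvants to antibiotics. Two quantitative analyses sit at
the heart of that inhibitor-discovery workflow, and this package
implements both:

1. **Turn geometry.** The CSR around residues 83-86 forms a classical
   beta-turn. Characterizing it — central torsions, the
   C-alpha(i)-C-alpha(i+3) distance, the i -> i+3 hydrogen bond, and the
   standard type assignment — motivates screening beta-turn
   peptidomimetics against the cleavage pocket.
2. **Cleavage kinetics.** Band-intensity time courses from RecA-mediated
   cleavage reactions, run across an inhibitor dilution series, are
   reduced to per-condition first-order rate constants and then to a
   single effectiveness parameter and dissociation constant for the
   inhibitor.

## Beta-turn detection and classification

A 4-residue window i..i+3 of consecutively bonded residues (C-N distance
at most 2.0 Å; torsions are never computed across larger gaps) is a
candidate turn when the C-alpha(i)-C-alpha(i+3) distance is at most 7.0 Å,
the classical detection criterion. Classification uses only the phi/psi
pairs of the two central residues, compared with the canonical values of
the eight named types:

| type | phi(i+1) | psi(i+1) | phi(i+2) | psi(i+2) | requires cis omega(i+2) |
|------|------|------|------|------|-----|
| I    | -60  | -30  | -90  | 0    | no  |
| I'   | 60   | 30   | 90   | 0    | no  |
| II   | -60  | 120  | 80   | 0    | no  |
| II'  | 60   | -120 | -80  | 0    | no  |
| VIII | -60  | -30  | -120 | 120  | no  |
| VIa1 | -60  | 120  | -90  | 0    | yes |
| VIa2 | -120 | 120  | -60  | 0    | yes |
| VIb  | -135 | 135  | -75  | 160  | yes |

A window matches a type when all four angles are within 30 degrees of the
canonical values, with at most one angle allowed out to 45 degrees (the
`relaxed` flag records when that allowance was used); differences are
taken on the circle, so classification is invariant to 360-degree wraps.
Types are tried in fixed table order with all-strict matches preferred
over relaxed ones, VI types are eligible only when the peptide bond into
i+2 is cis (omega within 30 degrees of 0), and type IV is the catch-all.
These canonical values and tolerances are the established
literature convention; newer clustering-derived nomenclatures (e.g. the
SC2-SC10 family) carry no agreed canonical table, so they are supported
only through user-supplied extension rows in `turn_type_table(extra =)`.

Helix exclusion (`exclude_helical`) is optional and purely torsion-based
(both central residues in phi in [-100, -30] and psi in [-80, -5]); it is
off by default because turn analysis here targets a short loop, not a
whole fold.

### Hydrogen-bond geometry

Crystallographic backbone coordinates carry no hydrogens, so the
O(i)...H(i+3) distance requires a constructed amide hydrogen. The package
places H 1.01 Å from N(i+3), in the peptide plane, opposite the bisector
of the N->C(i+2) and N->C-alpha(i+3) bond directions — the standard
idealized in-plane placement. Prolines at i+3 have no amide hydrogen and
report only the heavy-atom O...N distance. Because the placement is
idealized, O...H distances should be read with ~0.1-0.2 Å slack.

### Reconstruction versus crystal geometry

The package builds test structures from prescribed torsions with fixed
ideal covalent geometry (bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329,
C=O 1.231 Å; angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees) by
sequential internal-to-Cartesian placement. Torsions recomputed from a
built chain reproduce the prescription to better than 1e-6 degrees, which
is the builder/analyzer consistency the test suite enforces.

One consequence worth stating plainly: torsions alone do not determine
inter-residue distances. Rebuilding the CSR turn from its published
phi/psi values under ideal covalent geometry yields a
C-alpha(83)-C-alpha(86) distance of about 4.96 Å and an O...H distance of
about 2.22 Å, whereas the deposited crystal structure — with its
non-ideal, refined bond angles — shows 5.405 Å and 2.610 Å. Distance-level
agreement with the crystal therefore requires the deposited coordinates
themselves; the reconstruction validates the torsion pipeline and the
type assignment (the rebuilt turn classifies as type II either way), not
the crystal's exact distances.

## The kinetics model

Autoproteolysis consumes the protein in a unimolecular reaction, so the
uncleaved fraction follows the integrated first-order rate law

$$\frac{[\mathrm{LexA}]}{[\mathrm{LexA}]_0} = e^{-kt}.$$

Band intensities are normalized by the t = 0 aliquot, which pins
f(0) = 1; the model therefore has a single free parameter and no floating
amplitude or offset. `fit_first_order()` minimizes unweighted residuals
on the fraction scale (no error model is assumed for densitometry),
initialized from the exact through-origin log-linear slope
$\hat k = -\sum_j t_j \log f_j / \sum_j t_j^2$ and constrained to
k >= 0; non-decaying data yield a flagged k = 0 boundary fit. On
noiseless exponential data the initializer is already exact, so the fit
recovers k to numerical precision.

Across an inhibitor titration, with r = [I]:[LexA] the molar ratio, the
per-condition rate constants follow

$$k_i = \frac{k_0}{1 + r/\Phi},$$

where k_0 is the uninhibited rate constant and the effectiveness Phi is
the molar ratio at which the rate halves: k_i(Phi) = k_0/2 identically.
The curve is strictly decreasing in r for positive parameters and
k_i(0) = k_0. Fitting is per-condition-k-first, then Phi — the two-stage
structure mirroring how titration experiments are read — with a joint
`fix_k0` mode available when the control rate is known. All k_i equal is
flagged as "no inhibition signal" with Phi reported as infinite rather
than as an arbitrary large number.

Under 1:1 binding, Phi rescales to a dissociation constant by
K_d = Phi × [LexA]_0. The protein concentration is an explicit input:
for 15 ug of protein in a 100 uL reaction at the default monomer weight
of 22,358 Da, [LexA]_0 = 6.709 uM and Phi = 43.422 gives
K_d = 291.3 uM. A published K_d of 286.36 uM for that same Phi implies
[LexA]_0 = 6.595 uM, i.e. an effective molecular weight near 22.7 kDa —
within the plausible 22.3-22.8 kDa band for the construct, which is why
the conversion keeps the molecular weight overridable instead of
hard-coding one.

### Uncertainty

`bootstrap_effectiveness()` case-resamples the (ratio, k) pairs and
refits, reporting 95% percentile intervals; it is deterministic given its
seed. Resamples with fewer distinct ratios than free parameters are
skipped and counted. The internal refitter does not insist on a ratio-0
point (unlike the exported fit, where the control anchors k_0), because
with n = 6 conditions roughly a third of resamples would otherwise be
discarded and the intervals biased. With small n, percentile intervals
from case resampling are known to run slightly anti-conservative; the
simulation study below measures the realized coverage rather than
assuming the nominal level.

## What the synthetic generator emulates

`simulate_cleavage_series()` reproduces the titration design: a two-fold
inhibitor dilution series 1000, 500, 250, 125, 62.5 uM plus a control,
aliquots at 0-25 minutes in 5-minute steps, protein at the molarity of
15 ug per 100 uL reaction (6.709 uM), k_0 = 0.1/min and Phi = 43.422 as
the reference parameter values. Noise is additive Gaussian on the
fraction scale (default sd 0.03), clipped at zero, with the t = 0 anchor
left noise-free because normalization makes the initial aliquot part of
every data point; a multiplicative log-normal alternative sits behind
`noise_model = "lognormal"`. All generators are pure functions of their
seed.

What this does not emulate: correlated densitometry errors within a gel,
lane-loading artifacts, background subtraction, partial RecA activation,
or inhibitor depletion at high protein loads. Parameter-recovery results
on the simulation therefore demonstrate estimator correctness and
calibration under a clean error model, not robustness to every gel-level
artifact.

The reference simulation study used throughout (tests and the acceptance
script) runs 200 seeded replicates of the full design with a
1000-replicate bootstrap each: median relative error of the recovered Phi
is about 6-7% and realized 95%-interval coverage lands at 90-92%,
consistent with mildly anti-conservative small-n percentile intervals.

## Screen bookkeeping and hydropathy

`hit_rate()` keeps the raw percentage alongside a half-up 2-decimal
display form. The virtual hit rate divides compounds selected for
purchase by compounds docked; the in-vitro hit rate divides active
compounds by compounds tested. With 133 selected from 2276 + 8607 docked
and 1 active of 133 tested, these display as 1.22% and 0.75%.
`hydropathy_profile()` embeds the published Kyte-Doolittle scale
(-4.5 for Arg to +4.5 for Ile) with a centered sliding-window mean;
edges narrower than the half-window are undefined rather than padded.

## Numerical choices

- Angles are degrees everywhere, reported in (-180, 180], with circular
  differences for all comparisons.
- Dihedrals follow the IUPAC sign convention (cis = 0, trans = 180),
  cross-checked in the tests against an independent torsion
  implementation.
- Alternate locations resolve to the highest-occupancy conformer, ties
  broken by the alphabetically first altloc code; model 1 of multi-model
  files is the default.
- Nonlinear fits use Levenberg-Marquardt (minpack.lm) with tight
  convergence tolerances (ftol = ptol = 1e-14) so that noiseless inputs
  are recovered to reporting precision; rate constants and Phi are
  box-constrained positive.
- Ties in classification resolve by fixed table order; strict beats
  relaxed regardless of order.

## Limitations

- No mmCIF input, sidechains, symmetry/assembly handling or hydrogen
  atoms from the input file; the structure layer is deliberately a
  backbone-only geometry engine.
- The turn classifier covers the eight canonical types plus a user
  extension hook; it is not a full secondary-structure assignment.
- The kinetics layer models unimolecular autoproteolysis only — no
  Michaelis-Menten machinery, no RecA filament kinetics, no pH
  dependence.
- K_d values inherit the uncertainty of the protein concentration used
  in the Phi -> K_d conversion; report the concentration (or molecular
  weight) alongside any K_d.
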