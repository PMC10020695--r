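# lexturn

Geometry of the LexA cleavage-site beta-turn, and first-order kinetics of
LexA autoproteolysis inhibition.

LexA represses the bacterial SOS regulon; DNA damage activates RecA
filaments that stimulate LexA self-cleavage in its cleavage site region
(CSR), derepressing the SOS genes and accelerating the evolution of
antibiotic resistance. Discovery of small-molecule cleavage inhibitors
rests on two quantitative analyses, both implemented here for structural
bioinformaticians and enzymologists working on LexA-family proteases:

- **Beta-turn analysis.** From backbone coordinates (PDB format), compute
  phi/psi/omega torsions, detect 4-residue turns by the
  Cα(i)–Cα(i+3) ≤ 7 Å criterion, classify them against the canonical
  types (I, I′, II, II′, VIII, VIa1, VIa2, VIb, IV catch-all; ±30° on the
  central phi/psi with one angle allowed ±45°), and measure the i → i+3
  hydrogen-bond geometry with an idealized amide hydrogen.
- **Cleavage kinetics.** Normalize band-intensity time courses to the
  fraction remaining f(t) = [LexA]/[LexA]₀, fit the first-order law
  f(t) = e^(−kt), fit the effectiveness model
  k_i = k₀ / (1 + r/Φ) across inhibitor:protein ratios r (Φ is the ratio
  halving the rate), and convert Φ to a dissociation constant
  K_d = Φ · [LexA]₀. Case-resampling bootstrap intervals quantify
  uncertainty.

Seeded generators supply every input synthetically: cleavage titrations
under the model above, peptide backbones built from prescribed torsions
(including ideal type-II turns), PDB fixtures, and toy screening tables.
Screening bookkeeping (hit rates, per-library summaries) and
Kyte–Doolittle hydropathy profiles round out the workflow.

## Worked example

Build an 8-residue peptide with an ideal type-II turn and analyze it:

```r
library(lexturn)
ch <- build_type2_turn_peptide(n_res = 8, turn_i = 3)
detect_turns(ch)
#>   i_resno        sequence phi1 psi1 phi2         psi2 omega2_cis  ca_dist
#> 1       3 ALA-ALA-GLY-ALA  -60  120   80 1.265574e-14      FALSE 4.869199
#>   o_n_dist o_h_dist type relaxed
#> 1 2.818453 1.891026   II   FALSE
```

One turn is found at residue 3, typed II from its central torsions
(−60, 120, 80, 0); the Cα(i)–Cα(i+3) distance of 4.87 Å is well under the
7 Å cutoff and the 2.82 Å O···N / 1.89 Å O···H distances indicate the
stabilizing i → i+3 hydrogen bond.

Simulate an inhibitor titration (two-fold dilutions 1000 → 62.5 µM plus
control, 0–25 min in 5-min steps, k₀ = 0.1/min, Φ = 43.422, noise
sd 0.03) and recover the parameters:

```r
cfg <- simulation_config(seed = 7)
per <- fit_timecourses(simulate_cleavage_series(cfg))
per
#>   label   ratio inhibitor_conc       k      k_se r_squared converged
#> 1 I1000 149.053       1000.0 0.02481 0.0005624    0.9942      TRUE
#> 2  I500  74.527        500.0 0.03241 0.0014769    0.9790      TRUE
#> 3  I250  37.263        250.0 0.05265 0.0020717    0.9901      TRUE
#> 4  I125  18.632        125.0 0.06686 0.0026261    0.9918      TRUE
#> 5 I62.5   9.316         62.5 0.08162 0.0021499    0.9969      TRUE
#> 6    I0   0.000          0.0 0.09998 0.0020165    0.9985      TRUE

fit_effectiveness(per$ratio, per$k, lexa0 = cfg$lexa0)
#> <effectiveness_fit> k0 = 0.099779 /min, phi = 40.29, Kd = 270.3 uM

bootstrap_effectiveness(per$ratio, per$k, n_boot = 1000, seed = 8,
                        lexa0 = cfg$lexa0)$ci
#>       lower   upper
#> k0    0.092   0.103
#> phi  35.664  50.551
#> kd  239.272 339.148
```

The rate constant falls monotonically with the inhibitor:protein ratio;
the recovered Φ of 40.3 (95% bootstrap CI 35.7–50.6) brackets the
generating value 43.422, and K_d = Φ·[LexA]₀ ≈ 270 µM at
[LexA]₀ = 6.709 µM (15 µg protein in a 100 µL reaction at 22,358 Da).

Screen bookkeeping reproduces published-style percentages exactly:

```r
hit_rate(133, 2276 + 8607)
#> 1.22% (raw 1.22209%)
```

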