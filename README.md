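# epibind

In-silico characterization of antibody–antigen binding: model
post-processing, epitope and steric-competition analysis, molecular-dynamics
interface metrics, and SPR binding-kinetics simulation and fitting — in one
tested R package.

## The problem

When a new monoclonal antibody is raised against an antigen (the motivating
case: anti-PD-L1 clones against the hamster immune-checkpoint ligand, where
no commercial reagents exist), much of its characterization can be done in
silico once predicted complex structures, MD trajectories and SPR
sensorgrams are available:

* **Which epitope does it bind, and whom does it displace?** Predicted
  complex models are trimmed of low-confidence termini (per-residue pLDDT
  < 70), ranked by pTM, and their interface confidence summarised from the
  PAE matrix. Poses are superposed on the shared antigen and scanned for
  steric clashes (0.3 nm cutoff) against a reference partner — e.g. the
  natural receptor bound at the checkpoint interface, or a second antigen
  copy at a dimerization interface. A clash means the antibody competes for
  that site.
* **How stably and tightly does it bind?** From replica MD ensembles
  (frames balanced across replicas, subsampled at 1 ns): antigen-fitted
  RMSD of the bound antibody with mean ± SEM across replicas and plateau
  summaries; per-residue center-of-mass RMSF about the average structure;
  heavy-atom contacts (< 4.5 Å) and geometric hydrogen bonds (donor–acceptor
  ≤ 3.5 Å, D–H⋯A angle ≥ 150°) as time series, with percent-difference
  statistics between antibodies.
* **What are its rate constants?** Sensorgrams at several analyte
  concentrations are fitted globally to a bivalent-analyte model

  dR₁/dt = ka₁·C·(Bmax − R₁ − R₂) − kd₁·R₁ − ka₂·R₁·(Bmax − R₁ − R₂) + kd₂·R₂
  dR₂/dt = ka₂·R₁·(Bmax − R₁ − R₂) − kd₂·R₂

  (or to a heterogeneous two-site alternative), with K_D,i = kd_i/ka_i.

Every stage has a seeded synthetic generator with analytically known ground
truth (`make_complex`, `make_ensemble`, `make_hbond_lattice`,
`make_sensorgrams`), so the whole pipeline is testable offline.

## Worked example

```r
library(epibind)

# equilibrium constants from published rates (KD = kd/ka)
tab <- reference_kinetics()
r11 <- tab[tab$clone == "11B12-1", ]
derive_kd(r11$ka1, r11$kd1)   # 1.45e-16 M
derive_kd(r11$ka2, r11$kd2)   # 9.28e-09 M

# a synthetic complex with a known epitope, mapped back exactly
cx <- make_complex(seed = 1, epitope = c(10, 11, 12))
epitope_map(cx$model, "chain A", "chain H L")
#>   chain_id residue_key residue_name n_contacts
#> 1        A          10          ALA          1
#> 2        A          11          ALA          1
#> 3        A          12          ALA          1

# simulate noisy 2.5/5/10 nM sensorgrams and fit them globally
g <- make_sensorgrams(noise_frac = 0.01, seed = 1)
fit <- fit_spr(g$sensorgrams, model = "bivalent", seed = 1)
summary(fit)
#> Global SPR kinetic fit (bivalent model)
#>        estimate std_error
#> ka1   2.010e+05 3.332e+03
#> kd1   1.988e-03 1.858e-04
#> ka2   5.150e-05 4.964e-06
#> kd2   5.643e-04 7.660e-05
#> Bmax1 9.932e+01 1.945e+00
#> KD1 = kd1/ka1 = 9.889e-09 M
#> KD2 = kd2/ka2 = 10.96 (ka2 1/(RU s))
#> RSS 1923.57 RU^2 over 1803 observations; converged: TRUE
```

The generating truth was ka₁ = 2×10⁵, kd₁ = 2×10⁻³, ka₂ = 5×10⁻⁵,
kd₂ = 5×10⁻⁴, Bmax = 100: every estimate lands within a few percent under
1% noise. `coef`, `predict`, `fitted`, `residuals`, `simulate` and `plot`
methods operate on the fitted object, and `validate_kd()` cross-checks
printed K_D values against their printed rates (it flags one published row
whose on-rate exponent is internally inconsistent by ten orders of
magnitude).

`run_pipeline(out_dir, seed = 1)` chains everything — generate, trim, rank,
map, compete, measure, fit — and writes TSV/JSON artifacts plus a manifest
with settings, seed and per-file checksums; a rerun with the same seed is
byte-identical.

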