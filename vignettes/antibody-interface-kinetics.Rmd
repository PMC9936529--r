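---
title: "Methods: antibody-antigen interface analysis and bivalent binding kinetics"
author: "epibind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antibody-antigen interface analysis and bivalent binding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibind)
```

# Scope and data model

`epibind` covers the in-silico arm of an antibody characterization
campaign: post-processing AI-predicted antibody-antigen complex models,
deciding by steric criteria which binding partners an antibody competes
with, quantifying the stability and tightness of a bound pose from
molecular-dynamics replica ensembles, and simulating and fitting surface
plasmon resonance (SPR) sensorgrams under two-step surface-binding kinetic
models. Neural structure prediction and the MD engine itself are outside
the package; `epibind` consumes their outputs (PDB coordinate files,
JSON confidence scores, multi-model PDB trajectories) and otherwise
generates its own synthetic inputs.

Everything structural flows through a single container, the
`structure_model`: an ordered atom table with coordinates in Angstrom,
author residue numbering (insertion codes appended to the residue key),
chain identifiers, element symbols (hydrogens flagged; needed for the
hydrogen-bond geometry) and the B-factor column, which for predicted
models carries the per-residue pLDDT confidence. Trajectories add a
`n_frames x n_atoms x 3` coordinate array with strictly increasing frame
times in nanoseconds; a `replica_ensemble` is a list of trajectories
sharing one topology. Internally all lengths are Angstrom and all times
nanoseconds (SPR uses seconds); thresholds quoted in nanometres (the 0.3
nm clash cutoff) are converted once at the interface.

PDB reading is deliberately strict about the contracts the analyses rely
on: fixed-column parsing with parse errors that carry the offending line
number, alternate locations collapsed to a single conformer (highest
occupancy, ties broken toward altloc `A`, which makes the choice
deterministic), the B-factor preserved verbatim, and multi-model files
checked for identical atom-identity sequences across frames. `HETATM`
records (waters, ions, ligands) are excluded unless requested, so polymer
atoms alone enter every analysis by default.

# Model post-processing

Predicted models are prepared in three steps, each with a fixed
convention:

* **Terminal trimming.** From each chain end inward, the maximal
  contiguous run of residues with pLDDT strictly below 70 is removed;
  interior low-confidence residues are retained, chains are trimmed
  independently, and a chain that would vanish entirely is an error
  rather than a silent deletion. The threshold is strict (`< 70`), so a
  residue at exactly 70.0 survives. The operation is idempotent.
* **Ranking.** Candidate models are ordered by descending pTM with
  lexicographic model-id tie-breaks, making the ranking a deterministic
  permutation of its input.
* **Interface confidence.** The predicted aligned error (PAE) matrix is
  summarised as the arithmetic mean over both inter-chain blocks (antigen
  rows against antibody columns and vice versa). The upstream tools
  publish the matrix without prescribing a scalar; this mean is a
  convention of this package, chosen because it is symmetric and
  insensitive to which chain is called "aligned".

Score files use a minimal JSON schema, `{"ptm": <scalar>, "pae":
[[...]]}` with the matrix row-major in Angstrom, documented here because
no standard schema exists.

# Pose analysis: epitopes and steric competition

Rigid superposition uses the least-squares (Kabsch) solution with the
proper-rotation correction, refusing fits with fewer than three pairs or
collinear fit atoms. The epitope of a pose is the set of antigen residues
with at least one heavy-atom pair strictly closer than 4.5 Angstrom to
the binder, with per-residue pair counts; the steric-clash criterion is
the same construction at 3.0 Angstrom (0.3 nm). Both thresholds are
strict (`<`), matching the "closer than" convention of the contact
definition; whether clash marking should include hydrogens is not
standardised, and heavy-atoms-only is adopted for consistency with the
contact rule.

Competition between an antibody pose and a reference binding partner
(say, the natural receptor bound to the same antigen, or a second antigen
copy at a dimerization interface) is decided by superposing the reference
complex onto the antibody complex via the shared antigen and scanning for
clashes between antibody and competitor: any clash pair means the two
cannot be accommodated simultaneously. Antigen pairing defaults to CA
atoms of residues common by author numbering — suited to homologous
antigens numbered consistently — with an explicit atom-pairing override
for cases where numbering differs.

Neighbour search is a vectorised full pairwise distance scan in blocks.
At the problem sizes this package addresses (hundreds to tens of
thousands of atoms) the vectorised scan outperforms an interpreted cell
list in R, and its correctness is pinned by brute-force enumeration
oracles in the test suite, so the spatial data structure is purely an
implementation detail.

# Trajectory metrics

All analyses first subsample trajectories on a 1 ns grid (keeping, for
each multiple of the interval, the first frame at or after it) and then
truncate every replica to the common minimum frame count, so each
independent simulation contributes an equal number of frames and long
replicas cannot bias ensemble statistics.

* **Antigen-fitted RMSD.** Each frame is rigidly fitted on the antigen
  selection and the RMSD is computed over the bound antibody alone; a
  stable plateau indicates the pose has settled. Replicas are summarised
  pointwise by the mean and the standard error of the mean (sample
  standard deviation over replicas divided by the square root of their
  number; undefined and reported missing for a single replica). Plateau
  summaries average the ensemble mean over the final window (200 ns by
  convention), with the uncertainty taken across replica window-means; a
  window longer than the series is clipped with a warning. Which atom set
  the fit should use is not standardised; CA atoms are the default and
  the selection is configurable.
* **Center-of-mass RMSF.** Per residue, the root-mean-square fluctuation
  of its (mass-weighted) center of mass about the average structure. The
  average structure is produced by a two-pass scheme — fit all frames to
  the first frame, average, re-fit all frames to that average, re-average
  — a deterministic, seed-independent approximation to iterative
  mean-structure fitting that converges for the small rigid-body
  corrections involved here.
* **Contacts.** Two heavy atoms from opposite groups strictly closer than
  4.5 Angstrom. Exact threshold semantics matter at the boundary: a pair
  at exactly 4.5 is not a contact.
* **Hydrogen bonds.** A donor-hydrogen-acceptor triple counts when the
  donor-acceptor heavy-atom distance is at most 3.5 Angstrom (inclusive)
  and the three-point angle at the hydrogen is at least 150 degrees. The
  often-quoted 150-210 degree band is the symmetric region around
  linearity of an angle that cannot exceed 180 degrees, hence a single
  lower bound. Without a bond topology file, donors are N/O heavy atoms
  carrying a hydrogen within 1.2 Angstrom (geometric bond inference) and
  acceptors are N/O heavy atoms; donors without a hydrogen are skipped
  rather than raising an error.
* **Percent difference.** Cross-complex comparisons (for example "one
  antibody makes X% more contacts than the other") are computed as
  `100 * (mean(a) - mean(b)) / mean(b)` where each ensemble mean averages
  per-replica time averages with equal replica weights. Averaging replica
  means rather than pooling frames keeps unequal-noise replicas from
  dominating; the alternative pooled convention differs only when replica
  lengths differ, which the balancing step rules out.

# SPR kinetics

Bivalent binders on a surface are described by two coupled states:

$$\frac{dR_1}{dt} = k_{a1} C (B_{max} - R_1 - R_2) - k_{d1} R_1
  - k_{a2} R_1 (B_{max} - R_1 - R_2) + k_{d2} R_2$$
$$\frac{dR_2}{dt} = k_{a2} R_1 (B_{max} - R_1 - R_2) - k_{d2} R_2$$

with analyte concentration $C$ during association and $C = 0$ during
dissociation, response $R_1 + R_2$, and $K_{D,i} = k_{d,i}/k_{a,i}$. In
this scheme the second step consumes surface sites, so $k_{a2}$ carries
units of $RU^{-1}s^{-1}$. Published parameter tables for such fits often
list *two* capacities ($B_{max1}$, $B_{max2}$), which the bivalent scheme
does not have; the interpretation consistent with two capacities is a
heterogeneous surface of two independent Langmuir sites. Both variants
are implemented (`simulate_bivalent`, `simulate_two_site`;
`fit_spr(model=)`), the bivalent one by name-match as the default, and
the fitted object records the $k_{a2}$ units to prevent silent misuse.
Mass-transport limitation is not modelled. The right-hand sides are
compiled C evaluated by `deSolve::lsoda` (stiff-safe), association and
dissociation integrated separately, with tolerances `rtol = 1e-8`,
`atol = 1e-10` RU for simulation; inside the fit objective a looser
`1e-6/1e-8` is used for speed and the final optimum is re-polished at the
tight tolerances.

Global fitting minimises the pooled squared residuals of all
concentrations simultaneously over log10-transformed parameters
(Levenberg-Marquardt trust region, `ftol = ptol = 1e-10`), inside a broad
box spanning typical antibody kinetics. Because the landscape has
deceptive local minima — a wrong-by-2x off-rate can reproduce curves to
milli-RU accuracy when rebinding is strong — the search is staged: a data-driven
heuristic start, a single-site prefit of $(k_{a1}, k_{d1}, B_{max})$ with
the second step frozen (the well-behaved subproblem), several
second-step magnitudes seeded around that prefit, and a pool of seeded
log-uniform random points; all candidates are screened by one residual
evaluation and the optimiser runs from the best `n_starts` (default 8).
The procedure is deterministic for a fixed seed. Standard errors come
from the Gauss-Newton covariance at the optimum, delta-transformed back
to the natural scale. All-zero input curves are flagged as a degenerate
fit (capacity at the box lower bound, not converged) instead of raising.

Worked consistency checks on published constants are exposed through
`reference_kinetics()` and `validate_kd()`: the latter recomputes
$K_D = k_d/k_a$ and compares with a printed value at three significant
figures, allowing one unit in the last figure since the printed inputs
are themselves rounded. One row of the shipped table is internally
inconsistent by ten orders of magnitude (an exponent typo in its printed
on-rate is the likely cause); the package reports the inconsistency and
the implied value rather than guessing a correction.

# Synthetic data and what it does (not) establish

The generators in `make_complex()`, `make_ensemble()`,
`make_hbond_lattice()` and `make_sensorgrams()` produce every input class
the pipeline consumes, each with analytically known ground truth, seeded
and bit-for-bit reproducible (single Mersenne-Twister stream per call,
caller RNG state restored).

* The synthetic complex is a three-chain bead model: a helical antigen
  (radius 10 Angstrom, 0.6 rad turn, 1.5 Angstrom rise, so ~6.1 Angstrom
  between consecutive beads) and two binder chains whose beads rest tens
  of Angstrom away except for one bead placed 3.8 Angstrom radially
  outward of each designated epitope residue. The helix matters: a
  straight-chain antigen leaves the roll about its axis unconstrained in
  a least-squares fit, and the superposition then scrambles every
  downstream fluctuation measure. Geometry guarantees the recovered
  epitope equals the requested set exactly.
* Ensembles add independent isotropic Gaussian jitter of per-axis width
  sigma (default 0.5 Angstrom) and optionally a rigid binder drift.
  Expected values are exact: center-of-mass RMSF of a jittered
  single-bead residue is $\sigma\sqrt{3}$, and the antigen-fitted RMSD of
  a binder drifting at velocity $v$ is $|v|t$. For the RMSF recovery the
  jitter is restricted to the binder chains so the fit frame is exact;
  jittering the fit atoms too adds lever-arm noise through the
  superposition itself, which is a property of fitting, not of the RMSF
  estimator.
* Hydrogen-bond fixtures place isolated donor-H-acceptor triples with
  exact requested distances and angles, 100 Angstrom apart so triples
  cannot interact, giving an exact expected count.
* Sensorgram generation simulates the chosen model and adds Gaussian
  noise of standard deviation `noise_frac * Bmax1`. The default
  generating kinetics ($k_{a1} = 2\times10^5\,M^{-1}s^{-1}$,
  $k_{d1} = 2\times10^{-3}\,s^{-1}$, $k_{a2} = 5\times10^{-5}
  \,RU^{-1}s^{-1}$, $k_{d2} = 5\times10^{-4}\,s^{-1}$, $B_{max} = 100$ RU,
  300 s association and 900 s dissociation at 2.5/5/10 nM) were chosen
  once, on identifiability grounds: both steps evolve on timescales
  observable within the injection design ($k_{a1}C$ and $k_{d1}$ of order
  $10^{-3} s^{-1}$, $k_{a2}B_{max} \approx k_{d1}$), so each rate leaves
  a distinct curve signature. In rebinding-dominated regimes
  ($k_{a2}B_{max} \gg k_{d1}$) the off-rate is structurally
  unidentifiable — curves agree to milli-RU across 2x changes in
  $k_{d1}$ — and no fitting procedure can recover it; a recovery fixture
  must therefore be an identifiable design.

What passing tests on these fixtures establish is the correctness of the
implemented estimators and solvers — threshold semantics, oracle-exact
counting, analytic limits, parameter recovery under the stated noise.
What they do not establish is behaviour on real systems: bead models have
no side-chain packing, no correlated motions, no solvent, harmonic
uncorrelated fluctuations instead of anharmonic dynamics, and synthetic
sensorgrams have white noise and no drift, bulk jumps or mass-transport
effects. Conclusions about a real antibody still require real predicted
models and real trajectories; the package then applies exactly the same
code paths to them.

# Problem sizes and numerical choices

The test-suite and pipeline default scales are deliberately small — a
60-residue antigen with two 50-residue binder chains, ensembles of 2-10
replicas at 10-100 frames, $10^4$ frames only for the RMSF convergence
check, and 20 fit replicates for the noisy-recovery statistics — chosen
so the complete pipeline runs end to end in seconds and the full suite in
a few minutes, while remaining large enough for the stochastic
expectations (2% RMSF tolerance needs $O(10^4)$ frames; fit-error medians
need ~20 replicates).

Remaining numerical conventions, collected: strict `<` for contacts and
clashes, inclusive `<= 3.5` for the hydrogen-bond distance, `>= 150` for
its angle (1e-9 guards against representation error at exact
thresholds); PDB coordinates round-trip at 1e-3 Angstrom (format
precision); Kabsch fits reject second singular values below 1e-8 of the
largest (collinearity); ensemble SEM uses the n-1 sample standard
deviation and is reported missing (not zero) for one replica; pTM ties
break lexicographically; altloc ties break toward `A`.

# Reproducible runs

`run_pipeline(out_dir, seed)` executes the whole synthetic chain —
complex generation, trimming, ranking, PAE summary, epitope map,
competition assessment, balanced ensemble metrics with plateau and RMSF,
contact series and cross-complex percent difference, sensorgram
simulation and global fit — writing TSV/JSON/CSV artifacts plus a
`manifest.json` with the settings, seed, package version and MD5 checksum
of every output. Identical calls produce byte-identical files, which the
test suite asserts. `analysis_settings()` carries every geometric
threshold with the conventional defaults (4.5 / 3.5 / 3.0 Angstrom, 150
degrees, pLDDT 70, 1 ns, 200 ns), and any override travels into the
manifest.

# Known limitations

mmCIF is not parsed (PDB only, plus adapters by contract for binary
trajectory formats); periodic-boundary unwrapping is assumed done
upstream; bond topology is inferred geometrically rather than read from
force-field files; the SPR models omit mass transport and bulk
refractive-index steps; and the two-site/bivalent duality is resolved by
documentation and unit metadata, not by model selection statistics.
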