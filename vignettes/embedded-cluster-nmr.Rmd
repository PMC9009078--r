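---
title: "Embedded-cluster models for molecular-crystal NMR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedded-cluster models for molecular-crystal NMR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedshield)
```

## The model

A molecular crystal is represented by its lattice cell, space-group
operations, and asymmetric-unit atoms; every atom of every image is
identified by the triple (generating site, generating operation, integer
lattice translation), which is what lets a change in the asymmetric unit
propagate consistently to the whole model. The embedded cluster built from
it has three layers:

* **QM1** — one asymmetric-unit molecule, the only one whose nuclei are
  reported;
* **QM2** — every distinct molecular image with at least one atom within a
  cutoff of any QM1 atom (all atoms count, hydrogens included; the
  criterion is deliberately not heavy-atom-only because the shortest
  intermolecular contacts in hydrogen-bonded crystals involve hydrogens);
* **MM** — one point charge at every remaining atom position of an
  *n*×*n*×*n* supercell centred on the home cell.

The underlying assumptions are those of any cluster treatment: the local
electronic structure of QM1 (including its explicit first shell) dominates
the shielding, and everything beyond the shell acts only electrostatically,
so it can be condensed to fixed point charges.

### Self-consistent charges

The MM charges are the atomic charges of QM1 mapped onto every symmetry
image. Since the charges polarize the molecule that defines them, they are
iterated: iteration 0 evaluates the charge provider with no environment,
each later iteration rebuilds the supercell field from the previous charges
and re-evaluates, and the loop stops when the per-atom maximum absolute
change drops to `tol`. The threshold default is 0.01 e per atom — the
strictest common reading of a bare "0.01" convergence statement; an RMS
metric is available by flag. Charges are carried at full precision between
iterations, neutrality is asserted at every step to 1e-6 e, and hitting
`max_iter` (default 50) raises a typed non-convergence error carrying the
full history rather than truncating silently.

The charge provider is an interface. Production use plugs in an engine's
ESP charges; the package's analytic provider polarizes reference charges
linearly in the mean-centred external potential and then round-trips them
through the same constrained least-squares ESP fit
(`esp_fit_charges()`) a CHELPG step would use: minimise
$\sum_g \big(V_g - \sum_i q_i/|r_g - r_i|\big)^2$ subject to
$\sum_i q_i = Q$, Coulomb kernel in atomic units. The fitting grid is a
0.5 Å cubic lattice clipped to the shell between 1.4× the van der Waals
radius and 2.8 Å — a documented dialect of the usual CHELPG settings, not
claimed identical to any engine's grid. Degenerate grids fall back to the
minimum-norm solution with a warning.

### Geometry protocol

Experimental structures keep their heavy atoms fixed: only the QM1
hydrogens are free (`freeze_mask()`), reflecting that X-ray hydrogen
positions are unreliable while heavy-atom positions are good. After the
(external) relaxation, `rebuild_cluster()` pushes the new hydrogen
positions back into the asymmetric unit by inverting QM1's generating
operation and re-resolves every QM2 molecule and MM site from its stored
identifiers — so all images move consistently, and rebuilding is idempotent.

### Vibrational correction

The hydrogen-only MD protocol is encoded as a snapshot schedule (defaults:
1 fs step, 40 ps run, 1 ps equilibration, 100 snapshots every 0.3 ps). The
first frame is taken at `equil + interval` (1.3 ps), which places the last
at 31.0 ps inside the run; the source protocol states only the spacing and
count, so the convention is documented here rather than asserted as
canonical. Snapshot shieldings are averaged per nucleus, and the **DIFF**
correction is the exact difference between that average and the rigid
result, computed once at a cheap level of theory and added to any other
method's rigid shieldings via `apply_correction()` — a missing nucleus is
an error, never a silent zero.

### Evaluation

Calculated shieldings are regressed on experimental shifts,
$\sigma = a\,\delta_{\mathrm{exp}} + b$, with the shielding as the
response; predicted shifts come from inverting that line, never from
re-fitting $\delta$ on $\sigma$. Because ordinary least squares zeroes the
residual mean, fit-referenced predictions always have zero mean signed
error; MAE, MaxAE (with the nucleus attaining it), and SDE (sample
standard deviation, $n-1$ denominator) quantify the scatter. The $n-1$
convention was validated against the published statistics at display
precision. Absolute referencing against a computed standard
($\delta = \sigma_{\mathrm{ref}} - \sigma$) is also provided; the gap
between a method's fitted intercept and its computed reference shielding
measures the systematic error the linear fit removes. Display rounding is
half-even at two decimals (four for $R^2$).

One identity-key subtlety: the benchmark labels nuclei per element, so the
same label can denote a proton in the ¹H table and a carbon in the ¹³C
table of the same system (the aspartic-acid COOH). All matching therefore
keys on (system, nucleus, element) whenever both sides carry an element.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| QM2 cutoff | 3.0 (2.5–3.5 per system) | Å | first-shell contact range of hydrogen-bonded organics |
| MM supercell `n` | 9 | cells | converges the Madelung-type field at negligible cost |
| bond tolerance | 0.25 | — | standard covalent-radius inflation for perception |
| charge threshold `tol` | 0.01 | e/atom | strictest reading of the production protocol |
| `max_iter` | 50 | — | generous for a contractive map; divergence errors out |
| ESP grid | 0.5 / 1.4×vdW / 2.8 | Å | CHELPG-like shell, documented dialect |
| merge tolerance | 1e-3 | Å | special-position image coincidence |
| MM clearance | 1e-4 | Å | no point charge may sit on a QM atom |
| snapshot schedule | 1 fs / 40 ps / 1 ps / 100×0.3 ps | — | production MD protocol |

The cutoff question — whether per-system cutoffs should be chosen to reach
a target shell size or vice versa — is left open in the sources; the
package exposes the cutoff-driven route directly (`select_qm2()`), and a
count-driven selection is a one-line wrapper: scan the sorted contact
distances it returns and cut after the desired number of molecules.

## The analytic engine stand-in

External electronic structure (SCF, GIAO shieldings, real ESP densities,
dispersion, PNO internals) is out of scope by design: the package writes
deterministic ORCA-style decks (QM1 atoms first, fragment tag 1, larger
basis; QM2 fragment 2, smaller basis; shieldings requested for fragment-1
nuclei only; multilevel PNO tiers emitted for the correlated methods) and
parses the results. So that every downstream stage is testable without an
engine, `mock_shieldings()` provides a closed-form environment-sensitive
backend:
$\sigma = \sigma_0(\mathrm{el}) + c(\mathrm{el})\,V$, with $V$ the Coulomb
potential (atomic units) at the nucleus from all QM2 partial charges and MM
charges. Baselines are 30 ppm (H) and 150 ppm (C); the response constants
(20 and 100 ppm per hartree/e) are fixed so typical toy-crystal fields
shift shieldings by a few ppm — large against numerical noise, small
against the baselines. The form is exactly translation- and
rotation-invariant and symmetric under symmetric charge arrangements,
which the tests exploit as oracles.

## What the synthetic generator emulates — and what it does not

`make_toy_crystal()` builds P1 or P2₁ crystals from a three-atom bent polar
(water-like) template at a seeded general position and orientation, with
known neutral reference charges per site. The default monoclinic
5 × 5.5 × 6 Å cell (β = 100°) packs nearest intermolecular contacts at
2.9–3.4 Å, the hydrogen-bond contact range the shell-selection defaults
presume; placements whose images approach within covalent-bonding distance
are rejected as unphysical. `demo_pipeline()` runs six such crystals with
graded cell volumes (scales 0.96–1.12) — six distinct crystal environments,
mirroring the six benchmark systems — converges their embedding charges,
evaluates the analytic backend, manufactures "experimental" shifts from a
planted line $\delta = (\sigma + \varepsilon - b_0)/a_0$ with
$\varepsilon \sim N(0, 0.01\ \mathrm{ppm})$, and fits them back. The noise
default keeps the relative scatter at the few-percent-of-spread level the
real benchmark regressions exhibit.

Two honest caveats about what passing these tests shows. First, the toy
shielding spread is generated purely by the electrostatic environment
(identical molecules in different fields), whereas the real benchmark's
spread is dominated by chemistry; the synthetic recovery therefore
validates the pipeline's bookkeeping and statistics, not any claim about
electronic structure. Second, because the planted noise sits on the shift —
the regressor — the fitted slope is attenuated by the classical
errors-in-variables factor $\lambda = 1 - \sigma_\varepsilon^2/(a_0^2
s_\delta^2)$; the parameter-recovery tests compare against that corrected
expectation within four standard errors, not against the raw planted value.

## Numerical choices

* Cartesian frame: **a** ∥ x, **b** in the xy-plane; all distances in Å;
  Coulomb kernels converted to bohr internally. Fractional/Cartesian
  round-trips are exact to 1e-10.
* Wrapping acts on molecular centroids, never on individual atoms, so
  molecules stay intact across cell boundaries; periodic perception uses
  minimum-image distances and unwraps components by breadth-first search.
* Frozen atoms may move by at most 1e-6 Å in a rebuild; more is an error.
* $R^2$ is computed from the residual and total sums of squares directly,
  which is exact for degenerate perfect-fit cases where `summary.lm` warns.
* The supercell bounding the QM2 search is 5³ cells; a shell reaching its
  boundary layer raises an error instead of silently truncating.
* Self-consistency histories store every iterate, so non-convergence
  reports carry the full trajectory.

## Problem sizes

Desk-scale defaults keep every stage fast: the test suite uses 3-atom
molecules, 3³–5³ supercells, shells of a handful of molecules, 50–1000
snapshot frames, and the full benchmark tables (45 nuclei × 5 methods);
the complete suite and the acceptance script each run in seconds on one
CPU.

## Known limitations

* Space groups are taken from the CIF operations as given; there is no
  space-group inference, and disorder handling is limited to selecting one
  stated conformer (the two cysteine S–H orientations are two independent
  cluster builds whose shieldings are averaged downstream).
* Multi-molecule asymmetric units are treated as a single rigid unit.
* X-ray structures lacking hydrogens must be completed before use; the
  pipeline requires H-complete input and does not place hydrogens itself.
* The quantum engine, and therefore every real shielding value, basis set,
  and PNO setting, is external; the deck dialect is frozen by golden files
  rather than guaranteed to match any particular engine version.
* Quantum vibrational treatments (path-integral or perturbative) are out
  of scope; the DIFF correction is a classical-snapshot estimate.
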