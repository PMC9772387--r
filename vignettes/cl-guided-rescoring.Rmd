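---
title: "Rescoring docked protein complexes with differential covalent labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring docked protein complexes with differential covalent labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clrescore)
```

## The measurement and the structural signal

Covalent labeling mass spectrometry exposes a protein to a reagent (hydroxyl
radicals, DEPC, NHSA, ...) that modifies solvent-accessible side chains; the
per-residue degree of modification — a rate or an extent, depending on the
experiment — reflects how exposed each residue is. *Differential* labeling
compares the unbound subunits with the assembled complex. A residue buried at
the binding interface loses solvent accessibility on binding, so its degree
of modification drops. The statistic used throughout this package is the
modification change

$$\mathrm{change} = \frac{M_\mathrm{unbound} - M_\mathrm{bound}}
                         {M_\mathrm{unbound}} \times 100\,\%$$

which is dimensionless (rates and extents give identical values under a
common rescaling), is at most 100 %, and is negative when a residue labels
*more* in the complex. Changes are undefined when $M_\mathrm{unbound} = 0$;
such rows are excluded at load time with a logged count.

The geometric counterpart is the **interface distance**: the shortest
distance between any heavy atom of the residue and any heavy atom of the
other docking partner. Residues within 10 Å of the partner count as interface
residues (boundary inclusive); residues with a change of at least 40 % count
as strongly protected. Both cutoffs are diagnostic conventions, configurable
in `scoring_params()`, and are *not* filters on which residues are scored.

## The calibration line

Pooling labeled residues across complexes, modification change falls off
approximately linearly with interface distance. `fit_calibration()` performs
the ordinary least-squares fit of change (%) on distance (Å) and reports
slope, intercept, $R^2$, RMSE, and NRMSE. When no fit is supplied,
`calibration_model()` defaults to the published pooled-benchmark constants,
slope $-2.07$ % per Å and intercept $46.27$ %: at the interface a residue is
expected to lose roughly half its labeling, and the expected change decays to
zero a little beyond 20 Å.

Two choices here were genuinely open:

* **NRMSE normalization.** Several conventions exist (mean, range, SD of the
  observations). This package reports RMSE divided by the *mean* observed
  change, alongside the raw RMSE, so any alternative normalization can be
  recomputed; no claim is made that this convention matches any particular
  published NRMSE value.
* **Pooling.** The calibration pools all complexes into a single fit
  (`run_calibrate()` does this across every complex in the labeling table);
  per-complex fits can be obtained by subsetting the table, but are not the
  default.

## The penalty and the combined score

For each labeled residue of a docked model, the model-implied interface
distance is converted to a predicted change via the calibration line (no
clamping — large distances predict negative changes on purpose), and the
deviation from the experimental change is fed through a logistic penalty

$$P = 1 - \frac{1}{1 + e^{A (d - B)}}$$

with steepness $A = 1.88$ per % and midpoint $B = 38$ %. A residue whose
deviation is $B$ contributes exactly 0.5; deviations below roughly
$B - 15\,\%$ contribute essentially nothing, and large disagreement
saturates at 1. Per-model penalties are summed over all labeled residues
that can be mapped onto the model (unmapped residues are skipped and
counted; models are not re-weighted by the number scored), the sums are
normalized by the ensemble maximum (all-zero sets normalize to all zeros),
and the combined score is

$$\mathrm{score} = \mathrm{Isc} + w \cdot \mathrm{CL}_\mathrm{norm},
\qquad w = 65,$$

where Isc is an externally computed interface energy (lower is better). With
$w = 0$ ranking reduces to the energy alone. Ranks are deterministic: ties
break by lower Isc, then lexicographic model id.

**Deviation sign.** The deviation $d$ is the *absolute* difference between
experimental and predicted change. A signed convention would leave any
over-prediction unpenalized no matter how large, which contradicts the
intent of penalizing disagreement in either direction; the signed mode
remains available (`deviation_mode = "signed"`) for sensitivity analysis.

**Homo-oligomers.** A labeling experiment on a homodimer cannot attribute a
residue's signal to one chain. A labeled residue with chain `"*"` maps to
every chain carrying that residue number and name, and its interface
distance is the minimum over the copies — the conservative choice, since
protection would be observed if any copy buries.

**Scale of sensitivity.** Because the calibration slope is $-2.07$ % per Å
and the sigmoid midpoint is 38 %, the penalty only responds once a residue's
interface distance is wrong by roughly $38 / 2.07 \approx 18$ Å. The score
term therefore separates *grossly* misplaced interfaces from approximately
correct ones; discriminating among poses that are all within a few Å is the
job of the interface energy. This is a property of the published constants,
not of this implementation, and it shapes both the synthetic benchmark below
and what a user should expect on real ensembles.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `A` | 1.88 | per % | penalty steepness |
| `B` | 38.0 | % | penalty midpoint (deviation giving 0.5) |
| `weight` | 65 | — | weight on the normalized CL term |
| `interface_cutoff` | 10 | Å | interface membership (inclusive) |
| `change_threshold` | 40 | % | strong-protection diagnostic (inclusive) |
| `deviation_mode` | `"abs"` | — | absolute vs signed deviation |
| slope | −2.07 | %/Å | calibration line |
| intercept | 46.27 | % | calibration line |

## Model-quality evaluation

`complex_rmsd()` pairs alpha carbons by chain, residue number and insertion
code, performs one joint Kabsch superposition over all matched residues of
all chains (never per-chain fitting), and reports the RMSD. The rotation is
guaranteed proper (determinant $+1$); mirror solutions are excluded. Two
consequences worth knowing:

* Graphics-tool alignment commands typically run a sequence alignment and
  reject outlier atom pairs before reporting an RMSD. Exact-correspondence
  Kabsch with no rejection — used here — gives systematically comparable but
  not identical values; comparisons against numbers produced by such tools
  should allow a few tenths of an Å.
* For decoys generated in the reference frame there is a second meaningful
  quantity, the RMSD *without* re-superposition (`fit = FALSE`). Translating
  one of two equal-sized partners by $t$ displaces half the alpha carbons by
  $t$, so the unfitted RMSD is exactly $t/\sqrt2$, while the fitted RMSD is
  strictly smaller because the superposition splits the difference between
  the partners. Reported decoy RMSDs are the fitted ones, matching the
  evaluation convention.

`interface_agreement_counts()` reproduces the classification analysis
(counts of strongly protected residues inside/outside the interface, mean
change per class), and `benchmark_summary()` aggregates top-model RMSDs with
and without the labeling term with a configurable success threshold (3.6 Å
default).

## The synthetic benchmark: what it emulates, and what it does not

`make_scenario()` builds a fully seeded desk-scale analogue of a labeling +
docking study:

* **Native complex** (`make_toy_complex()`): two chains of CA+CB
  pseudo-residues. About a third of each chain forms a contiguous interface
  block with partner distances spread over ≈3.5–9 Å (the chain-B block
  slopes gently so the calibration sees a genuine range of distances); all
  other residues sit beyond 15 Å. Small seeded jitter makes seeds distinct
  while each seed is bit-reproducible.
* **Decoys**: the native, a few near-native rigid perturbations (RMSD well
  under 2 Å), and wrong-site contact poses (`make_wrongsite_decoys()`): the
  second partner is randomly reoriented (60–180°) and slid along a random
  direction until just in contact (≈4 Å heavy-atom gap) — wrong poses stay
  *docked*, as a randomized rigid-body docking run produces, rather than
  floating free. One caveat is intrinsic to distance restraints: a sparse
  distance pattern occasionally fails to reject a mirror-like wrong-side
  approach whose residue-to-partner distances all match the native. No
  distance-derived score could distinguish such a pose, so the generator
  resamples candidates until at least 3 residues have their distance
  disrupted by ≥ 20 Å (at most 50 draws) — the benchmark's purpose is a
  planted, detectable signal, and the guarantee is geometric, computed
  without any scoring machinery.
* **Labeling table** (`simulate_labeling()`): each residue's change is the
  calibration prediction at its native interface distance plus Gaussian
  noise (default SD 5 %), back-solved to degrees of modification with
  $M_\mathrm{unbound} = 1$. The tables are written and re-read through the
  real TSV parser so the file path is exercised end to end.
* **Surrogate interface energy** (`surrogate_isc()`): linear in true RMSD
  plus Gaussian noise. The scenario default is *misleading*: slope −0.2
  energy units per Å (the energy mildly favors wrong poses) with noise SD
  1.5. A signal-0 pure-noise energy makes the identity of the energy-top
  model a per-seed lottery, whereas a mildly negative slope reproduces the
  failure mode of interest — the energy's global minimum falls on a wrong
  pose — deterministically, which keeps the benchmark's expected behaviour
  stable across seeds.

What the synthetic path does **not** emulate: side-chain chemistry and
reagent specificity (every residue is labelable), intrinsic reactivity
differences, conformational change on binding, flexible-backbone decoys, and
any physics in the surrogate energy. Passing the synthetic benchmark shows
the scoring machinery is correct and that the method recovers planted signal
under its own model assumptions; it does not by itself demonstrate accuracy
on experimental ensembles.

```{r example}
sc <- make_scenario(seed = 1)
ev <- evaluate_scenario(sc)
head(ev$scores[, c("model_id", "isc", "cl_norm", "cl_score", "rank")], 3)
c(top_rmsd_with_cl = ev$top_rmsd_cl, top_rmsd_energy_only = ev$top_rmsd_isc)
```

## Numerical and degenerate-input choices

* Alternate locations resolve to the highest-occupancy conformer, ties to
  the first encountered; multi-model files use the first model only.
* A residue number matching several insertion codes is a lookup error, never
  a silent pick.
* The sigmoid is evaluated as `plogis(A * (d - B))`; in double precision it
  reaches exactly 1 once $A(d-B) \gtrsim 36$, i.e. beyond $d \approx 57$ %
  deviation at the defaults. Bounds are strict on the representable range.
* An ensemble whose raw penalty sums are all zero normalizes to all zeros
  (every model agrees equally with the data) rather than dividing by zero.
* All generators draw from seeded sub-streams derived deterministically from
  the scenario seed and restore the caller's RNG state.

## Problem sizes

The test suite and the acceptance script run the full pipeline on ensembles
of 41 models (native + 3 near-native + 37 wrong-site decoys) of 10-residue
per-chain toy complexes with 20 labeled residues, over 10 seeded scenarios;
oracle equivalences (brute-force distances, normal-equation fits, quaternion
superposition) use 100 randomized cases each. These sizes were chosen so the
statistical checks (e.g. slope recovery within sampling error, 9/10 scenario
successes) are meaningful while any single run of the suite stays fast.

## Limitations

* The method assumes no large conformational change on binding: the
  calibration maps change onto *rigid* interface distances.
* Distance-only restraints cannot reject mirror-like poses that reproduce
  the native distance pattern; the interface energy must carry that burden.
* With the published constants the penalty is insensitive to interface
  errors below ≈18 Å per residue, so the CL term re-ranks coarsely; final
  discrimination among near-native poses comes from the energy term.
* TM-score and DockQ are not implemented; externally computed values can be
  reported alongside but are never derived here.
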