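---
title: "Predicting amide protection factors from protein motions and structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting amide protection factors from protein motions and structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poppet)
```

## The exchange model

A backbone amide hydrogen in a folded protein exchanges for deuterium
only while transiently "open". With opening and closing rates $k_{open}$
and $k_{close}$ and the intrinsic (unstructured-chain) rate $k_{int}$,

$$k_{ex} = \frac{k_{open}\,k_{int}}{k_{close} + k_{open} + k_{int}},$$

implemented in `exchange_rate()`. In the EX2 regime
($k_{close} \gg k_{open}, k_{int}$) this reduces to
$K_{open} k_{int}$ with $K_{open} = k_{open}/k_{close}$; in the EX1
regime ($k_{int} \gg k_{close}$) it approaches $k_{open}$. The
protection factor is $PF = k_{int}/k_{ex} \approx 1/K_{open}$ and
$\Delta G_{ex} = RT \ln PF$ with $R = 1.9872\times10^{-3}$ kcal/(mol K).

**Logarithm convention.** The public interface uses base-10 logPF
throughout; the free-energy relation and the phenomenological
approximation are natural-log internally and converted explicitly
(`logpf()`, `dg_from_pf()`, `phenomenological_logpf()`). Measured
"logPF" inputs are treated as log10. A single documented convention
avoids silent factor-of-2.303 errors; `phenomenological_logpf(...,
assume_log10 = TRUE)` reproduces a literal base-10 reading of that
formula for sensitivity analysis.

## The log-linear protection-factor model

`poppet()` fits
$$\mathrm{logPF} = \beta_0 + \beta_1\,\mathrm{UD} + \beta_2\,\mathrm{EX1}
 + \beta_3\,(\mathrm{UD{+}EX1}) + \beta_4\,\mathrm{helix}
 + \beta_5\,\beta\text{-sheet} + \beta_6\,\mathrm{burial}
 + \beta_7..\beta_9\,(\text{H-bond category}) + \varepsilon,
 \qquad \varepsilon \sim N(0, \sigma^2)$$

with indicator coding and reference levels: motion `L` (local
fluctuations), secondary structure `no`, hydrogen bond `no`. Fitting is
ordinary least squares on the full design followed by backward
elimination at `alpha = 0.05`.

**Factor-wise elimination is the default.** In factor mode a categorical
factor's p-value is the smallest among its levels, and the whole factor
is kept or dropped together. This is the only procedure consistent with
a published fit of this model in which the β-sheet level is retained at
p = 0.068 while the stated threshold is 0.05: the helix level carries
the secondary-structure factor. Term-wise mode (`elimination = "term"`)
is provided for sensitivity analysis and judges each indicator column on
its own p-value.

**Reporting eliminated terms.** Hydrogen-bond terms are part of the
candidate design by default and, when eliminated, are still reported
with their full-design estimates and p-values (`$coefs$table`), so the
evidence for dropping them is visible.

**Degenerate designs.** Constant indicator columns (a category absent
from the data) are dropped before fitting with a message and recorded in
`$coefs$dropped`; columns that become aliased inside the fit are handled
the same way. Perfect (zero-residual) fits produce NaN t-tests in R;
the elimination loop treats a non-zero estimate with zero residual
variance as infinitely significant and a zero estimate as removable.

The published coefficient set ships as the preset
`poppet_coefficients("poppet-2018")` (motion, secondary structure and
burial retained; intercept 2.19940, UD 1.63431, EX1 2.12078, UD+EX1
2.15429, helix 0.59534, β-sheet 0.35710, burial 0.04371). Refitting is a
separate, explicit operation so the preset stays reproducible.

## Structural covariates

* **Burial** (`compute_burial()`): count of non-hydrogen atoms within
  6.5 Å (inclusive — an arbitrary but fixed boundary choice) of the
  amide nitrogen, excluding the nitrogen itself. Waters and HETATM
  records are excluded by default because burial is meant to measure
  protein packing; `include_het = TRUE` exists for sensitivity checks,
  and `scope = "backbone-only"` restricts to N/CA/C/O for the
  backbone-only phenomenological preset.
* **Secondary structure** (`ss_category()`): from HELIX/SHEET records of
  the coordinate file. α- and 3/10-helices map to `helix`; π-helices do
  too, as the closest of the three available groups; strands and bridges
  map to `beta-sheet`. No DSSP-style recomputation is attempted.
* **Hydrogen bonding** (`hbond_category()`): geometric criterion with
  the amide N–H as donor — N···O distance ≤ 3.5 Å and N–H···O angle
  ≥ 120°, relaxed values standard for survey-style H-bond detection.
  The amide hydrogen is taken from the file when present and otherwise
  rebuilt in the plane of C(i−1), N, CA at 1.01 Å along the external
  bisector. Acceptors covalently adjacent to the donor are excluded.
  When several acceptors qualify, the category follows the precedence
  main-chain O > side-chain O > water — one category per hydrogen is
  required, ties are not described by the model's source, and main-chain
  bonds dominate real data — while the returned count `n_hbond` keeps
  all qualifying acceptors (it is the $N_i^H$ of the phenomenological
  approximation).
* **Motion category** (`classify_motion()`): from the dependence of
  $\Delta G_{ex}$ on denaturant concentration. A fitted slope magnitude
  below 0.5 kcal/mol/M → `L`; otherwise a quadratic lack-of-fit term
  significant at α = 0.05 → `UD` (sub-global unfolding); otherwise
  `UD+EX1` (strong linear dependence, global unfolding). The qualitative
  rules ("little change", "non-linear", "strong linear") are not
  quantified anywhere authoritative, so both thresholds are exposed as
  arguments; the defaults are the package's own calibration. A guard
  requires the fitted curvature to contribute non-negligibly over the
  concentration range, so numerically perfect linear series cannot be
  called `UD` through round-off. `EX1` is an experimental elevated-pH
  label and is never produced by the classifier; it enters through
  annotation tables.

## Intrinsic rates

`intrinsic_rate()` implements the standard reference parameterization
for hydrogen-to-deuterium exchange in D2O: per-residue acid/base
inductive log-factors for the residue's own side chain and its
predecessor, poly-DL-alanine reference constants
($\log k_A = 1.62$, $\log k_B = 10.18$, $\log k_W = -1.5$ per minute,
$pK_D = 15.05$), N/C-terminal charge factors, and Arrhenius corrections
(14/17/19 kcal/mol) from the 293.15 K reference. The factor table is a
versioned CSV under `inst/extdata/` and can be replaced via
`bai_params(path = ...)`. Rates are stored in 1/s (labelling times in
HDX-MS span seconds to days); the CLI converts to 1/min on request.
Default conditions are pD 7.0 and 293.15 K — typical HDX bench
conditions, configurable because experimental conditions for any given
dataset are rarely the defaults. pD is used directly; no glass-electrode
correction is applied.

## Deuterium uptake

`residue_uptake()` is the single-exponential EX2-style forward model
$D_i(t) = 1 - e^{-(k_{int,i}/PF_i)t}$; `peptide_uptake()` sums residues
2..n of a peptide. Only the first residue is excluded — not the first
two, as some HX conventions have it — and prolines contribute zero and
reduce the attainable maximum. Back exchange is available only as an
optional scalar multiplier (default 1), a deliberate simplification:
residue-level back-exchange modelling would need per-residue handling
conditions that are out of scope. The default time grid is 16 points
from 30 s to 16 days; the endpoints are fixed by convention in the
datasets this package targets, the geometric spacing is the package's
choice (uptake curves are viewed on log-time axes), and any explicit
grid can be supplied instead. The infinite-protection sentinel
(`PF = Inf`, from a zero exchange rate or an empty COREX denominator)
propagates to zero uptake at all finite times rather than erroring.

## COREX-style aggregation

`corex_pf()` consumes an externally generated microstate ensemble:
Boltzmann probabilities over state free energies (log-sum-exp
stabilised, shift-invariant), then
$PF_i = (\sum_{folded, \neg exposed} \Pr(s) - \Pr(i)) /
        (\sum_{unfolded, exposed} \Pr(s) - \Pr(i))$.
$\Pr(i)$ — the probability that residue *i* is solvent accessible
natively or through unfolding of others — cannot be computed from the
ensemble flags alone, so it is an input column (per residue) and
defaults to 0 with a warning. Ensemble generation (ASA-based
$\Delta G_s$, conformational entropy, window/partition enumeration) is
deliberately out of scope.

## Synthetic data: what it does and does not emulate

`simulate_pf_dataset()` draws covariates from a `covariate_spec()` and
generates logPF as linear predictor plus $N(0, \sigma^2)$ noise — by
construction exactly the model's assumed data-generating process.
Defaults emulate a globular α/β protein: motion L/UD/EX1/UD+EX1 with
probabilities 0.4/0.2/0.2/0.2, secondary structure no/helix/sheet
0.3/0.45/0.25, H-bonding dominated by main-chain acceptors (0.75), and
burial Poisson with mean 59.1 — the mean burial of the training
hydrogens the published coefficient set was fitted to. Default noise is
σ = 0.5 logPF units, the order of scatter seen between measured and
well-predicted logPFs.

What the generator does **not** emulate: spatial correlation along the
chain, correlation between covariates (helical residues are also
buried and H-bonded in real proteins), non-Gaussian measurement error,
and any misspecification of the linear model itself. Passing
recovery tests therefore demonstrates the estimator and the plumbing,
not that the model is adequate for real proteins. The synthetic
structures (`make_synthetic_structure()`) are idealised poly-alanine
backbones (canonical α-helix: φ = −57°, ψ = −47°, rise ≈ 1.5 Å, twist
≈ 100°/residue, O(i)···N(i+4) ≈ 3.1 Å) and exact-distance point clouds;
they validate geometry code, not biology.

## Numerical and interface choices

* CSV interchange writes doubles with 17 significant digits, so
  write/read round-trips are bit exact; tables are validated against
  closed category sets and key uniqueness on both read and write.
* PDB input keeps only MODEL 1 of multi-model files (single-conformer
  feature definitions) and resolves alternate locations to the
  highest-occupancy conformer, ties broken alphabetically ('A' wins) for
  determinism. Element symbols missing from columns 77–78 are inferred
  from atom names (`" CA "` is a C-α carbon, not calcium); this
  inference targets standard protein/solvent atoms and can misread
  exotic two-letter HETATM elements that lack element columns.
* Author residue numbering (with insertion codes) is the coordinate
  system everywhere, matching HELIX/SHEET records and per-residue
  experiment tables. No renumbering is ever applied.
* The pipeline configuration is JSON — one bit-exact, dependency-free
  format; every setting is also a function argument, and the run
  manifest records input/output checksums, package version, seed and
  parameters so runs are byte-reproducible.
* Test problem sizes are chosen to keep the default suite fast while
  leaving statistical headroom: coefficient recovery uses n = 500
  observations at σ = 0.3 over 100 seeds with a 3-standard-error
  criterion; the covariate-coverage check uses n = 200 at σ = 0.5 over
  40 replicates; oracle equivalence for burial runs on 100 random point
  clouds of up to ~40 atoms.

## Known limitations

* The published coefficient set comes from 30 training hydrogens of a
  single protein; it is a demonstration that motion information carries
  most of the signal, not a transferable universal model. Refit on your
  own system when measured logPFs and motion assignments exist.
* Motion categories must be supplied (or derived from denaturant
  series); no structure-only predictor of the motion category exists
  here.
* The intrinsic-rate implementation covers the standard D2O
  parameterization with termini factors; side-chain ionisation-state
  variants (protonated Asp/Glu at low pD, cis-proline) are not
  separately tabulated.
* EX1 bimodal isotope envelopes, per-residue back exchange and
  mmCIF input are out of scope.
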