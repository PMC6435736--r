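---
title: "Ensemble order parameters and disorder-predictor benchmarking"
author: "DisorderBench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble order parameters and disorder-predictor benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DisorderBench)
```

## The problem

Intrinsically disordered proteins and disordered regions lack a stable
tertiary structure, and dozens of sequence-based predictors estimate a
per-residue probability of disorder. Judging those predictors requires a
ground truth, and the usual ones are problematic: curated disorder
databases cover few proteins and label whole regions, while missing
electron density in X-ray structures is rare (a few percent of residues)
and short-ranged, so both give heavily imbalanced, binary labels.

`DisorderBench` implements an alternative built on two continuous,
site-specific measures:

* **chemical-shift Z-scores** -- per-residue deviations of assigned NMR
  chemical shifts from random-coil reference values. High Z means
  ordered; `Z < 8` is the conventional binary disorder criterion. The
  package consumes these as input (or simulates them); it does not
  compute them from shifts.
* **structural variation across an NMR ensemble**, summarised by two
  per-residue order parameters, `S` (dihedral-angle route) and `T`
  (coordinate route), both in (0, 1] with 1 = rigid.

Around these it provides the full benchmarking toolbox: correlation of
predicted probabilities with Z, ROC/AUC and Matthews correlation at the
`Z < 8` criterion, a bias/discrimination decomposition of the predicted
probabilities, and Jensen-Shannon divergences between conditional
Z-score distributions.

## The order parameters

For one backbone dihedral angle observed in `N` conformers, the circular
concentration statistic is

$$S_{HW}(\theta) = \frac{1}{N}\sqrt{\Big(\sum_{i=1}^N \sin\theta_i\Big)^2 +
  \Big(\sum_{i=1}^N \cos\theta_i\Big)^2},$$

the length of the mean unit vector on the circle: 1 when the angle is
identical in every conformer, 0 under symmetric dispersion. Residue
`i`'s dihedral order parameter averages the six angles flanking it
(phi and psi of residues `i-1`, `i`, `i+1`):

$$D_i = \frac{1}{6}\sum_{j=i-1}^{i+1}\big(S_{HW}(\varphi_j) + S_{HW}(\psi_j)\big),$$

which is converted to an effective torsion-angle standard deviation
`s(i) = 2 arccos(1 + ln(D_i)/2)` (degrees).

The coordinate route is superposition-free. The inter-atomic variance
matrix holds the population variance (divisor `N`) of every
CA(i)--CA(j) distance over the conformers. For residue `i`, its row --
excluding the diagonal and the next-to-diagonal elements, whose
distances are fixed by covalent geometry -- is sorted ascending into
$\lambda_{i1} \le \dots \le \lambda_{in}$ and averaged with rank weights
that emphasise the most invariant distances:

$$t(i) = \frac{\sum_j w_j \sqrt{\lambda_{ij}}}{\sum_j w_j}, \qquad
  w_j = e^{-\beta (j/n)^2}, \quad \beta = 10.$$

Both variation measures map onto order parameters through the same
Lorentzian,

$$S = \frac{1}{1 + (s/s_0)^2}, \qquad T = \frac{1}{1 + (t/t_0)^2},$$

with reference values `s0 = 75` degrees and `t0 = 1.5` Angstrom: zero
variation gives 1, variation at the reference gives 0.5.

```{r order-example}
sim <- genEnsemble(generatorConfig(seed = 3, L = 40, nConformers = 10))
prof <- ensembleOrderProfile(sim$ensemble)
head(orderTable(prof), 3)
```

### Numerical choices

* **Termini and chain breaks.** The six-term sum defining `D_i` loses
  terms at chain ends (phi of the first residue and psi of the last are
  undefined), across chain breaks (consecutive CA--CA distance above
  4.5 Angstrom in any conformer, a generous bound on peptide geometry),
  and at missing backbone atoms. The implementation averages the
  *defined* terms -- the divisor is their count -- which keeps
  `D_i` in [0, 1]; a residue with no defined flanking angle is flagged
  `NA`. Undefined is always `NA`, never a silent zero.
* **Saturation of `s`.** For `D` below `exp(-4)` the arccos argument
  falls below -1; it is clamped, so `s` saturates continuously at 360
  degrees.
* **The rank count `n`.** For interior residues the retained row length
  is the number of residues minus 3; edge rows retain one element more.
  The per-row count is used so the weights stay well defined for every
  row.
* **Variance divisor.** Population (`1/N`), not sample (`1/(N-1)`), and
  computed in two passes so an ensemble of identical conformers gives
  exactly zero.
* **Dihedral convention.** IUPAC, degrees in (-180, 180], validated in
  the tests against both a forward geometry constructor and the
  `bio3d` torsion routine.

## Benchmarking metrics

Predictions are matched to Z-scores on residue number; residues present
in only one profile are excluded, and metrics are computed over all
residues pooled across the cohort (a per-protein route can be had by
benchmarking profiles individually). Because Z grows with *order* while
p estimates *disorder*, a good predictor has Pearson correlation `R_P`
near -1; methods are ranked by `|R_P|`, with AUC and name as
tie-breaks. Spearman correlation `R_S` and AUC are reported `n.a.` for
binary predictors, for which they are not meaningful.

The ROC is built over unique probability cutoffs with ties grouped --
coarsely rounded server outputs produce visibly edgy curves -- and
integrated with the trapezoidal rule, which with grouped ties equals
the tie-corrected Mann-Whitney statistic; the test suite asserts that
equivalence exactly against an exhaustive pairwise count. The confusion
analysis predicts disordered at `p >= 0.5` by default (configurable per
method, since some published analyses used other cutoffs without
printing them) and labels disordered at `Z < 8`, strictly: `Z = 8` is
ordered. MCC uses the zero-marginal convention (0 when a row or column
of the table is empty).

The bias decomposition averages the predicted probability over truly
disordered (`pZL`, mean p where `Z < 8`) and truly ordered residues
(`pZH`, mean p where `Z > 8`; Z exactly 8 enters neither mean,
following the strict inequalities that define both sides). Then
`pZA = (pZL + pZH)/2` measures bias -- 0.5 is unbiased, below 0.3 the
method considerably under-predicts disorder, above 0.7 it over-predicts
-- and `pZD = pZL - pZH` measures discrimination.

`optimalZThreshold()` scans a grid of candidate Z thresholds and
returns the one maximising the mean MCC across methods. MCC was chosen
as the objective because it is the balanced confusion summary already
used throughout the analysis; this is a design choice of the package,
with ties broken toward 8.0 and then toward the smaller threshold.

Raw outputs of NMR-trained predictors are calibrated into
pseudo-probabilities before benchmarking: secondary-structure
populations via `p = 1 - (pHelix + pSheet)` and backbone order
parameters via the bijection `p = sqrt(1 - S2)`.

## Jensen-Shannon divergences

To quantify how much a structural classification tells about the
Z-score, the package histograms Z conditional on the two classes --
order parameter above/below 0.5 (equivalently, variation below/above
its reference value; the package pairs the angular reference with
degrees and the distance reference with Angstrom throughout), or X-ray
observed vs. missing -- and computes

$$JSD(P, Q) = \tfrac{1}{2} D(P\|M) + \tfrac{1}{2} D(Q\|M), \qquad
  M = \tfrac{1}{2}(P + Q),$$

with `D` the Kullback-Leibler divergence. The natural logarithm is the
default (bound `ln 2`); base 2 is exposed. Bins are 1.0 Z-units wide
over [-5, 20] with open outer bins, wide enough to resolve the bimodal
Z structure without empty-bin noise; since `M` dominates both
arguments, no pseudo-counts are needed.

## The synthetic-data generator

Real inputs -- a chemical-shift Z-score database and the outputs of
dozens of predictor web servers -- cannot be bundled or downloaded at
test time, so every analysis stage is exercised on simulated data with
*planted* truth:

* **Z-scores** come from a two-component Gaussian mixture over an
  ordered/disordered segmentation: disordered residues
  `N(3.0, 2.0)`, ordered `N(12.0, 2.0)`. These defaults straddle the
  `Z = 8` criterion with modest overlap, reproducing the bimodal,
  four-quadrant structure of real Z-vs-p scatter plots; the component
  parameters are adjustable (the threshold-recovery analyses use means
  4 and 12, planting the class boundary exactly at 8).
* **Predictors** are two-level with additive Gaussian noise:
  `p = b + d/2` on disordered and `b - d/2` on ordered residues, so the
  planted bias `b` and discrimination `d` are analytically exact
  expectations of `pZA` and `pZD` -- the property the recovery tests
  rely on. A logistic-in-Z variant is provided for more realistic ROC
  shapes but is not used as a recovery target.
* **Ensembles** are idealised poly-alanine backbones (standard peptide
  bond lengths and angles, rebuilt from internal coordinates per
  conformer) whose phi/psi receive per-residue Gaussian perturbations:
  3 degrees on ordered residues, 60 degrees on disordered ones by
  default.
* **X-ray labels** flag disordered residues missing with a configurable
  rate, reproducing the class imbalance of crystallographic disorder.

All generators are pure functions of their configuration: the RNG is
seeded from `config@seed` plus a fixed per-generator offset, and the
caller's RNG state is restored.

What the generator does *not* emulate: per-residue correlation of
Z-scores along the sequence, heavy-tailed or method-specific predictor
error profiles, physically realistic conformational sampling (excluded
volume, side chains), and sequence-dependent flexibility. Passing
recovery tests therefore demonstrates the correctness of the metrics
and their estimators under the stated statistical conditions, not
predictor performance on real proteins.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run on deliberately small
cohorts chosen to keep the whole suite interactive while leaving the
stochastic checks well concentrated: recovery of planted bias and
discrimination uses 5000 residues and 10 seeds (binomial standard
errors near 0.003, an order of magnitude below the 0.03 acceptance
band); threshold recovery pools 10000 residues; ensemble analyses use
40--60 residues and 8--10 conformers. `scripts/acceptance.R` re-runs
the full pipeline from a single `--seed` and writes every headline
quantity as JSON.

## Limitations

* Chemical-shift Z-scores are consumed, never computed; benchmarking
  against real data requires the user to supply Z-score tables.
* PDB parsing is deliberately narrow: ATOM/MODEL/SEQRES/REMARK 465
  records, one chain at a time, no insertion codes (rejected with an
  error rather than mishandled), altloc `' '`/`'A'` only, no mmCIF.
* SEQRES carries no residue numbers; observed/missing labels anchor the
  SEQRES sequence at the smallest numbered residue seen in ATOM or
  REMARK 465 records, which is correct for single-segment numbering
  but approximate for exotic numbering schemes.
* The per-residue `S`/`T` profiles describe ensemble heterogeneity; for
  an NMR bundle that reflects restraint density as well as true
  dynamics, so they are a proxy for, not a measurement of, local
  disorder.
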