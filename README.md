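# DisorderBench

Site-specific protein disorder from NMR structure ensembles, and
benchmarking of per-residue disorder predictors against continuous
chemical-shift Z-scores.

## What it is for

Intrinsically disordered proteins and regions lack stable tertiary
structure; many sequence-based predictors estimate a per-residue
probability of disorder *p*. Evaluating them against curated disorder
databases or missing X-ray density means evaluating against sparse,
imbalanced, binary labels. This package targets users who instead have
(or simulate) two *continuous* site-specific measures:

* **Z-scores** derived from NMR chemical shifts (high Z = ordered;
  `Z < 8` is the binary disorder criterion), and
* **structural variation across a conformer ensemble**, summarised per
  residue by a dihedral-angle order parameter **S** and a
  superposition-free coordinate order parameter **T**, both in (0, 1].

The core quantities:

* circular order parameter of one dihedral over N conformers:
  `S_HW = (1/N) * sqrt((Σ sin θ)² + (Σ cos θ)²)`; residue-level
  `D_i = (1/6) Σ_{j=i-1..i+1} (S_HW(φ_j) + S_HW(ψ_j))`, converted to an
  angular standard deviation `s = 2 arccos(1 + ln(D)/2)`;
* inter-atomic variance matrix `v_ij = (1/N) Σ_k (d_ijk − d̄_ij)²` of
  all CA–CA distances, reduced per residue to a rank-weighted variation
  `t(i) = Σ w_j sqrt(λ_ij) / Σ w_j`, `w_j = exp(−β (j/n)²)`, β = 10;
* order parameters `S = 1/(1 + (s/s0)²)`, `T = 1/(1 + (t/t0)²)` with
  s0 = 75°, t0 = 1.5 Å;
* benchmarking metrics: Pearson/Spearman correlation of (p, Z), ROC/AUC
  at `Z < 8`, confusion counts with MCC/FPR/FNR, the bias decomposition
  pZL/pZH/pZA/pZD, bias classification (pZA < 0.3 under-predicts,
  pZA > 0.7 over-predicts), Z-threshold optimization by mean MCC, and
  Jensen-Shannon divergence between conditional Z distributions;
* I/O for multi-model PDB ensembles, SEQRES/REMARK 465 missing-residue
  labels, Z-score and predictor tables, TSV+JSON benchmark reports;
* a fully seeded synthetic-data generator (bimodal Z profiles,
  predictors with planted bias *b* and discrimination *d*, poly-alanine
  ensembles with planted flexibility) so the whole analysis is testable
  offline.

## Worked example

Benchmark two simulated predictors — one well-calibrated and sharp
(b = 0.5, d = 0.8), one biased and blunt (b = 0.2, d = 0.2) — on a
three-protein cohort:

```r
library(DisorderBench)
cfg <- runConfig(nProteins = 3,
                 generator = generatorConfig(seed = 42, L = 500,
                                             fractionDisordered = 0.5),
                 methods = data.frame(name = c("sharp", "blunt"),
                                      bias = c(0.5, 0.2),
                                      discrimination = c(0.8, 0.2)))
res <- runBenchmark(cfg)
res$table[, c("method", "n", "R_P", "R_S", "AUC", "MCC", "pZA", "pZD")]
#>   method    n    R_P    R_S   AUC   MCC   pZA   pZD
#> 1  sharp 1500 -0.906 -0.741 0.984 0.972 0.491 0.777
#> 2  blunt 1500 -0.818 -0.749 0.983 0.000 0.198 0.196
res$biasCategories
#>                     sharp                     blunt
#>          "unbiased-range" "under-predicts-disorder"
```

Reading the row for `sharp`: its predicted probabilities correlate
strongly and negatively with Z (R_P = −0.906; Z measures order, p
measures disorder, so −1 is perfect), it separates the classes almost
perfectly (AUC 0.984, MCC 0.972), and its recovered bias/discrimination
(pZA ≈ 0.49, pZD ≈ 0.78) sit at the planted values (0.5, 0.8). `blunt`
still ranks residues well (AUC 0.983) but its probabilities are shifted
low: pZA ≈ 0.2 flags it as under-predicting disorder, and at the
p ≥ 0.5 cutoff it predicts nothing disordered, so its MCC collapses to
0 — exactly the failure mode the bias decomposition is designed to
expose.

Order parameters of a simulated ensemble with a rigid core and a floppy
tail:

```r
sim <- genEnsemble(generatorConfig(seed = 7, L = 40, nConformers = 10))
prof <- ensembleOrderProfile(sim$ensemble)
prof
#> OrderParameterProfile 'sim': 40 residues, mean S = 0.825, mean T = 0.822
head(orderTable(prof), 3)
#>   resno resname     D    s     S      t     T
#> 1     1     ALA 0.999 3.29 0.998 0.0973 0.996
#> 2     2     ALA 0.999 4.16 0.997 0.0970 0.996
#> 3     3     ALA 0.999 3.85 0.997 0.0879 0.997
```

The planted-rigid residues average S ≈ 0.99, the planted-floppy tail
S ≈ 0.44.

## Documentation

The methods vignette (`vignettes/disorder-benchmarking.Rmd`) describes
the model, the numerical conventions (termini, chain breaks, variance
divisor, histogram binning, tie-breaks), what the synthetic generator
does and does not emulate, and the package's design decisions.
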