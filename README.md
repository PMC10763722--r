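# TitinScope

Quantitative analysis of truncated-titin integration into the human cardiac
sarcomere, for muscle biophysicists and cardiac genetics labs working with
STED super-resolution images of antibody-labelled myofibrils and
high-resolution SDS-agarose titin gels.

Heterozygous truncating variants in *TTN* (TTNtv) are the leading genetic
cause of dilated cardiomyopathy. Because truncated titin carries no unique
epitope, its sarcomeric integration must be inferred from the geometry of
sequence-specific antibody bands — MIR at the I/A junction, A170 at the
titin-kinase (TK) region — measured as a function of sarcomere length (SL),
and from gel densitometry of the truncated protein band. TitinScope
implements that entire inference chain, together with a seeded generative
simulator so that every stage is testable without patient data.

## The model at its core

For a sarcomere of length $L$ with M-line at $M = L/2$, epitope band
positions are affine in SL per genotype:

* MIR (full-length): $M \pm L_A(L)/2$, with A-band titin length
  $L_A(L) = L_A^{slack} + m_A (L - 1.8\,\mu m)$
  (TTNtv–: $L_A^{slack} = 1400$ nm, $m_A = 236$ nm/µm);
* A170: $M \pm d_{TK}(L)$, with
  $d_{TK}(L) = d^{slack} + m_d (L - 1.8\,\mu m)$
  (TTNtv–: $d^{slack} = 70$ nm, $m_d = +25$ nm/µm; TTNtv+: 80 nm and
  $m_d < 0$);
* truncated molecules (TTNtv+, fraction 0.5): MIR displaced Z-ward by
  $\max(0, 30 - 35\,(L - 1.8\,\mu m))$ nm and no A170 epitope.

The profiler recovers these quantities from two-channel line profiles by
prominence-gated Gaussian peak fitting, assignment of the epitope grammar
[MIR, A170, A170, MIR], the 20% cross-M-line intensity-fluctuation QC
rule, and the per-sarcomere metrics (A-band titin length, M-to-TK
distance = half the A170 doublet separation, FWHMs, A170/MIR intensity
ratio). The densitometry module adds mobility calibration
(migration vs log10 MW), baseline-corrected band integration, the titin
stoichiometry ratios (N2BA/N2B, T1/MyHC, T2/T1, truncated/T1, integrated
titin/MyHC), and truncated-band identification by mass match against the
residue-coordinate model of the 35,991-residue titin IC isoform.

## Worked example

```r
library(TitinScope)

# simulate 200 TTNtv- profiles at slack and recover the nanostructure
p  <- stedSimParams(genotype = "TTNTV_NEG", seed = 1)
m  <- profileDataset(simulateStretchSeries(p, 1.8, 200))
mq <- m[m$qc_pass, ]
round(c(a170_sep = mean(mq$a170_separation_nm),
        dtk      = mean(mq$dtk_nm),
        aband    = mean(mq$aband_titin_len_nm)), 2)
#> a170_sep      dtk    aband
#>   140.30    70.15  1400.02
```

The A170 doublet separation (~140 nm) and M-to-TK distance (~70 nm) match
the generative slack geometry; the A-band titin length recovers 1400 nm.
Stretch series expose the genotype contrast:

```r
s   <- stedSimParams(genotype = "TTNTV_NEG", seed = 2)
ms  <- profileDataset(simulateStretchSeries(s, c(1.8, 2.0, 2.2, 2.4, 2.6), 50))
fitLengthRegression(ms, "aband_titin_len_nm")
#> lengthRegression of aband_titin_len_nm: slope 234.719 +/- 1.839 per um,
#>   intercept at 1.8 um 1400.34 (n=441)
```

a slope within two standard errors of the generative 236 nm/µm. The
cohort module reproduces sample-level variant summaries from a TSV:

```r
summarizeCohort(loadVariantTable(syntheticCohortPath()))
#> cohortSummary: 127 samples; TTNtv+ 19 (15.0%); DCM-gene+ 35 (27.6%)
#>   TTN truncating consequences: frameshift=8, nonsense=11, splice=0
```

and `intensityRatioSummary(0.1765, 0.2646)` gives the A170/MIR
between-group ratio 0.667 (a 33% reduction), consistent with roughly half
of the sarcomeric titins lacking the TK-region epitope at heterozygous
truncation dosage.

## Layout

* `R/` — S4 classes (`TitinIsoformModel`, `GenotypeParams`,
  `EpitopeLayout`, `IntensityProfile`, `GelLaneProfile`,
  `MobilityCalibration`) and the module functions.
* `inst/extdata/` — titin IC isoform region/epitope fixture (JSON) and a
  synthetic DCM cohort variant table (TSV).
* `vignettes/titin-sarcomere-analysis.Rmd` — the methods vignette:
  model assumptions, simulator scope, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance suites.
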