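# radialFISH

Quantitative analysis of **radial gene positioning** in FISH images of
interphase nuclei, and evaluation of positioning patterns as tissue
stratification biomarkers.

Most gene loci occupy preferred radial positions in the interphase nucleus,
and individual loci reposition in disease. Given 2D label masks of segmented
nuclei and matching FISH intensity channels, `radialFISH` measures, for
every detected allele, its **relative radial position**

RRP = EDT(spot) / max EDT(nucleus) ∈ [0, 1]

where EDT is the Euclidean distance transform of the nucleus mask (0 =
nuclear periphery, 1 = nuclear center). Pooling all alleles of a gene in a
tissue gives its relative radial distribution (RRD); pooling the RRDs of
normal tissues gives the pooled normal distribution (PND). A tissue is
called *repositioned* for a gene when the two-sample Kolmogorov–Smirnov
test of RRD vs PND gives p < 0.01, labeled **I** (more internal, median RRP
above the reference) or **P** (more peripheral). The `strata` layer groups
tissues by Gleason score/grade, T stage, metastatic status and composite
clinical risk, and scores single or multiplexed gene markers by their false
negative and false positive rates.

A synthetic tissue simulator (`simulateTissue()`) generates labeled nuclei
and FISH channels with *known* ground-truth radial distributions, so the
entire measurement pipeline is testable without external image data. A
curated prostate cohort (32 cancers, 25 benign tissues; *SP100*, *TGFB3*,
*SATB1*, *LMNA*) ships with the package for worked examples.

## Worked example

```r
library(radialFISH)
cohort <- loadProstateCohort()

subgroupSummary(cohort$calls, cohort$clinical, "SP100", "gleason_group")
#>          group n_assayed n_repositioned  pct_any n_internal pct_internal n_peripheral pct_peripheral
#> 1          low        11              6 54.54545          0            0            6            100
#> 2 intermediate         8              3 37.50000          3          100            0              0
#> 3         high         8              3 37.50000          2     66.66667            1       33.33333
```

*SP100* repositions in about half of the low-Gleason cancers — always
toward the nuclear periphery — while in Gleason ≥ 7 cancers the shifts are
predominantly internal. Scoring peripheral *SP100* as a low-Gleason marker:

```r
cl <- cohort$clinical
low     <- cl$tissue_id[cl$tissue_class == "cancer" & cl$gleason_group == "low"]
others  <- setdiff(cl$tissue_id, low)
evaluateMarker(cohort$calls, low, others, c(SP100 = "P"))
#> Marker rule [SP100:P]
#>   positives: 11 (flagged 6) -> FNR 45.5%
#>   negatives: 28 (flagged 1) -> FPR 3.6%
#>   excluded (not fully assayed): C27, C30, C9, C18, C19, N3, N4, ...
```

High sensitivity it is not (FNR 45.5%), but the false positive rate is low
because the peripheral direction is specific to the low-Gleason subgroup.

End-to-end on synthetic data:

```r
tissues <- data.frame(tissue_id = c("N1", "N2", "C1"),
                      tissue_class = c("normal", "normal", "cancer"))
models <- list(normal = list(G = radialModel("beta", 2, 2)),
               cancer = list(G = radialModel("beta", 2, 5)))  # peripheral shift
out <- runFullPipeline(tissues, models,
                       simTissueConfig(nNuclei = 25, canvasSize = c(500, 500),
                                       noiseSd = 0),
                       seed = 7, minNuclei = 10)
out$calls[out$calls$tissue_id == "C1", c("tissue_id", "ks_D", "p_value", "call")]
#>   tissue_id     ks_D      p_value call
#> 3        C1 0.419519 3.512492e-05    P
```

See the vignette (`vignettes/radial-gene-positioning.Rmd`) for the model,
parameter defaults, simulator scope and design notes.

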