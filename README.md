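# radialFISH

Radial positioning of chromosome territories from FISH images of
interphase nuclei.

Interphase chromosomes occupy discrete territories whose radial nuclear
position — peripheral, intermediate or interior — is non-random and
changes when cells leave the cell cycle. In human dermal fibroblasts
the position of chromosome 10 even distinguishes the two
non-proliferating states: it is intermediate in young proliferating
cells, peripheral in serum-starved quiescent cells and interior in
replicatively senescent cells, making its radial position a candidate
senescence biomarker. This package implements the two classical
measurements behind such statements, for cell biologists who want a
scripted, tested version of the assay:

* **2D erosion-shell analysis.** The DAPI-segmented nucleus is divided
  into five concentric shells of equal area (shell 1 = periphery). For
  shell *k*, the normalized signal is

  ```
  N_k = (% probe signal in shell k) / (% DAPI signal in shell k)
  ```

  so `N_k = 1` means "distributed like bulk DNA". Profiles are averaged
  over nuclei (mean ± SEM, customarily n = 50) and categorized by the
  skew `P − I`, with `P = mean(N_1, N_2)` and `I = mean(N_4, N_5)`:
  peripheral if `P − I > δ`, interior if `I − P > δ`, intermediate
  otherwise (δ = 0.1).

* **3D centre-to-edge analysis.** In confocal stacks (0.2 µm axial
  step) each territory contributes the anisotropy-corrected distance
  (µm) from its geometric centre to the nearest nuclear edge; distances
  from ≥ 20 nuclei are binned in 0.5 µm increments into frequency
  distributions.

* **Statistics.** Per-shell and per-distribution comparisons use the
  unpaired, unequal-variance, two-tailed (Welch) t-test; the
  chromosome-size-vs-position association uses Kendall's tau-b on a
  packaged table of GRCh37 sizes and per-condition categories.

* **Synthetic data.** A generator of 2D FISH-like images and 3D stacks
  with exact ground truth (territory placement at a controlled
  normalized radial fraction), including presets for the
  proliferating / quiescent / senescent chromosome-10 pattern, so the
  whole pipeline is testable without microscope data.

## Worked example

Simulate a senescent-preset dataset, run the 2D erosion assay and
categorize the aggregate profile:

```r
library(radialFISH)

ds <- simulateConditionDataset("senescent", n = 10, seed = 42)
profiles <- analyzeCondition2D(ds$images)
head(profiles, 5)
#>                    id shell probe_pct dapi_pct normalized
#> 1 chr10-senescent-001     1  14.95191 19.98335  0.7482184
#> 2 chr10-senescent-001     2  15.23758 19.99468  0.7620815
#> 3 chr10-senescent-001     3  14.99523 19.98923  0.7501654
#> 4 chr10-senescent-001     4  14.90804 20.01979  0.7446650
#> 5 chr10-senescent-001     5  39.90725 20.01295  1.9940714

cp <- aggregateProfiles(profiles, "senescent", "10")
cp
#> ConditionProfile 'senescent' (chromosome 10), n = 10 nuclei
#>   mean +/- SEM per shell (1 = periphery):
#>   0.695+/-0.011  0.697+/-0.012  0.698+/-0.012  0.695+/-0.011  2.214+/-0.045

categorizePosition(cp)
#> [1] interior
#> Levels: interior < intermediate < peripheral
```

Each nucleus holds ~20% of its DAPI in every equal-area shell, while
the probe signal of this preset concentrates in shell 5 — the nuclear
interior — so the normalized profile skews inward and the condition is
categorized `interior`. `plotShellProfile(cp)` draws the standard
shell histogram with SEM bars.

The packaged size/category table shows positioning following
chromosome size more strongly out of cycle:

```r
tab <- chromosomePositions()
rbind(sizeCategoryAssociation(tab, "proliferating"),
      sizeCategoryAssociation(tab, "quiescent"),
      sizeCategoryAssociation(tab, "senescent"))
#>       condition  n       tau      p_value
#> 1 proliferating 24 0.4653422 4.709679e-03
#> 2     quiescent 24 0.6361173 1.395000e-04
#> 3     senescent 24 0.7226817 1.517025e-05
```

For the 3D assay, see `simulateStack3D()`, `analyzeCondition3D()`,
`binDistances()` and `compareDistributions()`; the methods vignette
(`vignettes/radial-positioning.Rmd`) documents the model, parameter
choices and limitations.

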