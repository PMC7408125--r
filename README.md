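# strainmet

Strain-level chemical and genomic heterogeneity analysis for bacterial
natural-product discovery.

## The problem

Strain prioritization ("dereplication") trims culture collections down to one
representative per species before screening for natural products, on the
assumption that conspecific strains make the same molecules. For specialized
metabolite producers such as *Streptomyces* that assumption fails in both
directions: biosynthetic gene clusters (BGCs) can be strain-specific, and even
a BGC conserved across all strains of a species can yield different compounds
at very different levels. `strainmet` packages the computational side of
testing that assumption: it quantifies, for a set of conspecific strains, how
much of the species' chemistry and BGC repertoire a single reference strain
would have revealed.

It is aimed at metabolomics/genome-mining practitioners who have per-strain
MS/MS runs (MGF), chromatographic traces, BGC presence/absence calls and
cluster coding sequences, and want reproducible strain-resolved statistics
rather than a web-service round trip.

## What it computes

* **Molecular networking.** Spectra are clustered into consensus nodes
  (greedy, minimum cluster size 4) and connected when their *modified cosine*
  exceeds a threshold. For peak weight vectors *w* (square-root intensities,
  L2-normalized) the score is

  `cos(A, B) = max over one-to-one matchings Σ w_A(i) · w_B(j)`

  where peaks match within the fragment tolerance either directly or offset
  by the precursor mass difference. Defaults: parent tolerance 0.01 Da,
  fragment tolerance 0.5 Da, cosine ≥ 0.7, library hits at score ≥ 0.5 with
  ≥ 2 matched peaks.
* **Tag-fragment classification.** Diagnostic fragments (m/z 121.06, 255.04,
  178.05) assign nodes to three bagremycin-related compound groups, with
  neutral-loss fallback and majority voting across cluster members.
* **Exact-mass formula tools.** Monoisotopic masses, electron-corrected ion
  m/z under both printed-formula conventions ([M+H]⁺ of a neutral vs. direct
  cation), signed ppm errors, RDBE, coarse isotope patterns, and exhaustive
  CHNOS decomposition of a target m/z within ppm tolerance.
* **Semi-quantification.** EIC extraction, baseline-subtracted trapezoidal
  peak areas, and relative abundance RA(s, c) = 100 · A(s, c)/A(ref, c) with
  the reference strain fixed to 100%; compounds the reference does not make
  are flagged instead of divided by zero.
* **Profile analytics.** Presence calls, strain-exclusive compound counts,
  new-compound-in-reference statistics, glog transform
  `x → log((x + √(x² + λ²))/2)` with Pareto scaling, and Euclidean /
  complete-linkage clustering of strains and metabolites.
* **Pan-BGC and mutation statistics.** Core/non-core/unique partitions of a
  strains × BGC-family matrix with "grape" network export, plus
  silent/non-silent/in-frame-deletion profiling of conserved-cluster CDSs
  (codon table 11) from affine-gap global alignments.
* **Synthetic data.** Every input above can be generated with a seeded,
  truth-tracked simulator, so the full pipeline is testable offline.

## Worked example

```r
library(strainmet)

ionMz("C10H11N2O4S+", "cation")            # group 2 tag fragment
#> [1] 255.0434
round(ionMz("C20H20N2O6S", "protonated"), 4)  # bagremycin C [M+H]+
#> [1] 417.1115
head(decomposeMass(417.1115, "protonated", tolPpm = 3)[, c("formula", "ppm")], 3)
#>       formula       ppm
#> 1 C20H20N2O6S 0.0387541
#> 2  C13H22NO14 0.4654600
#> 3  C19H22N5S3 1.1742769

# packaged 33-compound table: how many of the 10 newly identified compounds
# does the reference strain make?
newInReference(loadCompoundTable(), "MM109")
#> $count     [1] 3
#> $nNew      [1] 10
#> $percent   [1] 30

# a simulated 7-strain, 24-compound study, end to end
cfg  <- simulationConfig(seed = 7)
lib  <- makeLibrary(cfg)
prod <- makeProduction(lib$library, cfg)
sp   <- simulateSpectra(lib$library, prod$production, cfg)   # 360 scans
net  <- assignNodeGroups(buildNetwork(clusterSpectra(sp)), sp)
net
#> MolecularNetwork: 24 nodes, 76 edges (min cosine 0.7)
length(constellations(net)); table(net@nodeGroups)
#> [1] 3
#> 1 2 3
#> 8 8 8

eic <- simulateEIC(lib$library, prod$production, cfg)
scm <- eicAbundanceMatrix(eic$traces,
                          setNames(lib$library$ionMz, lib$library$name))
relativeAbundance(scm)
#> RAMatrix: 7 strains x 24 compounds, reference MM109 = 100%
#>   (8 reference-nonproducer columns)

panBGCStats(makeBGCMatrix(18, 18, 19, 5, seed = 7)$matrix, "S1")
#> PanBGCStats: union 42 | core 18 | non-core 24 (57.1% strain-specific) |
#>   type strain 27 | absent from type strain 15 | unique 5
```

Every node of the simulated network recovers its planted tag group (8/8/8),
the three constellations are exactly the three planted compound families, and
the pan-BGC summary reads back the core/accessory/unique structure the
generator planted. `runPipeline(pipelineConfig(seed = 7))` runs all stages in
one call and writes MGF/TSV/GraphML/Newick artifacts plus a JSON report.

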