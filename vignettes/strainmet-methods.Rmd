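---
title: "Methods and design of strainmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of strainmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmet)
```

`strainmet` quantifies how much specialized-metabolite and BGC diversity a
set of conspecific bacterial strains hides below the species level. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the design decisions taken where the methodology was genuinely open.

## Exact-mass arithmetic

All mass computation is built on a single table of monoisotopic atomic
masses (C, H, N, O, S, P, Na, K, Cl, Fe) plus the proton
(1.007276466621 Da) and electron (0.000548579909 Da) masses. Two ion
conventions coexist in published compound tables and both are supported by
`ionMz()`:

* **protonated**: the printed formula is the neutral molecule M and the ion
  is $[M+zH]^{z+}$, so $m/z = (M + z\,m_p)/z$;
* **cation**: the printed formula already includes the ionizing proton, so
  $m/z = (M - z\,m_e)/z$.

The electron-mass correction (~0.5 mDa) is what makes 4-decimal agreement
with high-resolution instruments possible; omitting it produces ~1–2 ppm
systematic error at m/z 300–600.

The packaged 33-compound table mixes both conventions row by row.
`loadCompoundTable()` resolves each row to whichever convention reproduces
the printed m/z within 1 ppm and flags the rest `inconsistent` (4 of 33
rows; one of them prints a formula whose mass is tens of ppm away from its
printed m/z, an apparent typesetting error). Flagged rows are kept, with
their printed annotations, but excluded from mass arithmetic — the fixture
stays honest about its source rather than silently "repairing" it. The
printed group 1 tag m/z (121.06) is likewise taken as authoritative over its
printed composition, which computes to 120.06.

`decomposeMass()` enumerates CHNOS compositions exhaustively within
per-element bounds (default C ≤ 60, H ≤ 80, N ≤ 6, O ≤ 15, S ≤ 3 — wide
enough for every compound in the packaged table with a small search space),
filters by |ppm| (default 3), RDBE ≥ −0.5 and an optional nitrogen-rule
check, and ranks by |ppm| with an atom-count tie-break. The enumeration
solves for the hydrogen count analytically per (C, N, O, S) combination, so
the loop is quadratic-ish rather than quintuple; the test suite pins it
against a literal five-nested-loop oracle on small bounds.

`isotopePattern()` is deliberately coarse: first-order heavy-isotope
abundance terms for M+1 and M+2 plus the two-heavy-atom term. Isotope
patterns are used as a qualitative plausibility check on formula
assignments, not for fine structure.

## Molecular networking

`cosineScore()` implements the modified cosine: peaks weighted by
intensity$^{0.5}$ (square-root weighting tempers base-peak dominance),
L2-normalized per spectrum, matched one-to-one within the fragment
tolerance either directly or shifted by the precursor mass difference.
Matching is greedy by descending weight product with deterministic
tie-breaking. Greedy matching can in principle fall short of the optimal
assignment; the tests bound it by an exhaustive-matching oracle on small
spectra and verify equality whenever candidate matches are unambiguous.
Scores are symmetric, in [0, 1], and 1 exactly for identical spectra.

`clusterSpectra()` re-implements consensus clustering as a greedy single
pass over precursor-sorted spectra: a scan joins the open cluster when its
precursor is within the parent tolerance of the cluster median *and* its
plain cosine against the running consensus meets the threshold. Clusters
below the minimum size (default 4 spectra) are discarded. Exact internals
of the original clustering tools are not published; a deterministic greedy
pass is used because reproducibility matters more here than bit-level
mimicry of any particular tool.

Defaults (`scoringParams()`): parent tolerance 0.01 Da, fragment tolerance
0.5 Da, cosine threshold 0.7 applied both to cluster joining and to network
edges (the two knobs are exposed separately but share the default, since
the source protocols do not distinguish them), minimum cluster size 4,
library matching at score 0.5 with at least 2 matched fragment peaks. No
topology pruning is applied by default; a top-K neighbor filter is
available but off, because no pruning parameters are part of the stated
protocol.

## Tag-fragment classification

Three diagnostic fragments assign bagremycin-related spectra to groups:
m/z 121.06 (group 1, p-vinylphenol series), 255.04 (group 2,
N-acetylcysteine sulfur series), 178.05 (group 3, lactones; alternative
unsaturated form at 176.0706). Screening (`screenTags()`) is absolute in Da
(default 0.01) because tags are printed at two decimals; ppm tolerances
would be tighter than the printed precision warrants. Groups 1 and 3 admit
a neutral-loss presentation: a fragment sitting the tag's neutral mass
(tag m/z minus a proton) below the precursor.

Classification (`classifyNode()`) is majority voting over member spectra,
with two deliberate conservatisms:

* **Direct evidence outranks neutral loss.** A precursor that happens to sit
  one tag-neutral-mass above an unrelated fragment would otherwise acquire a
  phantom second group; one compound in the packaged table does exactly this
  (its precursor minus its own group 1 tag equals the group 3 neutral mass
  to 0.1 mDa). Neutral-loss evidence is therefore only consulted when no
  charged tag was seen.
* **Multi-tag spectra go to ND**, not to multiple labels — published group
  assignments are single-valued per compound.

## Semi-quantification

`integratePeak()` integrates baseline-subtracted trapezoids. The baseline
is the median intensity outside the integration window — robust, parameter
free, and testable; vendor integrator behavior is neither published nor
portable. The automatic window is apex ± 3σ with σ from the full width at
half maximum, capturing 99.7% of a Gaussian peak (the tests require 2%
accuracy on closed-form Gaussian areas, and <1% relative-abundance recovery
on noise-free simulated chromatograms).

`relativeAbundance()` fixes the reference strain to 100% per compound. When
the reference does not produce a compound there is no denominator; rather
than inventing a pseudo-reference, those columns keep absolute areas and a
`reference-nonproducer` flag. Downstream best-producer calls work on either
representation since they only compare within a column.

## Profiles

Presence defaults to "any nonzero signal" (threshold 0 as a fraction of the
per-compound maximum), matching the detection semantics of published
producing-strain tables; a stricter fraction is configurable.
`glogPareto()` applies the generalized log
$x \mapsto \log((x + \sqrt{x^2 + \lambda^2})/2)$ with λ defaulting to the
matrix's smallest nonzero value (the upstream tool that popularized this
transform does not publish its λ), then Pareto scaling — centering and
division by the *square root* of the column standard deviation, the
standard definition. Clustering is Euclidean distance with complete linkage
on both axes; the row/metabolite axis might arguably use a different
distance, but with no stated alternative the same default is applied to
both.

## Pan-BGC and mutation profiling

`panBGCStats()` is set algebra over family columns: union, core (present in
all strains), non-core and its exact percent fraction, the type strain's
count and complement, and unique-to-one-strain families. "Strain-specific"
is operationalized as *absent from at least one strain* (non-core); the
package reports exact unrounded fractions because published rounded
percentages for such partitions are often mutually inconsistent.

CDS comparison uses global affine-gap alignment (open 10, extend 0.5,
match +2, mismatch −3) via Biostrings, with the reference defining the
reading frame. `classifyMutations()` walks codons in the reference frame:
equal translations (bacterial codon table 11 — the organisms are
*Streptomyces*) are silent, others non-silent; gap runs divisible by 3 are
single in-frame deletion events, normalized to a codon boundary when the
sequence context allows the gap to slide (standard indel left-alignment);
frame-breaking gaps are flagged `frameshift` and excluded from the
silent/non-silent tally. Mutation events are counted at codon level; an
identical event shared by several strains counts once per strain in
per-strain totals and once in the distinct-event total, the bookkeeping
used by shared-symbol mutation tables.

## The synthetic-data generator

The generator exists so that every pipeline stage has inputs with known
ground truth. Its defaults describe the emulated study: 7 strains (a
reference plus six others), three tag groups of 8 compounds each (the
packaged table's scale), strain-exclusive production probability 0.1
(3 of the table's 33 compounds are single-strain), per-strain production
probability 0.55 (the table's mean producer fraction), log-normal
abundances (multiplicative biology, meanlog log(1e5), sdlog 1 — a wide
spread with exact structural zeros), 4 replicate scans per produced
compound (the minimum consensus cluster size), 6 family-shared backbone
fragments plus 2 private fragments and the group tag per spectrum, 5 noise
peaks capped at 5% of the base peak, and 0.002 Da m/z jitter
(high-resolution instrument scale). Group counts are fixed per
configuration rather than multinomially sampled — the study design being
emulated fixes its compound classes; the stochastic layers are production,
abundance, jitter and noise. Precursors are kept ≥ 0.1 Da apart so planted
compounds are resolvable at the 0.01 Da parent tolerance.

Chromatograms are single Gaussians (σ = 4 s on a 0.5 s grid) with area
equal to the true abundance, on a shared retention-time grid — no RT drift,
no co-elution beyond what channel tolerance creates, no chimeric spectra,
no realistic bond-level fragmentation chemistry. Mutated CDS sets plant
single-codon substitutions (classified at planting time) and single-codon
in-frame deletions whose flanking context forbids gap sliding, so the
planted truth has a unique optimal alignment and recovery can be required
to be *exact*.

Passing recovery tests on these inputs demonstrates that the pipeline's
logic is correct under its own assumptions; it does not demonstrate
robustness to RT drift, chimeras, isotopic interference or real
fragmentation variability, which are outside the emulation.

## Numerical and testing choices

All generators are pure functions of (configuration, seed). Tests run the
pipeline at deliberately small problem sizes — libraries of 6–24 compounds,
3–7 strains, 3-gene/2-strain CDS sets over 50 seeds, 100-matrix pan-BGC
sweeps — sizes chosen to exercise every code path while keeping the whole
suite fast enough to run habitually. Degenerate inputs have defined
behavior throughout: empty MGF files warn and return empty lists, blank
matrix cells impute 0 with a warning, zero-variance columns center without
scaling, all-zero compounds get a `"none"` best producer, and empty
consensus output is a message, not an error.

## Known limitations

* MGF is the only spectrum format; mzML/mzXML conversion is upstream.
* Adducts other than $[M+H]^+$/printed cation, multiple charging beyond the
  `z` argument, and fine isotope structure are out of scope.
* The greedy consensus pass is order-deterministic but, like any greedy
  clustering, not invariant to pathological precursor spacings near the
  parent tolerance.
* Absolute quantification is explicitly out of scope: areas are
  semi-quantitative and only meaningful relative to the reference strain.
* BGC family assignment (orthology clustering of cluster predictions) is
  consumed as a matrix, not computed from genome sequence.
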