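# FDGnet

Metabolic covariance networks from regional FDG-PET SUVR data.

Neurodegenerative dementias reorganize brain glucose metabolism, and the
*covariance* of metabolism between regions — not just its regional level —
distinguishes diagnoses. In Alzheimer's disease (AD) inter-regional
metabolic coupling is diffusely weakened; in dementia with Lewy bodies
(DLB) the loss is patchier, with some systems preserved and others (the
posterior cingulate network among them) hit harder. FDGnet is for
neuroimaging researchers who have subject × region SUVR tables
(standardized uptake value ratio: regional uptake over a cerebellar
reference) and want to quantify these differences with weighted
graph-theoretical measures and proper permutation inference.

## What it computes

For each diagnostic group the package builds the **metabolic connectivity
matrix** — the cross-subject Pearson correlation $r_{ij}$ between every
pair of the 68 cortical parcels of the bundled FreeSurfer
(Desikan–Killiany) atlas — and converts it to a weighted undirected graph
(negative correlations zeroed by default, no further threshold). On this
graph it computes eight global measures (average strength, average
eccentricity, characteristic path length, global efficiency, local
efficiency, clustering coefficient, transitivity, Louvain modularity
$Q = \frac{1}{2m}\sum_{ij}[w_{ij} - \gamma s_i s_j/2m]\,\delta(c_i,c_j)$)
and eight nodal measures (degree, strength, weighted triangles,
eccentricity, path length, clustering, nodal global efficiency,
closeness), with shortest paths on edge lengths $1/w_{ij}$. Groups are
compared by a two-tailed subject-relabeling permutation test with
max-statistic family-wise error control, the whole pipeline recomputed on
every permutation.

Because patient-level SUVR tables of this kind are not publicly deposited,
the package includes a seeded block latent-factor simulator
(`defaultDesign()`) that reproduces the three observed correlation
regimes — dense homogeneous (CN-like, n = 142), diffusely attenuated
(AD-like, n = 45), and patchy (DLB-like, n = 18) — with a closed-form
correlation oracle for testing.

## Worked example

```r
library(FDGnet)

atlas  <- readAtlas(dk68AtlasFile())
design <- defaultDesign(atlas, masterSeed = 1)
groups <- splitByGroup(simulateCohort(design))

sapply(groups, function(g)
    globalMeasures(toGraph(correlationMatrix(g)), seed = 1))
```

```
                                CN      AD     DLB
average_strength           47.1295 16.8420 11.9564
average_eccentricity        1.5863  6.1617  8.2055
characteristic_path_length  1.4249  3.8164  4.7866
global_efficiency           0.7034  0.2872  0.2829
local_efficiency            0.7034  0.2901  0.3333
clustering_coefficient      0.7030  0.2327  0.2130
transitivity                0.7030  0.2353  0.2197
modularity                  0.0000  0.0534  0.3866
```

The CN-like group is a dense, efficient, unmodular network (strength ~47,
path length ~1.4, Q ~0); both disease analogs lose strength, efficiency
and clustering and gain path length and eccentricity; the patchy DLB-like
group is additionally strongly modular (Q = 0.39) because whole blocks of
regions decouple.

```r
res <- permutationTest(groups$CN, groups$DLB, nPermutations = 1000,
    seed = 1, measures = "nodal_strength")
res
```

```
PermutationResult: CN vs DLB (difference = DLB - CN), 1000 permutations
  alpha = 0.05 (maxstat FWE); significant: 0 global, 54 nodal
```

```r
head(summarizeComparison(res)[order(summarizeComparison(res)$difference), ], 5)
```

```
   region  measure value_a value_b difference    p_fwe
38   rENT strength   47.93   2.698     -45.23 0.000999
47  rPERI strength   47.47   3.184     -44.29 0.000999
39   rFUS strength   46.47   2.551     -43.92 0.000999
46   rPCG strength   46.71   3.094     -43.61 0.000999
35   rBKS strength   47.90   4.806     -43.10 0.000999
```

Every node of the two attenuated simulation blocks (34 regions, including
the posterior cingulate label rPCG) loses strength significantly after FWE
correction; the difference column is group B minus group A (here
DLB − CN), matching the sign convention of published AD/DLB comparison
tables. `exportBrainNet()` writes `.node`/`.edge` files for BrainNet
Viewer; `runPipeline()` (or `inst/scripts/fdgnet.R` from a shell) runs the
whole load → correlate → measure → compare → export chain from a YAML
config with provenance headers on every output.

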