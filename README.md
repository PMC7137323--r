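# HEPT — essential protein prediction with a tensor-extended HITS random walk

Essential proteins are those whose loss kills the cell or leaves it
infertile; finding them computationally from protein–protein interaction
(PPI) networks is a standard problem in systems biology, and purely
topological centralities (degree, betweenness, closeness, ...) are known to
be limited by the noise and incompleteness of high-throughput PPI data.
HEPT integrates the network with three further data sources — protein
domain content, Gene Ontology (GO) annotations, orthology conservation and
subcellular localization — and ranks proteins with a random-walk model that
scores proteins and *relation types* simultaneously.

The package is aimed at computational biologists who have a PPI edge list
plus standard annotation tables (Pfam-style domains, GO, InParanoid-style
ortholog counts, COMPARTMENTS-style localization) and want a ranked
candidate list of essential proteins, together with the evaluation
machinery (top-K counts, precision–recall, jackknife curves) used in this
literature.

## The model

**Relation tensor.** Over the n network proteins a sparse symmetric tensor
T (n × n × 3) is built, one slice per relation:

- *co-neighbor* — `t(i,j,1) = |N_i ∩ N_j|² / ((|N_i|−1)(|N_j|−1))` when both
  proteins have more than one PPI neighbor, else 0 (clipped to 1);
- *co-domain* — `t(i,j,2) = P_D(i) · P_D(j)` for pairs sharing a domain
  type, where `P_D` is the min–max-normalized sum of `1/NP_d` over the
  protein's domains (`NP_d` = number of proteins carrying domain d);
- *co-annotation* — `t(i,j,3) = |F_i ∩ F_j| / √(|F_i||F_j|)` over the
  proteins' GO term sets, after discarding GO terms annotating fewer than
  10 or more than 200 proteins.

**Tensor HITS.** Normalizing T along each mode gives three probability
transfer tensors (all-zero fibers become uniform 1/n or 1/m). Three score
vectors — authority VA, hub VH, and edge-type importance VE — are then
iterated to a fixed point:

    VA(i) ← (1−α)·D(i) + α·Σ_jk  ta(i,j,k)·VH(j)·VE(k)
    VH(j) ←             Σ_ik  th(i,j,k)·VA(i)·VE(k)
    VE(k) ←             Σ_ij  te(i,j,k)·VA(i)·VH(j)

with each vector L1-normalized after its update, until the summed L1 change
drops below ε (default 1e−8). The restart vector D personalizes the walk
toward conserved, well-localized proteins: `D(i) ∝ I(i)·S(i)` with
`I(i) = NI(i)/max_j NI(j)` (ortholog species counts) and `S(i)` the best
compartment score `F_S(c) = |p_c|/max_k |p_k|` among the protein's
compartments. The mixing weight α defaults to 0.3, where accuracy peaks on
the yeast DIP benchmark. Proteins are ranked by descending VA.

## Worked example

The package ships a generator of self-consistent synthetic input bundles
with planted essential proteins (scale-free topology whose hubs, domain
content, GO co-annotation, conservation and localization are all enriched
for the planted set — `bias = 1` switches every signal off):

```r
library(HEPT)
b <- syntheticBundle(nProteins = 200, nEssential = 20, bias = 5, seed = 1)
run <- runHeptOnBundle(b)
run$result
#> HeptResult: 200 proteins, 3 edge types
#>   converged after 13 iterations (final L1 change 5.44e-09)
#>   alpha = 0.3, epsilon = 1e-08
#>   edge-type importance: co_neighbor = 0.49150, co_domain = 0.09294, co_annotation = 0.41560
head(run$ranking, 5)
#>   rank protein      score
#> 1    1    P012 0.02153742
#> 2    2    P004 0.02142974
#> 3    3    P166 0.02118831
#> 4    4    P162 0.02014195
#> 5    5    P066 0.01963673
topKEssentialCount(run$ranking, b$essential, 40)
#> [1] 20
jackknifeCurve(run$ranking, b$essential)$aucNormalized
#> [1] 1
topKEssentialCount(degreeCentralityBaseline(b$network), b$essential, 40)
#> [1] 10
```

All 20 planted essentials are recovered in the top 40 (a normalized
jackknife area of 1 means every essential precedes every non-essential),
while plain degree centrality finds 10. The edge-type importances show the
walk leaning on the co-neighbor and co-annotation slices for this bundle.

With real data, use the file-based entry point instead:

```r
res <- heptFromFiles("ppi.tsv", domains = "domains.tsv", go = "go.tsv",
  orthologs = "orthologs.tsv", subcellular = "subcellular.tsv",
  essential = "essential.txt")
writeRanking(res$ranking, "ranking.tsv", topN = 600)
```

A command-line wrapper with the same options (plus a `synth` subcommand for
generating bundles) is installed at `inst/scripts/hept.R`.

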