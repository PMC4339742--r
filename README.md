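# phenomarker

Turn high-throughput molecular phenotypes into genetic markers and maps.

In a cross between two inbred strains (RILs by selfing, backcross, F2),
a gene-expression, protein or metabolite phenotype controlled by a
single major QTL separates into one cluster per genotype class and shows
a clearly multimodal distribution across the population. `phenomarker`
fits a Gaussian mixture to every phenotype, keeps the ones whose
component proportions match the expected segregation ratio (1:1, or
1:2:1 for F2) and whose multimodality survives a parametric-bootstrap
likelihood-ratio test, and converts them into discrete genotype calls
through the posterior probabilities: call = argmax component when its
posterior reaches a threshold, missing otherwise,

> LOD(single-QTL scan) = (n/2) · log10(RSS0 / RSS1),
> Kosambi d = 25 · ln((1+2r)/(1−2r)), RIL expansion R = 2r/(1+2r).

Candidate markers then pass QTL-based quality control — candidates
showing genotype-by-environment interaction (LOD ≥ 7.5), multiple QTL
(second-QTL LOD > 15), pairwise epistasis (LOD ≥ 7.5) or no significant
QTL (LOD ≤ 5) are removed — and the survivors either **saturate** an
existing genetic map (placed at their interval-mapping peak, map
re-estimated, duplicates and co-locating markers dropped) or build one
**de novo** (linkage groups, mirrored-group merging for parent-free
phasing, marker ordering, Kosambi/Haldane distances, chromosome naming
and orientation from known physical positions). Everything is written
out as R/qtl-compatible rotated-CSV (`csvr`) cross files and GFF3 maps.

It is aimed at quantitative geneticists working with expression-QTL
style data sets: hundreds of thousands of probes, ~100–400 segregants,
a sparse or absent marker map.

## Worked example

Simulate the package's default study design — 148 selfed RILs, five
100 cM chromosomes, four environments, parents replicated twice per
environment — with 30 strong local-eQTL phenotypes and 10 noise
phenotypes, then saturate the sparse 10 cM map:

```r
library(phenomarker)

sim <- simulate_study(n_ind = 148, counts = c(clean_local = 30, no_qtl = 10),
                      effect = 4, seed = 42)
sim$cross
#> Cross (riself): 148 individuals, 55 markers on 5 chromosome(s)
#>   environments: env1, env2, env3, env4

cands <- find_candidate_markers(sim$pheno, cross_type = "riself",
                                parental = sim$parental, seed = 43)
cands
#> Candidate markers: 29 of 40 phenotypes

sat <- saturate_map(sim$cross, cands, step_two = 10)
sat$report
#> Saturation report
#>   input                        40
#>   parental_selected            30
#>   mixture_selected             29
#>   removed_multi_qtl            1
#>   placed                       28
#>   removed_duplicate            5
#>   removed_colocalized          3
#>   final_new_markers            20
#>   spacing_before               10
#>   spacing_after                6.822
#>   ...
sat$cross
#> Cross (riself): 148 individuals, 75 markers on 5 chromosome(s)
```

Reading the report: the parental Welch t-test kept 30 of 40 phenotypes
(the 10 noise phenotypes have identical parents), the mixture +
segregation filters kept 29, QTL quality control removed one candidate
that behaved like two QTL, 28 were placed at their interval-mapping
peak, and after dropping 5 duplicates and 3 markers co-locating with
original ones, 20 new markers remain: average marker spacing fell from
10 cM to 6.8 cM. The theoretical floor for this population is
`theoretical_resolution(148)` = 100/148 = **0.68 cM** — reachable only
with a saturating supply of candidate phenotypes.

`write_cross_csvr(sat$cross, "saturated.csvr")` writes the result for
R/qtl; `write_gff()` exports any map with physical positions for genome
browsers. `build_denovo_map()` runs the map-from-nothing path, and
`inst/scripts/phenomarker.R` wraps simulate/saturate/denovo as a command
line:

```sh
Rscript inst/scripts/phenomarker.R simulate --out sim --seed 3
Rscript inst/scripts/phenomarker.R saturate --pheno sim/phenotypes.tsv \
    --cross sim/cross.csvr --parents-a sim/parent_A.tsv \
    --parents-b sim/parent_B.tsv --env sim/environments.txt --out out
```

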