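# chromdyn

Integrative analysis of chromatin accessibility dynamics during a rapid,
inducible pluripotent-to-somatic transition: an AP-1 factor is switched on
in embryonic stem cells and, within hours, thousands of chromatin loci open
while pluripotency loci close, the BAF (mSWI/SNF) remodeling complex
relocates from closing to opening loci, somatic genes activate, and
label-free IP-MS probes which protein complexes the factors actually form.
`chromdyn` implements the downstream analysis of such a design for
epigenomics analysts working from processed inputs — called peak sets,
normalized signal matrices, TPM tables and protein intensity matrices.

## What it computes

**Accessibility-dynamics (CAD) classes.** Each consensus locus gets a
binary open/closed trajectory over the timecourse (0/4/8/12 h by default),
matched against monotone templates:

| trajectory | label |
|---|---|
| (0,1,1,1), (0,0,1,1), (0,0,0,1) | CO1, CO2, CO3 (closed → open, by window) |
| (1,0,0,0), (1,1,0,0), (1,1,1,0) | OC1, OC2, OC3 (open → closed) |
| (1,1,1,1) | PO, split by r = (s_last + ε)/(s_first + ε): POU (r ≥ 2), POD (r ≤ ½), PON |
| (0,0,0,0) | NONE; any non-monotone pattern → OTHER |

**Expression groups and integration.** TPM trajectories are grouped with a
1.5 fold change (Group3 down at the end; Group2 immediately up; Group1 up
later; else Unchanged), peaks map to genes through TSS ± 10 kb windows,
and row-normalized composition tables link the two classifications in both
directions.

**Occupancy relocation.** Lost / retained / gained partitions of a
factor's binding sites between timepoints (with the coverage identities
lost + retained = t0 total, retained + gained = t1 total), two-fold
down / permanent / up signal dynamics, the CAD-class composition of
binding sites with the aggregate *open-associated* fraction
(PON + CO + POU), and co-occupancy counts against histone-mark sets.

**IP-MS interactors.** 2-of-3 observation filtering, log2 transform,
left-tail imputation, then per protein a two-sided two-sample Student's
t-test; an interactor requires p < 0.01 *and* ≥ 2-fold enrichment.
Interactome sets support exact venn region counts and cross-bait
intersections.

**Synthetic data.** A fully seeded generator (`simParams()`,
`simulateAll()`) emits every input with planted ground truth — trajectory
classes, coupled expression groups, planted relocation and planted
interactors — so the entire pipeline runs and is tested without any
external data.

## Worked example

```r
library(chromdyn)

cfg <- pipelineConfig(outdir = file.path(tempdir(), "demo"), seed = 7,
                      sim = list(nLoci = 600, nGenes = 300,
                                 ipms = list(nProteins = 300, nTrue = 20,
                                             nShared = 3)))
report <- runPipeline(cfg)

unlist(report$cad$counts)
#>   CO1   CO2   CO3   OC1   OC2   OC3   POU   POD   PON  NONE OTHER
#>   179    36    12    29    26    34    73    78   115     0    16

unlist(report$relocation$counts)
#>     lost retained   gained t0_total t1_total
#>      133       15      255      148      270

report$relocation$cadComposition$openAssociated
#> [1] 0.9259259

do.call(rbind, lapply(report$cooccupancy, as.data.frame))
#>       mark shared rank
#> 1  H3K27ac    235    1
#> 2  H3K4me1    129    2
#> 3 H3K27me3     13    3
```

The 600 simulated loci are classified into the nine dynamics classes (the
first closed-to-open wave, CO1, dominates, as planted); the simulated
factor keeps only 15 of its 148 t0 binding loci and gains 255 new ones —
the planted relocation from closing to opening loci; 92.6% of its 8 h
binding sites sit in open-associated (PON/CO/POU) chromatin; and the mark
planted with the highest co-occupancy probability ranks first. The run
directory additionally holds `cad_labels.tsv`, the composition tables,
`interactors.tsv`, `venn.json` and a `report.json` whose internal
identities (venn sums, row normalization) are checked on every run.

See the vignette (`vignettes/chromatin-dynamics.Rmd`) for the model,
parameter conventions, and what the generator does and does not emulate.

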