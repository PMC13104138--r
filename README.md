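# riboutr

Staged translatome analysis from ribosome profiling: translation
efficiency across a developmental series and discovery of translated
ORFs in UTRs and noncoding transcripts.

## The problem

Ribosome profiling (Ribo-seq) reads out where ribosomes sit on mRNA.
Paired with RNA-seq across a developmental series — the motivating
design is ten maize anther stages (0.5–5.0 mm plus mature pollen) in
five phases, two replicates each — it answers two questions that
transcript abundance alone cannot:

1. **How strongly is each gene translated, per stage?** Translation
   efficiency is the footprint-to-mRNA density ratio,

   `TE = (RPKM_Ribo + 1) / (FPKM_RNA + 1)`,

   with RPKM over the gene's union CDS length and FPKM over its union
   exon length. Genes classify as *high* (TE > 2 at a stage where
   FPKM or RPKM ≥ 50), *very high* (additionally phase-mean TE > 5),
   *low* (TE < 0.5), or *fluctuating* (both), and the
   translatome-vs-transcriptome spread is quantified as the population
   variance of `log2(x+1)` expression across genes per stage.

2. **Which AUG-initiated ORFs outside annotated CDS are actually
   translated?** Candidate ORFs (AUG to first in-frame stop, same-stop
   candidates collapsed to the longest) in 5' UTRs, 3' UTRs and
   noncoding transcripts are accepted when their P-sites — on codons not
   overlapping any annotated mORF CDS — show 3-nucleotide periodicity:
   frame-0 fraction ≥ 0.6, one-sided binomial p ≤ 0.05 against
   `Bin(n, 1/3)`, n ≥ 10, in at least one stage. Each call carries its
   Kozak context (strong = A/G at −3 and G at +4) and can be
   corroborated by peptide substring matches and containment in
   independent transcript-isoform models.

The package is aimed at computational biologists who have per-sample
P-site tracks (or 5'-end placements plus an annotation, from which it
calibrates read-length-specific offsets by metagene mode) and want a
tested, deterministic path from those tracks to TE profiles, ORF calls,
gene classes, clusters and enrichment — with a synthetic-data generator
that emulates the full study design (frame-biased footprints of
25–33 nt, staged abundances, planted UTR-ORFs with ground truth) so that
every step is validated end to end.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
default synthetic design (500 genes, ten stages × two replicates,
420 planted UTR/noncoding ORFs, half of them translated):

```sh
Rscript analysis/01_simulate.R          # writes results/simdata/
Rscript analysis/02_qc_periodicity.R
Rscript analysis/03_quantify_te.R
Rscript analysis/04_orf_discovery.R
Rscript analysis/05_te_classification_variation.R
Rscript analysis/06_clustering_enrichment.R
Rscript analysis/07_corroboration.R
```

Output the scripts printed at seed 1:

```
01: planted ORFs: 420 ( 170 5' / 170 3' / 80 nc ) — 210 translated, 210 untranslated
    Ribo-seq P-sites: 2709233 | RNA fragments: 8037778
02: footprints in 25-33 nt: 100.0% | in 25-30 nt: 84.0%
    frame-0 fraction over mORFs: 0.741-0.743 across stages
03: TE recovery: Pearson r = 0.986 over 500 genes; median est/true = 1.096
04: candidates: 5565 | accepted: 209 ( 85 5' / 84 3' / 40 nc )
    vs truth: sensitivity 0.995, FDP 0.000, category accuracy 1.000
    strong Kozak among accepted: 53.6%
06: genes entering clustering (min TE > 1): 390
    enrichment rows: 216 | significant at adj p < 0.05: 0
07: peptides matched to accepted ORFs: 209 of 210 true, decoy hits: 0 of 25
    isoform-backed accepted ORFs supported: 56 / 56; non-backed flagged: 0
```

Reading this: the simulated libraries look like ribosome footprints
(length window, ~0.74 frame-0 fraction, matching the generator's frame
probabilities); TE estimated by the pseudocounted density ratio tracks
the simulation's true TE almost perfectly; of 210 planted translated
ORFs, 209 are recovered with zero false discoveries and every recovered
ORF carries its true class; random term sets show no spurious
enrichment; reversed decoy peptides never match; all 56 isoform-backed
accepted 3' ORFs are structurally supported and nothing else is.

The same machinery is available programmatically:

```r
library(riboutr)
sim  <- simulate_dataset(sim_config(seed = 1))
expr <- quantify_expression(sim$annot, sim$rna$counts, sim$ribo$track,
                            sim$config$stage_names)
te   <- compute_te(expr)
orfs <- discover_orfs(sim$annot, sim$genome)
acc  <- accept_translated(orfs, sim$ribo$track, sim$annot,
                          sim$config$stage_names)
acc$orfs[accepted == TRUE, .N, by = category]
```

`run_pipeline(sim_config(seed = 1), "out/")` orchestrates all steps with
one configuration (or a YAML file with `simulate:` / `inputs:` /
`params:` sections) and writes a JSON manifest with per-step wall-clock
and md5 checksums; reruns with the same seed are byte-identical.

## Layout

```
R/                  package code (annotation IO, simulator, periodicity,
                    quantification, ORF discovery, TE analysis,
                    clustering/enrichment, corroboration, pipeline)
analysis/           numbered narrative drivers over the package
scripts/acceptance.R   headline-quantity recomputation (JSON out)
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette (model, parameters, design choices)
```
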