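---
title: "Methods: staged translatome analysis and UTR-ORF discovery with riboutr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged translatome analysis and UTR-ORF discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`riboutr` implements a staged translatome analysis for paired ribosome
profiling (Ribo-seq) and RNA-seq data, of the kind collected across a
developmental series — the motivating design is ten maize anther samples
(anther lengths 0.5–5.0 mm plus mature pollen) grouped into five
developmental phases, with two biological replicates per stage. The
pipeline starts from per-sample read placements or P-site tracks (not raw
reads: trimming and alignment are upstream concerns) and produces:

* footprint QC (length histogram, per-frame P-site fractions, P-site
  offset calibration);
* gene-level FPKM (RNA over union exon length) and RPKM (Ribo over union
  CDS length), expressed/translated gene calls, and translation
  efficiency, `TE = (RPKM + 1) / (FPKM + 1)`;
* discovery of AUG-initiated ORFs in 5' UTRs, 3' UTRs and noncoding
  transcripts, accepted by a 3-nucleotide periodicity test and annotated
  with Kozak context;
* TE-based gene classes, the translatome-vs-transcriptome
  expression-variation statistic, and ORF-feature-vs-TE relationships;
* max-normalized k-means TE coexpression clusters, UPGMA stage
  dendrograms, hypergeometric enrichment;
* corroboration of ORF calls by peptide lists and isoform models.

Because the real datasets live in sequencing archives and are far beyond
desk scale, the package ships a first-class synthetic-data generator
whose defaults emulate the study design, with full ground truth. Every
claim the test suite makes is a property of pipeline + generator, checked
end to end.

# Coordinates and containers

All internal coordinates are 0-based half-open; on-disk formats keep
their native conventions (GFF3 1-based inclusive, BED 0-based half-open).
This removes the off-by-one ambiguity that plagues mixed-format
pipelines; conversion happens only in the readers/writers
(`read_gff3()`, `write_gff3()`, BED12 export). All transcript-level logic
runs in transcript orientation (position 0 is the 5' end regardless of
strand); genome-level tracks keep strand as an explicit key. UTRs are
never stored: the 5' UTR is the exonic interval `[0, cds_tstart)` in
transcript coordinates and the 3' UTR is `[cds_tend, tx_len)`, which
guarantees `|5'UTR| + |CDS| + |3'UTR| = spliced length` by construction.
CDS lengths that are not multiples of 3 are flagged
(`cds_len_ok = FALSE`), never silently accepted.

# Quantification and TE

Counting mirrors the multi-overlap convention of featureCounts' `-O`: a
placement overlapping features of k genes credits each of the k genes,
strand-matched, against the union of the gene's exon (RNA) or CDS (Ribo)
intervals. Library totals are the sums of counted placements. Replicates
are normalized to FPKM/RPKM first and averaged afterwards; TE is computed
on the replicate means with pseudocount 1 on both layers, so `TE = 1`
exactly when both layers are 0 and low-expression ratios are shrunk
toward 1. A gene is called transcribed (translated) at a stage when its
mean FPKM (RPKM) is at least 1, inclusive.

The `expr_min = 50` gate for TE classification applies per stage
(`max(FPKM, RPKM) >= 50`); a gene enters the classification if any stage
qualifies. Stage labels use `TE > 2` (high) and `TE < 0.5` (low) at
qualifying stages. Gene classes: *high* (high somewhere), *very high*
(high, and some phase's mean TE exceeds 5 — the phase mean is the
arithmetic mean of the stage TEs in that phase, which the source analysis
leaves undefined and we fix here), *low* (low somewhere, never high),
*fluctuating* (both), *none* otherwise. The `TE < 0.5` reading of
"translation less than half the transcript level" is conservative for
weakly expressed genes because of the pseudocount; the `>= 50` expression
gate is what keeps that bias harmless.

Expression variation is the population variance (1/n denominator) across
genes of `log2(x + 1)`-transformed FPKM/RPKM at each stage, computed over
the identical gene set for both layers (genes with median expression > 1
in each layer, filters intersected). The raw-scale variance is also
emitted, but the log2 scale is the headline: the variance formula is
stated on raw values in the source methods while the figure that reports
the 11–56% range is computed on log-transformed values, and the
log-scale statistic is the one that is stable across the orders of
magnitude spanned by expression data.

# Periodicity testing

Active translation imprints a 3-nucleotide periodicity on P-site
positions. The acceptance test used here is deliberately simple and fully
specified: for an ORF with per-frame P-site counts `(n0, n1, n2)` —
frames defined relative to the ORF's *own* start codon, so nested and
overlapping ORFs are evaluated independently — the p-value is the exact
one-sided binomial tail `P[X >= n0]`, `X ~ Bin(n, 1/3)`, and an ORF
passes when `n >= 10`, `f0 = n0/n >= 0.6`, and `p <= 0.05`. The
`f0 >= 0.6` gate is the frame-fraction parameter the source analysis
passes to RiboCode; the multitaper spectral machinery of RiboTaper is a
non-goal and this binomial gate is the package's declared substitute with
the same acceptance semantics. Calibration properties (checked in the
acceptance suite): under uniform frames with n = 60 the pass rate is
below 0.075 without the f0 gate and below 0.001 with it; with the
generator's frame bias (p0 = 0.75) and n = 50 the power exceeds 0.9.

Codons of a candidate ORF that overlap any annotated mORF CDS on the same
strand are masked out of the tally. This is what makes 5' ORFs that
overlap the mORF start testable at all: only their UTR codons carry
independent evidence, and the mask restricts the test to exactly those.
An ORF is accepted when it passes in at least one stage (replicates
pooled), matching the idea that a UTR ORF translated in any
developmental window is a discovery.

# ORF enumeration, collapsing, Kozak

`enumerate_orfs()` reports every AUG with an in-frame stop before the
transcript end, in all three frames, spans including the stop codon. The
default minimum length is 3 codons (start + one amino acid + stop), a
choice the source leaves open; `min_codons` is exposed. Candidates
sharing a stop codon are collapsed to the one with the most-upstream AUG
("the longer ORF was retained"). The alternative reading — grouping with
the *mORF's* stop codon to form C-terminal extensions — is rejected here
because independent-isoform evidence in the motivating study points to
free-standing ORFs; the collapse reading is also the only one that makes
the retention rule well defined. Classification looks only at the AUG:
in the 5' UTR (and not the annotated CDS span itself) → 5' ORF; at or
past the stop → 3' ORF; on a noncoding/intergenic transcript → ncORF;
inside the mORF CDS → `internal`, excluded from the three classes.

Kozak context is the 11-nt window −6..+5 around the AUG (A = +1), padded
with `N` at transcript edges; *strong* means A or G at −3 **and** G at
+4. `N` never satisfies the rule, so edge AUGs are never called strong.

# P-site offset calibration

When inputs are raw 5'-end placements rather than P-sites, the offset for
each read length L is the modal distance from 5' ends to annotated CDS
starts over a metagene window (40 nt upstream to 10 nt downstream), ties
broken toward 12 nt; lengths with fewer than 20 metagene reads fall back
to 12 nt and are flagged, as is the degenerate case of no covered starts.
The mode is well defined on real-shaped data because initiation enriches
the start codon itself; the generator reproduces this with an
initiation-peak weight (default 8×) on codon 0 — without such a peak a
codon-uniform profile would tie all in-frame distances.

# Clustering and enrichment

TE profiles of genes with minimum TE > 1 across stages are divided by
their row maximum (each profile in (0, 1], peak at 1) and clustered with
k-means, k = 18, 30 Lloyd iterations, fixed seed 19960912 — the source
analysis' parameters. Initialization is seeded k-means++; the source
fixes the seed but not the init scheme, and k-means++ both stabilizes and
improves the objective. A cluster is *phase-specific* when its centroid
peaks in a phase and the centroid mean inside that phase exceeds the mean
outside by at least 0.2 (a configurable margin; the source never defines
phase specificity operationally). Stage relationships use UPGMA on
Euclidean distances between stage columns, exported as Newick.

Enrichment is the upper-tail hypergeometric probability `P[X >= k]` with
Benjamini–Hochberg adjustment across terms within each set (the source
reports "adjusted p values" without naming a procedure; BH is the field
default). Stars (`*` < 0.05, `**` < 0.01) follow the raw p-value to match
the figure convention that motivated them; both columns are emitted. Term
annotations are opaque two-column (term, gene) tables — ontology
structure is out of scope.

# Corroboration

Peptide evidence is exact substring matching of uppercase peptides
against ORF translations (optionally collapsing I/L, isobaric in MS),
with a minimum peptide length of 7 to bound random-match probability;
peptides matching several ORFs report all of them, and peptides that also
match an annotated mORF are emitted with the match, not filtered.
Isoform support requires (a) every ORF base inside the isoform's exons,
(b) matching strand, and (c) splice-identity over the ORF (consecutive
ORF bases stay adjacent in the isoform), which keeps AUG and stop intact
in one frame — the operational reading of ORFs "corresponding precisely"
to isoforms. Containment is deterministic, so the planted
isoform-backed ORFs in the generator are recovered with sensitivity and
specificity 1.

# The synthetic-data generator

`sim_config()` defaults *are* the study conditions: 10 stages × 2
replicates (stage→phase map 1–3 → PI, 4–7 → PII, 8 → PIII, 9 → PIV,
10 → PV), 500 protein-coding genes (5' UTRs 180–300 nt, CDS 100–300
codons, 3' UTRs 180–300 nt, 30% with one intron, strands mixed), 80
intergenic noncoding transcripts, footprint lengths 25–33 nt peaked at
28–29, frame probabilities (0.75, 0.15, 0.10) in translated ORFs and
uniform elsewhere, log-normal mRNA abundance (meanlog log 20, sdlog 1)
with per-stage jitter (sdlog 0.5), log-normal TE (meanlog 0, sdlog 0.5),
and 170/170/80 planted 5'/3'/nc ORFs (10–45 codons), half with strong
Kozak context and exactly half translated with their own log-normal
translation levels. Counts are Poisson (an optional negative-binomial
dispersion knob exists for robustness studies); depths are set so a
typical gene receives a few hundred RNA fragments and ~200 footprints
per library — large enough for stable statistics, small enough that the
whole study simulates in under a minute. Values the source does not pin
down (UTR-ORF effect sizes, background footprint density of 2% of mean
coding density, ORF translation levels) are free parameters of the
config, stated here once and not tuned thereafter.

Planted ORFs are constructed, not merely annotated: the generator writes
an AUG, stop-free interior and in-frame stop into the UTR sequence, sets
the −3/+4 bases to the requested Kozak strength, and *scrubs* any
same-frame upstream AUG that is not separated by an in-frame stop
(mutating `ATG → ATC`, never touching the mORF start codon), because such
an AUG would absorb the planted ORF under same-stop collapsing and make
the truth table ambiguous. Translated regions receive an
initiation-peak-weighted multinomial over codons and the frame
multinomial within codons; untranslated planted ORFs receive only the
uniform background, which is what the null calibration of the
periodicity test assumes.

One subtlety deserves its own paragraph: what "true TE" means. RPKM
normalizes by CDS kilobases and the Ribo library total, FPKM by exon
kilobases and the RNA total, so the density-ratio estimand differs from
the generative TE parameter by a per-stage constant determined by library
composition — no choice of sequencing depth removes it, because depth
cancels in library-size normalization. The truth table therefore records
both `te_param` (the generative ratio) and `te_true`, the noiseless value
of the estimand (expected RPKM over expected FPKM from expected counts).
Parameter-recovery statements ("estimated TE correlates with truth at
r ≥ 0.9; the median estimate/truth ratio lies in [0.8, 1.25]") are made
against `te_true`, i.e. truth is the infinite-depth value of the measured
quantity — the standard convention for simulation benchmarks of
relative-abundance estimators.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: alignment and mapping artifacts, multimapping,
splice-isoform mixtures within a gene (one transcript per gene, plus
planted intergenic isoform models), non-AUG starts, stop-codon
readthrough, codon-level dwell-time structure, batch effects, and
overdispersion beyond the optional NB knob. The classifier thresholds
(1, 50, 2, 5, 0.5), the f0 gate (0.6), and the clustering parameters
(18, 30, 19960912) are the quoted study constants and appear as named
configuration keys, not magic numbers.

# Numerical and degenerate-input choices

* The binomial tail is computed as `pbinom(n0 - 1, n, 1/3, lower = FALSE)`
  — exact, vectorized, and identical to `binom.test()`.
* `n = 0` regions (e.g. fully masked ORFs) carry `NA` p-values and never
  pass; they are reported, not dropped.
* The hypergeometric tail uses `phyper(k - 1, ...)`; the test suite pins
  it to an exhaustive binomial-coefficient enumeration over all
  `N <= 50` grids at 1e-12.
* Variance uses the population (1/n) denominator, as in the source
  formula; the test suite pins it against a two-pass oracle at 1e-12.
* k-means ties and initialization are fixed by the seed; Lloyd iteration
  guarantees a non-increasing objective, which is asserted.
* Tukey HSD letters come from `stats::TukeyHSD` pairwise adjusted
  p-values with an insert-and-absorb compact letter display; groups with
  fewer than 2 observations fall back to a single letter.
* Degenerate correlations (fewer than 3 informative stages, zero
  variance) are `NA`, not 0.

# Problem sizes

The shipped analysis scripts and the acceptance checks run the full
default design (500 genes, ten stages, two replicates, ~2.5 M simulated
footprints) in a few minutes on one core; unit tests use a cached 60-gene
version of the same design. These sizes were chosen to make every
statistical property (null calibration at 1e-3, sensitivity ≥ 0.9 over
210 planted translated ORFs, variance recovery within ±5 points) sharply
testable while keeping a full from-scratch rebuild cheap.

# Known limitations

The periodicity caller is a frame-fraction test, not a spectral one: ORFs
translated in a frame other than their own AUG frame, overlapping
translation on the opposite strand, and dual-coding regions are outside
its guarantees. Counting is single-end/point-based; fragment-level
paired-end semantics of real RNA-seq are reduced to fragment counts.
Enrichment treats terms as opaque sets. The pipeline assumes one
annotated transcript per gene when inferring UTRs; alternative isoforms
enter only as corroboration targets, not as quantification units.
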