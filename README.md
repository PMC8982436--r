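# embryoquant

Single-cell smFISH quantification with ground-truthed synthetic embryos.

`embryoquant` re-implements, as tested and reusable R code, the analysis
chain used in single-molecule FISH (smFISH) studies of transcription in the
early *Drosophila* embryo: counting mature mRNAs per segmented cell,
detecting active transcription sites (TS) with intron-targeting probes,
quantifying local cell-to-cell dispersion of counts, comparing genotypes
(wild type vs a miRNA knockout with slowed mRNA decay), and measuring
background-adjusted protein immunofluorescence. Because raw microscope data
for such studies are rarely deposited, the package ships a first-class
synthetic-embryo generator that emulates the statistical structure of the
images — so every stage can be validated against known ground truth.

It is aimed at quantitative biologists who want either (a) a desk-scale,
fully reproducible smFISH analysis pipeline to adapt to their own images, or
(b) a calibrated simulation harness for benchmarking spot-counting and
dispersion statistics.

## The models at the core

**Transcription.** Each allele follows the telegraph model: the promoter
switches OFF→ON at rate *k*<sub>on</sub> and ON→OFF at *k*<sub>off</sub>,
transcribes at *k*<sub>tx</sub> while ON, and transcripts decay first-order
at *k*<sub>deg</sub>. At stationarity, per cell with *n*<sub>a</sub>
independent alleles:

- E[*m*] = *n*<sub>a</sub> · *k*<sub>on</sub>/(*k*<sub>on</sub>+*k*<sub>off</sub>) · *k*<sub>tx</sub>/*k*<sub>deg</sub>
- Var[*m*] = E[*m*] · (1 + *k*<sub>tx</sub>*k*<sub>off</sub> / ((*k*<sub>on</sub>+*k*<sub>off</sub>)(*k*<sub>on</sub>+*k*<sub>off</sub>+*k*<sub>deg</sub>)))

The knockout genotype divides *k*<sub>deg</sub> by `ko_deg_factor` (slower
decay → more transcripts). An allele that is ON at the observation time is a
transcription site; TSs appear in both the exon- and intron-probe channels,
mature mRNAs in the exon channel only — the physical basis of the
intron-probe TS assay.

**Dispersion.** For each non-border cell, the neighbor cluster is the cell
plus its immediate neighbors (label adjacency in the segmentation). Over the
cluster's counts, the Fano factor FF = variance/mean and coefficient of
variation CV = sd/mean; FF = 1 for Poisson counts.

**Seed sites.** The scanner reports the three canonical miRNA site types on
a 3'UTR: 8mer (reverse complement of miRNA nt 2–8 followed by A), 7mer-m8
(reverse complement of nt 2–8), 7mer-A1 (reverse complement of nt 2–7
followed by A), with precedence 8mer > 7mer-m8 > 7mer-A1 at overlapping
positions.

## Worked example

Replicated count experiment — two independent replicate experiments, three
embryos per genotype each, simulated at the count level, filtered (cells
with fewer than 10 mRNAs excluded), and compared:

```r
library(embryoquant)
cfg <- sim_config(n_cols = 12, n_rows = 10, cell_pitch_px = 8, seed = 42,
                  domain_spec = list(rho = c(0, 1), mir9a = c(0, 1)))
rep <- run_experiment_counts(cfg, n_embryos = 3, n_replicates = 2)
rep$comparisons$counts
```

which prints (seed 42):

```
W = 505058, p = 3.01e-213
median WT = 49, median KO = 75, HL shift = 26.0
mean Fano WT = 1.31, KO = 1.49 (p = 0.000266)
```

The knockout carries ~1.5× more transcripts per cell (its decay rate is
1.5× slower; the wild-type stationary mean is 50), the rank-sum test
detects the shift decisively, and neighbor-cluster Fano factors are
super-Poissonian (bursty transcription) with a mild knockout excess —
the qualitative signature the pipeline is designed to measure. TS classes
(0 / 1 / 2+ active sites per cell) split near the binomial ON-probability
law, here roughly 80 / 335 / 300 per genotype arm.

Scanning the bundled *synthetic* 3'UTR (planted sites; real *rho* 3'UTR
coordinates depend on annotation version and are not bundled) against
miR-9a-5p:

```r
batch_scan(system.file("extdata", "synthetic_utr.fa", package = "embryoquant"),
           system.file("extdata", "mirnas.fa", package = "embryoquant"))
#>              utr_id      mirna_id position site_type site_sequence
#> 1 synthetic_rho_utr dme-miR-9a-5p      120      8mer      ACCAAAGA
#> 2 synthetic_rho_utr dme-miR-9a-5p      308   7mer-A1       CCAAAGA
```

Positions are 0-based site starts (`one_based = TRUE` for 1-based;
`alias_7mer = TRUE` for the `7_m8`/`7_A1` aliases).

For image-level work, `simulate_embryo(cfg, "WT", render = TRUE)` renders
the four channels (exon, intron, membrane, nuclei), and
`quantify_embryo()` runs segmentation → LoG spot detection → TS calling →
per-cell aggregation; `write_embryo_tiff()` / `read_embryo_tiff()` handle
multi-page 16-bit TIFF.

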