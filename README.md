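# aeropollen

Molecular airborne pollen monitoring by DNA metabarcoding, as a tested,
fully self-contained R pipeline.

Pollen monitoring networks count airborne pollen under the microscope, but
many allergenic groups (nettles, grasses, cypresses/yews) are
*stenopalynous* — their pollen is morphologically identical — so species
information is lost exactly where it matters clinically.  Metabarcoding a
short plastid marker (trnL P6 loop) and a nuclear ribosomal marker (nrITS2)
from the same air samples recovers species-level composition, and the
*relative read abundance* (RRA) of a taxon — its share of a sample's reads
— tracks its share of the microscopically counted pollen concentration
(pollen/m³/24h) well enough for semi-quantitative monitoring.  This package
implements the full analysis chain behind that claim, plus the synthetic
data needed to test every stage without any external sequencing data:

* **Amplicon processing** — pair merging (min overlap 10 bp, mismatch
  ratio ≤ 0.25), linked-primer trimming (mismatch fraction ≤ 0.2,
  marker-specific length floors), dereplication, and unoise-style
  denoising into zero-radius OTUs: a unique at edit distance *d* from a
  centroid is an error of it when `abundance_ratio ≤ β(d) = 2^-(αd+1)`
  (α = 2), after discarding uniques with < 10 reads.
* **Taxonomy** — local-priority dual-database assignment; hits tied at the
  maximum alignment score are collapsed by lowest common ancestor; the
  final rank is capped by identity tiers (≥ 97% species, ≥ 90% genus,
  ≥ 80% family) and marker coverage gates (100% trnL-like, ≥ 90%
  nrITS2-like).  BLAST outfmt-6-style hit tables are accepted as an
  alternative input.
* **Contamination filtering** — the six-step cascade: (a) blank-dominant
  OTU removal, (b) < 10 reads/cell zeroing, (c) a data-driven tag-jump
  threshold `t* = max over (OTU, blank) of c/T` whose application provably
  zeroes every blank, (d) < 3000-read replicate removal, (e) excluded
  clades (fungi, bryophytes, green algae) and listed food contaminants,
  (f) presence in ≥ 2 PCR replicates; plus positive-control purity checks.
* **Quantification** — replicate-averaged RRA, morphotype mapping,
  per-target and pooled (> 5% microscope share) least-squares regressions
  of RRA on microscopic relative abundance.
* **Community comparison** — Bray-Curtis `d = Σ|x−y| / Σ(x+y)`, one-factor
  perMANOVA with permutation p-values (999 permutations; exhaustive mode
  for small n), and NMDS minimising Kruskal stress-1 with
  pool-adjacent-violators isotonic regression — all from first principles.
* **Synthetic data** — hierarchically diverged reference databases
  (within-genus ≥ 97% identity, 90–96% between genera, 80–89% between
  families), marker-specific log-normal amplification bias,
  Dirichlet-multinomial replicate overdispersion, read errors, leakage
  into blanks, food contaminants, and multinomial microscope counts, with
  full ground truth for recovery tests.

## Worked example

```r
library(aeropollen)

cfg <- pipeline_config(out_dir = "demo_run", seed = 42)
cfg$simulate$design <- list(n_samples_per_cell = 2, n_pcr_negatives = 3,
                            depth_mean = 6000, n_species_pool = 25)
cfg$simulate$db <- list(n_families = 4, n_genera_per_family = 3,
                        n_species_per_genus = 3)
res <- run_pipeline(cfg)

unlist(res$positive_controls)
#>   trnL nrITS2
#>   TRUE   TRUE

res$quantification[res$quantification$target == "combined", ]
#>    target marker     slope    intercept r_squared      p_value  n
#>  combined   trnL 1.0248960 -0.003182259 0.8851837 5.033117e-18 37
#>  combined nrITS2 0.9511784  0.009856727 0.9532191 7.291768e-25 37

res$permanova
#>  marker factor    f_stat r_squared p_value n_perm
#>    trnL   site 4.0184423 0.4011045   0.037    999
#>    trnL season 0.9510207 0.1368174   0.473    999
#>  nrITS2   site 3.0379934 0.3361358   0.099    999
#>  nrITS2 season 0.9079701 0.1314380   0.488    999
```

Reading the output: both markers' pooled RRA-vs-microscope regressions are
close to the 1:1 line, with the low-amplification-bias nrITS2-like marker
fitting more tightly (R² 0.95 vs 0.89) — the designed marker contrast.
Positive controls contain only the spiked control taxon, and after the
filter cascade every extraction-blank and PCR-negative column is exactly
zero (`res$filtered[[marker]]$report` itemises what each of steps a–f
removed).  The perMANOVA detects the simulated between-site composition
shift at this small demo size for trnL (p = 0.037); season effects need
more than 8 samples to reach significance here.

At full scale (the default config: 24 samples × 3 replicates × ~5000
reads × 2 markers) the pipeline runs end-to-end in a few minutes on one
CPU; `run_pipeline(pipeline_config(out_dir = "run", seed = 1))` writes all
stage outputs (OTU tables, assignments, filter reports, RRA regressions,
Bray-Curtis matrices, NMDS coordinates, perMANOVA summaries) as TSV plus
an md5 manifest making reruns verifiable.

A thin CLI wrapper lives in `inst/scripts/aeropollen-cli.R`
(`Rscript aeropollen-cli.R all --config cfg.json --out run --seed 1`).

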