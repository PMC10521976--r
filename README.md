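# clonepulse

Clone tracking and drug-resistance classification for lentiviral
cellular-barcoding experiments.

## The problem

When a barcoded tumour cell population (every founder clone tagged with a
unique, heritable 48-nt DNA barcode at MOI ≈ 0.1) is split into a vehicle
(DMSO) control and three independently drug-treated replicate cultures,
amplicon sequencing of the barcode before and after selection measures each
clone's fitness under drug. Resistant clones that existed **before**
treatment expand in *every* replicate (the replicates share the founder
pool); clones that acquire resistance **during** treatment expand in only
*one*. `clonepulse` implements this analysis end-to-end for 3D-spheroid-style
selection experiments:

* positional barcode extraction from 150-bp paired-end FASTQ (forward window
  = read bases 21–68, reverse window = bases 80–127, mean-Phred ≥ 20);
* direct matching of windows against the barcode library (exact, or unique
  Hamming-1 with a library min-distance safety check), counting forward and
  reverse directions;
* the core statistic, the per-week clonal growth rate

  $$ r = \frac{1}{T}\,\log\frac{f_R}{f_0} $$

  ($f_R$, $f_0$: barcode frequency in a treated replicate and in the DMSO
  control; $T$: weeks of selection), after removing barcodes with counts < 2
  in all treated samples and the control;
* classification of every detected barcode–replicate pair: $r>0$ in ≥ 2
  replicates → **pre-existing**, $r>0$ in exactly 1 → **de novo**,
  $r\le 0$ → **sensitive**, plus read-frequency-weighted class shares;
* companion whole-exome post-filters: ≥ 10-read coverage gating, per-replicate
  2× VAF enrichment with vehicle-control exclusion
  (conserved/private labelling), and copy-number consensus across ≥ 2
  replicates (p < 0.05, reciprocal overlap ≥ 0.5, absent from DMSO) with gene
  annotation;
* normalized log-inhibitor IC50 fitting
  ($Y = 100/(1+10^{X-\log IC_{50}})$), resistance fold changes, and
  $2^{-\Delta\Delta C_t}$ qPCR fold changes;
* a synthetic-data generator that emulates the full design (initial sample,
  DMSO control, three treated replicates, exponential selection over
  $T$ weeks, multinomial sequencing, FASTQ emission with the exact cassette
  geometry) with planted ground truth for every stage.

Who it is for: groups running barcode lineage-tracing selection screens who
want a transparent, tested reimplementation of this analysis, and method
developers who need a generator with planted truth to benchmark classifiers.

## Worked example

```r
library(clonepulse)

cfg <- clone_sim_config(n_clones = 500, library_size = 2000,
                        frac_preexisting = 0.05, p_denovo = 0.01,
                        T_weeks = 4, depth = 1e5, seed = 42)
pop    <- simulate_population(cfg)
counts <- sample_counts(pop, cfg$depth, seed = 42)
fit    <- classify_barcodes(counts, c("RepA", "RepB", "RepC"), "DMSO",
                            T_weeks = 4)
fit
#> Clonal dynamics classification (500 barcodes, T = 4 weeks, control = DMSO)
#>
#>               RepA RepB RepC
#>   denovo         6    9    5
#>   preexisting   27   27   26
#>   sensitive    467  464  469
#>
#> Read-frequency-weighted class shares (%):
#>   replicate preexisting denovo sensitive
#> 1      RepA       32.44  6.154     61.40
#> 2      RepB       32.09  6.149     61.77
#> 3      RepC       32.91  4.365     62.72
```

Reading this: ~27 unique barcodes per replicate expanded in ≥ 2 replicates
(pre-existing resistance), and those clones carry ~32% of each replicate's
reads after 4 weeks of selection; 5–9 barcodes per replicate expanded
privately (de novo); the remaining barcodes declined relative to the DMSO
control. Against the generator's planted truth:

```r
m <- recovery_metrics(fit, truth_labels(pop))
m[m$replicate == "all", ]
#>  replicate       class precision    recall        f1 n_true n_pred
#>        all preexisting    0.9375 1.0000000 0.9677419     75     80
#>        all      denovo    0.6500 1.0000000 0.7878788     13     20
#>        all   sensitive    1.0000 0.9915014 0.9957326   1412   1400
```

(At the simulator's default depth of 10^6 reads/sample all three F1 scores
exceed 0.96; the shallow 10^5-read example above leaves a little multinomial
noise in the rare de novo class.) A dose-response fit:

```r
d <- simulate_dose_response(0.5, 10^seq(-2, 3, length.out = 8),
                            noise_sd = 5, seed = 1)
fit_ic50(d)
#> IC50 fit (normalized log-inhibitor model)
#>   log10(IC50) = 0.5613   IC50 = 3.642 uM
#>   residual norm = 10.471 over 8 points
```

A thin command-line wrapper for the FASTQ-facing steps is shipped at
`inst/scripts/clonepulse.R` (`extract`, `count`, `table`, `classify`,
`ic50`).

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package: it simulates a barcoded selection experiment, writes and
re-reads paired FASTQ, verifies the extract→count round trip, classifies
clones and scores them against the planted truth, runs the variant/CNA
filters on planted tables, and fits a noisy dose-response curve; it then
writes its JSON report to `--out`.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
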