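---
title: "Quantifying pre-existing and de novo drug resistance from cellular barcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pre-existing and de novo drug resistance from cellular barcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepulse)
```

## The experimental design this package models

In a lentiviral cellular-barcoding experiment, a founder cell population is
infected at low multiplicity of infection (MOI ~0.1) with a library of ~10^6
distinct 48-nt DNA barcodes, so that essentially every infected cell carries a
single, unique, heritable tag. The barcoded population is split into one
*initial* sample, a vehicle (*DMSO*) control, and three independently
drug-treated replicate cultures (*RepA*, *RepB*, *RepC*), grown as 3D
spheroids under escalating drug for a fixed selection time `T` (weeks).
Amplicon sequencing of the barcode cassette before and after selection turns
clone abundances into read counts, and the change in a barcode's frequency
under drug — relative to the same barcode's frequency in the vehicle control —
measures that clone's fitness under treatment.

Two modes of resistance leave distinct signatures. A clone that was resistant
*before* treatment (pre-existing) is expected to expand in **every**
independently treated replicate, because the replicates were split from the
same founder pool. A clone that *acquires* resistance during treatment (de
novo) expands only in the replicate where the event happened. This asymmetry
is the core of the classifier.

## The growth-rate statistic and classifier

For barcode $i$ in treated replicate $R$:

$$ r = \frac{1}{T}\,\log\!\left(\frac{f_R}{f_0}\right) $$

where $f_R$ is the barcode's read frequency in the replicate, $f_0$ its
frequency in the matched DMSO control, and $T$ the weeks from first treatment
to harvest (a per-arm constant supplied by the caller, e.g. 16 for a long
dabrafenib-style arm, 4 for a short irinotecan-style arm — never inferred
from data). Barcodes with counts below 2 in *all* treated samples and the
control are removed before frequencies are computed; frequencies are
normalized over the retained barcodes in the control and replicate columns.

Classification, per barcode and replicate:

* $r > 0$ in **two or more** replicates → *pre-existing* (in each positive
  replicate);
* $r > 0$ in **exactly one** replicate → *de novo* (in that replicate);
* $r \le 0$ → *sensitive*.

`class_frequency_summary()` then reports, per replicate, the share of reads
carried by each class — the quantity that makes "45% of the resistant
population was pre-existing"-type statements.

### Numerical choices

* **Log base.** Natural log. The label depends only on the sign of $r$,
  which is base-invariant; `log_base` is an argument for reporting taste.
* **Zeros.** $f_0 = 0$ (typical for de novo clones absent from the control)
  makes the ratio undefined. A pseudo-frequency of `pseudo_reads` (default
  0.5 reads) divided by the column read sum is added *only to zero entries*,
  so barcodes observed on both sides are completely unaffected (tested as an
  invariant). The magnitude is a knob, not a tuned constant.
* **Ties.** $r = 0$ exactly is labelled sensitive: the rule partitions into
  "positive" and "negative" and ties are measure-zero on real data; fixing
  the boundary makes the brute-force test oracle well defined.
* **"Detected in at least two replicates".** Read as "has *positive growth
  rate* in ≥ 2 replicates" (the stricter reading, consistent with the
  contrast against "detected only in one replicate"). The looser
  nonzero-count reading is available as `detect_rule = "nonzero_count"`;
  with it, a clone present but shrinking in a second replicate would be
  promoted from de novo to pre-existing.
* **Undetected pairs.** A barcode with zero reads in a given replicate is
  labelled `excluded` there: it contributes no reads to that replicate's
  class shares, and "absent" is not evidence of sensitivity at finite depth.
* **Baseline.** $f_0$ comes from the DMSO control, not the initial sample;
  the initial sample is carried through for reporting only.

## What the synthetic-data generator emulates

`simulate_population()` states the experiment as a generative model:

| Parameter | Default | Meaning |
|---|---|---|
| `n_clones` | 1000 | founder clones after MOI-limited infection |
| `library_size` | 10^4 (tests), 10^6 supported | distinct library barcodes |
| `frac_preexisting` | 0.05 | clones resistant before treatment (shared across replicates) |
| `p_denovo` | 0.01 | per-replicate probability of private acquisition by a sensitive clone |
| `fitness_resistant` | +0.3 /week | log growth advantage under drug |
| `fitness_sensitive` | −0.3 /week | log decline under drug |
| `fitness_dmso` | 0.1 | total log-scale SD of neutral control drift |
| `T_weeks` | 4 (16 for the long arm) | selection duration |
| `depth` | 10^6 | reads per sample |
| `error_rate` | 0 | per-base substitution rate in emitted reads |

Treated abundances are the deterministic exponential
`initial × exp(fitness × T)`; sequencing is multinomial at fixed depth;
reads are emitted with the exact cassette geometry (20-nt constant flank +
barcode on the forward read; 79-nt flank + reverse-complement barcode on the
reverse read; neutral filler to 150 nt) so the positional extractor is
exercised end-to-end.

Deliberate simplifications, hence what a green test does *not* establish:

* **Dose escalation is flattened** into one constant per-week fitness per
  clone. Endpoint-only barcode data cannot resolve within-arm dose steps, so
  a richer schedule would be unidentifiable anyway.
* **De novo timing.** Acquisition is modelled as replicate-private positive
  fitness from $t=0$, not a stochastic acquisition time — indistinguishable
  at endpoint, and the simpler model keeps planted truth exact. If a
  sensitive clone draws acquisition in more than one replicate (probability
  ~3×10⁻⁴ per clone at defaults), one replicate is kept at random so that
  "de novo" always means private.
* **Control drift.** DMSO abundances drift log-normally with total σ =
  `fitness_dmso` (default 0.1). The scale is deliberately small relative to
  the fitness signal |±0.3| × T: neutral drift must not flip growth-rate
  signs at default depth, otherwise planted labels and classifier output
  diverge for reasons unrelated to the classifier. (With σ accumulated
  per-week as σ√T the flip probability at T = 4 is already ~2% per clone,
  which visibly corrupts pre-existing precision — the total-σ reading is the
  stated world.)
* **No PCR amplification bias, no spatial spheroid structure, no
  death/cell-cycle mechanics.** The sequencing model is pure multinomial.
* **Library representation** after MOI selection is uniform-random; real
  libraries have skewed representation. Initial clone sizes are log-normal
  (sdlog 0.5) to reflect unequal founder expansion — a shape choice, not a
  fitted value.

## Barcode extraction and counting

Extraction is strictly positional, mirroring fixed trimming parameters
(forward: drop 20, keep 48 → bases 21–68; reverse: drop 79, keep 48 → bases
80–127; 1-based inclusive): no adapter scanning, no alignment. Reads with
mean Phred < 20 are dropped (boundary inclusive); the alternative reading of
"masking" (per-base) would behave identically inside an exact-match window,
where any masked base is simply a mismatch.

Counting matches each extracted window directly against the 48-nt library —
forward windows against the barcode, reverse windows against its reverse
complement — and the two mates of a pair are counted independently (an
error-free pair contributes 2). This replaces k-mer-index-based
quantification with its transparent fixed-length equivalent; equivalence is
claimed (and tested) on error-free input, not read-for-read on noisy data.
Optional single-mismatch correction assigns a window to a *unique*
Hamming-distance-1 neighbour; it is off by default, and enabled only when the
library's minimum pairwise distance is ≥ 3 (checked by hashing every
barcode's Hamming-1 ball), which guarantees a one-error read can never sit
within distance 1 of a wrong barcode.

## Whole-exome post-filters

These consume externally produced tables (variant calls, Control-FREEC-style
segment calls); calling itself is out of scope.

* **Coverage gate:** depth ≥ 10 in *every* sample and position inside the
  capture panel.
* **VAF enrichment:** replicate flagged when `VAF_rep ≥ 2 × VAF_initial` and
  the DMSO control is *not* similarly enriched — drift that also appears in
  the vehicle is never drug-selected. Enrichment is evaluated per replicate;
  a variant enriched in all three replicates is *conserved*, in exactly one
  *private*. `VAF_initial = 0` is floored at half a read,
  `1/(2·depth_initial)`, a configurable convention recorded in the output.
  The boundary is inclusive (exactly 2× counts).
* **CNA consensus:** significant calls (p < 0.05, strict) from ≥ 2 replicates,
  same direction (gain with gain, loss with loss — mixing directions in one
  consensus would be incoherent), mutually overlapping at reciprocal overlap
  ≥ 0.5 (a stated convention; no overlap criterion exists in the source
  method), and not overlapped by any significant same-direction control
  call. The reported region is the intersection of the supporting calls, and
  supports are maximal cliques of the pairwise-compatibility graph.

## Dose-response and qPCR metrics

`fit_ic50()` fits the normalized log-inhibitor model
$Y = 100/(1 + 10^{(X - \log IC_{50})})$ with asymptotes pinned at 100/0 and
slope −1 (the normalized-response convention; a variable Hill slope is behind
a flag). The single free parameter is found by a deterministic coarse grid
plus golden-section refinement; a grid optimum on the boundary (e.g. a flat
100% curve) returns an explicit non-converged result. Printed fold changes in
the source study are not reproducible from its rounded printed IC50 means
(they come from unrounded inputs), so fold changes here are always computed
from this package's own fits. `ddct_fold_change()` implements
$2^{-\Delta\Delta C_t}$ with the standard efficiency-2 assumption.

## Worked example

```{r example}
set.seed(1)
cfg <- clone_sim_config(n_clones = 500, library_size = 2000,
                        frac_preexisting = 0.05, p_denovo = 0.01,
                        T_weeks = 4, depth = 1e5, seed = 42)
pop <- simulate_population(cfg)
counts <- sample_counts(pop, cfg$depth, seed = 42)
fit <- classify_barcodes(counts, c("RepA", "RepB", "RepC"), "DMSO",
                         T_weeks = 4)
fit
recovery_metrics(fit, truth_labels(pop))[1:3, ]
```

```{r plot, fig.width = 5, fig.height = 4}
plot(fit, main = "Clonal composition after selection")
```

## Known limitations

* Growth rates use endpoint frequencies only; clones with identical endpoint
  frequency but different trajectories are indistinguishable by design.
* The de novo / pre-existing distinction relies on replicate independence; a
  resistance event occurring *before* the split inflates pre-existing calls,
  and only-one-surviving-replicate designs cannot separate the classes.
* Exact matching discards reads with sequencing errors in the barcode window
  unless single-mismatch correction is enabled; at per-base error 0.001,
  about 4.7% of windows carry ≥ 1 error.
* The classifier's per-replicate labels allow one barcode to be pre-existing
  in two replicates and sensitive in a third; unique-barcode tallies per
  class are therefore per-replicate quantities, not a global partition.
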