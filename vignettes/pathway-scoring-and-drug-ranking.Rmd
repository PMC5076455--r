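---
title: "Pathway activation scoring and geroprotector ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activation scoring and geroprotector ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(geroscope)
```

## The model

Aging leaves a reproducible footprint in the transcriptome: signaling
pathways that drive senescence-associated programs are up-regulated in cells
from old donors, and pathways that protect against them are attenuated. The
idea behind this package is to (i) summarize that footprint pathway by
pathway, and (ii) search a library of compounds with known protein targets
for drugs whose pharmacology is predicted to push the aged signalome back
toward the young state.

### Pathway activation strength

For a case group (old donors) against a reference group (young donors), each
gene $n$ gets a case-to-normal ratio $\mathrm{CNR}_n$ — the ratio of the mean
case intensity to the mean reference intensity on the linear scale — and a
binary significance flag $\mathrm{BTIF}_n$ derived from a two-sided
equal-variance Student's t-test with Benjamini–Hochberg FDR control:
$\mathrm{BTIF}_n = 1$ iff the adjusted p-value falls below $\alpha$ (0.05 by
default). A pathway $p$ with member weights $\mathrm{ARR}_n \in [-1,1]
\setminus \{0\}$ (positive for activators of the pathway, negative for
repressors, magnitude $< 1$ for weak roles) is then scored as

$$\mathrm{PAS}_p = \sum_{n \in p} \mathrm{ARR}_n \cdot \mathrm{BTIF}_n \cdot
\lg \mathrm{CNR}_n .$$

Positive PAS means the pathway is up-regulated in the case state, negative
means down-regulated. Only significantly changed genes contribute, so a
sample whose PAS is exactly zero for *every* pathway carries no significant
pathway signal at all; such samples are treated as insignificantly perturbed
and excluded (`filter_zero_pas_samples()`).

Per-sample profiles reuse the group-level significance flags — a single
sample cannot support a t-test — while the ratios are the sample's own
values against the reference mean. This is the one consistent reading of
individual-sample scoring on top of a group-level test, and it makes the
average of per-sample scores track the group score closely on homogeneous
groups (asserted in the tests, up to the concavity gap between the log of a
mean and the mean of logs).

### GeroScore

Each drug $d$ in the target database is scored as

$$\mathrm{GS}_d = \sum_t \mathrm{DTI}_{dt} \sum_p \mathrm{NII}_{tp} \,
\mathrm{ARR}_{tp} \, \mathrm{PAS}_p \, \mathrm{PAR}_p$$

with $\mathrm{DTI}_{dt} = +1$ if the drug inhibits target $t$, $-1$ if it
activates it; $\mathrm{NII}_{tp} \in \{0,1\}$ membership of $t$ in pathway
$p$; $\mathrm{ARR}_{tp}$ the target's own member weight in that pathway;
and $\mathrm{PAR}_p = +1$ for pro-aging, $-1$ for anti-aging pathways. The
sign bookkeeping rewards exactly the interventions a geroprotector should
make: inhibiting activators of up-regulated pro-aging pathways, or restoring
down-regulated anti-aging pathways. NII, ARR and PAR are structural database
constants; only PAS varies between case samples. Scores are computed per
case sample, aggregated by the arithmetic mean (median available), and drugs
are ranked by descending aggregate with lexicographic tie-breaks so that
rankings are fully reproducible.

When several datasets are screened independently (different platforms or
cell types), `combine_geroscore_tables()` z-scores each dataset's aggregate
scores before averaging, so datasets with different score scales contribute
equally. The z-score rule is this package's choice of a simple
scale-equalizing combination; any monotone alternative would preserve
per-dataset rankings but weigh datasets differently.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | FDR threshold gating gene contributions (dimensionless) |
| `log_base` | 10 | base of the PAS logarithm; rescales all PAS by a constant |
| `epsilon` | 1e-6 | floor on group means in CNR, keeps ratios finite on zero-expression genes (intensity units) |
| `young_min`, `young_max` | 15, 30 | inclusive age window of the young reference group (years) |
| `old_min` | 60 | exclusive lower bound of the old case group (years) |
| `shortlist_n` | 10 | candidates retained from the ranking |

The age windows read the recruitment rule literally: 15–30 inclusive on both
ends, strictly over 60 for old donors; donors between the windows are
excluded. Gene symbols are matched case-insensitively (uppercased on entry)
because public pathway and drug sources mix symbol capitalization.
Equal-variance (not Welch) t-tests are used deliberately — the classic
Student test is what the scoring model specifies — and two degenerate cases
are defined by convention rather than left as errors: constant groups with
equal means give $p = 1$, with unequal means $p = 0$. Genes with fewer than
two usable values on a side are untestable: they keep their CNR but are
flagged insignificant and excluded from the FDR family. Pathways none of
whose members are measured score 0 but carry a `no_coverage` flag so the
zero-PAS exclusion rule never confuses "no data" with "no change".

## Plate-matched perturbation designs

For compound-perturbation expression data (L1000-style screens), the
reference for each compound is built from vehicle (DMSO) wells *on the same
RNA plate(s)* as the treated wells, so plate effects cancel in the ratio.
Doses are matched with 1% relative tolerance to absorb inconsistent rounding
in annotation files; cell-line filtering is an explicit argument rather than
a hard-coded choice. Compounds lacking treated wells or same-plate vehicle
wells are skipped with a logged reason, never silently. Replicate plates for
one compound are pooled into a single design.

## The synthetic-data module

`simulate_pathway_db()`, `simulate_expression()` and `simulate_drug_db()`
generate data with known ground truth so every stage — and the end-to-end
ranking — can be validated without any external data:

- intensities are log-normal, $10^{\mu + N(0,\sigma)}$ on the log10 scale
  with baseline $\mu = 2$ and $\sigma = 0.1$ by default, matching the
  positive, right-skewed shape of normalized microarray intensities and
  making expected log-ratios analytic;
- pathway membership is disjoint, which keeps the expected PAS of each
  pathway independent and the oracle tractable;
- planted pathways have their member means multiplied by
  $\mathrm{fc}^{\,\mathrm{sign(ARR)}}$ in the case group — activators up,
  repressors down — so the planted PAS is positive, and they are fixed to
  $\mathrm{PAR}=+1$ so the planted contrast reads as an activated pro-aging
  signature from which an ideal opposing drug is well-defined for every
  seed;
- the planted "ideal geroprotector" inhibits the activator members and
  activates the repressor members of the planted pathways; decoys get the
  same number of targets, drawn at random with random interaction signs,
  so the benchmark compares drugs of equal annotation size.

The default benchmark conditions — 2000 genes, 10 pathways of 15 genes, 3
planted at fold change 4, noise sd 0.1, 8 case vs 8 reference samples, 30
decoys, 100 replicate seeds — describe a strong but realistic age contrast
at small-cohort sample sizes. `run_recovery_benchmark()` reruns the whole
pipeline per seed and reports the fraction of seeds placing the planted drug
at rank 1. At the defaults this recovery is essentially 1; at fold change 1
(no effect) almost every replicate loses all its samples to the zero-PAS
filter — under a global null the FDR correction rarely flags any gene — so
observed null recovery falls at or below the nominal 1-in-31 chance level.
Replicates whose samples are all filtered count as non-recoveries.

What the simulation does *not* emulate: probe-level artifacts, batch and
plate effects in the aging cohorts, correlated noise between genes,
overlapping pathway membership, and dose–response structure. Passing the
recovery benchmark therefore demonstrates that the statistics and the sign
conventions are implemented coherently end to end — not that real screens
enjoy the same power, which depends on effect sizes and confounding the
generator deliberately idealizes.

## Numerical choices

- CNR uses arithmetic means of linear intensities with an `epsilon` floor;
  no logs are taken before averaging, so zeros never produce infinities.
- PAS sums are plain floating-point sums over at most a few hundred members;
  the tests pin them to brute-force term-by-term oracles at `1e-12`.
- Ranking ties are broken lexicographically by drug id — exact score ties do
  occur (duplicate target annotations) and must not depend on input order.
- All tabular I/O is UTF-8 TSV with `.` decimals; write/read round-trips are
  bit-exact, and a rerun of a screen from the same inputs is byte-identical
  (the manifest records parameters and input checksums).

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
cfg <- sim_config(seed = 42)
files <- write_simulated_bundle(cfg, n_decoys = 30, out_dir = dir)
res <- run_aging_screen(run_config(
  expression = files$expression, annotations = files$annotations,
  pathways = files$pathways, drugs = files$drugs,
  out_dir = file.path(dir, "out")))
res$shortlist[1]   # the planted drug, "GERO_IDEAL"
```

Problem sizes in the shipped tests and the acceptance script are 300–2000
genes, 4–10 pathways, 50–100 replicate seeds; the full suite and the script
each run in well under a minute of compute per benchmark on one core.

## Limitations

The method is a qualitative ranking, not an effect-size estimate: PAS mixes
significance gating with log-ratios, so scores are comparable within one
screen but not across datasets without the z-score combination. The
per-sample profiles inherit the group-level significance flags, so an
individual sample's score reflects the group's differential-expression
structure. Topology-aware pathway scoring, enrichment statistics,
dose–response modeling and target-affinity weighting are out of scope.
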