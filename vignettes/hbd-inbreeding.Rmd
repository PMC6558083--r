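---
title: "Age-partitioned inbreeding from HBD mosaics, with copy-loss correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-partitioned inbreeding from HBD mosaics, with copy-loss correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mosaicf)
library(dplyr)
```

## The model

`mosaicf` estimates how inbred an individual is *and how long ago* the
inbreeding happened, from ordinary SNP-array genotypes. The underlying model
treats each diploid genome as a mosaic of homozygous-by-descent (HBD)
segments — stretches where both haplotypes descend from a single ancestral
haplotype — interleaved with non-HBD segments. Segment lengths are
exponential on the genetic map: a segment of class $k$ has mean length
$1/R_k$ Morgans, where the rate $R_k$ is tied to the number of generations
$G$ back to the common ancestor through $R \approx 2G$ (each meiosis adds
recombination opportunities, so older ancestry leaves shorter segments).
Partitioning HBD into classes with fixed rates therefore partitions
inbreeding by age: mass in a rate-4 class reflects a common ancestor roughly
two generations back; mass in a rate-1024 class reflects ancestry hundreds
of generations old.

The default configuration uses eleven HBD classes with doubling rates
$2, 4, 8, \ldots, 2048$ plus one non-HBD class at rate 2048, a genotyping
error rate $e = 0.001$, and a minor-allele-frequency floor of 0.01. Rates
are deliberately *not* estimated: with fixed rates, each class has a stable
meaning across individuals and breeds, and only the per-individual mixing
proportions $\pi$ (the probability that a new segment belongs to each
class) are fit. Because the literature is ambiguous about whether the
doubling grid should be read as rates $R$ or generations $G$ (i.e. rates
$2G$), the rate vector is fully configurable, so either reading is runnable;
the default uses the listed values directly as rates.

### Hidden Markov model

Markers are the observation sequence of an HMM whose hidden state is the
segment class. Emissions depend on the population B-allele frequency $p$
and the error rate $e$:

* HBD state: $P(AA) = (1-e)(1-p) + e(1-p)^2$, $P(AB) = e\,2p(1-p)$,
  $P(BB) = (1-e)p + ep^2$ — heterozygotes arise only through error;
* non-HBD state: Hardy–Weinberg proportions $(1-p)^2$, $2p(1-p)$, $p^2$;
* missing or MAF-floored markers emit probability 1 in every state, which
  keeps the genomic coordinate system (and hence ROH lengths) intact
  instead of deleting markers.

Between adjacent markers separated by $d$ Morgans, the current segment of
class $k$ survives with probability $e^{-R_k d}$; otherwise a new segment
class is drawn from $\pi$, so any class can follow any class:

$$T_{kj}(d) = e^{-R_k d}\,[k = j] + \left(1 - e^{-R_k d}\right)\pi_j.$$

Chromosomes are independent chains with initial distribution $\pi$.
Posteriors come from scaled forward–backward sweeps (per-site scaling
constants, no log-space arithmetic); the per-individual EM holds rates fixed
and sets each $\pi_k$ proportional to the expected number of segment
*entries* into class $k$ (initial state plus switch events), iterating until
the log-likelihood gain falls below `em_tol` ($10^{-6}$ by default, capped
at 1000 iterations with a warning on non-convergence). EM guarantees a
non-decreasing log-likelihood, which the test suite asserts on every fit.

Two numerical details matter in practice. Inter-marker distances are floored
at $10^{-8}$ Morgans so duplicate map positions cannot create a degenerate
zero-distance transition. And the survival probabilities $e^{-R_k d_t}$
depend only on the map, so they are precomputed once per individual and
reused across all EM iterations (the compiled core is $O(TK)$ per sweep
thanks to the stay/switch decomposition of $T$).

### Inbreeding coefficients

Averaging the posterior mass of class $k$ over all markers gives the
realized class inbreeding $F_k$; their sum over HBD classes is the global
coefficient $F_G = \sum_k F_k$, identical to one minus the mean non-HBD
posterior. ROH-based coefficients complement it: called segments give
$F_{ROH}$ (all segments) and $F_{ROH>2Mb}$ (strictly longer than 2 Mb, for
comparability with window-based callers), both divided by the mapped genome
length (sum over chromosomes of last-minus-first marker position).

### Calling ROH

Two segment definitions are provided, and they serve different purposes:

* **Posterior seed/extend** (default): a segment must contain a marker with
  total HBD probability above 0.999 and extends over all surrounding
  markers above 0.99, stopping at the first marker below the threshold.
  No bridging across a single sub-threshold marker is performed. This rule
  is precise about *what is confidently HBD* but is conservative near
  boundaries: the posterior needs roughly $\log(1/\pi_k)$ nats of
  cumulative evidence — of the order of ten markers at 50k density — to
  cross 0.99 after a true boundary.
* **Viterbi** (`mode = "viterbi"`): maximal runs of HBD states in the
  maximum a-posteriori path. Because every homozygous marker inside a true
  HBD segment carries positive log-likelihood-ratio for HBD, the Viterbi
  boundary sits within a couple of marker intervals of the truth (it
  overshoots only while flanking non-HBD markers happen to be homozygous,
  about $1/(2pq)$ markers on average). Boundary-accuracy checks therefore
  use this mode.

Ties in the Viterbi backtrack go to the lowest class index,
deterministically. Each segment is annotated with the modal Viterbi class of
its markers. Coordinates are 0-based half-open internally; PED/MAP positions
are treated as 1-based points and converted on ingest. Segment length is
`end - start` over the first/last included marker, consistent with the
mapped-length denominator.

### Hemizygous-deletion correction

Array genotyping cannot represent a single-copy (hemizygous) region: a
deletion on one haplotype is typed as if homozygous, and a run of such
markers is indistinguishable from ROH in the genotypes alone. The
correction consumes externally produced CNV calls, intersects copy-loss
calls (copy number 0 or 1; duplications are excluded) with called ROH per
individual, and confirms hemizygosity with intensity evidence: a region
whose mean log R ratio (LRR) over its markers is below $-0.3$ is flagged as
a genuine copy loss. Flagged regions are merged per individual (so
overlapping calls are not double-counted) and their total length $L$,
expressed as the fraction $L/\text{denominator}$, is subtracted from
$F_{ROH}$ and $F_G$; the $F_{ROH>2Mb}$ metric subtracts only flagged
lengths hosted in ROH longer than 2 Mb. All adjusted values are clamped at
zero. Regions containing no markers cannot be LRR-classified and are
reported but never flagged. Subtracting a *length fraction* from $F_G$ is
the only dimensionally coherent reading of removing these regions from a
genome-fraction metric, and it keeps every adjusted value bounded by its
raw value — an invariant the tests assert per individual and metric.

## The synthetic-data generator

Real cohorts with known autozygosity do not exist, so the package ships a
generator that emulates exactly the statistical structure the model assumes,
making every downstream stage testable end to end:

* chromosomes are tiled left to right by a renewal process: class from the
  mixing proportions, length exponential with the class rate (the first
  segment is drawn like all others; the missing stationarity correction
  vanishes for long chromosomes);
* genotypes are emitted with error $e$ from allele frequencies drawn
  uniformly on $(0,1)$ and truncated to $[0.01, 0.99]$;
* the genetic map is a constant 1 cM/Mb (configurable), the common default
  for livestock arrays;
* hemizygous deletions recode genotypes homozygous for a retained allele
  (drawn per marker with probability $p$ — simpler than haplotype-coherent
  retention, and downstream only ever sees homozygosity and intensity),
  emit a copy-number-1 CNV call, and depress LRR to
  $\mathcal{N}(-0.55, 0.20)$ against a $\mathcal{N}(0, 0.15)$ baseline.
  These intensity magnitudes are choices consistent with Illumina-array
  behaviour and comfortably separated by the $-0.3$ discriminant; no
  published value fixes them. BAF is dosage/2 plus clipped
  $\mathcal{N}(0, 0.03)$ noise, so deletions concentrate BAF at the poles;
* deletions are placed in the non-HBD genome by default — the configuration
  in which a deletion masquerades as ROH, which is the phenomenon the
  correction targets.

The helper `mixing_for_autozygosity()` converts a target autozygous
fraction into two-point mixing proportions using the renewal identity
$F = \frac{\sum_{HBD} \pi_k / R_k}{\sum_j \pi_j / R_j}$ (classes weighted
by mean segment length), which the generator's long-run output provably
converges to — one of the property tests.

What the generator does **not** emulate: linkage disequilibrium between
markers beyond the HBD structure itself, allele-frequency ascertainment of
real chips, pedigree structure between individuals, and X-chromosome
biology. Passing tests therefore demonstrate correct inference *under the
model's own assumptions*, not robustness to every violation real data can
present.

## A worked example

```{r example}
cfg <- sim_config(
  n_individuals = 6,
  chromosomes = setNames(rep(5e7, 6), paste0("chr", 1:6)),
  marker_density = 25,
  mixing_proportions = mixing_for_autozygosity(0.15),
  n_deletions = 2,
  deletion_length_law = function(n) pmin(pmax(rexp(n, 1 / 2e6), 5e5), 8e6),
  seed = 20
)
sim <- simulate_dataset(cfg)
fit <- fit_hbd(sim$data)
glance(fit)
```

```{r roh}
roh <- call_roh(fit)
metrics <- roh_metrics(roh, sim$data$map,
                       individuals = rownames(sim$data$geno))
losses <- intersect_roh_losses(roh, sim$cnv) |>
  classify_copy_loss(sim$intensity, sim$data$map)
adjust_inbreeding(metrics, global_and_class_inbreeding(fit)$global, losses)
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(fit)
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `hbd_rates` | 2, 4, …, 2048 | class rates per Morgan; class $k$ ≈ ancestors $R_k/2$ generations back |
| `nonhbd_rate` | 2048 | rate of the non-HBD class (shares the largest HBD rate) |
| `genotype_error` | 0.001 | probability an autozygous marker shows an ordinary genotype |
| `maf_min` | 0.01 | below this MAF a marker is uninformative, not deleted |
| `cm_per_mb` | 1 | map scaling when no genetic positions are supplied |
| `seed_prob` / `extend_prob` | 0.999 / 0.99 | posterior ROH seed and extension thresholds (strict `>`) |
| `lrr_threshold` | −0.3 | mean-LRR rule confirming a copy loss |
| `em_tol` / `em_max_iter` | 1e-6 / 1000 | EM stopping rule |

Quality control follows the usual array pipeline: markers with missingness
above 2% are removed first, then individuals above 4% (the order is fixed
and tested); markers failing an exact Hardy–Weinberg test at $p < 0.001$
(pooled across all individuals — per-breed testing is a documented
alternative the package does not perform) are removed; allele frequencies
come from the retained calls. The exact test was chosen over the chi-squared
approximation because low-MAF array markers routinely violate the
large-count assumption; monomorphic markers get $p = 1$ and are handled by
the MAF floor instead.

## Design choices made where the design was open

* **Per-individual EM.** Each animal gets its own mixing proportions, since
  inbreeding coefficients are reported per animal; pooling would shrink
  extreme individuals toward the cohort.
* **Marker-before-individual filter order** in QC, with "call rate ≤ x%"
  read as "missingness above x% removes the unit" — the reading under which
  a fully typed cohort passes intact.
* **Low-MAF masking instead of deletion**, so the MAF floor is a model
  parameter (as it enters the HMM) rather than a map-altering QC step.
* **Two ROH definitions, both first-class.** The posterior rule is the
  default; the Viterbi rule is the boundary-accurate alternative. No
  merging across single sub-threshold markers.
* **Mean LRR per (individual, region)**, not pooled across carriers of a
  shared region: carriers can genuinely differ in copy number.
* **Zero-marker intersections are never flagged** — conservative, since no
  intensity evidence exists.

## Problem sizes and verification

The package's own acceptance experiments (reproduced by
`scripts/acceptance.R` and mirrored in the test suite) use cohorts of 50
individuals with 30 chromosomes of ~1,000 markers each for parameter
recovery across autozygosity strata {0, 0.05, 0.1, 0.25}; 10 individuals at
25 markers/Mb for segment recovery; 1,000 replicate deletions for the
copy-loss flag's sensitivity; and a 12-individual cohort with multi-megabase
deletions (exponential mean 2 Mb, truncated to [0.5, 8] Mb) injected into
non-HBD genome for correction efficacy. The deletion lengths for that last
experiment sit deliberately in the regime where deletions actually get
miscalled as ROH: at array density a copy loss spanning only a dozen
markers rarely accumulates enough apparent-homozygosity evidence to pass
the 0.99 posterior rule, so few-marker deletions are correctly never
called — consistent with observed ROH/copy-loss intersections in real
cohorts being individually small but reaching into the megabases.

## Known limitations

* Rates are fixed by design; misspecifying the rate grid biases the age
  attribution (though weakly the total $F_G$).
* The non-HBD class shares the largest rate, so extremely short non-HBD
  gaps between HBD segments can be absorbed into neighbouring classes.
* The posterior ROH rule undercalls segment ends by construction;
  length-sensitive downstream analyses should use the Viterbi mode.
* CNV calls are consumed, never discovered: the correction is only as good
  as the supplied copy-number calls and intensity data.
* The generator's independence assumptions (no background LD) make the
  simulated inference problem slightly easier than real data at equal
  density.
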