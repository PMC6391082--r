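---
title: "Methods: from enhancer landscapes to Treg suppression statistics"
author: "tregmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from enhancer landscapes to Treg suppression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregmir)
```

tregmir implements the computational backbone of a common experimental
arc in regulatory T cell (Treg) biology: find a miRNA gene flanking a
lineage-factor-bound super-enhancer, screen for its direct mRNA
targets, and quantify the functional consequence in suppression and
reporter assays. This vignette explains each model, its assumptions,
the tunable parameters, and the design choices made where the
published descriptions leave the procedure open.

## Super-enhancer calling

Enhancer peaks scored by ChIP-Seq signal are first **stitched**:
same-chromosome peaks separated by at most the stitch distance
(default 12,500 bp, the convention of the standard rank-ordering
algorithm this stage follows) are unioned, so clusters of constituent
enhancers are treated as one regulatory unit. Stitching is implemented
on `GenomicRanges::reduce()` and is idempotent and monotone in the
stitch distance. No TSS-exclusion window is applied by default: the
upstream tool's default was adopted because nothing in the source
description indicates one was used; pre-filtering the peak table
achieves the same effect when desired.

Each stitched region's **signal** is treatment minus input density
summed over the region, clamped at zero — negative densities are
artifacts of subtraction, not evidence.

For the **cutoff**, regions are sorted ascending by signal and both
the rank index and the signal are rescaled to [0, 1]. The resulting
curve is the familiar hockey stick: a long flat background and a sharp
high-signal elbow. The calling rule is the discrete analogue of the
tangent-of-slope-1 geometry: scanning from the low-signal end, the
cutoff is the signal at the first point whose forward slope exceeds 1,
and every region *strictly* above it is a super-enhancer. A discrete
forward-difference rule was chosen over spline tangency because it is
deterministic, exactly testable against an exhaustive scan, and
scale-invariant (rescaling all signals by a positive constant leaves
the called set unchanged). Degenerate geometry — all signals equal —
calls nothing and warns. Ties in ranking are broken by chromosome then
start coordinate so results never depend on input order.

**Locus association** finds, per query locus, the super-enhancer on
the same chromosome minimizing the gap distance (0 when overlapping);
cross-chromosome matches are never made, and equidistant candidates
resolve to the higher-ranked one. Upstream/downstream is reported on
the locus strand: for a minus-strand locus, upstream lies at higher
genomic coordinates.

## The three-criteria target screen

A candidate direct target must satisfy, simultaneously:

1. **Site evidence** — at least one canonical seed-match site in its
   3′ UTR lying *entirely within* an AGO2 CLIP binding interval. Full
   containment rather than mere overlap is the stricter, deterministic
   reading of a site being "within" a binding footprint.
2. **De-repression** — upregulated more than 2-fold at p < 0.05 in
   miRNA-knockout versus wild-type Tregs.
3. **Treg-biased repression** — downregulated more than 2-fold at
   p < 0.05 in wild-type Tregs versus effector T cells.

Both thresholds are strict inequalities, matching the ">2-fold,
P < 0.05" convention, and no multiple-testing correction is applied by
default (the published screen used raw p-values); a
Benjamini–Hochberg mode is available via `adjust = TRUE`.

**Seed scanning** uses the canonical site classes. The scanner finds
every occurrence of the reverse complement of miRNA positions 2–7
(the 6mer core) and classifies by two determinants: a match to
position 8 on the 5′ flank (m8) and an adenosine opposite position 1
on the 3′ flank (A1), giving 8mer (m8+A1) > 7mer-m8 > 7mer-A1 > 6mer,
one site per core occurrence at its highest class. This replaces the
external thermodynamic predictor used in the original analysis — that
predictor's output can be imported as a site table via
`run_screen(site_table = ...)` — because the screen's logic, not the
prediction algorithm, is what this package contributes. The mature
miRNA sequence is always supplied by the caller (miRBase is the
natural source); it is deliberately not hard-coded.

`simple_moderated_de()` exists so synthetic cohorts can be pushed
through the screen without an external fitting package: log2 fold
change is the log2 ratio of linear group means, and the t-statistic is
computed on log2 data with per-gene variance shrunk toward the pooled
median (prior df `d0 = 4`, reference df `d + d0`). Empirically its
null p-values are calibrated (≈5% below 0.05 at 2,000 genes; the test
suite checks a 3σ binomial band). It is a convenience for simulation,
not a replacement for a dedicated DE framework on real arrays. Note
that under the null a gene essentially never passes the joint
"p < 0.05 AND >2-fold" gate at realistic replication, so the
calibration check disables the fold gate (`fold_threshold = 1`);
that is the only reading under which a ≈5% null pass rate is the
expected behaviour.

Genes quantified in only one of the two comparisons cannot satisfy
both expression criteria and are excluded with a warning rather than
an error, so one incomplete annotation cannot abort a screen.

## Suppression assay statistics

Dye-dilution data exploit the halving of a covalent dye per division:
generation *g* peaks at `gen0 / 2^g`. Events are assigned to the
**nearest theoretical center in log-fluorescence** over generations
0..`max_generations` (default 8, the practical resolution limit of
CellTrace-class dyes); events dimmer than
`gen0 / 2^(max_generations + 0.5)` are below the floor and discarded
with a reported count. Nearest-center assignment was chosen over
mixture-model deconvolution because it is deterministic, matches
peak-gating practice, and is exactly testable; it assumes peaks are
resolved (log10 spread per peak ≲ 0.15, i.e. half the log10(2)
spacing).

The undivided-peak center is calibrated as the modal 1%-trimmed log10
fluorescence of a *known-undivided* well (a time-0 aliquot). This
matters: calibrating from a well that has already proliferated places
the "first peak" on a later generation and silently shifts every
assignment, so the synthetic generator always emits an undivided
calibration well, and `suppression_curve()` prefers wells with
`condition == "undivided"` for calibration.

**Precursor cohort analysis** divides each generation's event count by
`2^g`, counting founding cells rather than their expanded progeny;
`percent_divided` is the percentage of precursors that divided at
least once. The percentage suppression statistic is

S = 100 − (c/d × 100),

with `c` the percent of proliferating precursors with Tregs and `d`
without. Negative values (proliferation above the reference) are
reported as-is. Replicate handling computes `c` and `d` per well and
averages the statistic within each Teff:Treg ratio — matching a
triplicate well-level design — with cocultures paired to the
Teff-alone reference of the same replicate when the metadata provides
one, and to the mean reference otherwise; event pooling across wells
is deliberately avoided because it would weight wells by cell count.

## Reporter and qPCR quantification

The reporter readout is the NGFR/Thy1.1 MFI ratio per well (medians
over gated events; the internal Thy1.1 control cancels transfection
efficiency, so the ratio is invariant to a common instrument gain).
Per construct, ratios are averaged within the miRNA-expressing and
empty-vector groups and the normalized value is their quotient, fixing
the empty-vector condition at exactly 1. A two-tailed two-sample t
test (Welch by default) on the per-well ratios accompanies each
construct; SD is taken across replicate ratios at the group level.
Relative expression uses 2^−ΔCt against the named endogenous control;
the ΔΔCt variant exists behind the `calibrator_dct` argument but is
unused by default.

## What the synthetic data emulate — and what they do not

Generator defaults are the study conditions the pipeline is tested
under, chosen once:

* **Landscape** (`gen_enhancer_landscape`): 300 background regions
  with uniform(0.5, 1.5) signal — a light-tailed positive law — and 10
  planted super-enhancers at 10× the background median, spread a
  further 1–1.7× so ranks are unambiguous; 1–3 constituent peaks per
  region within the stitch window; the query locus 2,000 bp upstream
  of the rank-5 super-enhancer, mirroring the flanking-miRNA geometry
  of interest. A uniform background keeps the background's own
  order-statistic gaps below the slope-1 threshold, so recovery
  failures indicate real cutoff defects rather than background tail
  accidents; heavy-tailed backgrounds (real ChIP) can place genuine
  intermediate regions near the elbow, which this generator does not
  emulate.
* **Screen cohort** (`gen_screen_cohort`): 53 genes — 3 planted
  targets and 50 decoys each failing exactly one criterion — planted
  linear folds drawn from (2.8, 4), log2-normal noise σ = 0.15, n = 4
  per group. At these settings each planted gene clears both
  expression filters with overwhelming margin, so exact recovery is
  the correct expectation; real microarray effect sizes sit closer to
  the threshold and would not give deterministic recovery. Accidental
  seed cores in random UTRs are scrubbed so site truth is exact.
* **Dilution wells** (`gen_dilution_wells`): 1,000 precursors per
  well, division number truncated-Poisson with mean 2.5 (a 72-hour
  activated-Teff scale), log10 fluorescence σ = 0.05 around each
  center, ratios 1:1–32:1 in triplicate, and Treg potency encoded as
  the division-rate multiplier θ(r) = r/(r+2). The Poisson kinetic is
  a modeling convenience — the precursor arithmetic is
  distribution-agnostic — and the true S per ratio is computed
  analytically from the truncated-Poisson percent-divided values, so
  recovery is checked against exact truth. Real data add overlapping
  peaks, autofluorescence floors and dead-cell contamination that the
  generator omits.
* **Reporter wells** (`gen_reporter_wells`): quadruplicate, 60%
  planted repression on the wild-type construct, none on the seed
  mutant, 10% multiplicative noise. A single quadruplicate estimate
  carries ≈7% sampling noise, so recovery tolerances are evaluated on
  the mean across simulated experiments.

Passing these suites therefore demonstrates correctness of the
*computations* under clean, resolved, planted conditions — not
robustness to the instrument- and biology-level artifacts listed
above.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at I/O edges (`read_bed(convention =
  "one_based_closed")` for 1-based tables).
* All writers emit tab-separated tables with fixed 6-significant-digit
  float formatting, so identical inputs give byte-identical files.
* Slope comparisons in the cutoff use the same `(n − 1) · Δy`
  formulation as the exhaustive reference scan, so implementation and
  oracle agree to the last bit even at exact slope-1 ties.
* One integer seed drives every generator through fixed per-module
  substreams (offsets 101/202/303/404), so any module's fixtures can
  be regenerated alone.
* Degenerate inputs error early and specifically: empty event lists,
  zero total precursors, `d = 0` reference wells, missing empty-vector
  groups, non-positive calibration centers, and unknown comparison
  labels.

## Scale of the simulation studies

The property suites run at 200–310 regions per landscape, 53–2,000
genes per cohort, 1,000 precursors per well and 20 seeds per claim —
sizes chosen so every distributional claim has comfortable sampling
margin while a full test run stays interactive on a single CPU.

## Known limitations

The real-data integration path (aligning the deposited ChIP-Seq
accession and reproducing the published rank of the locus-flanking
super-enhancer) requires downloading and processing an external
accession and is not part of the offline test suite. FCS, CEL and BAM
parsing are out of scope: events and expression arrive as plain
tables, exported upstream. The seed-match scanner intentionally
ignores non-canonical (bulged, 3′-supplementary) sites, and no
conservation scoring is performed.
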