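# tregmir

Regulatory T cells (Tregs) keep self-reactive effector T cells (Teffs)
in check, and microRNAs are part of the circuitry that makes that
suppression work. A recurring analysis arc in this field runs: find a
miRNA gene flanking a super-enhancer bound by the lineage-determining
transcription factor, screen for the miRNA's direct mRNA targets, and
quantify the functional consequence in coculture suppression and
reporter assays. **tregmir** implements that arc as one tested R
pipeline, with synthetic-data generators (known ground truth,
serialized alongside every dataset) so every stage is verifiable
offline.

The four analysis stages:

* **Super-enhancer calling** — peaks are stitched (gap ≤ 12,500 bp by
  default), scored by input-subtracted signal, rank-ordered, and cut at
  the point of the [0,1]-rescaled signal curve where the discrete slope
  first exceeds 1 (the tangent-slope-1 rule); query loci are then
  associated with their nearest super-enhancer with distance, rank and
  strand-aware relative position.
* **Three-criteria target screen** — candidate targets must have
  (1) a canonical seed site (8mer / 7mer-m8 / 7mer-A1 / 6mer) contained
  in an AGO2 CLIP interval, (2) >2-fold upregulation (p < 0.05) in
  miRNA-knockout vs wild-type Tregs, and (3) >2-fold downregulation
  (p < 0.05) in wild-type Tregs vs Teffs.
* **Suppression assay** — dye-dilution events are assigned to division
  generations (nearest center in log space, centers halving per
  generation), precursors back-calculated as n<sub>g</sub>/2<sup>g</sup>, and
  suppression scored as **S = 100 − (c/d × 100)**, where *c* and *d*
  are the percentages of proliferating precursors with and without
  Tregs, across a 1:1–32:1 Teff:Treg titration.
* **Reporter / qPCR quantification** — per-well NGFR/Thy1.1 MFI
  ratios, normalized so the empty-vector condition is exactly 1, with
  a two-tailed t test per construct; relative expression by 2^−ΔCt.

## Worked example

The numbered scripts under `analysis/` run each stage on synthetic
data with planted truth. For example:

```sh
Rscript analysis/02_target_screen.R
#> Candidates: gene006, gene019, gene038
#> Planted:    gene006, gene019, gene038
#> Decoy false positives: 0 of 50
```

The screen recovered exactly the three planted targets out of 53 genes;
each of the 50 decoys fails exactly one of the three criteria, so any
decoy in the output would be a false positive.

```sh
Rscript analysis/03_suppression_assay.R
#> Suppressive Treg:   S(1:1) = 38.6%, falling to 1% at 32:1 (max |error| vs truth 1.68 points)
#> Non-suppressive Treg: S stays near zero (max |S| = 1.09 points) -- the functional null
```

Suppression is strongest at 1:1 and titrates out toward 32:1, matching
the generative truth within ~2 points; a Treg with no planted effect
produces a flat near-zero curve — the pattern expected from a
functionally inert knockout Treg.

The same stages are available programmatically:

```r
library(tregmir)
land <- gen_enhancer_landscape(seed = 1)
res  <- call_super_enhancers(land$peaks, land$treatment, land$control,
                             loci = land$loci)
res$associations
#>         locus             super_id rank distance_bp relative_position
#> 1 mirna_locus chr1:2803102-2806978    5        2000          upstream
```

The planted miRNA-like locus is found 2,000 bp upstream of the
fifth-ranked super-enhancer — the geometry the generator planted.

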