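---
title: "Calling transcription-factor footprints from capillary electrophoresis peak tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transcription-factor footprints from capillary electrophoresis peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footcall)
library(dplyr)
```

## The measurement

Automated DNase I footprinting identifies protein-bound DNA at base-pair
resolution. A region of interest (here the canonical use case is a 1.3 kb
promoter-upstream fragment, analyzed through overlapping 300–500 bp
subclones) is amplified with one FAM-labeled primer so that each DNase I
cleavage product appears, after capillary electrophoresis, as a peak whose
called size locates the cut residue and whose fluorescence height measures
how often that residue was cut. A bound transcription factor shields its
binding site, so peaks inside the site shrink in the protein condition
relative to a BSA mock-binding control. Each DNA sample is run with an
internal size standard (LIZ-type) in a separate dye channel, and in
replicate capillary runs.

footcall starts where the fragment-analysis software stops: from exported
peak tables (called size, height) per sample, with samples defined by
condition (BSA or FOXO protein), protein concentration (600 or 1200 nM),
labeled strand (forward or reverse), and replicate (five per sample by
default).

## Coordinates and geometry

All internal coordinates are 1-based inclusive positions on the forward
strand of the analyzed region, position 1 being the most distal residue.
TSS-relative positions are `p - (region_length + 1)`, so the proximal end of
a 1300 bp region is −1. BED6 output is the only 0-based half-open surface,
and the conversion happens exactly once, in the io module.

Because every subclone sits in the same vector, forward-labeled products
share the first 69 vector residues and reverse-labeled products the last 48.
Insert residue *i* therefore produces a forward-read product of called size
≈ 69 + *i*; on the reverse read, residue *j* counted from the insert 3′ end
gives size ≈ 48 + *j* and maps back to forward-strand position
*L* − *j* + 1. Peaks snap to the nearest integer residue within a tolerance
of ±0.5 bp (size calling at these lengths is sub-base-pair precise; the
tolerance is configurable). When two peaks snap to one residue the taller
wins — shoulder peaks are artifacts of imperfect peak deconvolution.

## From peaks to protection ratios

Per sample, every signal height is divided by the mean height of all
standard-channel peaks of that sample, pooled across its replicates; this
removes run-to-run injection and labeling differences and makes the ratio
statistic scale-invariant per sample. Per residue, the mean is taken over
the replicates in which a peak was observed: an absent peak may mean either
no cleavage or dropout, so absence contributes nothing to the mean rather
than a zero. A sample needs at least 3 of its replicate maps to yield a
profile, and residues seen in fewer than 2 replicates are flagged
low-support. Residues absent from *every* replicate stay in the profile
with an `NA` mean, so downstream steps can treat full absence explicitly.

The protection ratio at a residue is the BSA mean divided by the FOXO mean;
a ratio of 1 means no protection. A residue observed under BSA but absent
from every FOXO replicate is the strongest protection signal (no cleavage
at all), but a literal division would be infinite, so the ratio is computed
against an epsilon floor — 5% of the FOXO sample's median normalized
height — and capped at 50, flagged `foxo_missing`. Residues missing from
BSA, or from both conditions, carry no ratio.

## Footprint criteria

Footprints are called by four rules applied in order:

1. a residue is **protected** iff its BSA/FOXO ratio is ≥ 2 (inclusive) at
   *either* protein concentration;
2. protected residues must be **clustered**: a cluster tolerates internal
   runs of at most `max_gap = 4` unprotected residues, and must contain at
   least 3 protected residues and span at least 9 bp;
3. when the footprinted sequence on one strand **overlaps** that on the
   complementary strand, the footprint extent follows the strand with the
   longer footprinted sequence (equal lengths: the union);
4. when the two strands are slightly **offset** (separation of at most
   `max_gap`), the footprint limits are the 5′ protected residues of each
   strand — the forward interval's lowest coordinate and the reverse
   interval's highest.

The threshold and the either-concentration rule are the method's own
definition; the clustering constants are this package's operationalization
of "clustered" — they are exposed in `caller_params()`, reported in the run
log, and chosen so that the minimum representable footprint is the 9 bp
floor of what the assay resolves. Rule 4 as stated presumes the usual DNase
geometry in which the reverse-strand cut pattern sits 3′ of the
forward-strand one; in the opposite (unobserved) arrangement the two 5′
limits would not bracket all protected residues, so the implementation
falls back to the union there, preserving the invariant that every
clustered protected residue lies inside a footprint. Footprints are named
`prefix`N (distal) … `prefix`1 (proximal), i.e. numbered outwards from the
promoter along the forward strand.

Whether the uneven placement of protected residues is real signal rather
than threshold noise is checked with a 2×2 chi-square test (1 df, no
continuity correction — the counts are in the hundreds) of
{protected, unprotected} × {inside, outside footprints}; if any expected
cell drops below 1 the test falls back to Fisher's exact test.

```{r pipeline}
cfg <- simulation_config(seed = 42)
ex <- simulate_experiment(cfg)
fc <- call_footprints(ex$peaks, ex$fragments, caller_params(name_prefix = "M"))
glance(fc)
tidy(fc)
```

## Motif annotation

Binding sites are annotated by exact degenerate-pattern matching (no PWM
scoring — the motif classes are short and the match semantics transparent):
the DBE cores `TTGTTT` and `TTATTT` shared by the FOXO-family DBE and IRE
elements, the near-DBE one-mismatch variants `TTGTTG` and `TTTTTT`, the
FKH core `TRTTK` recognized by all FORKHEAD-domain proteins, and a derived
degenerate consensus `TTDTTKNB`. Both strands are scanned; reverse-strand
hits are reported in forward coordinates. Because the FKH core is contained
in every DBE, FKH hits overlapping a DBE or near-DBE span are flagged
`subsumed` and excluded from counts: only FKH copies *outside* DBE motifs
count as additional sites.

Local density statistics use a fixed partition of the region (defaults
258 / 392 / 650 bp, the internal boundaries corresponding to TSS-relative
−1042 and −650). The counting unit is the distinct hit span — a span
matched on both strands counts once — a hit belongs to the fragment
containing its start, densities are per kb rounded to one decimal and
percentages to integers, matching how such tables are conventionally
printed. Near-DBE occurrences are included in the DBE+FKH counts by
default (switchable via `count_classes`).

```{r motifs}
hits <- scan_motifs(ex$sequence) |>
  assign_hits_to_footprints(fc$footprints)
motif_density(hits, region_partition())
```

The degenerate consensus of a site collection is derived per column: bases
with frequency ≥ 0.10 (the default; no published cutoff exists, and 0.10
keeps singleton bases out of small collections while retaining genuinely
variable positions) are covered by the minimal IUPAC code. A threshold no
base reaches is an error, never an empty symbol. Note one documented
ambiguity in the source literature for the Drosophila consensus: the
results section prints `TTDTTKNB` while the discussion writes `TTDTTKNN`;
this package treats the results form as canonical.

## Cross-species projection

Conservation of footprints across species is assessed through a *supplied*
multiple alignment (gapped FASTA) — alignment construction is out of scope.
Footprint positions map to alignment columns and on to the other species'
coordinates, skipping columns gapped there; a footprint mapping less than
half its length is unalignable. Orientation segments, supplied in a sidecar
table rather than auto-detected, mark column intervals where a species'
row is reverse-complemented (e.g. a microinversion): coordinate maps
decrease across such segments, projections through them come back flagged
inverted, and a footprint spanning an orientation breakpoint is split with
a warning. Two footprints are conserved homologs iff their column spans
share at least one column (`min_overlap`, configurable — the literature
states no overlap rule); a footprint conserved pairwise with every species
of a clade is clade-conserved. Motif agreement inside conserved footprints
is deliberately *not* part of the conservation call; position-only
conservation is reported and motif content can be compared separately.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates the full design: a random region with
planted protected sites (each carrying a real DBE-core motif), overlapping
subfragments in vector context, both labeled strands, both conditions at
both concentrations, five replicates. The stochastic structure is:

* per-position, per-strand cleavage propensity ~ log-normal (sdlog 0.5),
  reflecting that DNase cutting rates vary strongly along any sequence;
* FOXO heights divided by the site's protection factor (default 4) at
  protected, strand-visible positions; the factor is applied identically at
  both concentrations, since the assay's definition of protection does not
  model concentration dependence;
* multiplicative log-normal replicate noise with unit mean (CV 10%),
  height-independent Bernoulli dropout (5%), Gaussian size jitter
  (sd 0.08 bp), and an independent-noise standard channel.

Planted sites must be disjoint and separated by at least `2 * max_gap` so
that truth intervals are unambiguous. What the simulator does **not**
model: sequence-specific DNase bias beyond random heterogeneity,
electrophoretic mobility artifacts, baseline/pull-up effects, or partial
protein occupancy gradients. Passing the recovery tests therefore shows the
caller is correct *given the assay's idealized error model*, not that any
particular real dataset will be this clean.

## Numerical choices and problem sizes

Ties between peaks snapping to one residue go to the taller peak;
equal-length strand overlaps go to the union; ratios against missing FOXO
peaks are capped at 50; the chi-square test drops the continuity
correction. The packaged validation runs 50 seeded simulated experiments
(1300 bp region, four subfragments, 160 samples each) for the recovery
statistic, 100 random 1 kb sequences against a brute-force IUPAC oracle for
the scanner, and 20 random 2×2 tables against a hand-computed chi-square;
these sizes give stable statistics at interactive runtimes.

## Limitations

In vitro footprints need not be occupied in vivo; ratio magnitude is not an
affinity estimate; the caller's clustering constants are a reasonable but
not unique reading of "clustered", and footprint boundaries shift by a few
bp under other choices (both are reported in all outputs). Real
reproduction of published per-species footprint sets additionally requires
the archived peak exports and deposited sequences; the package ships only
programmatic fixtures.
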