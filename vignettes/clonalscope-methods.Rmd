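---
title: "Methods: clonal population structure from mixed-ploidy microsatellite genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal population structure from mixed-ploidy microsatellite genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalscope)
```

## The problem

*Brettanomyces bruxellensis*, the main spoilage yeast of red wine, propagates
clonally and occurs as both diploid and allotriploid strains. A panel of 12
codominant microsatellite markers resolves three things at once: the putative
ploidy of an isolate (the maximum number of distinct alleles seen at any
locus), its genetic group (one of six reference-anchored clusters such as
*Wine 2N* / CBS 2499-like or *1st Wine 3N* / AWRI1499-like), and its clonal
identity (two isolates identical at all 12 loci are treated as the same
clone). From a table of genotyped isolates with winery, geography and vintage
metadata, clonalscope reconstructs population structure, clonal diversity,
cellar persistence, geographic dispersal and the temporal dynamics of the
genetic groups.

## Data model and conventions

A genotype cell holds 0–3 integer allele sizes in bp, written
`"228/234/240"`; an empty cell or `NA` is a missing datum (typical runs show
around 6% missing cells). Alleles are exact integers — fragment-analyzer
rounding is assumed upstream. A genotype's canonical key (loci in panel
order, alleles ascending, `.` for a missing locus) is the unit of clone
identity.

Microplate drift is handled by a control strain genotyped on every plate:
per plate and locus, the offset is the *modal* difference between the
plate's and the reference plate's sorted control alleles, and that integer
is subtracted from every allele of the plate at that locus. The mode is
robust to a single discordant control allele; a per-locus (rather than
global) offset reflects dye- and locus-specific drift. The operation is
idempotent and preserves missingness. Because strain ids must be unique,
control replicates carry an `"@<plate>"` suffix and `drop_controls()`
removes them once normalization is done. Normalization shifts allele calls
by default; `check_only = TRUE` merely reports the offsets, since a lab may
prefer flagging to correcting.

## Group assignment and ploidy

The six genetic groups were originally delimited by clustering a larger,
multi-substrate collection; that clustering is not re-derived here. Instead,
assignment is supervised: each isolate is labeled with the nearest reference
genotype under the allele-sharing (Dice) distance,
\(d(A,B) = \mathrm{mean}_\ell\, 1 - 2|A_\ell \cap B_\ell| /
(|A_\ell| + |B_\ell|)\),
averaged over loci non-missing in both genotypes. The Dice form is
size-agnostic, so diploid and triploid loci are compared on equal footing; a
stepwise-mutation-aware (Bruvo-style) distance is available as
`stepwise_distance()` but is not the default, because nearest-reference
recovery on separated groups does not need it and the simpler metric is
easier to audit. Loci missing in either genotype are excluded pairwise, never
imputed — imputation is reserved for the PCA. Ties break toward the earlier
group in the reference panel, and the runner-up margin is reported as a
confidence proxy for peripheral isolates.

Putative ploidy is `max(2, max distinct alleles per locus)`: loci with a
single allele are homozygous, not haploid, so a fully homozygous genotype is
still a putative diploid; any 3-allele locus makes a putative triploid.

## Structure: imputation, PCA, MST, 2N constraint

For the PCA only, missing cells are replaced by the closest neighbour's
data. The donor for each missing cell is the nearest isolate *that carries
data at that locus* (allele-sharing distance on mutually non-missing loci;
ties to the smallest strain id). Restricting donors per locus, rather than
using one global nearest neighbour, guarantees that every cell can be filled
whenever any comparable isolate has data there; the donor's whole allele set
is copied, never single alleles.

The imputed table is expanded into a binary allele-presence matrix (one
column per observed locus–allele pair), which treats 2N and 3N genotypes
uniformly. PCA is computed on centered, unscaled columns; each component's
sign is fixed by making its largest-magnitude loading positive, so
embeddings are reproducible to the digit. The minimum spanning tree is built
on the first two component scores (configurable via `n_axes`) with
Kruskal's algorithm; edges are ordered by weight and then lexicographically
by strain id, so ties — including the zero-weight edges between co-located
clones — resolve deterministically.

The 2N-constraint control asks whether diploid/triploid clustering is a
trivial consequence of allele *counts*: for every 3-allele cell one allele
is deleted uniformly at random, and the structure analysis is repeated.
`clustering_concordance()` quantifies label stability. Each cell draws from
its own sub-stream, derived by hashing (strain id, locus) with the master
seed, so edits elsewhere in a table never shift an unrelated cell's draw.

## Diversity statistics

Within each group, isolates are tallied by genotype key into a frequency
spectrum. The indices are the plug-in forms: Shannon \(H = -\sum p_i \ln
p_i\) in nats, evenness \(E_H = H / \ln R\), inverse Simpson \(D = 1 / \sum
p_i^2\), and Simpson equitability \(E_D = D / R\), with \(R\) the genotype
richness. The natural-log Shannon and the *inverse* Simpson are the variants
whose ratios reproduce the published group-table identities for this species
(e.g. \(0.972/\ln 58 = 0.239\) and \(31.53/50 = 0.631\)); base-2 or
complement-form alternatives fail those checks and were rejected. No
small-sample bias correction is applied, matching the printed arithmetic.
Groups with one isolate are reported `NA` ("not relevant"). Genotype keys
carry the missing-locus token, so two isolates differing only in *which*
cells are missing count as distinct genotypes: missing data inflate
richness (and depress dominance) relative to the complete-data truth. Clone
detection avoids this by excluding incomplete isolates outright; the
spectrum keeps them because dropping half the cohort would bias abundances
much more than key fragmentation does.

Confidence intervals are 95% percentile bootstrap over 100 replicates,
resampling *isolates* (not genotypes) within the group — resampling the
population is also what the temporal analysis does. Because resampling can
merge but never split genotypes, the upper CI bound often coincides with the
observed value in high-evenness groups; this is expected behaviour, not a
bug.

## Clones in space and time

Clones are isolates identical at **all 12 loci**, evaluated on raw
(non-imputed) genotypes. An isolate with any missing locus cannot prove
identity, so it is excluded from multi-member clone groups and kept as a
singleton; this strict rule may slightly under-group relative to a tolerant
matcher, and the excluded count is reported.

Winery persistence lists every (winery, clone) pair observed in two or more
distinct vintages with its interval in years. Vintage — the year the wine
was produced — drives all temporal analyses, not the isolation year: an
isolate taken in 2006 from a 1909 wine witnesses the 1909 population.
Twenty-year vintage bins are anchored so that 1981–2000 and 2001–2020 are
bins. Per-bin group proportions carry percentile bootstrap CIs from
resampling the bin's isolates.

Dispersal distances are great-circle (haversine) kilometres on a sphere of
radius 6371.0088 km (IUGG mean; no ellipsoid — sub-0.5% error is irrelevant
against winery-level coordinate precision). All unordered pairs within a
clone group with known coordinates are measured, deliberately including
same-sample pairs, which drifts the distribution toward zero; the class
bins \[0,1), \[1,100), \[100,750), \[750,1000), \[1000,∞) km are half-open
on the left edge (a pair at exactly 100 km falls in \[100,750)), and the
"local" fraction is the sum below 100 km — the plausible reach of natural
vectors.

## The synthetic cohort generator

The raw genotype matrix behind this kind of study is typically not
deposited, so the generator stands in for it with full ground truth. Its
defaults are the study conditions themselves: five groups with the published
per-group isolate/genotype counts (521/58, 69/50, 229/88, 551/118, 40/26;
the single-isolate Tequila/Bioethanol group is omitted), 12 loci on a 2 bp
repeat unit, ~6% missing cells, per-plate offsets in {−2, 0, +2} bp, a
1921–2020 vintage calendar in which triploid groups only appear from 1990
on, and sampling weights heavily skewed toward Bordeaux wineries.

Where the source material states no value, the following were chosen once as
field-realistic and not revisited: founder genotypes separated by at least
0.6 allele-sharing distance (groups are clearly distinct clusters); derived
genotypes produced by 1 + Poisson(2) rounds of stepwise mutation at per-
allele rate 0.05 (within-group diversity small against between-group
separation); Zipf clone-size exponent 1.1 (largest-clone share matching the
published 2-to-114 skew); cross-country relocation probability 0.05 per
isolate (giving a minority of long-range clone pairs); coordinate jitter of
0.002° around the winery (a few hundred metres of within-estate scatter).
Founders are drawn per locus inside a 15-step allele window so each locus
has its own size region, as real microsatellite panels do.

The generator emulates group structure, clonality, missingness, plate
drift, persistence and dispersal. It does **not** emulate genotyping error,
null alleles, linkage, admixed or recombinant genotypes, or peripheral
isolates that sit between groups — so a clean pass of the recovery suite
shows the pipeline is correct under its stated model, not that real data
are free of those complications.

## Numerical and degenerate-input choices

Plate-offset mode ties resolve toward the smallest difference. All-missing
genotypes cannot be assigned (labeled `"unassigned"` with a warning) and
have undefined ploidy (error). Pairs of genotypes with no shared non-missing
locus are incomparable (error in the pairwise function, `NA` in the matrix
form). PCA requests beyond the matrix rank truncate with a warning; a
zero-variance matrix is an error. Empty distance lists yield an all-zero
class distribution with a warning. Evenness is undefined at \(R = 1\)
(`NA` with a warning). The bootstrap and every other stochastic step take
explicit integer seeds; the pipeline derives stage seeds from one master
seed, and reruns are checksum-identical.

## Problem sizes

The test suite exercises the full default scale (1410 isolates + plate
controls) once, end to end, in well under a minute; unit and property tests
run on tables of 2–200 isolates, the brute-force MST oracle on up to 7
points (all \(\binom{21}{6}\) spanning subsets enumerated), and the
bootstrap-coverage experiment on 100 simulations of 500 isolates. The
`scripts/acceptance.R` report regenerates the full-scale cohort from
scratch on every run.

## Limitations

Nearest-reference assignment presumes the six published groups and cannot
discover new ones; genuinely admixed isolates get a nearest label with a
small margin rather than an "admixed" call. The strict 12-locus clone rule
under-groups isolates with missing data. Spherical distances and winery-
or region-level coordinates bound the precision of the distance classes.
Diversity estimates are plug-in values; with strongly uneven sampling
across groups, comparisons between groups inherit that bias.
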