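---
title: "Curating and interpreting bulk-sample COI metabarcoding data with darktaxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and interpreting bulk-sample COI metabarcoding data with darktaxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darktaxa)
```

## The problem

Large-scale insect monitoring with Malaise traps produces bulk samples with
thousands of specimens that no taxonomic workforce can identify one by one.
DNA metabarcoding of a mitochondrial COI fragment turns each sample into a
table of Operational Taxonomic Units (OTUs, 97%-similarity clusters used as
species proxies) with read counts per sequencing library. `darktaxa` starts
*after* clustering and taxonomic assignment and answers four questions:

1. Which reads are trustworthy? (curation: replicate consensus, contamination
   subtraction, pseudogene screening, name hygiene)
2. Which species-level records are credible? (multi-criteria validation)
3. Was the sequencing and sampling effort adequate? (rarefaction,
   Michaelis–Menten asymptotics, Chao2/iChao2)
4. How many species hide behind the unnamed OTUs, and how many of those are
   "dark taxa"? (OTU-per-species normalisation and the reference-coverage
   partition)

plus an accounting model for the laboratory cost and time of the workflow.

## Curation model and assumptions

Every biological sample is sequenced as two technical replicates, and each
96-library plate carries 12 negative controls. Curation proceeds in a fixed
order:

1. **Replicate consensus** — an OTU's reads are summed across the two
   replicates only if present in both; otherwise the cell is zeroed. A read
   must be seen twice to count, which suppresses sporadic false positives.
2. **Negative subtraction** — for each OTU, the maximum read count observed
   in any negative control is subtracted from every sample (floored at
   zero), treating the worst observed contamination level as the systematic
   background.
3. **Stop-codon screen** — an OTU is kept if at least one forward reading
   frame translates without stop codons under the invertebrate mitochondrial
   code (NCBI table 5; stops TAA and TAG). OTUs with stops in all frames are
   presumed nuclear pseudogene copies (NUMTs). The amplicon's orientation is
   fixed by the primers but its post-trim frame is not, hence the
   any-forward-frame rule; reverse-complement checking is available behind a
   flag and off by default. Codons containing N are treated as non-stop
   (they cannot be called).
4. **Dataset split** — dataset 1: OTUs assigned a species name; dataset 2:
   OTUs assigned to class Insecta.
5. **Name hygiene** — only clean two-token Latin binomials (letters only)
   survive; names with digits, punctuation, "sp."-style placeholders or BIN
   suffixes indicate incomplete reference records. Hyphenated epithets are
   dropped under the strict rule, restorable via `allow_hyphen = TRUE`.
6. **Species merge** — OTUs sharing a species name are summed, and the
   number of contributing OTUs per species is recorded for later
   normalisation.

The order is a convention where the narrative leaves it open (in particular
whether the stop-codon screen precedes or follows subtraction); because the
screen acts on sequences and the subtraction on counts, the two commute at
the level of which OTUs survive with positive reads.

## Species validation

A named species becomes **validated** when at least two of three criteria
hold (`min_criteria = 2`, configurable):

- **expert** — membership in an expert-accepted species list (the package's
  stand-in for human plausibility judgement);
- **checklist** — membership in a national checklist (GBOL/Entomofauna-
  Germanica-like), with synonyms resolved through one shared table;
- **occurrence** — at least one occurrence record (GBIF-like extract) falls
  within the convex hull of the traps where the species was detected,
  buffered by 200 km.

The buffered hull generalises the "records within 200 km of the trap" rule:
with a single detection trap it reduces to a geodesic disc, with two traps
to a stadium. Geometry is computed on a local azimuthal-equidistant plane
centred on the detection traps' centroid; at a 200-km scale over a
country-sized extent the projection error is far below the 0.5-km tolerance
band the test oracles allow. The 200-km default accommodates patchy public
occurrence records and the mobility of flying insects.

`agreement_matrix()` reports pairwise percent agreement between criteria, a
useful diagnostic of whether public databases alone could replace expert
screening.

## Effort sufficiency and richness

**Read-based rarefaction** subsamples reads without replacement (exact
multivariate hypergeometric; one shared permutation per iteration yields all
depths at once) in increments of 0.1% of the total, 50 iterations per depth.
A Michaelis–Menten curve \(R(d) = R_{max} d/(K+d)\) is fitted to the mean
curve by unweighted least squares (`nls`, port algorithm; start values
\(R_{max,0} = 1.05\,\max R\), \(K_0\) = effort at half \(R_{max,0}\)).
The relative gain from doubling the achieved depth \(D\) has the closed form
\(K/(K+2D)\); depth is deemed sufficient when the gain is below 5% (strict
inequality, so the boundary case counts as insufficient). Fitting to the
mean curve rather than per-iteration points is a convention; with 50
iterations per level the difference is negligible.

**Sample-based rarefaction** draws random subsets of sampling units in
increments of 5 and tracks observed richness plus the iChao2 estimate. With
\(Q_k\) the number of species found in exactly \(k\) of \(T\) units:

\[ \widehat{S}_{Chao2} = S_{obs} + \frac{T-1}{T}\frac{Q_1^2}{2Q_2}, \qquad
   \widehat{S}_{iChao2} = \widehat{S}_{Chao2} + \frac{T-3}{4T}\frac{Q_3}{Q_4}
   \max\!\Big(Q_1 - \frac{T-3}{2(T-1)}\frac{Q_2Q_3}{Q_4},\,0\Big). \]

Corner cases follow the estimator literature's standard corrections: the
bias-corrected Chao2 form when \(Q_2 = 0\), \(Q_4 \to 1\) when \(Q_4 = 0\),
and plain Chao2 for subsets of fewer than four units; both corrections are
exposed as arguments.

## Plausible species and dark taxa

Unnamed OTU counts per order (or family) are divided by the mean number of
OTUs per *validated* species of the same taxon, rounding half to even, which
corrects the over-splitting caused by pseudogenes and intraspecific
divergence. Taxa whose ratio is grossly inflated by pseudogenes —
Orthoptera by default — are excluded. The choice to normalise *unnamed*
OTUs (rather than all OTUs followed by subtracting validated species) is
deliberate: plausible species are defined as those not yet carrying a name;
the alternative differs whenever named species have ratio > 1 and remains
available by composing the exported primitives. Taxa without validated
species fall back to the global mean ratio and are flagged.

The partition uses regional reference coverage: `known - barcoded` species
form the capacity of the "missing reference barcode" explanation; plausible
species beyond that capacity are potential dark taxa. Taxa absent from the
reference table get capacity 0 — conservative about missing-reference
claims. Order-level and family-level estimates are both computed and both
reported; they legitimately differ because the strata differ.

## Cost model

Per-step material costs, labour costs and times are authoritative inputs
(vendor list prices and measured robot runtimes), not re-derived from
rate × time: published per-step figures are generally not exact rate × time
reconstructions. Aggregation happens on integer cents, so totals are exact.
Placeholder cells ("—", "<0.01") contribute zero to sums, matching how such
tables total their columns; as a consequence a summed per-sample material
column can differ from a printed total by a cent. Durations parse from
`H:MM:SS` or `H:MM` and round-trip through `format_duration()`.

## The synthetic stated world

`community_spec()` defaults describe a deliberately desk-scale analogue of a
nationwide monitoring design, chosen once and not revisited:

- 6 orders × 60 species; OTU inflation `1 + Poisson(0.3)` per species
  (mean 1.3, inside the 1.0–1.5 range typical of 97% COI clustering), with
  10% of the *extra* OTUs being pseudogenes;
- 8 traps × 10 samples split over two years; duplicate libraries; 12
  negatives per 96-library plate; occupancy 0.15 per species and sample;
- lognormal read abundances (meanlog 5, sdlog 1.2 — median ≈ 150 reads,
  heavy-tailed as in bulk samples); Poisson(0.5) contamination reads per OTU
  and negative; replicate dropout 5%;
- 50% reference coverage (half the species assignable), 90% checklist and
  95% expert coverage among named species; Poisson(3) occurrence records per
  named species, placed uniformly within 100 km of an occupied trap so the
  200-km criterion passes for truly present species by construction.

Sequences are 205-base fragments assembled from sense codons of the
invertebrate mitochondrial code; pseudogene OTUs receive a 12-base window
containing stop codons in all three forward frames, so the screen removes
them deterministically (a single in-frame stop would leave a predictable
fraction surviving through a coincidentally stop-free shifted frame, making
the rate-zero contracts flaky). What the generator does *not* emulate —
sequence evolution, PCR/sequencing error, tag switching, abundance
correlations between species — bounds what a green test establishes: the
pipeline's arithmetic and decision rules, not robustness to upstream
artefacts.

With these defaults, validated + plausible species recover the true species
total to within a few percent; the acceptance suite requires |error| < 10%
over 20 seeded replicates.

## Numerical choices and limitations

- Counts are integer throughout curation; subtraction floors at zero.
- Geodesy is spherical (radius 6371.0088 km); test oracles use independent
  haversine/great-circle routes with a 0.5-km boundary exclusion band.
- `nls` failures surface as errors carrying the start values rather than
  silently returning a flat curve.
- Species detected but zeroed out by filtering are skipped by the occurrence
  criterion with a warning.
- The package does not model coverage-based standardisation, Hill numbers,
  extrapolation variance, BIN-based accounting, or live database queries;
  local files stand in for GBIF/GBOL extracts.
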